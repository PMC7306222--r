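#' Canonicalize an outline
#'
#' Puts an outline into the deterministic form the rest of the pipeline
#' assumes: consecutive duplicate points merged, counterclockwise
#' orientation (signed area > 0 in y-up coordinates), and the start vertex
#' rotated to the vertex of minimal y (ties broken by minimal x). Elliptic
#' Fourier normalization later removes any residual start-point dependence;
#' the canonical start simply makes results reproducible across digitizers.
#'
#' @param x an [outline].
#' @return a canonical [outline]; idempotent.
#' @export
canonicalize <- function(x) {
  p <- unclass(x)
  # merge consecutive duplicates (incl. wrap-around)
  d <- rbind(diff(p), p[1L, , drop = FALSE] - p[nrow(p), , drop = FALSE])
  keep <- rowSums(abs(d)) > 0
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 3L) stop("degenerate outline: fewer than 3 distinct points")
  a <- outline_signed_area(outline(p, min_points = 3L))
  if (a == 0) stop("degenerate outline: zero signed area")
  if (a < 0) p <- p[nrow(p):1L, , drop = FALSE]
  i0 <- order(p[, 2L], p[, 1L])[1L]
  if (i0 > 1L) p <- p[c(i0:nrow(p), 1L:(i0 - 1L)), , drop = FALSE]
  outline(p, min_points = 3L)
}

#' Resample an outline at equal arc-length spacing
#'
#' Places `n_points` vertices at equal arc-length intervals along the closed
#' curve (linear interpolation along edges). Required before comparing
#' elliptic Fourier descriptors of differently digitized outlines; preserves
#' the perimeter to well within 0.5% for reasonably dense inputs.
#'
#' @param x an [outline].
#' @param n_points number of output vertices, at least 8.
#' @return an [outline] with `n_points` vertices, starting at the original
#'   start vertex.
#' @export
resample_outline <- function(x, n_points) {
  if (n_points < 8L) stop("n_points must be at least 8")
  p <- unclass(x)
  pc <- rbind(p, p[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pc)^2))
  tt <- c(0, cumsum(seg))
  total <- tt[length(tt)]
  if (total <= 0) stop("zero-perimeter outline")
  s <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  xs <- stats::approx(tt, pc[, 1L], xout = s, method = "linear", ties = "ordered")$y
  ys <- stats::approx(tt, pc[, 2L], xout = s, method = "linear", ties = "ordered")$y
  outline(cbind(xs, ys), min_points = 3L)
}

#' Mirror an outline across the vertical axis through its centroid
#'
#' Left-sided appendages are mirrored before analysis so that all hooks face
#' the same way. Reflection alone reverses the trace direction, so the
#' vertex order is reversed again (keeping the start vertex first) to
#' preserve orientation. `mirror_outline(mirror_outline(x))` returns `x`
#' exactly.
#'
#' @param x an [outline].
#' @return the mirrored [outline].
#' @seealso [mirror_efd()] for the equivalent transform on coefficients.
#' @export
mirror_outline <- function(x) {
  p <- unclass(x)
  cx <- outline_centroid(x)[1L]
  p[, 1L] <- 2 * cx - p[, 1L]
  n <- nrow(p)
  p <- p[c(1L, n:2L), , drop = FALSE]
  outline(p, min_points = 3L)
}

#' Smooth an outline by closed-curve neighbor averaging
#'
#' Each iteration replaces every vertex by the (1/4, 1/2, 1/4) average of
#' its neighborhood on the closed curve, attenuating high-frequency detail
#' such as digitization jitter or residual setae. Zero iterations is the
#' identity; the reproduction pipeline defaults to no smoothing because the
#' source drawings were cleaned manually.
#'
#' @param x an [outline].
#' @param iterations non-negative integer.
#' @return the smoothed [outline].
#' @export
smooth_outline <- function(x, iterations = 1L) {
  if (iterations < 0) stop("iterations must be non-negative")
  p <- unclass(x)
  n <- nrow(p)
  for (k in seq_len(iterations)) {
    prev <- p[c(n, 1:(n - 1L)), , drop = FALSE]
    nxt <- p[c(2:n, 1L), , drop = FALSE]
    p <- 0.25 * prev + 0.5 * p + 0.25 * nxt
  }
  outline(p, min_points = 3L)
}

#' Cap specification for closing a hook base
#'
#' The proximal articulation of a dactylus is concave in most published
#' drawings, which destabilizes outline analysis; the remedy is to close
#' the base with a rounded convex cap. `cap_kind = "semicircle"` uses a
#' semicircular cap on the base chord; `cap_kind = "arc"` uses a circular
#' arc whose sagitta is `arc_bulge` times the base chord, so
#' `arc_bulge = 0.5` reproduces the semicircle.
#'
#' @param cap_kind `"semicircle"` (default) or `"arc"`.
#' @param arc_bulge sagitta as a fraction of the base chord, in (0, 1];
#'   ignored for `"semicircle"` (which corresponds to `arc_bulge = 0.5`).
#' @param n_cap_points number of interior vertices on the cap arc; odd
#'   counts place a vertex exactly at the cap apex.
#' @return a `base_spec` list.
#' @export
base_spec <- function(cap_kind = c("semicircle", "arc"), arc_bulge = 1,
                      n_cap_points = 25L) {
  cap_kind <- match.arg(cap_kind)
  if (!(arc_bulge > 0 && arc_bulge <= 1)) stop("arc_bulge must be in (0, 1]")
  structure(list(cap_kind = cap_kind, arc_bulge = arc_bulge,
                 n_cap_points = as.integer(n_cap_points)),
            class = "base_spec")
}

# circular arc from p to q with given sagitta, bulging in direction bulge_dir
# (unit normal to the chord); returns interior points only (excludes p, q)
arc_points <- function(p, q, sagitta, bulge_dir, n) {
  chord <- sqrt(sum((q - p)^2))
  if (chord == 0) stop("cap endpoints coincide")
  h <- sagitta
  r <- (h^2 + (chord / 2)^2) / (2 * h)   # circle radius from sagitta + half-chord
  m <- (p + q) / 2
  center <- m + (h - r) * bulge_dir
  a1 <- atan2(p[2L] - center[2L], p[1L] - center[1L])
  a2 <- atan2(q[2L] - center[2L], q[1L] - center[1L])
  am <- atan2(m[2L] + h * bulge_dir[2L] - center[2L],
              m[1L] + h * bulge_dir[1L] - center[1L])
  # sweep from a1 to a2 passing through the apex angle am
  sweep <- (a2 - a1) %% (2 * pi)
  mid <- (am - a1) %% (2 * pi)
  if (mid > sweep) sweep <- sweep - 2 * pi   # go the other way around
  ang <- a1 + sweep * seq_len(n) / (n + 1L)
  cbind(center[1L] + r * cos(ang), center[2L] + r * sin(ang))
}

#' Close an open curve with a convex proximal cap
#'
#' Takes an open vertex sequence whose two endpoints are the proximal
#' articulation points of the dactylus and closes it with a convex circular
#' arc bulging away from the curve's interior, yielding a closed, simple
#' outline suitable for elliptic Fourier analysis.
#'
#' @param open_curve numeric matrix of ordered points; first and last rows
#'   are the base articulation points.
#' @param spec a [base_spec()].
#' @return a closed [outline] (orientation as traced; not canonicalized).
#' @export
cap_base <- function(open_curve, spec = base_spec()) {
  p <- as.matrix(open_curve)
  storage.mode(p) <- "double"
  if (nrow(p) < 3L) stop("open curve needs at least 3 points")
  a <- p[nrow(p), ]   # cap runs from the curve's end back to its start
  b <- p[1L, ]
  chord <- sqrt(sum((b - a)^2))
  nrm <- c(-(b[2L] - a[2L]), b[1L] - a[1L]) / chord
  # interior side: centroid of the chord-closed polygon
  ctr <- outline_centroid(outline(p, min_points = 3L))
  m <- (a + b) / 2
  side <- sign(sum((ctr - m) * nrm))
  if (side == 0) side <- 1
  bulge_dir <- -side * nrm
  bulge <- if (spec$cap_kind == "semicircle") 0.5 else spec$arc_bulge
  sag <- bulge * chord
  cap <- arc_points(a, b, sag, bulge_dir, spec$n_cap_points)
  out <- outline(rbind(p, cap), min_points = 3L)
  if (!is_simple(out)) {
    stop("capped outline self-intersects; try a smaller arc_bulge")
  }
  out
}
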