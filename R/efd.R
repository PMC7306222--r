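#' Elliptic Fourier descriptors of a closed outline
#'
#' Computes the closed-form elliptic Fourier coefficients of a closed
#' polygonal outline parameterized by arc length (the Kuhl-Giardina
#' formulation). The x and y coordinates along the curve are each expanded
#' as a truncated Fourier series
#' \deqn{x(t) = A_0 + \sum_{n=1}^{N} a_n \cos\frac{2\pi n t}{T} + b_n \sin\frac{2\pi n t}{T}}
#' and likewise \eqn{y(t)} with offset \eqn{C_0} and coefficients
#' \eqn{c_n, d_n}, where \eqn{T} is the perimeter. For a piecewise-linear
#' curve the integrals have an exact closed form, used here; no numerical
#' quadrature is involved.
#'
#' @param x an [outline] (canonical orientation recommended; see
#'   [canonicalize()]).
#' @param n_harmonics number of harmonics N, at least 1.
#' @return an object of class `efd`: list with `A0`, `C0`, `coef`
#'   (N x 4 matrix with columns `a`, `b`, `c`, `d`), `n_harmonics`, and the
#'   source perimeter `T`.
#' @references Kuhl, F.P. & Giardina, C.R. (1982) Elliptic Fourier features
#'   of a closed contour. Computer Graphics and Image Processing 18:236-258.
#' @export
compute_efd <- function(x, n_harmonics = 20L) {
  if (n_harmonics < 1L) stop("n_harmonics must be at least 1")
  p <- unclass(x)
  d <- edge_vectors(p)
  # shift so segment i runs from vertex i to i+1; deltas relative to start
  dx <- d[, 1L]; dy <- d[, 2L]
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) stop("outline has zero-length edges; canonicalize first")
  tt <- cumsum(dt)
  T <- tt[length(tt)]
  if (T <= 0) stop("zero-perimeter outline")
  t0 <- c(0, tt[-length(tt)])
  n <- seq_len(n_harmonics)
  w <- 2 * pi * outer(tt, n) / T      # K x N matrix of phases at segment ends
  w0 <- 2 * pi * outer(t0, n) / T
  const <- T / (2 * pi^2 * n^2)
  dcos <- cos(w) - cos(w0)
  dsin <- sin(w) - sin(w0)
  a <- const * colSums((dx / dt) * dcos)
  b <- const * colSums((dx / dt) * dsin)
  cc <- const * colSums((dy / dt) * dcos)
  dd <- const * colSums((dy / dt) * dsin)
  # arc-length average of the piecewise-linear coordinates (exact trapezoid)
  pnext <- p[c(2:nrow(p), 1L), , drop = FALSE]
  A0 <- sum(dt * (p[, 1L] + pnext[, 1L]) / 2) / T
  C0 <- sum(dt * (p[, 2L] + pnext[, 2L]) / 2) / T
  structure(list(A0 = A0, C0 = C0,
                 coef = cbind(a = a, b = b, c = cc, d = dd),
                 n_harmonics = as.integer(n_harmonics), T = T),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("<%s> %d harmonics, A0=%.4g, C0=%.4g\n",
              paste(class(x), collapse = "/"), x$n_harmonics, x$A0, x$C0))
  print(utils::head(x$coef, 3L))
  if (x$n_harmonics > 3L) cat("...\n")
  invisible(x)
}

# rotate the parameter (start point) by angle theta: per-harmonic right
# multiplication by the 2x2 rotation of n*theta
rotate_start <- function(coef, theta) {
  n <- seq_len(nrow(coef))
  cn <- cos(n * theta); sn <- sin(n * theta)
  cbind(a = coef[, 1L] * cn + coef[, 2L] * sn,
        b = -coef[, 1L] * sn + coef[, 2L] * cn,
        c = coef[, 3L] * cn + coef[, 4L] * sn,
        d = -coef[, 3L] * sn + coef[, 4L] * cn)
}

# rotate the shape in space by -psi: left multiplication by rotation matrix
rotate_space <- function(coef, psi) {
  cp <- cos(psi); sp <- sin(psi)
  cbind(a = cp * coef[, 1L] + sp * coef[, 3L],
        b = cp * coef[, 2L] + sp * coef[, 4L],
        c = -sp * coef[, 1L] + cp * coef[, 3L],
        d = -sp * coef[, 2L] + cp * coef[, 4L])
}

#' Normalize elliptic Fourier descriptors for size, rotation and start point
#'
#' Standardizes coefficients on the first-harmonic ellipse: the start point
#' is re-phased to the ellipse's semi-major axis, the shape is rotated so
#' that axis lies along x, and all coefficients are divided by the
#' semi-major axis length. After normalization `a1 = 1`, `b1 = c1 = 0`, and
#' `d1` is the signed first-harmonic aspect ratio (positive for
#' counterclockwise outlines; see [canonicalize()]). The residual 180-degree
#' ambiguity of the major axis is resolved deterministically by requiring
#' `a1 > 0` before rescaling.
#'
#' @param efd an `efd` object from [compute_efd()].
#' @return an object of class `c("normalized_efd", "efd")` with `A0 = C0 = 0`
#'   and normalization metadata: `scale` (the removed semi-major axis length
#'   lambda), `rotation` (psi, radians), `start_shift` (theta, radians).
#' @export
normalize_efd <- function(efd) {
  coef <- efd$coef
  a1 <- coef[1L, 1L]; b1 <- coef[1L, 2L]; c1 <- coef[1L, 3L]; d1 <- coef[1L, 4L]
  if (max(abs(c(a1, b1, c1, d1))) == 0) stop("degenerate first harmonic")
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  co <- rotate_start(coef, theta)
  psi <- atan2(co[1L, 3L], co[1L, 1L])
  co <- rotate_space(co, psi)
  # the half-angle formula may phase the start onto the minor axis; if so,
  # advance the start a quarter period and re-align the major axis with x
  if (abs(co[1L, 1L]) < abs(co[1L, 4L])) {
    co <- rotate_start(co, pi / 2)
    theta <- theta + pi / 2
    psi2 <- atan2(co[1L, 3L], co[1L, 1L])
    co <- rotate_space(co, psi2)
    psi <- psi + psi2
  }
  # residual 180-degree start ambiguity (theta vs theta + pi) flips the sign
  # of every even harmonic; resolve by requiring the first discriminating
  # even-harmonic coefficient, in the fixed order d2, c2, b2, a2, d4, c4,
  # ..., to be positive. A fixed order keeps the canonical form continuous
  # across shape families as long as the leading discriminant stays away
  # from zero; for centrally symmetric shapes all even harmonics vanish and
  # the ambiguity is immaterial.
  if (nrow(co) >= 2L) {
    even <- seq(2L, nrow(co), by = 2L)
    disc <- as.vector(t(co[even, 4:1, drop = FALSE]))   # d2 c2 b2 a2 d4 ...
    nz <- which(abs(disc) > 1e-9)
    if (length(nz) && disc[nz[1L]] < 0) {
      sgn <- (-1)^(seq_len(nrow(co)) + 1L)   # start + pi, then space + pi
      co <- co * sgn
      theta <- theta + pi
      psi <- psi + pi
    }
  }
  lambda <- co[1L, 1L]
  if (lambda <= 0) stop("degenerate first harmonic: non-positive semi-major axis")
  co <- co / lambda
  out <- efd
  out$A0 <- 0
  out$C0 <- 0
  out$coef <- co
  out$scale <- unname(lambda)
  out$rotation <- unname(psi)
  out$start_shift <- unname(theta)
  class(out) <- c("normalized_efd", "efd")
  validate_normalized_efd(out)
  out
}

validate_normalized_efd <- function(x, tol = 1e-9) {
  co <- x$coef
  if (abs(co[1L, 1L] - 1) > tol || abs(co[1L, 2L]) > tol || abs(co[1L, 3L]) > tol) {
    stop("normalized EFD invariants violated (a1 != 1 or b1/c1 != 0)")
  }
  invisible(x)
}

#' Construct a normalized EFD object from a coefficient matrix
#'
#' Used by the `.nef` reader and the eigen-shape machinery; checks the
#' normalization invariants (`a1 = 1`, `b1 = c1 = 0` within `tol`) unless
#' `check = FALSE`.
#'
#' @param coef N x 4 numeric matrix with columns a, b, c, d.
#' @param check verify normalization invariants (default TRUE).
#' @param tol invariant tolerance.
#' @return a `normalized_efd` object.
#' @export
as_normalized_efd <- function(coef, check = TRUE, tol = 1e-6) {
  coef <- as.matrix(coef)
  storage.mode(coef) <- "double"
  if (ncol(coef) != 4L) stop("coefficient matrix must have 4 columns")
  colnames(coef) <- c("a", "b", "c", "d")
  out <- structure(list(A0 = 0, C0 = 0, coef = coef,
                        n_harmonics = nrow(coef), T = NA_real_,
                        scale = NA_real_, rotation = NA_real_,
                        start_shift = NA_real_),
                   class = c("normalized_efd", "efd"))
  if (check) validate_normalized_efd(out, tol = tol)
  out
}

#' Mirror elliptic Fourier descriptors
#'
#' Coefficient-space equivalent of reflecting the outline across a vertical
#' axis while keeping the counterclockwise trace direction:
#' \eqn{(a_n, b_n, c_n, d_n) \to (-a_n, b_n, c_n, -d_n)}, followed by
#' re-normalization for normalized input. An involution.
#'
#' @param efd an `efd` or `normalized_efd`.
#' @return object of the same class, mirrored.
#' @export
mirror_efd <- function(efd) {
  out <- efd
  out$coef[, c(1L, 4L)] <- -out$coef[, c(1L, 4L)]
  out$A0 <- -out$A0
  if (inherits(efd, "normalized_efd")) {
    class(out) <- "efd"
    out <- normalize_efd(out)
  }
  out
}

#' Reconstruct an outline from elliptic Fourier descriptors
#'
#' Truncated Fourier synthesis at `n_points` equally spaced parameter
#' values. As the harmonic count grows the reconstruction converges to the
#' source outline.
#'
#' @param efd an `efd` or `normalized_efd`.
#' @param n_points number of output vertices, at least 16.
#' @param n_harmonics optionally synthesize with fewer harmonics than stored.
#' @return an [outline].
#' @export
reconstruct_outline <- function(efd, n_points = 256L, n_harmonics = NULL) {
  if (n_points < 16L) stop("n_points must be at least 16")
  N <- if (is.null(n_harmonics)) efd$n_harmonics else min(n_harmonics, efd$n_harmonics)
  t <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  n <- seq_len(N)
  ph <- 2 * pi * outer(t, n)
  C <- cos(ph); S <- sin(ph)
  xs <- efd$A0 + C %*% efd$coef[n, 1L] + S %*% efd$coef[n, 2L]
  ys <- efd$C0 + C %*% efd$coef[n, 3L] + S %*% efd$coef[n, 4L]
  outline(cbind(xs, ys), min_points = 3L)
}

#' Per-harmonic power and cumulative power fraction
#'
#' Harmonic power \eqn{(a_n^2 + b_n^2 + c_n^2 + d_n^2)/2} is the standard
#' criterion for choosing a harmonic truncation: report the smallest N whose
#' cumulative fraction exceeds a threshold such as 0.9999.
#'
#' @param efd an `efd`.
#' @return data frame with columns `harmonic`, `power`, `cumulative_fraction`.
#' @export
harmonic_power <- function(efd) {
  pw <- rowSums(efd$coef^2) / 2
  data.frame(harmonic = seq_along(pw), power = pw,
             cumulative_fraction = cumsum(pw) / sum(pw))
}

#' Coefficients in long format
#'
#' @param efd an `efd`.
#' @param name record identifier to attach.
#' @return data frame with columns `name`, `harmonic`, `a`, `b`, `c`, `d`.
#' @export
efd_to_long <- function(efd, name = "shape") {
  data.frame(name = name, harmonic = seq_len(efd$n_harmonics),
             a = efd$coef[, 1L], b = efd$coef[, 2L],
             c = efd$coef[, 3L], d = efd$coef[, 4L],
             row.names = NULL)
}
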