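#' Closed outline of a 2-D shape
#'
#' An `outline` is an ordered closed polygon of 2-D points in y-up
#' mathematical coordinates, the digital form of a redrawn dactylus
#' silhouette. The edge from the last point back to the first is implicit;
#' the last vertex must not repeat the first.
#'
#' @param points numeric matrix (or two-column data frame) with columns x, y;
#'   at least 8 rows for a valid shape outline (3 are tolerated for internal
#'   geometric helpers via `min_points`).
#' @param min_points minimum vertex count accepted (default 8).
#' @return an object of class `outline`: a numeric matrix with columns
#'   `x`, `y`.
#' @examples
#' sq <- outline(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), min_points = 3)
#' outline_area(sq)
#' @export
outline <- function(points, min_points = 8L) {
  pts <- as.matrix(points)
  if (is.data.frame(points)) pts <- as.matrix(points[, 1:2])
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L) stop("outline points must have two columns (x, y)")
  if (any(!is.finite(pts))) stop("outline points must be finite")
  if (nrow(pts) < min_points) {
    stop(sprintf("outline needs at least %d points, got %d", min_points, nrow(pts)))
  }
  # drop an explicit closing vertex
  n <- nrow(pts)
  if (n > 1L && all(pts[1L, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  d <- rbind(diff(pts), pts[1L, ] - pts[nrow(pts), ])
  if (any(rowSums(abs(d)) == 0)) stop("outline has consecutive duplicate points")
  colnames(pts) <- c("x", "y")
  structure(pts, class = c("outline", "matrix"))
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf(
    "<outline> %d vertices, perimeter %.4g, signed area %.4g (%s)\n",
    nrow(x), outline_perimeter(x), outline_signed_area(x),
    if (is_ccw(x)) "counterclockwise" else "clockwise"
  ))
  invisible(x)
}

edge_vectors <- function(pts) {
  rbind(diff(pts), pts[1L, , drop = FALSE] - pts[nrow(pts), , drop = FALSE])
}

#' Signed area (shoelace), positive for counterclockwise outlines
#' @param x an [outline] or coordinate matrix.
#' @return signed area in coordinate units squared.
#' @export
outline_signed_area <- function(x) {
  p <- unclass(x)
  xs <- p[, 1L]; ys <- p[, 2L]
  xn <- c(xs[-1L], xs[1L]); yn <- c(ys[-1L], ys[1L])
  sum(xs * yn - xn * ys) / 2
}

#' Absolute enclosed area
#' @inheritParams outline_signed_area
#' @export
outline_area <- function(x) abs(outline_signed_area(x))

#' Perimeter (closed arc length)
#' @inheritParams outline_signed_area
#' @export
outline_perimeter <- function(x) {
  sum(sqrt(rowSums(edge_vectors(unclass(x))^2)))
}

#' Area centroid of the polygon
#' @inheritParams outline_signed_area
#' @return length-2 numeric (x, y).
#' @export
outline_centroid <- function(x) {
  p <- unclass(x)
  xs <- p[, 1L]; ys <- p[, 2L]
  xn <- c(xs[-1L], xs[1L]); yn <- c(ys[-1L], ys[1L])
  cr <- xs * yn - xn * ys
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(abs(p)) * nrow(p)) {
    return(colMeans(p))
  }
  c(sum((xs + xn) * cr), sum((ys + yn) * cr)) / (6 * a)
}

#' Is the outline traced counterclockwise (y-up convention)?
#' @inheritParams outline_signed_area
#' @export
is_ccw <- function(x) outline_signed_area(x) > 0

#' Check that an outline is simple (no self-intersections)
#'
#' Segment-intersection scan over all non-adjacent edge pairs; O(n^2), meant
#' for validation of fixtures and generated shapes, not bulk data.
#'
#' @inheritParams outline_signed_area
#' @return logical.
#' @export
is_simple <- function(x) {
  p <- unclass(x)
  n <- nrow(p)
  a1 <- p
  a2 <- p[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (share a vertex), incl. the wrap pair (1, n)
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    d1 <- cross2(a1[i, 1L], a1[i, 2L], a2[i, 1L], a2[i, 2L], a1[js, 1L], a1[js, 2L])
    d2 <- cross2(a1[i, 1L], a1[i, 2L], a2[i, 1L], a2[i, 2L], a2[js, 1L], a2[js, 2L])
    d3 <- cross2(a1[js, 1L], a1[js, 2L], a2[js, 1L], a2[js, 2L],
                 rep(a1[i, 1L], length(js)), rep(a1[i, 2L], length(js)))
    d4 <- cross2(a1[js, 1L], a1[js, 2L], a2[js, 1L], a2[js, 2L],
                 rep(a2[i, 1L], length(js)), rep(a2[i, 2L], length(js)))
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
    # collinear overlap: treat exact touching of non-adjacent edges as non-simple
    touch <- (d1 == 0 & d2 == 0)
    if (any(touch)) {
      for (j in js[touch]) {
        r1 <- range(a1[i, 1L], a2[i, 1L]); r2 <- range(a1[j, 1L], a2[j, 1L])
        s1 <- range(a1[i, 2L], a2[i, 2L]); s2 <- range(a1[j, 2L], a2[j, 2L])
        if (r1[1L] <= r2[2L] && r2[1L] <= r1[2L] && s1[1L] <= s2[2L] && s2[1L] <= s1[2L]) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}
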