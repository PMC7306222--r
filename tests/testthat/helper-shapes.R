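# Shape constructors and independent oracles shared across the suite.

make_circle <- function(n = 256L, r = 1, center = c(0, 0), start_frac = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n + 2 * pi * start_frac
  outline(cbind(center[1L] + r * cos(th), center[2L] + r * sin(th)),
          min_points = 3L)
}

make_ellipse <- function(n = 512L, a = 2, b = 1, angle = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  p <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  outline(p %*% t(R), min_points = 3L)
}

unit_square <- function() {
  outline(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), min_points = 3L)
}

# random simple (star-shaped) polygon around the origin
random_star_polygon <- function(n = 24L, r_range = c(0.5, 1.5)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  # enforce distinct angles so no zero-length edges
  th <- th + seq_len(n) * 1e-9
  r <- stats::runif(n, r_range[1L], r_range[2L])
  outline(cbind(r * cos(th), r * sin(th)), min_points = 3L)
}

# rigid transform + start-point shift of an outline
transform_outline <- function(o, angle = 0, scale = 1, shift = c(0, 0),
                              start = 0L) {
  p <- unclass(o)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  p <- scale * p %*% t(R)
  p <- sweep(p, 2L, -shift)
  n <- nrow(p)
  start <- start %% n
  if (start > 0L) p <- p[c((start + 1L):n, 1L:start), , drop = FALSE]
  outline(p, min_points = 3L)
}

# Independent oracle: elliptic Fourier coefficients by dense trapezoidal
# quadrature of the arc-length Fourier integrals. Samples include every
# vertex so the integrand is smooth on each subinterval.
efd_quadrature <- function(o, n_harmonics, samples_per_edge = NULL) {
  p <- unclass(o)
  pc <- rbind(p, p[1L, , drop = FALSE])
  K <- nrow(p)
  m <- if (is.null(samples_per_edge)) max(10L, ceiling(3e5 / K)) else samples_per_edge
  ts <- xs <- ys <- vector("list", K)
  t_off <- 0
  for (i in seq_len(K)) {
    u <- seq(0, 1, length.out = m + 1L)
    seg <- pc[i + 1L, ] - pc[i, ]
    len <- sqrt(sum(seg^2))
    ts[[i]] <- t_off + u * len
    xs[[i]] <- pc[i, 1L] + u * seg[1L]
    ys[[i]] <- pc[i, 2L] + u * seg[2L]
    t_off <- t_off + len
  }
  drop_last <- function(l) lapply(seq_along(l), function(i) {
    if (i < length(l)) l[[i]][-length(l[[i]])] else l[[i]]
  })
  t <- unlist(drop_last(ts)); x <- unlist(drop_last(xs)); y <- unlist(drop_last(ys))
  T <- t[length(t)]
  trapz <- function(f) sum(diff(t) * (f[-length(f)] + f[-1L]) / 2)
  coef <- matrix(0, n_harmonics, 4L,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    cn <- cos(2 * pi * n * t / T); sn <- sin(2 * pi * n * t / T)
    coef[n, ] <- (2 / T) * c(trapz(x * cn), trapz(x * sn),
                             trapz(y * cn), trapz(y * sn))
  }
  list(A0 = trapz(x) / T, C0 = trapz(y) / T, coef = coef, T = T)
}

# Independent oracle: convex hull area by brute force. A point is a hull
# vertex iff it is not strictly inside any triangle of three other points;
# hull vertices are then ordered by angle about their centroid.
brute_force_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3L) return(0)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
    s2 <- (c[1L] - b[1L]) * (p[2L] - b[2L]) - (c[2L] - b[2L]) * (p[1L] - b[1L])
    s3 <- (a[1L] - c[1L]) * (p[2L] - c[2L]) - (a[2L] - c[2L]) * (p[1L] - c[1L])
    (s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0)
  }
  keep <- rep(TRUE, n)
  tri <- utils::combn(n, 3L)
  for (k in seq_len(ncol(tri))) {
    a <- pts[tri[1L, k], ]; b <- pts[tri[2L, k], ]; c <- pts[tri[3L, k], ]
    for (i in seq_len(n)) {
      if (keep[i] && !(i %in% tri[, k]) && in_triangle(pts[i, ], a, b, c)) {
        keep[i] <- FALSE
      }
    }
  }
  hv <- pts[keep, , drop = FALSE]
  ctr <- colMeans(hv)
  ord <- order(atan2(hv[, 2L] - ctr[2L], hv[, 1L] - ctr[1L]))
  hv <- hv[ord, , drop = FALSE]
  xs <- hv[, 1L]; ys <- hv[, 2L]
  abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys) / 2)
}

max_coef_diff <- function(e1, e2) max(abs(e1$coef - e2$coef))
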