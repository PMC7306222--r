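#' Assemble the normalized-coefficient matrix for PCA
#'
#' Builds the specimens x coefficients matrix fed to the morphospace PCA.
#' Columns are ordered `a2..aN, b2..bN, c2..cN, d1..dN`; the constants
#' `a1`, `b1`, `c1` (fixed by normalization) are excluded, giving
#' `4N - 3` columns. Records carrying more harmonics than `n_harmonics`
#' are truncated.
#'
#' @param efds named list of `normalized_efd` objects (names are specimen
#'   ids, must be unique).
#' @param n_harmonics harmonic count N used for the matrix.
#' @return numeric matrix with specimen row names and coefficient column
#'   names (`a2`, ..., `dN`).
#' @export
assemble_coefficient_matrix <- function(efds, n_harmonics = 20L) {
  nm <- names(efds)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("efds must be a uniquely named list of specimen records")
  }
  N <- as.integer(n_harmonics)
  short <- nm[vapply(efds, function(e) e$n_harmonics < N, logical(1L))]
  if (length(short)) {
    stop("records with fewer than ", N, " harmonics: ",
         paste(short, collapse = ", "))
  }
  cols <- c(paste0("a", 2:N), paste0("b", 2:N), paste0("c", 2:N),
            paste0("d", 1:N))
  mat <- t(vapply(efds, function(e) {
    co <- e$coef[seq_len(N), , drop = FALSE]
    c(co[2:N, 1L], co[2:N, 2L], co[2:N, 3L], co[1:N, 4L])
  }, numeric(4L * N - 3L)))
  dimnames(mat) <- list(nm, cols)
  mat
}

#' Principal component analysis of the coefficient matrix
#'
#' Covariance PCA (centered, unscaled) of the normalized elliptic Fourier
#' coefficients: the eigenvectors of the column covariance matrix define
#' the morphospace axes. Coefficients are already commensurate after
#' normalization, so no rescaling to correlations is applied. Loading signs
#' are fixed so each component's largest-magnitude loading is positive,
#' making scores reproducible across eigen-solvers.
#'
#' @param mat specimens x coefficients matrix from
#'   [assemble_coefficient_matrix()] (>= 3 rows, >= 2 columns).
#' @return a `morphospace` object: list with `eigenvalues` (non-increasing),
#'   `variance_fraction`, `scores` (specimen x PC), `loadings`
#'   (coefficient x PC), `mean_vector`, `n`.
#' @export
run_pca <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("PCA needs at least 3 specimens")
  if (ncol(mat) < 2L) stop("PCA needs at least 2 coefficient columns")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- pc$x
  load <- pc$rotation
  # deterministic sign: largest-|loading| entry of each PC made positive
  for (j in seq_len(ncol(load))) {
    piv <- load[which.max(abs(load[, j])), j]
    if (piv < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total <- sum(ev)
  vf <- if (total > 0) ev / total else rep(0, length(ev))
  structure(list(eigenvalues = ev, variance_fraction = vf,
                 scores = scores, loadings = load,
                 mean_vector = colMeans(mat), n = nrow(mat)),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat(sprintf("<morphospace> %d specimens, %d components\n",
              x$n, length(x$eigenvalues)))
  cat("variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Variance-explained table
#'
#' @param ms a `morphospace`.
#' @param k number of components to report (default all).
#' @return data frame with `component`, `eigenvalue`, `percent`,
#'   `cumulative_percent`.
#' @export
variance_table <- function(ms, k = length(ms$eigenvalues)) {
  k <- min(k, length(ms$eigenvalues))
  data.frame(component = paste0("PC", seq_len(k)),
             eigenvalue = ms$eigenvalues[seq_len(k)],
             percent = 100 * ms$variance_fraction[seq_len(k)],
             cumulative_percent = 100 * cumsum(ms$variance_fraction)[seq_len(k)])
}

#' Reconstruct the outline at a position along a principal component
#'
#' Builds the coefficient vector `mean + k_sd * sqrt(eigenvalue) * loading`,
#' re-inserts the normalization constants (`a1 = 1`, `b1 = c1 = 0`) and
#' synthesizes the outline. With `k_sd = 0` this is the mean shape. Sweeping
#' `k_sd` along PC1 or PC2 makes the axes inspectable — here, degree of hook
#' curvature and relative thickness respectively.
#'
#' @param ms a `morphospace` fitted on a matrix from
#'   [assemble_coefficient_matrix()].
#' @param component PC index (1-based).
#' @param k_sd position in standard deviations along the component,
#'   `|k_sd| <= 5`.
#' @param n_points vertices in the reconstructed outline.
#' @return an [outline].
#' @export
eigen_shape <- function(ms, component = 1L, k_sd = 0, n_points = 256L) {
  if (abs(k_sd) > 5) stop("|k_sd| must be at most 5")
  if (component < 1L || component > ncol(ms$loadings)) {
    stop("component out of range")
  }
  vec <- ms$mean_vector +
    k_sd * sqrt(ms$eigenvalues[component]) * ms$loadings[, component]
  efd <- coefficient_vector_to_efd(vec)
  reconstruct_outline(efd, n_points = n_points)
}

# inverse of the assemble_coefficient_matrix row layout
coefficient_vector_to_efd <- function(vec) {
  p <- length(vec)
  if ((p + 3L) %% 4L != 0L) stop("coefficient vector length must be 4N - 3")
  N <- (p + 3L) %/% 4L
  co <- matrix(0, N, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  co[1L, ] <- c(1, 0, 0, 0)
  co[2:N, 1L] <- vec[seq_len(N - 1L)]
  co[2:N, 2L] <- vec[N:(2L * N - 2L)]
  co[2:N, 3L] <- vec[(2L * N - 1L):(3L * N - 3L)]
  co[1:N, 4L] <- vec[(3L * N - 2L):(4L * N - 3L)]
  as_normalized_efd(co, check = FALSE)
}

#' Convex-hull occupation of groups in a PC plane
#'
#' Quantifies per-group morphospace occupation as the convex-hull area of
#' the group's scores in the chosen PC plane; groups with fewer than three
#' members or collinear members get area zero.
#'
#' @param ms a `morphospace`.
#' @param groups factor or character vector, one label per specimen (score
#'   row), or a data frame of label columns which are pasted together.
#' @param pc_pair length-2 integer, which components span the plane.
#' @return list of `group_summary` entries: `group`, `n`, `hull_area`,
#'   `hull_vertices` (counterclockwise coordinate matrix).
#' @export
group_hulls <- function(ms, groups, pc_pair = c(1L, 2L)) {
  sc <- ms$scores[, pc_pair, drop = FALSE]
  if (is.data.frame(groups)) {
    groups <- do.call(paste, c(groups, sep = "/"))
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(sc)) stop("one group label per specimen required")
  lapply(split(seq_along(groups), groups), function(idx) {
    pts <- sc[idx, , drop = FALSE]
    hull <- convex_hull(pts)
    structure(list(group = groups[idx[1L]], n = length(idx),
                   hull_area = polygon_area(hull), hull_vertices = hull),
              class = "group_summary")
  })
}

# counterclockwise convex hull of a point matrix (grDevices::chull is
# clockwise in standard orientation; reorder to CCW by signed area)
convex_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) < 3L) return(pts)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) >= 3L && polygon_signed_area(hull) < 0) {
    hull <- hull[nrow(hull):1L, , drop = FALSE]
  }
  hull
}

polygon_signed_area <- function(p) {
  if (nrow(p) < 3L) return(0)
  xs <- p[, 1L]; ys <- p[, 2L]
  xn <- c(xs[-1L], xs[1L]); yn <- c(ys[-1L], ys[1L])
  sum(xs * yn - xn * ys) / 2
}

polygon_area <- function(p) abs(polygon_signed_area(p))

#' Intersection area of two convex hulls
#'
#' Sutherland-Hodgman clipping of one convex polygon by the half-planes of
#' the other; the result is the area of the convex intersection, symmetric
#' in its arguments and bounded by the smaller hull area.
#'
#' @param a,b `group_summary` objects from [group_hulls()], or coordinate
#'   matrices of convex polygon vertices.
#' @return intersection area (>= 0).
#' @export
hull_overlap <- function(a, b) {
  pa <- if (inherits(a, "group_summary")) a$hull_vertices else as.matrix(a)
  pb <- if (inherits(b, "group_summary")) b$hull_vertices else as.matrix(b)
  if (nrow(pa) < 3L || nrow(pb) < 3L) return(0)
  if (polygon_signed_area(pa) < 0) pa <- pa[nrow(pa):1L, , drop = FALSE]
  if (polygon_signed_area(pb) < 0) pb <- pb[nrow(pb):1L, , drop = FALSE]
  clipped <- pa
  nb <- nrow(pb)
  for (i in seq_len(nb)) {
    if (nrow(clipped) < 3L) return(0)
    e1 <- pb[i, ]
    e2 <- pb[(i %% nb) + 1L, ]
    clipped <- clip_halfplane(clipped, e1, e2)
  }
  if (nrow(clipped) < 3L) return(0)
  polygon_area(clipped)
}

# keep the part of convex polygon `poly` on the left of edge e1 -> e2
clip_halfplane <- function(poly, e1, e2) {
  n <- nrow(poly)
  out <- matrix(numeric(0), 0L, 2L)
  side <- function(p) (e2[1L] - e1[1L]) * (p[2L] - e1[2L]) -
    (e2[2L] - e1[2L]) * (p[1L] - e1[1L])
  for (i in seq_len(n)) {
    cur <- poly[i, ]
    nxt <- poly[(i %% n) + 1L, ]
    sc <- side(cur); sn <- side(nxt)
    if (sc >= 0) out <- rbind(out, cur)
    if ((sc > 0 && sn < 0) || (sc < 0 && sn > 0)) {
      t <- sc / (sc - sn)
      out <- rbind(out, cur + t * (nxt - cur))
    }
  }
  out
}

#' Ontogenetic shape-change vectors in a PC plane
#'
#' For every species x appendage cell with both stages present, computes the
#' displacement `adult score - immature score` in the chosen PC plane, its
#' magnitude and its angle. The dispersion summary reports the mean
#' magnitude and the circular concentration \eqn{\bar R} (length of the mean
#' unit vector, in \[0, 1\]): \eqn{\bar R} near 1 means all species change
#' in the same morphospace direction through ontogeny, \eqn{\bar R} near 0
#' means there is no shared trajectory.
#'
#' @param ms a `morphospace`.
#' @param metadata data frame aligned with the score rows (columns
#'   `specimen_id`, `species`, `stage`, `appendage`); `specimen_id` must
#'   match the score row names.
#' @param pc_pair length-2 integer.
#' @return list with `vectors` (data frame: species, appendage, dx, dy,
#'   magnitude, angle) and `summary` (mean_magnitude, r_bar, n_pairs).
#'   Unpaired cells are skipped with a warning.
#' @export
ontogenetic_vectors <- function(ms, metadata, pc_pair = c(1L, 2L)) {
  md <- validate_specimen_metadata(metadata)
  sc <- ms$scores[, pc_pair, drop = FALSE]
  if (is.null(rownames(sc)) || !all(md$specimen_id %in% rownames(sc))) {
    stop("metadata specimen_id values must match score row names")
  }
  cells <- split(md, paste(md$species, md$appendage, sep = "|"))
  rows <- list()
  skipped <- character(0)
  for (cell in cells) {
    ad <- cell$specimen_id[cell$stage == "adult"]
    im <- cell$specimen_id[cell$stage == "immature"]
    if (length(ad) != 1L || length(im) != 1L) {
      skipped <- c(skipped, paste(cell$species[1L], cell$appendage[1L]))
      next
    }
    d <- sc[ad, ] - sc[im, ]
    rows[[length(rows) + 1L]] <- data.frame(
      species = cell$species[1L], appendage = cell$appendage[1L],
      dx = d[1L], dy = d[2L],
      magnitude = sqrt(sum(d^2)), angle = atan2(d[2L], d[1L]))
  }
  if (length(skipped)) {
    warning("skipping unpaired species/appendage cell(s): ",
            paste(skipped, collapse = "; "))
  }
  if (!length(rows)) stop("no paired species/appendage cells")
  vec <- do.call(rbind, rows)
  rownames(vec) <- NULL
  units <- cbind(cos(vec$angle), sin(vec$angle))
  r_bar <- sqrt(sum(colMeans(units)^2))
  list(vectors = vec,
       summary = list(mean_magnitude = mean(vec$magnitude),
                      r_bar = r_bar, n_pairs = nrow(vec)))
}
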