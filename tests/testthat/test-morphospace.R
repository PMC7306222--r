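test_that("the coefficient matrix has the documented layout", {
  efds <- study_efds()
  mat <- assemble_coefficient_matrix(efds, 20L)
  expect_equal(dim(mat), c(60L, 77L))   # 4 * 20 - 3
  expect_false(any(c("a1", "b1", "c1") %in% colnames(mat)))
  expect_true(all(c("a2", "b2", "c2", "d1", "d20") %in% colnames(mat)))
  expect_identical(rownames(mat), names(efds))
  short <- c(efds[1:3], list(short = as_normalized_efd(
    cbind(c(1, 0), 0, 0, c(0.3, 0.1)))))
  expect_error(assemble_coefficient_matrix(short, 20L), "short")
})

test_that("PCA satisfies its algebraic invariants", {
  ms <- run_pca(assemble_coefficient_matrix(study_efds(), 20L))
  expect_equal(sum(ms$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(ms$eigenvalues) <= 1e-12))
  expect_true(all(ms$eigenvalues >= -1e-12))
  expect_lt(max(abs(colMeans(ms$scores))), 1e-9)
  # reconstruction: scores %*% t(loadings) + mean == data
  mat <- assemble_coefficient_matrix(study_efds(), 20L)
  rec <- ms$scores %*% t(ms$loadings) + rep(1, nrow(mat)) %o% ms$mean_vector
  expect_lt(max(abs(rec - mat)), 1e-8)
  # deterministic sign: largest loading of each PC positive
  for (j in 1:5) {
    expect_gt(ms$loadings[which.max(abs(ms$loadings[, j])), j], 0)
  }
})

test_that("degenerate and constructed PCA cases behave as expected", {
  one <- normalize_efd(compute_efd(generate_hook(hook_params()), 10L))
  copies <- stats::setNames(rep(list(one), 10L), paste0("s", 1:10))
  ms <- run_pca(assemble_coefficient_matrix(copies, 10L))
  expect_lt(max(ms$eigenvalues), 1e-20)

  # two tight clusters along a real shape direction: PC1 separates them
  mk <- function(kappa, tag, seeds) {
    efds <- lapply(seeds, function(s) {
      normalize_efd(compute_efd(generate_hook(
        hook_params(kappa = kappa + 0.01 * (s %% 3), tau = 0.25,
                    noise_sd = 0.002, seed = s)), 10L))
    })
    stats::setNames(efds, paste0(tag, seeds))
  }
  efds <- c(mk(1.0, "lo", 1:8), mk(2.0, "hi", 11:18))
  ms2 <- run_pca(assemble_coefficient_matrix(efds, 10L))
  expect_gt(ms2$variance_fraction[1L], 0.9)
  lo <- ms2$scores[1:8, 1L]; hi <- ms2$scores[9:16, 1L]
  expect_true(max(lo) < min(hi) || max(hi) < min(lo))
})

test_that("eigenvalues are invariant under rigid rotation of the columns", {
  mat <- assemble_coefficient_matrix(study_efds(), 10L)
  set.seed(4)
  q <- qr.Q(qr(matrix(stats::rnorm(ncol(mat)^2), ncol(mat))))
  ms1 <- run_pca(mat)
  ms2 <- run_pca(mat %*% q)
  expect_lt(max(abs(ms1$eigenvalues - ms2$eigenvalues)), 1e-9)
})

test_that("eigen-shapes are the mean at k_sd = 0 and vary in curvature along PC1", {
  # curvature-only family so PC1 is the curvature axis
  kappas <- seq(0.9, 2.1, length.out = 15L)
  efds <- stats::setNames(lapply(kappas, function(k) {
    normalize_efd(compute_efd(generate_hook(hook_params(kappa = k)), 15L))
  }), sprintf("k%02d", 1:15))
  ms <- run_pca(assemble_coefficient_matrix(efds, 15L))
  m0 <- eigen_shape(ms, 1L, 0)
  m0b <- eigen_shape(ms, 2L, 0)
  expect_lt(max(abs(unclass(m0) - unclass(m0b))), 1e-12)
  ks <- vapply(c(-2, 0, 2), function(k_sd) {
    o <- eigen_shape(ms, 1L, k_sd)
    expect_true(is_simple(o))
    estimate_curvature_thickness(o)$kappa_hat * outline_perimeter(o)
  }, numeric(1L))
  expect_true(all(diff(ks) > 0) || all(diff(ks) < 0))
  expect_error(eigen_shape(ms, 99L, 1), "out of range")
  expect_error(eigen_shape(ms, 1L, 7), "k_sd")
})

test_that("group hulls match analytic and brute-force areas", {
  fake <- list(scores = cbind(PC1 = c(0, 1, 2, 0, 1, 0.5),
                              PC2 = c(0, 1, 2, 1, 0, 0.5)))
  class(fake) <- "morphospace"
  hulls <- group_hulls(fake, c("line", "line", "line", "sq", "sq", "sq"))
  expect_equal(hulls$line$hull_area, 0)
  sq <- list(scores = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  class(sq) <- "morphospace"
  expect_equal(group_hulls(sq, rep("g", 4L))$g$hull_area, 1)

  set.seed(9)
  for (i in 1:5) {
    pts <- matrix(stats::rnorm(100L), 50L)
    fk <- list(scores = pts); class(fk) <- "morphospace"
    h <- group_hulls(fk, rep("g", 50L))$g
    expect_equal(h$hull_area, brute_force_hull_area(pts), tolerance = 1e-9)
    expect_true(all(diff(sign(rep(1, nrow(h$hull_vertices)))) == 0))
  }
})

test_that("hull area never decreases when points are added", {
  set.seed(21)
  pts <- matrix(stats::rnorm(60L), 30L)
  areas <- vapply(5:30, function(k) {
    fk <- list(scores = pts[1:k, , drop = FALSE]); class(fk) <- "morphospace"
    group_hulls(fk, rep("g", k))$g$hull_area
  }, numeric(1L))
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("hull overlap is symmetric, bounded and exact on rectangles", {
  sq1 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sq2 <- sq1; sq2[, 1L] <- sq2[, 1L] + 0.5
  far <- sq1; far[, 1L] <- far[, 1L] + 5
  expect_equal(hull_overlap(sq1, sq1), 1)
  expect_equal(hull_overlap(sq1, sq2), 0.5, tolerance = 1e-12)
  expect_equal(hull_overlap(sq2, sq1), 0.5, tolerance = 1e-12)
  expect_equal(hull_overlap(sq1, far), 0)
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(stats::rnorm(20L), 10L)
    b <- matrix(stats::rnorm(20L, 0.5), 10L)
    fka <- list(scores = a); class(fka) <- "morphospace"
    fkb <- list(scores = b); class(fkb) <- "morphospace"
    ha <- group_hulls(fka, rep("a", 10L))$a
    hb <- group_hulls(fkb, rep("b", 10L))$b
    ov <- hull_overlap(ha, hb)
    expect_gte(ov, 0)
    expect_lte(ov, min(ha$hull_area, hb$hull_area) + 1e-12)
    expect_equal(ov, hull_overlap(hb, ha), tolerance = 1e-12)
  }
})

test_that("ontogenetic vectors measure trajectory concentration", {
  md <- data.frame(
    specimen_id = c("s1i", "s1a", "s2i", "s2a", "s3i", "s3a"),
    species = rep(c("sp1", "sp2", "sp3"), each = 2L),
    stage = rep(c("immature", "adult"), 3L),
    site = "gill", appendage = "P1")
  # identical displacements -> r_bar = 1
  sc <- rbind(c(0, 0), c(1, 1), c(2, 0), c(3, 1), c(0, 2), c(1, 3))
  rownames(sc) <- md$specimen_id
  fk <- list(scores = sc); class(fk) <- "morphospace"
  ov <- ontogenetic_vectors(fk, md)
  expect_equal(ov$summary$r_bar, 1, tolerance = 1e-12)
  expect_equal(ov$summary$n_pairs, 3L)
  expect_equal(ov$vectors$magnitude, rep(sqrt(2), 3L))

  # displacements at 0, 120, 240 degrees -> r_bar = 0
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  sc2 <- matrix(0, 6L, 2L, dimnames = list(md$specimen_id, NULL))
  sc2[c(2L, 4L, 6L), ] <- cbind(cos(ang), sin(ang))
  fk2 <- list(scores = sc2); class(fk2) <- "morphospace"
  expect_lt(ontogenetic_vectors(fk2, md)$summary$r_bar, 1e-12)

  # unpaired species are skipped with a warning, not an error
  md3 <- rbind(md, data.frame(specimen_id = "s4i", species = "sp4",
                              stage = "immature", site = "gill",
                              appendage = "P1"))
  sc3 <- rbind(sc, s4i = c(5, 5))
  fk3 <- list(scores = sc3); class(fk3) <- "morphospace"
  expect_warning(ov3 <- ontogenetic_vectors(fk3, md3), "sp4")
  expect_equal(ov3$summary$n_pairs, 3L)
})

test_that("a thickness-only stage effect displaces along the thickness axis", {
  ds <- generate_dataset(design_spec(
    site_effects = list(mouth = c(0, 0), gill = c(0, 0), external = c(0, 0)),
    stage_effects = list(immature = c(0, 0), adult = c(0, 0.07)),
    species_sd = c(0.25, 0.005), noise_sd = 0.003, seed = 31L))
  prep <- run_efd_pipeline(ds$outlines)
  res <- run_morphospace_pipeline(prep$efds, ds$metadata)
  # thickness-loading direction in the PC plane: the direction along which
  # scores track the generating tau (regression of scores on tau)
  m <- merge(data.frame(specimen_id = rownames(res$pca$scores),
                        pc1 = res$pca$scores[, 1L],
                        pc2 = res$pca$scores[, 2L]),
             ds$true_params, by = "specimen_id")
  fit <- stats::lm(cbind(pc1, pc2) ~ tau, data = m)
  u <- stats::coef(fit)["tau", ]
  u <- u / sqrt(sum(u^2))
  ov <- ontogenetic_vectors(res$pca, ds$metadata)
  disp <- colMeans(cbind(ov$vectors$dx, ov$vectors$dy))
  cosang <- abs(sum(disp * u)) / sqrt(sum(disp^2))
  expect_gt(cosang, 0.9)
})
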