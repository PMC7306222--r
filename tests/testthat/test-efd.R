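test_that("a circle is a pure first harmonic", {
  e <- compute_efd(make_circle(256L), 2L)
  expect_equal(unname(e$coef[1L, "a"]), 1, tolerance = 1e-3)
  expect_equal(unname(e$coef[1L, "d"]), 1, tolerance = 1e-3)
  expect_lt(abs(e$coef[1L, "b"]), 1e-3)
  expect_lt(abs(e$coef[1L, "c"]), 1e-3)
  expect_lt(max(abs(e$coef[2L, ])), 1e-3)
  expect_lt(abs(e$A0), 1e-9)
  expect_lt(abs(e$C0), 1e-9)
  hp <- harmonic_power(compute_efd(make_circle(256L), 10L))
  expect_gt(hp$cumulative_fraction[1L], 0.999)
})

test_that("ellipse coefficients match the arc-length quadrature oracle", {
  ell <- make_ellipse(n = 1024L)
  e <- compute_efd(ell, 4L)
  # frozen oracle values for the arc-length parameterized 2:1 ellipse
  # (dense trapezoidal quadrature of the Fourier integrals)
  expect_equal(unname(e$coef[1L, "a"]), 1.82841186, tolerance = 1e-4)
  expect_equal(unname(e$coef[1L, "d"]), 1.07301718, tolerance = 1e-4)
  expect_lt(abs(e$coef[1L, "b"]), 1e-6)
  expect_lt(abs(e$coef[1L, "c"]), 1e-6)
  ne <- normalize_efd(e)
  expect_equal(unname(ne$coef[1L, "d"]), 0.58685748, tolerance = 1e-4)
})

test_that("closed-form coefficients equal dense numerical quadrature", {
  sq <- unit_square()
  e <- compute_efd(sq, 10L)
  q <- efd_quadrature(sq, 10L)
  expect_lt(max(abs(e$coef - q$coef)), 1e-6)
  expect_lt(abs(e$A0 - q$A0), 1e-8)
  expect_lt(abs(e$C0 - q$C0), 1e-8)

  set.seed(3)
  for (i in 1:5) {
    p <- random_star_polygon(14L)
    e <- compute_efd(p, 6L)
    q <- efd_quadrature(p, 6L)
    expect_lt(max(abs(e$coef - q$coef)), 1e-6)
  }
})

test_that("coefficients are invariant to collinear vertex insertion and translation", {
  sq <- unit_square()
  dense <- resample_outline(sq, 64L)   # inserts collinear vertices
  e1 <- compute_efd(sq, 8L)
  e2 <- compute_efd(dense, 8L)
  expect_lt(max(abs(e1$coef - e2$coef)), 1e-9)
  e3 <- compute_efd(transform_outline(sq, shift = c(13.2, -4.1)), 8L)
  expect_lt(max(abs(e1$coef - e3$coef)), 1e-12)
  expect_equal(e3$A0 - e1$A0, 13.2, tolerance = 1e-12)
})

test_that("normalization removes rotation, scale, translation and start point", {
  circ <- make_circle(258L)
  n0 <- normalize_efd(compute_efd(circ, 6L))
  n1 <- normalize_efd(compute_efd(
    transform_outline(circ, angle = 37 * pi / 180, start = 86L), 6L))
  expect_lt(max_coef_diff(n0, n1), 1e-6)

  ell0 <- make_ellipse(n = 600L)
  ell30 <- make_ellipse(n = 600L, angle = 30 * pi / 180)
  ne <- normalize_efd(compute_efd(ell30, 6L))
  expect_equal(ne$coef[1L, ], c(a = 1, b = 0, c = 0, d = 0.58685748),
               tolerance = 1e-4)
  expect_lt(max_coef_diff(ne, normalize_efd(compute_efd(ell0, 6L))), 1e-6)

  h <- generate_hook(hook_params(kappa = 1.5, tau = 0.25))
  nh <- normalize_efd(compute_efd(h, 20L))
  nsc <- normalize_efd(compute_efd(transform_outline(h, scale = 3.7), 20L))
  expect_lt(max_coef_diff(nh, nsc), 1e-9)
  expect_equal(nsc$scale / nh$scale, 3.7, tolerance = 1e-9)
  expect_gt(nh$coef[1L, "d"], 0)   # counterclockwise trace convention
})

test_that("degenerate first harmonics are rejected", {
  e <- compute_efd(unit_square(), 4L)
  e$coef[1L, ] <- 0
  expect_error(normalize_efd(e), "degenerate")
})

test_that("reconstruction converges to the source outline", {
  circ <- make_circle(256L)
  rec <- reconstruct_outline(compute_efd(circ, 1L), 256L)
  rad <- sqrt(rowSums(unclass(rec)^2))
  expect_lt(mean(abs(rad - 1)), 1e-3)

  h <- resample_outline(generate_hook(hook_params(kappa = 1.9, tau = 0.3)), 512L)
  e <- compute_efd(h, 20L)
  dev_at <- function(N) {
    r <- unclass(reconstruct_outline(e, 512L, n_harmonics = N))
    mean(sqrt(rowSums((r - unclass(h))^2)))
  }
  expect_lt(dev_at(20L), dev_at(5L))
})

test_that("synthesis and analysis are mutually consistent", {
  # smooth shape with negligible truncation residual: round trip to 1e-4
  th <- 2 * pi * (0:799) / 800
  r <- 1 + 0.15 * sin(2 * th) + 0.08 * cos(3 * th)
  blob <- outline(cbind(r * cos(th), r * sin(th)), min_points = 3L)
  e <- compute_efd(blob, 12L)
  rt <- compute_efd(reconstruct_outline(e, 2048L), 12L)
  expect_lt(max(abs(rt$coef - e$coef)), 1e-4)
  expect_lt(abs(rt$A0 - e$A0), 1e-4)
  # sharper shapes: the round-trip discrepancy is the arc-length
  # reparameterization error of the truncated curve, shrinking with N
  h <- resample_outline(generate_hook(hook_params(kappa = 1.3, tau = 0.2)), 512L)
  errs <- vapply(c(12L, 20L, 30L), function(N) {
    e <- compute_efd(h, N)
    max(abs(compute_efd(reconstruct_outline(e, 2048L), N)$coef - e$coef))
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3L], 2e-3)
})

test_that("harmonic power is normalized, stable and start-shift invariant", {
  h <- generate_hook(hook_params())
  e <- compute_efd(h, 30L)
  hp <- harmonic_power(e)
  expect_true(all(diff(hp$cumulative_fraction) >= -1e-15))
  expect_equal(hp$cumulative_fraction[30L], 1, tolerance = 1e-12)
  n_star <- function(o) {
    hp <- harmonic_power(compute_efd(o, 30L))
    which(hp$cumulative_fraction >= 0.9999)[1L]
  }
  expect_lte(abs(n_star(resample_outline(h, 256L)) -
                   n_star(resample_outline(h, 512L))), 1L)
  # Parseval-style: total power invariant under start-point shift
  p1 <- sum(harmonic_power(compute_efd(h, 30L))$power)
  p2 <- sum(harmonic_power(compute_efd(
    transform_outline(h, start = 100L), 30L))$power)
  expect_lt(abs(p1 - p2) / p1, 1e-9)
})

test_that("coefficient long format and nef export agree", {
  h <- sample_hooks(1L)[[1L]]
  ne <- normalize_efd(compute_efd(h, 10L))
  long <- efd_to_long(ne, "h")
  expect_equal(nrow(long), 10L)
  expect_equal(long$a[1L], 1)
  expect_equal(as.matrix(long[, c("a", "b", "c", "d")]), ne$coef,
               ignore_attr = TRUE)
})
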