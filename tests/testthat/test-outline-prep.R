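test_that("canonicalize fixes orientation and start and is idempotent", {
  cw <- outline(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)), min_points = 3L)
  expect_lt(outline_signed_area(cw), 0)
  can <- canonicalize(cw)
  expect_equal(outline_signed_area(can), 1)
  expect_equal(unclass(can)[1L, ], c(x = 0, y = 0))
  expect_identical(unclass(canonicalize(can)), unclass(can))

  set.seed(11)
  for (i in 1:100) {
    p <- random_star_polygon(16L)
    p <- transform_outline(p, angle = stats::runif(1, 0, 2 * pi),
                           start = sample.int(16L, 1L))
    c1 <- canonicalize(p)
    expect_identical(unclass(canonicalize(c1)), unclass(c1))
    expect_true(is_ccw(c1))
  }
})

test_that("degenerate outlines are rejected", {
  expect_error(canonicalize(outline(cbind(0:3, rep(0, 4)), min_points = 3L)),
               "degenerate")
})

test_that("equal-arc-length resampling spaces vertices evenly and keeps the perimeter", {
  circ <- make_circle(1024L)
  r <- resample_outline(circ, 64L)
  d <- sqrt(rowSums((unclass(r)[c(2:64, 1L), ] - unclass(r))^2))
  expect_lt(diff(range(d)) / mean(d), 1e-6)
  expect_lt(abs(outline_perimeter(r) - outline_perimeter(circ)) /
              outline_perimeter(circ), 0.005)
  expect_error(resample_outline(circ, 7L), "at least 8")

  h <- generate_hook(hook_params())
  expect_lt(abs(outline_perimeter(resample_outline(h, 256L)) -
                  outline_perimeter(h)) / outline_perimeter(h), 0.005)
})

test_that("EFDs are stable across resampling resolutions", {
  h <- generate_hook(hook_params(kappa = 1.8, tau = 0.28))
  e256 <- normalize_efd(compute_efd(resample_outline(h, 256L), 20L))
  e512 <- normalize_efd(compute_efd(resample_outline(h, 512L), 20L))
  expect_lt(max(abs(e256$coef - e512$coef)), 1e-3)
})

test_that("mirroring is an involution and commutes with the coefficient transform", {
  h <- generate_hook(hook_params(kappa = 1.4, tau = 0.3))
  expect_lt(max(abs(unclass(mirror_outline(mirror_outline(h))) - unclass(h))),
            1e-9)
  # mirror of a symmetric shape has identical normalized EFDs
  ell <- make_ellipse()
  ne <- normalize_efd(compute_efd(ell, 10L))
  nm <- normalize_efd(compute_efd(canonicalize(mirror_outline(ell)), 10L))
  expect_lt(max_coef_diff(ne, nm), 1e-6)
  # commutation: normalize(mirror(outline)) == mirror_efd(normalize(outline))
  n_out <- normalize_efd(compute_efd(canonicalize(mirror_outline(h)), 20L))
  n_coef <- mirror_efd(normalize_efd(compute_efd(canonicalize(h), 20L)))
  expect_lt(max_coef_diff(n_out, n_coef), 1e-6)
  # involution in coefficient space
  ne_h <- normalize_efd(compute_efd(canonicalize(h), 20L))
  expect_lt(max_coef_diff(mirror_efd(mirror_efd(ne_h)), ne_h), 1e-9)
})

test_that("smoothing is identity at zero iterations and clips corners", {
  sq <- unit_square()
  expect_identical(unclass(smooth_outline(sq, 0L)), unclass(sq))
  s1 <- smooth_outline(resample_outline(sq, 64L), 1L)
  expect_lt(outline_area(s1), 1)
  expect_true(is_simple(s1))
})

test_that("smoothing attenuates high-frequency harmonic power", {
  h <- resample_outline(generate_hook(hook_params()), 128L)
  p <- unclass(h)
  ctr <- outline_centroid(h)
  dir <- sweep(p, 2L, ctr)
  dir <- dir / sqrt(rowSums(dir^2))
  spikes <- 0.02 * sin(2 * pi * 28 * seq_len(nrow(p)) / nrow(p))
  spiky <- outline(p + dir * spikes, min_points = 3L)
  hp_before <- harmonic_power(compute_efd(canonicalize(spiky), 30L))
  sm <- smooth_outline(spiky, 5L)
  hp_after <- harmonic_power(compute_efd(canonicalize(sm), 30L))
  high <- function(hp) sum(hp$power[hp$harmonic > 15L])
  expect_lt(high(hp_after), 0.1 * high(hp_before))
})

test_that("prep operations preserve closure and simplicity on the hook family", {
  for (h in sample_hooks(5L)) {
    expect_true(is_simple(h))
    expect_true(is_simple(canonicalize(h)))
    expect_true(is_simple(resample_outline(h, 128L)))
    expect_true(is_simple(mirror_outline(h)))
    expect_true(is_simple(smooth_outline(h, 2L)))
  }
})

test_that("capping a half circle completes the circle", {
  th <- seq(0, pi, length.out = 128L)
  half <- cbind(cos(th), sin(th))
  full <- cap_base(half, base_spec("semicircle"))
  expect_true(is_simple(full))
  ne <- normalize_efd(compute_efd(resample_outline(canonicalize(full), 256L), 10L))
  hp <- harmonic_power(ne)
  expect_lt(1 - hp$cumulative_fraction[1L], 1e-3)
})

test_that("cap sagitta follows the bulge specification on a straight chord", {
  # open curve: three sides of a rectangle, base chord from (0,0) to (1,0)
  curve <- cbind(c(0, 0, 0.25, 0.5, 0.75, 1, 1), c(0, 1, 1, 1, 1, 1, 0))
  capped <- cap_base(curve, base_spec("arc", arc_bulge = 0.5))
  p <- unclass(capped)
  # sagitta: how far below y=0 the cap reaches = 0.5 * chord
  expect_equal(min(p[, 2L]), -0.5, tolerance = 1e-9)
  shallow <- cap_base(curve, base_spec("arc", arc_bulge = 0.2))
  expect_equal(min(unclass(shallow)[, 2L]), -0.2, tolerance = 1e-9)
})

test_that("the cap is strictly convex", {
  h_open <- {
    th <- seq(0.2, pi - 0.2, length.out = 60L)
    cbind(cos(th), sin(th))
  }
  capped <- cap_base(h_open, base_spec("semicircle", n_cap_points = 16L))
  p <- unclass(capped)
  cap_idx <- (nrow(p) - 16L):nrow(p)
  cap <- p[cap_idx, ]
  e <- diff(cap)
  cr <- e[-nrow(e), 1L] * e[-1L, 2L] - e[-nrow(e), 2L] * e[-1L, 1L]
  expect_true(all(cr > 0) || all(cr < 0))
})
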