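#' Parameters of a synthetic hook outline
#'
#' The synthetic hook family is built from a circular-arc centerline of
#' curvature `kappa` and arc length `length`, wrapped in a width profile
#' `w(s) = tau * L * (1 - s/L)^taper + w_min` that tapers toward the tip,
#' joined by a rounded tip and closed proximally with a convex base cap.
#' The two free shape parameters — centerline curvature and relative
#' thickness — correspond to the curvature and thickness axes that dominate
#' real dactylus variation.
#'
#' @param kappa centerline curvature (1 / length units); `kappa * length`
#'   must stay below `2 * pi` so the hook does not self-overlap.
#' @param length centerline arc length L (default 1; sets the length unit).
#' @param tau relative thickness, max width / L, in (0, 0.6).
#' @param taper exponent >= 1 controlling how fast the width decays tipward.
#' @param cap_bulge proximal cap sagitta as a fraction of the base chord,
#'   in (0, 1] (0.5 = semicircle).
#' @param noise_sd radial vertex noise as a fraction of L (Gaussian,
#'   seeded).
#' @param seed RNG seed for the noise, or NULL for no seeding.
#' @return a `hook_params` list.
#' @export
hook_params <- function(kappa = 1.5, length = 1, tau = 0.25, taper = 1.5,
                        cap_bulge = 0.5, noise_sd = 0, seed = NULL) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa * length >= 2 * pi) stop("kappa * length must be below 2*pi")
  if (!(tau > 0 && tau < 0.6)) stop("tau must be in (0, 0.6)")
  if (taper < 1) stop("taper must be at least 1")
  if (noise_sd < 0 || noise_sd > 0.05) stop("noise_sd must be in [0, 0.05]")
  if (!(cap_bulge > 0 && cap_bulge <= 1)) stop("cap_bulge must be in (0, 1]")
  structure(list(kappa = kappa, length = length, tau = tau, taper = taper,
                 cap_bulge = cap_bulge, noise_sd = noise_sd, seed = seed),
            class = "hook_params")
}

#' Generate a synthetic hook outline
#'
#' Deterministic given `params$seed`; the output is canonicalized
#' (counterclockwise, deterministic start vertex) and guaranteed simple.
#'
#' @param params a [hook_params()].
#' @param n_points approximate number of vertices in the result (the
#'   outline is resampled to exactly `n_points` at equal arc length).
#' @return an [outline].
#' @export
generate_hook <- function(params, n_points = 256L) {
  k <- params$kappa
  L <- params$length
  w_min <- 0.02 * L
  m <- 121L
  s <- seq(0, L, length.out = m)
  if (k < 1e-9) {
    cx <- s; cy <- rep(0, m)
    tx <- rep(1, m); ty <- rep(0, m)
  } else {
    cx <- sin(k * s) / k
    cy <- (1 - cos(k * s)) / k
    tx <- cos(k * s); ty <- sin(k * s)
  }
  nx <- -ty; ny <- tx               # left normal
  w <- params$tau * L * (1 - s / L)^params$taper + w_min
  left <- cbind(cx + nx * w / 2, cy + ny * w / 2)
  right <- cbind(cx - nx * w / 2, cy - ny * w / 2)
  # rounded tip: semicircle of radius w(L)/2 from the left side to the right
  rt <- w[m] / 2
  phi <- seq(0, pi, length.out = 13L)[-c(1L, 13L)]
  tip <- cbind(cx[m] + rt * (cos(phi) * nx[m] + sin(phi) * tx[m]),
               cy[m] + rt * (cos(phi) * ny[m] + sin(phi) * ty[m]))
  open_curve <- rbind(left, tip, right[m:1L, ])
  out <- cap_base(open_curve, base_spec(cap_kind = "arc",
                                        arc_bulge = params$cap_bulge))
  out <- canonicalize(out)
  out <- resample_outline(out, n_points)
  if (params$noise_sd > 0) {
    p <- unclass(out)
    ctr <- outline_centroid(out)
    dir <- sweep(p, 2L, ctr)
    nrm <- sqrt(rowSums(dir^2))
    dir <- dir / pmax(nrm, 1e-12)
    # low-frequency radial wobble: Gaussian at coarse knots, interpolated
    # periodically, emulating redrawing error without crossing adjacent edges
    nk <- 48L
    knots <- with_seed(params$seed, stats::rnorm(nk, 0, params$noise_sd * L))
    u <- (seq_len(nrow(p)) - 1L) / nrow(p) * nk
    noise <- stats::approx(0:nk, c(knots, knots[1L]), xout = u,
                           ties = "ordered")$y
    p <- p + dir * noise
    out <- canonicalize(outline(p, min_points = 3L))
  }
  if (!is_simple(out)) {
    stop("generated hook outline self-intersects; reduce kappa, tau or noise_sd")
  }
  out
}

# evaluate expr under a temporary RNG state; NULL seed leaves RNG alone
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Estimate centerline curvature and relative thickness of a hook outline
#'
#' Independent shape estimator used as the oracle for PC-axis
#' interpretation: it never sees the generator's parameters. The outline's
#' farthest vertex pair splits it into two side chains; each core point of
#' one side is paired with its nearest point on the other, so the pair
#' midpoints approximate the medial axis and the pair distances the local
#' width. Curvature is taken from a least-squares circle fit to the medial
#' points (tip and base regions trimmed); relative thickness is the maximum
#' width divided by the medial curve length. Estimates are averaged over
#' the outline and its mirror image, making the result exactly invariant
#' under reflection.
#'
#' @param x a hook-like [outline] (single dominant concavity).
#' @return list with `kappa_hat` and `tau_hat` (both finite).
#' @export
estimate_curvature_thickness <- function(x) {
  e1 <- estimate_hook_raw(x)
  e2 <- estimate_hook_raw(mirror_outline(x))
  out <- list(kappa_hat = (e1$kappa_hat + e2$kappa_hat) / 2,
              tau_hat = (e1$tau_hat + e2$tau_hat) / 2)
  if (!is.finite(out$kappa_hat) || !is.finite(out$tau_hat)) {
    stop("non-hook topology: curvature estimate undefined")
  }
  out
}

# signed curvature of the circumcircle through three points (positive for a
# left turn a -> m -> b); zero when collinear
signed_circumcurvature <- function(a, m, b) {
  cr <- (b[1L] - a[1L]) * (m[2L] - a[2L]) - (b[2L] - a[2L]) * (m[1L] - a[1L])
  la <- sqrt(sum((m - b)^2))
  lb <- sqrt(sum((a - b)^2))
  lc <- sqrt(sum((a - m)^2))
  if (la * lb * lc == 0) return(0)
  2 * cr / (la * lb * lc)
}

estimate_hook_raw <- function(x) {
  out <- resample_outline(canonicalize(x), 256L)
  p <- unclass(out)
  n <- nrow(p)
  # farthest pair splits the outline into the two sides (tip vs base end)
  d2 <- as.matrix(stats::dist(p))
  ij <- arrayInd(which.max(d2), dim(d2))
  i <- min(ij); j <- max(ij)
  s1 <- p[i:j, , drop = FALSE]
  s2 <- p[c(j:n, 1:i), , drop = FALSE]
  k <- 200L
  r1 <- resample_open(s1, k)
  r2 <- resample_open(s2[nrow(s2):1L, , drop = FALSE], k)
  # medial points from nearest-point pairing of one side's core against the
  # other side (tip/cap ends excluded); curvature as the mean signed
  # circumcurvature of wide point triples, so the O(taper-slope^2) pairing
  # bias cancels when the two pairing directions are averaged
  one_dir <- function(a, b) {
    lo <- round(0.2 * k); hi <- round(0.8 * k)
    core <- a[lo:hi, , drop = FALSE]
    tgt <- b[round(0.1 * k):round(0.9 * k), , drop = FALSE]
    dd <- outer(core[, 1L], tgt[, 1L], "-")^2 +
      outer(core[, 2L], tgt[, 2L], "-")^2
    nn <- apply(dd, 1L, which.min)
    mid <- (core + tgt[nn, , drop = FALSE]) / 2
    nm <- nrow(mid)
    ks <- c(
      signed_circumcurvature(mid[1L, ], mid[round(nm / 2), ], mid[nm, ]),
      signed_circumcurvature(mid[round(0.1 * nm), ], mid[round(0.5 * nm), ],
                             mid[round(0.9 * nm), ]),
      signed_circumcurvature(mid[round(0.2 * nm), ], mid[round(0.5 * nm), ],
                             mid[round(0.8 * nm), ]))
    list(sk = mean(ks), w = sqrt(dd[cbind(seq_len(nrow(core)), nn)]))
  }
  o1 <- one_dir(r1, r2)
  o2 <- one_dir(r2, r1)
  clen <- sum(sqrt(rowSums(diff((r1 + r2) / 2)^2)))
  if (!is.finite(clen) || clen <= 0) {
    stop("non-hook topology: degenerate medial curve")
  }
  list(kappa_hat = abs((o1$sk + o2$sk) / 2),
       tau_hat = max(c(o1$w, o2$w)) / clen)
}

# resample an open polyline to k points at equal arc length
resample_open <- function(p, k) {
  seg <- sqrt(rowSums(diff(p)^2))
  tt <- c(0, cumsum(seg))
  s <- seq(0, tt[length(tt)], length.out = k)
  cbind(stats::approx(tt, p[, 1L], xout = s, ties = "ordered")$y,
        stats::approx(tt, p[, 2L], xout = s, ties = "ordered")$y)
}

#' Study design for a synthetic hook dataset
#'
#' Mirrors the real sampling design: `n_species_per_site` species per
#' attachment site, each contributing four outlines (two stages x two
#' appendages), so the default yields 3 x 5 x 2 x 2 = 60 outlines. Site and
#' stage act as additive shifts on the mean (kappa, tau); species add a
#' random effect on both parameters, drawn once per species and shared
#' across its four outlines.
#'
#' @param n_species_per_site species per attachment site (default 5).
#' @param base_kappa,base_tau grand means of curvature and relative
#'   thickness.
#' @param site_effects named list of length-2 numeric `(kappa, tau)` shifts,
#'   one per site.
#' @param stage_effects same, per stage.
#' @param appendage_effects same, per appendage (defaults to no shift).
#' @param species_sd length-2 SD of the per-species random effect on
#'   (kappa, tau); default 10% of the base means.
#' @param noise_sd vertex noise forwarded to [hook_params()].
#' @param seed dataset RNG seed.
#' @return a `design_spec` list.
#' @export
design_spec <- function(n_species_per_site = 5L,
                        base_kappa = 1.5, base_tau = 0.25,
                        site_effects = list(mouth = c(0.3, -0.02),
                                            gill = c(0, 0.02),
                                            external = c(-0.3, 0)),
                        stage_effects = list(immature = c(0, 0),
                                             adult = c(0.2, -0.03)),
                        appendage_effects = list(P1 = c(0, 0),
                                                 P6 = c(0, 0)),
                        species_sd = c(0.15, 0.025),
                        noise_sd = 0.005, seed = 1L) {
  stopifnot(n_species_per_site >= 1L,
            all(sort(names(site_effects)) == sort(specimen_levels$site)),
            all(sort(names(stage_effects)) == sort(specimen_levels$stage)),
            all(sort(names(appendage_effects)) == sort(specimen_levels$appendage)))
  structure(list(n_species_per_site = as.integer(n_species_per_site),
                 base_kappa = base_kappa, base_tau = base_tau,
                 site_effects = site_effects, stage_effects = stage_effects,
                 appendage_effects = appendage_effects,
                 species_sd = species_sd, noise_sd = noise_sd, seed = seed),
            class = "design_spec")
}

#' Generate a labeled synthetic hook dataset
#'
#' Fully reproducible from `design$seed`: species random effects are drawn
#' once per species and shared across that species' four outlines, then
#' each cell's (kappa, tau) is the base value plus site, stage and appendage
#' shifts plus the species effect. Out-of-range parameter combinations
#' raise an error naming the offending cell.
#'
#' @param design a [design_spec()].
#' @param n_points vertices per outline.
#' @return list with `metadata` (validated specimen table, one row per
#'   outline), `outlines` (named list of [outline]s), and `true_params`
#'   (data frame of the kappa/tau actually used per specimen).
#' @export
generate_dataset <- function(design = design_spec(), n_points = 256L) {
  sites <- specimen_levels$site
  stages <- specimen_levels$stage
  apps <- specimen_levels$appendage
  nsp <- design$n_species_per_site
  species <- unlist(lapply(sites, function(s) {
    sprintf("%s_sp%02d", s, seq_len(nsp))
  }))
  site_of <- rep(sites, each = nsp)
  eff <- with_seed(design$seed, {
    matrix(stats::rnorm(2L * length(species), 0, rep(design$species_sd, each = length(species))),
           ncol = 2L)
  })
  # per-outline noise seeds, derived deterministically from the design seed
  seed0 <- if (is.null(design$seed)) 0L else as.integer(design$seed)
  md <- list(); outs <- list(); truth <- list()
  i <- 0L
  for (sp_i in seq_along(species)) {
    for (stg in stages) {
      for (ap in apps) {
        i <- i + 1L
        kappa <- design$base_kappa + design$site_effects[[site_of[sp_i]]][1L] +
          design$stage_effects[[stg]][1L] + design$appendage_effects[[ap]][1L] +
          eff[sp_i, 1L]
        tau <- design$base_tau + design$site_effects[[site_of[sp_i]]][2L] +
          design$stage_effects[[stg]][2L] + design$appendage_effects[[ap]][2L] +
          eff[sp_i, 2L]
        id <- sprintf("%s_%s_%s", species[sp_i], stg, ap)
        if (kappa <= 0 || kappa >= 2 * pi || tau <= 0.01 || tau >= 0.6) {
          stop(sprintf("parameters out of range in cell %s (kappa=%.3f, tau=%.3f)",
                       id, kappa, tau))
        }
        prm <- hook_params(kappa = kappa, tau = tau,
                           noise_sd = design$noise_sd,
                           seed = (seed0 * 1000L + i) %% .Machine$integer.max)
        outs[[id]] <- generate_hook(prm, n_points = n_points)
        md[[i]] <- data.frame(specimen_id = id, species = species[sp_i],
                              stage = stg, site = site_of[sp_i], appendage = ap)
        truth[[i]] <- data.frame(specimen_id = id, kappa = kappa, tau = tau)
      }
    }
  }
  metadata <- validate_specimen_metadata(do.call(rbind, md))
  list(metadata = metadata, outlines = outs,
       true_params = do.call(rbind, truth))
}

#' Write a synthetic dataset as on-disk fixtures
#'
#' Emits the formats the readers consume: a `.chc` chain-code file (outlines
#' digitized onto a pixel grid), a `.nef` normalized-coefficient file, and a
#' metadata CSV.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param n_harmonics harmonics for the nef file.
#' @param raster_height pixel height used when digitizing outlines to chain
#'   codes.
#' @return named list of written paths.
#' @export
write_dataset_fixtures <- function(dataset, dir, n_harmonics = 20L,
                                   raster_height = 150L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chains <- lapply(names(dataset$outlines), function(id) {
    mask <- rasterize_outline(dataset$outlines[[id]], height = raster_height)
    outline_to_chain(trace_boundary(mask), name = id)
  })
  chc <- file.path(dir, "outlines.chc")
  write_chc(chains, chc)
  efds <- lapply(dataset$outlines, function(o) {
    normalize_efd(compute_efd(o, n_harmonics = n_harmonics))
  })
  nef <- file.path(dir, "outlines.nef")
  write_nef(efds, nef)
  meta <- file.path(dir, "metadata.csv")
  write_specimen_metadata(dataset$metadata, meta)
  list(chc = chc, nef = nef, metadata = meta)
}
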