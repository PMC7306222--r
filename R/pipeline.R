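#' Prepare outlines and compute normalized elliptic Fourier descriptors
#'
#' The outline-to-coefficients step of the workflow: each outline is
#' optionally mirrored, smoothed, canonicalized and resampled, then its
#' elliptic Fourier descriptors are computed and normalized. A prep
#' manifest records what was done to every record.
#'
#' @param outlines named list of [outline]s (names are specimen ids).
#' @param n_harmonics harmonics to compute (default 20).
#' @param resample_n vertices after equal-arc-length resampling
#'   (default 256).
#' @param mirror character vector of specimen ids to mirror (left-sided
#'   parts), or TRUE for all.
#' @param smooth_iters smoothing iterations applied before resampling
#'   (default 0; the source drawings are assumed already clean).
#' @param skip_bad if TRUE, records failing preparation are dropped with a
#'   warning instead of aborting the run.
#' @return list with `efds` (named list of `normalized_efd`) and `manifest`
#'   (data frame: specimen_id, mirrored, smooth_iters, resample_n,
#'   n_harmonics, ok).
#' @export
run_efd_pipeline <- function(outlines, n_harmonics = 20L, resample_n = 256L,
                             mirror = character(0), smooth_iters = 0L,
                             skip_bad = FALSE) {
  if (!length(outlines)) stop("no records")
  nm <- names(outlines)
  if (is.null(nm) || any(nm == "")) stop("outlines must be a named list")
  if (isTRUE(mirror)) mirror <- nm
  efds <- list()
  rows <- list()
  for (id in nm) {
    res <- tryCatch({
      o <- outlines[[id]]
      if (id %in% mirror) o <- mirror_outline(o)
      if (smooth_iters > 0L) o <- smooth_outline(o, smooth_iters)
      o <- canonicalize(o)
      o <- resample_outline(o, resample_n)
      normalize_efd(compute_efd(o, n_harmonics = n_harmonics))
    }, error = function(e) e)
    ok <- !inherits(res, "error")
    if (!ok && !skip_bad) {
      stop(sprintf("record '%s' failed preparation: %s", id,
                   conditionMessage(res)))
    }
    if (ok) efds[[id]] <- res else {
      warning(sprintf("skipping record '%s': %s", id, conditionMessage(res)))
    }
    rows[[id]] <- data.frame(specimen_id = id, mirrored = id %in% mirror,
                             smooth_iters = smooth_iters,
                             resample_n = resample_n,
                             n_harmonics = n_harmonics, ok = ok)
  }
  if (!length(efds)) stop("no records survived preparation")
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(efds = efds, manifest = manifest)
}

#' Run the morphospace analysis over normalized coefficients
#'
#' PCA of the coefficient matrix plus every downstream group summary the
#' study reports: variance table, plot-ready score table, per-group convex
#' hulls and pairwise overlaps in the PC plane, and ontogenetic displacement
#' vectors per appendage.
#'
#' @param efds named list of `normalized_efd` objects.
#' @param metadata specimen metadata (validated with
#'   [validate_specimen_metadata()]); ids must match `names(efds)`.
#' @param n_harmonics harmonics used in the coefficient matrix.
#' @param pc_pair PC plane for hulls/vectors (default PC1 x PC2).
#' @return list with `pca`, `variance`, `scores` (long table with labels),
#'   `hulls`, `hull_table`, `overlap_table`, `ontogeny` (per appendage),
#'   `panels`.
#' @export
run_morphospace_pipeline <- function(efds, metadata, n_harmonics = 20L,
                                     pc_pair = c(1L, 2L)) {
  md <- validate_specimen_metadata(metadata)
  orphan_shape <- setdiff(names(efds), md$specimen_id)
  orphan_meta <- setdiff(md$specimen_id, names(efds))
  if (length(orphan_shape) || length(orphan_meta)) {
    stop("id mismatch between shapes and metadata; orphans: ",
         paste(c(orphan_shape, orphan_meta), collapse = ", "))
  }
  efds <- efds[md$specimen_id]
  mat <- assemble_coefficient_matrix(efds, n_harmonics = n_harmonics)
  ms <- run_pca(mat)
  scores <- data.frame(specimen_id = rownames(ms$scores),
                       PC1 = ms$scores[, 1L], PC2 = ms$scores[, 2L],
                       row.names = NULL)
  scores <- merge(scores, md, by = "specimen_id", sort = FALSE)
  # site x stage occupation hulls
  hulls <- group_hulls(ms, md[, c("site", "stage")], pc_pair = pc_pair)
  hull_table <- do.call(rbind, lapply(hulls, function(h) {
    data.frame(group = h$group, n = h$n, hull_area = h$hull_area)
  }))
  rownames(hull_table) <- NULL
  cmb <- utils::combn(seq_along(hulls), 2L)
  overlap_table <- data.frame(
    group_a = vapply(cmb[1L, ], function(i) hulls[[i]]$group, ""),
    group_b = vapply(cmb[2L, ], function(i) hulls[[i]]$group, ""),
    overlap_area = apply(cmb, 2L, function(ij) {
      hull_overlap(hulls[[ij[1L]]], hulls[[ij[2L]]])
    }))
  ontogeny <- lapply(stats::setNames(nm = specimen_levels$appendage), function(ap) {
    sub <- md[md$appendage == ap, , drop = FALSE]
    sub_ms <- ms
    sub_ms$scores <- ms$scores[sub$specimen_id, , drop = FALSE]
    ontogenetic_vectors(sub_ms, sub, pc_pair = pc_pair)
  })
  list(pca = ms, variance = variance_table(ms), scores = scores,
       hulls = hulls, hull_table = hull_table,
       overlap_table = overlap_table, ontogeny = ontogeny,
       panels = panel_tables(scores))
}

#' Panel groupings of the morphospace score plots
#'
#' The study presents each appendage's morphospace five ways: (A) all
#' specimens, (B) adults only, and (C, D, E) one attachment site at a time
#' with both stages. This returns those groupings as filtered score tables,
#' per appendage.
#'
#' @param scores long score table from [run_morphospace_pipeline()].
#' @return nested list `panels[[appendage]][[panel]]` of data frames;
#'   panels are `all`, `adults`, `mouth`, `gill`, `external`.
#' @export
panel_tables <- function(scores) {
  lapply(stats::setNames(nm = specimen_levels$appendage), function(ap) {
    s <- scores[scores$appendage == ap, , drop = FALSE]
    list(all = s,
         adults = s[s$stage == "adult", , drop = FALSE],
         mouth = s[s$site == "mouth", , drop = FALSE],
         gill = s[s$site == "gill", , drop = FALSE],
         external = s[s$site == "external", , drop = FALSE])
  })
}

#' Simulation-and-recovery study
#'
#' Generates synthetic datasets with known effects and checks that the
#' morphospace machinery recovers them: (i) with only curvature varying,
#' the leading PC tracks kappa; (ii) with only thickness varying, the
#' leading PC tracks tau; (iii) a coherent stage effect yields a high
#' circular concentration of ontogenetic vectors while per-species random
#' stage effects yield a low one.
#'
#' @param seed base RNG seed; every sub-experiment derives its seed from it.
#' @param n_sweep hooks per single-parameter sweep.
#' @param n_harmonics,resample_n forwarded to the EFD step.
#' @param n_random_reps replicate randomized-direction datasets averaged
#'   for the incoherent-trajectory arm.
#' @return list with `corr_pc1_kappa`, `corr_pc_tau` (correlation of the
#'   best-aligned leading PC with tau), `r_bar_coherent`,
#'   `r_bar_random` (mean over replicates), and the underlying tables.
#' @export
recovery_study <- function(seed = 1L, n_sweep = 30L, n_harmonics = 20L,
                           resample_n = 256L, n_random_reps = 3L) {
  sweep_corr <- function(vary, seed_off) {
    kappas <- seq(0.8, 2.2, length.out = n_sweep)
    taus <- seq(0.12, 0.38, length.out = n_sweep)
    efds <- list()
    truth <- numeric(n_sweep)
    for (i in seq_len(n_sweep)) {
      kp <- if (vary == "kappa") kappas[i] else 1.5
      tu <- if (vary == "tau") taus[i] else 0.25
      truth[i] <- if (vary == "kappa") kp else tu
      o <- generate_hook(hook_params(kappa = kp, tau = tu, noise_sd = 0.003,
                                     seed = seed * 100L + seed_off + i),
                         n_points = resample_n)
      efds[[sprintf("h%02d", i)]] <- normalize_efd(
        compute_efd(o, n_harmonics = n_harmonics))
    }
    ms <- run_pca(assemble_coefficient_matrix(efds, n_harmonics))
    # the effect should load on the first component; report |corr| with the
    # best of PC1/PC2 so axis swaps under near-equal eigenvalues are visible
    c1 <- abs(stats::cor(ms$scores[, 1L], truth))
    c2 <- abs(stats::cor(ms$scores[, 2L], truth))
    list(corr_pc1 = c1, corr_best = max(c1, c2),
         leading = if (c1 >= c2) 1L else 2L, ms = ms, truth = truth)
  }
  kap <- sweep_corr("kappa", 0L)
  tau <- sweep_corr("tau", 1000L)

  # trajectory logic: coherent stage effect vs per-species random directions
  coh_design <- design_spec(stage_effects = list(immature = c(0, 0),
                                                 adult = c(0.45, 0)),
                            site_effects = list(mouth = c(0, 0),
                                                gill = c(0, 0),
                                                external = c(0, 0)),
                            species_sd = c(0.08, 0.012),
                            seed = seed + 11L)
  r_bar_coherent <- dataset_r_bar(generate_dataset(coh_design),
                                  n_harmonics, resample_n)
  r_rand <- vapply(seq_len(n_random_reps), function(r) {
    ds <- random_stage_effect_dataset(seed = seed + 100L + r)
    dataset_r_bar(ds, n_harmonics, resample_n)
  }, numeric(1L))
  list(corr_pc1_kappa = kap$corr_pc1,
       corr_pc_tau = tau$corr_best,
       tau_leading_pc = tau$leading,
       r_bar_coherent = r_bar_coherent,
       r_bar_random = mean(r_rand),
       r_bar_random_reps = r_rand)
}

# pooled R-bar over both appendages of a dataset
dataset_r_bar <- function(ds, n_harmonics, resample_n) {
  prep <- run_efd_pipeline(ds$outlines, n_harmonics = n_harmonics,
                           resample_n = resample_n)
  res <- run_morphospace_pipeline(prep$efds, ds$metadata,
                                  n_harmonics = n_harmonics)
  ov <- ontogenetic_vectors(res$pca, ds$metadata)
  ov$summary$r_bar
}

#' Dataset whose stage effect points in a random direction per species
#'
#' The counterfactual for trajectory analysis: each species x appendage cell
#' gets an adult-minus-immature shift of fixed magnitude in a random
#' direction of (kappa, tau) space, so there is no shared ontogenetic
#' trajectory by construction.
#'
#' @param seed RNG seed.
#' @param magnitude shift magnitude in scaled (kappa, tau) units.
#' @return dataset as from [generate_dataset()].
#' @export
random_stage_effect_dataset <- function(seed = 1L, magnitude = 0.45) {
  base <- generate_dataset(design_spec(
    stage_effects = list(immature = c(0, 0), adult = c(0, 0)),
    site_effects = list(mouth = c(0, 0), gill = c(0, 0), external = c(0, 0)),
    species_sd = c(0.08, 0.012), noise_sd = 0.005, seed = seed))
  md <- base$metadata
  cells <- unique(md[, c("species", "appendage")])
  angles <- with_seed(seed + 7L, stats::runif(nrow(cells), 0, 2 * pi))
  outs <- base$outlines
  truth <- base$true_params
  for (r in seq_len(nrow(cells))) {
    idx <- which(md$species == cells$species[r] &
                 md$appendage == cells$appendage[r] & md$stage == "adult")
    id <- md$specimen_id[idx]
    # shift in (kappa, tau): tau scaled down to keep units comparable
    dk <- magnitude * cos(angles[r])
    dtau <- 0.15 * magnitude * sin(angles[r])
    kp <- truth$kappa[truth$specimen_id == id] + dk
    tu <- truth$tau[truth$specimen_id == id] + dtau
    kp <- min(max(kp, 0.3), 2.6)
    tu <- min(max(tu, 0.08), 0.45)
    outs[[id]] <- generate_hook(hook_params(kappa = kp, tau = tu,
                                            noise_sd = 0.005,
                                            seed = seed * 131L + r),
                                n_points = 256L)
    truth$kappa[truth$specimen_id == id] <- kp
    truth$tau[truth$specimen_id == id] <- tu
  }
  list(metadata = md, outlines = outs, true_params = truth)
}
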