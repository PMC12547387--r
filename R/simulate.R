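# Ground-truth specification and 4-D run/cohort simulation.

#' Ground truth for synthetic runs
#'
#' Specifies the planted neural effect amplitudes, the noise model and the
#' compartment nuisance structure of a simulated cohort. Amplitudes are
#' *pre-hemodynamic* neural amplitudes in percent signal change: a positive
#' amplitude combined with the reversed-sign response function produces a
#' signal *decrease* in the measured intensity.
#'
#' The default amplitude table emulates the study's signal structure: an
#' A1-like primary auditory region (and IC-like midbrain) responding to all
#' 8 sound subcategories, F5-like and pMTG-like regions responding positively
#' to macaque vocalizations and negatively to non-vocal sounds, and an
#' aTVA-like region responding to vocalizations only.
#'
#' @param amplitude_table Data.frame with columns `region_name`,
#'   `subcategory`, `amplitude_pct`.
#' @param noise List: `ar1` (lag-1 autocorrelation, in `[0, 1)`), `sd`
#'   (marginal noise sd in intensity units), `drift_sd` (per-order sds of
#'   random orthonormal-polynomial drift coefficients, intensity units).
#' @param nuisance List: `n_latent` components per compartment, `ar` latent
#'   smoothness, `amplitude` loading sd inside white/CSF compartments
#'   (intensity units), `gray_leak` attenuation factor for the gray-matter
#'   footprint of the same latents (CompCor premise: compartment signals are
#'   clean measurements of global physiological fluctuations).
#' @param baseline Baseline intensity (arbitrary units).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(amplitude_table = default_amplitudes(),
                         noise = list(ar1 = 0.3, sd = 20,
                                      drift_sd = c(10, 5, 3)),
                         nuisance = list(n_latent = 2, ar = 0.6,
                                         amplitude = 8, gray_leak = 0.3),
                         baseline = 1000) {
  stopifnot(is.data.frame(amplitude_table),
            all(c("region_name", "subcategory", "amplitude_pct") %in%
                  names(amplitude_table)),
            all(is.finite(amplitude_table$amplitude_pct)))
  noise <- utils::modifyList(list(ar1 = 0.3, sd = 20, drift_sd = c(10, 5, 3)),
                             noise)
  nuisance <- utils::modifyList(list(n_latent = 2, ar = 0.6, amplitude = 8,
                                     gray_leak = 0.3), nuisance)
  if (noise$ar1 < 0 || noise$ar1 >= 1) stop("`ar1` must lie in [0, 1)")
  if (noise$sd < 0) stop("noise sd must be >= 0")
  structure(list(amplitude_table = amplitude_table, noise = noise,
                 nuisance = nuisance, baseline = baseline),
            class = "ground_truth")
}

#' Default planted amplitude table (percent signal change)
#' @export
default_amplitudes <- function() {
  sub <- subcategory_table()
  voc <- sub$subcategory[sub$main_category == "macaque_vocal"]
  one <- function(region, subcats, amp)
    data.frame(region_name = region, subcategory = subcats,
               amplitude_pct = amp, stringsAsFactors = FALSE)
  sel <- function(region, pos, neg)
    rbind(one(region, voc, pos),
          one(region, setdiff(sub$subcategory, voc), neg))
  rbind(one("A1-like-left", sub$subcategory, 1.0),
        one("A1-like-right", sub$subcategory, 1.0),
        one("IC-like", sub$subcategory, 0.8),
        sel("F5-like-left", 0.5, -0.5),
        sel("F5-like-right", 0.5, -0.5),
        sel("pMTG-like-left", 0.5, -0.5),
        sel("pMTG-like-right", 0.5, -0.5),
        sel("aTVA-like", 0.4, 0.0))
}

#' Simulate one functional run
#'
#' Voxel time series are
#' `baseline * (1 + sum_c amplitude(region, c)/100 * regressor_c(t))`
#' plus polynomial drift, AR(1) noise and compartment nuisance components;
#' task regressors are the block boxcars convolved with the (reversed-sign)
#' response function, evaluated at the acquisition timestamps.
#'
#' @param atlas A [make_phantom()] atlas.
#' @param design A [make_run_design()] schedule.
#' @param truth A [ground_truth()].
#' @param rf A [mion_rf()] response function.
#' @param seed Integer seed (bit-identical output for equal seeds).
#' @param subject_id,run_id Provenance labels.
#' @return An object of class `run_image`: `data` (4-D array), `timestamps_s`,
#'   `grid`, and provenance fields.
#' @export
simulate_run <- function(atlas, design, truth = ground_truth(),
                         rf = mion_rf(), seed = 1,
                         subject_id = "sub-01", run_id = "run-01") {
  stopifnot(inherits(atlas, "tissue_atlas"), inherits(design, "run_design"),
            inherits(truth, "ground_truth"))
  bad <- setdiff(unique(truth$amplitude_table$region_name),
                 atlas$region_table$region_name)
  if (length(bad))
    stop(sprintf("ground truth references region(s) absent from atlas: %s",
                 paste(bad, collapse = ", ")))
  n <- design$n_volumes
  V <- prod(atlas$grid$dims)
  reg <- build_task_regressors(design, rf, "subcategory")

  Y <- matrix(truth$baseline, n, V)
  # planted task effects, region by region
  amp <- truth$amplitude_table
  for (region in unique(amp$region_name)) {
    vox <- which(atlas_mask(atlas, region))
    rows <- amp[amp$region_name == region, ]
    a <- stats::setNames(rep(0, ncol(reg$X)), colnames(reg$X))
    a[rows$subcategory] <- rows$amplitude_pct
    sig <- truth$baseline * as.vector(reg$X %*% (a / 100))
    Y[, vox] <- Y[, vox] + sig
  }

  with_seed(derive_seed(seed, 101L), {
    # polynomial drift, independent coefficients per voxel
    dsd <- truth$noise$drift_sd
    if (length(dsd) && any(dsd > 0)) {
      P <- stats::poly(design$volume_times_s, degree = length(dsd))
      P <- sweep(P, 2, sqrt(colSums(P^2)), "/") * sqrt(n)  # unit-RMS columns
      C <- matrix(stats::rnorm(length(dsd) * V, sd = dsd), length(dsd), V)
      Y <- Y + P %*% C
    }
    # AR(1) noise, stationary marginal sd = truth$noise$sd
    if (truth$noise$sd > 0) {
      rho <- truth$noise$ar1
      eps <- matrix(stats::rnorm(n * V, sd = truth$noise$sd * sqrt(1 - rho^2)),
                    n, V)
      if (rho > 0) {
        E <- stats::filter(eps, rho, method = "recursive",
                           init = matrix(stats::rnorm(V, sd = truth$noise$sd),
                                         1, V))
        Y <- Y + matrix(as.numeric(E), n, V)
      } else Y <- Y + eps
    }
    # compartment nuisance: latents loaded in white/CSF, attenuated in gray
    nu <- truth$nuisance
    if (nu$n_latent > 0 && nu$amplitude > 0) {
      gray <- which(atlas_mask(atlas, "brain"))
      for (comp in c("white", "csf")) {
        vox <- which(atlas_mask(atlas, comp))
        if (!length(vox)) next
        L <- stats::filter(matrix(stats::rnorm(n * nu$n_latent), n), nu$ar,
                           method = "recursive")
        L <- scale(matrix(as.numeric(L), n, nu$n_latent))  # unit-sd latents
        # physiological fluctuations load coherently (same sign, moderate
        # spatial variation) across a compartment and, attenuated, across
        # gray matter
        load_c <- matrix(nu$amplitude *
                           (1 + 0.3 * stats::rnorm(length(vox) *
                                                     nu$n_latent)),
                         ncol = nu$n_latent)
        Y[, vox] <- Y[, vox] + L %*% t(load_c)
        if (nu$gray_leak > 0) {
          load_g <- matrix(nu$amplitude * nu$gray_leak *
                             (1 + 0.3 * stats::rnorm(length(gray) *
                                                       nu$n_latent)),
                           ncol = nu$n_latent)
          Y[, gray] <- Y[, gray] + L %*% t(load_g)
        }
      }
    }
  })
  structure(list(data = array(t(Y), c(atlas$grid$dims, n)),
                 timestamps_s = design$volume_times_s, grid = atlas$grid,
                 subject_id = subject_id, run_id = run_id, seed = seed),
            class = "run_image")
}

#' @export
print.run_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<run_image> %s %s: %d x %d x %d voxels, %d volumes (seed %d)\n",
              x$subject_id, x$run_id, d[1], d[2], d[3], d[4], x$seed))
  invisible(x)
}

# n x V matrix view of a run image (volumes in rows)
image_matrix <- function(image) {
  d <- dim(image$data)
  t(matrix(image$data, prod(d[1:3]), d[4]))
}

#' Simulate and write a cohort of subjects to disk
#'
#' Writes per-run NIfTI volumes and BIDS-style event tables, the atlas label
#' volume, the ground-truth record (YAML) and a tab-separated manifest.
#' Default cohort size matches the study: 11 subjects with run counts drawn
#' uniformly from 10..14 (median 12 in expectation). One master seed expands
#' into per-run sub-seeds via [derive_seed()], so any run is regenerable in
#' isolation.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param runs_per_subject `NULL` (draw 10..14 per subject), a scalar, or a
#'   vector of length `n_subjects`.
#' @param atlas,truth,rf,protocol Generator components (defaults as documented
#'   in each constructor).
#' @param seed Master seed.
#' @param out_dir Writable output directory (created if needed).
#' @return The manifest data.frame (subject_id, run_id, image, events, seed),
#'   invisibly also written to `manifest.tsv`.
#' @export
simulate_cohort <- function(n_subjects = 11, runs_per_subject = NULL,
                            atlas = make_phantom(volume_grid(c(24, 24, 18))),
                            truth = ground_truth(), rf = mion_rf(),
                            protocol = sparse_protocol(), seed = 1,
                            out_dir) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  if (missing(out_dir)) stop("`out_dir` is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create out_dir '%s'", out_dir))
  if (is.null(runs_per_subject))
    runs_per_subject <- with_seed(derive_seed(seed, 999L),
                                  sample(10:14, n_subjects, replace = TRUE))
  if (length(runs_per_subject) == 1)
    runs_per_subject <- rep(runs_per_subject, n_subjects)
  stopifnot(length(runs_per_subject) == n_subjects, all(runs_per_subject >= 1))

  write_volume(atlas$labels, file.path(out_dir, "atlas.nii.gz"), atlas$grid)
  yaml::write_yaml(list(
    baseline = truth$baseline, noise = truth$noise, nuisance = truth$nuisance,
    amplitude_table = truth$amplitude_table),
    file.path(out_dir, "truth.yaml"))

  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("sub-%02d", s)
    for (r in seq_len(runs_per_subject[s])) {
      rid <- sprintf("run-%02d", r)
      rseed <- derive_seed(seed, s, r)
      design <- make_run_design(rseed, protocol)
      img <- simulate_run(atlas, design, truth, rf, seed = rseed,
                          subject_id = sid, run_id = rid)
      ipath <- file.path(out_dir, sprintf("%s_%s_bold.nii.gz", sid, rid))
      epath <- file.path(out_dir, sprintf("%s_%s_events.tsv", sid, rid))
      write_volume(img$data, ipath, atlas$grid)
      write_events(design$blocks, epath)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, run_id = rid, image = ipath, events = epath,
        seed = rseed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
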