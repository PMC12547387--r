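# Shared small fixtures, built once per test session.

tiny_grid <- function() volume_grid(c(16, 16, 14))

# memoized atlas/design/regressors to keep the suite fast
.fix <- new.env()

tiny_atlas <- function() {
  if (is.null(.fix$atlas)) .fix$atlas <- make_phantom(tiny_grid())
  .fix$atlas
}

tiny_design <- function(seed = 11) {
  key <- paste0("design_", seed)
  if (is.null(.fix[[key]])) .fix[[key]] <- make_run_design(seed)
  .fix[[key]]
}

tiny_rf <- function() {
  if (is.null(.fix$rf)) .fix$rf <- mion_rf()
  .fix$rf
}

tiny_design_matrix <- function(seed = 11, level = "subcategory",
                               drift_order = 3) {
  key <- paste0("dm_", seed, "_", level, "_", drift_order)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- assemble_design_matrix(
      build_task_regressors(tiny_design(seed), tiny_rf(), level),
      drift_order = drift_order)
  .fix[[key]]
}

# noise-free, nuisance-free truth with the default amplitude table
clean_truth <- function() {
  ground_truth(noise = list(ar1 = 0, sd = 0, drift_sd = 0),
               nuisance = list(amplitude = 0))
}

# pure-noise truth (no task signal anywhere)
noise_truth <- function(ar1 = 0.3, sd = 20, drift_sd = 0) {
  ground_truth(amplitude_table = default_amplitudes()[0, ],
               noise = list(ar1 = ar1, sd = sd, drift_sd = drift_sd),
               nuisance = list(amplitude = 0))
}

# quick toy contrast map for combination/jackknife mechanics
toy_map <- function(effect, sd = 1, df = 100) {
  effect <- as.numeric(effect)
  sdv <- rep_len(sd, length(effect))
  structure(list(effect = effect, sd = sdv, t = effect / sdv, df = df,
                 grid = NULL, name = "toy"),
            class = "contrast_map")
}

# normalization factor turning wrap-smoothed white noise into a unit-variance
# stationary Gaussian field (product of per-axis kernel L2 norms)
smooth_field_scale <- function(fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  sqrt(sum(w^2))^3
}

# one stationary unit-variance Gaussian null field on a box search region:
# generated with wrap-around smoothing on a padded grid, then cropped, so
# the box resel counts describe its true search geometry
smooth_null_field <- function(dims, fwhm_mm = 3, voxel_size_mm = 1.5) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  rk <- max(1L, ceiling(4 * sigma))
  big <- dims + 2L * rk
  f <- smooth_volumes(array(stats::rnorm(prod(big)), big), fwhm_mm,
                      volume_grid(big, voxel_size_mm), boundary = "wrap") /
    smooth_field_scale(fwhm_mm, voxel_size_mm)
  f[(rk + 1):(rk + dims[1]), (rk + 1):(rk + dims[2]),
    (rk + 1):(rk + dims[3])]
}
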