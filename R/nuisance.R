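# CompCor-style nuisance covariates: eroded compartment masks, PCA time
# courses, and per-subject component-count optimisation.

#' Erode a binary mask with a cubic structuring element
#'
#' Morphological erosion with a cube whose voxel-center extent spans
#' `kernel_mm` per axis (3 x 3 x 3 voxels for a 3 mm kernel on a 1.5 mm
#' grid). Used to shrink white-matter/CSF masks away from gray matter before
#' extracting nuisance time series. The result is always a subset of the
#' input; an empty result is legal and triggers a warning.
#'
#' @param mask Logical (or 0/1) 3-D array on the functional grid.
#' @param kernel_mm Cube extent in mm (center-to-center span).
#' @param grid A [volume_grid()] giving the voxel size; alternatively pass
#'   `kernel_vox` directly.
#' @param kernel_vox Odd cube side in voxels (overrides `kernel_mm`).
#' @return Logical 3-D array.
#' @export
erode_mask <- function(mask, kernel_mm = 3.0, grid = NULL,
                       kernel_vox = NULL) {
  stopifnot(length(dim(mask)) == 3)
  mask <- mask > 0
  if (is.null(kernel_vox)) {
    vs <- if (is.null(grid)) 1.5 else grid$voxel_size_mm
    kernel_vox <- 2L * as.integer(round(kernel_mm / (2 * vs))) + 1L
  }
  if (kernel_vox %% 2 != 1 || kernel_vox < 1)
    stop("`kernel_vox` must be a positive odd integer")
  r <- (kernel_vox - 1L) %/% 2L
  if (r == 0L) return(mask)
  out <- mask
  for (ox in -r:r) for (oy in -r:r) for (oz in -r:r) {
    if (ox == 0 && oy == 0 && oz == 0) next
    out <- out & shift_array(mask, c(ox, oy, oz), fill = FALSE)
    if (!any(out)) break
  }
  if (!any(out))
    warning("erosion produced an empty mask (structure thinner than kernel)")
  out
}

#' Principal components of compartment time series
#'
#' Extracts the voxel time series inside an (eroded) compartment mask,
#' centers each voxel's series, and returns the top-k left singular time
#' courses (mutually orthogonal, unit norm) with their explained-variance
#' fractions.
#'
#' @param image A `run_image` or an n x V matrix / 4-D array.
#' @param mask Logical 3-D array (or voxel index vector).
#' @param k Number of components (>= 0; at most the rank of the masked data).
#' @param compartment Optional label ("white"/"csf") for bookkeeping.
#' @return An object of class `compartment_pcs`: `components` (n x k),
#'   `explained_variance`, `k`, `compartment`, `mask`.
#' @export
compute_pcs <- function(image, mask, k, compartment = NULL) {
  if (k < 0) stop("`k` must be >= 0")
  Y <- if (inherits(image, "run_image")) image_matrix(image)
       else if (length(dim(image)) == 4)
         t(matrix(image, prod(dim(image)[1:3]), dim(image)[4]))
       else as.matrix(image)
  vox <- if (is.logical(mask) || length(dim(mask)) == 3) which(mask > 0)
         else as.integer(mask)
  if (!length(vox)) stop("compartment mask is empty")
  Ym <- Y[, vox, drop = FALSE]
  Ym <- sweep(Ym, 2, colMeans(Ym))          # center each voxel's series
  sv <- svd(Ym, nu = min(dim(Ym)), nv = 0)
  pos <- sum(sv$d > max(dim(Ym)) * .Machine$double.eps * max(sv$d, 1))
  if (k > pos)
    stop(sprintf("requested k = %d components but masked data has rank %d",
                 k, pos))
  comp <- sv$u[, seq_len(k), drop = FALSE]
  if (k > 0) colnames(comp) <- sprintf("%s_pc%d",
                                       compartment %||% "comp", seq_len(k))
  structure(list(components = comp,
                 explained_variance = if (length(sv$d))
                   sv$d^2 / sum(sv$d^2) else numeric(0),
                 k = k, compartment = compartment, mask = vox),
            class = "compartment_pcs")
}

#' @export
print.compartment_pcs <- function(x, ...) {
  cat(sprintf("<compartment_pcs> %s: k = %d over %d voxels",
              x$compartment %||% "compartment", x$k, length(x$mask)))
  if (x$k > 0)
    cat(sprintf(" (explained variance %s)",
                paste(sprintf("%.1f%%", 100 * x$explained_variance[
                  seq_len(x$k)]), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Choose nuisance component counts by optimizing Sound vs. Silence
#'
#' For each candidate pair `(k_white, k_csf)` the subject's runs are refit
#' with that many compartment components as covariates of no interest, the
#' run-level Sound-vs-Silence contrasts are combined into a subject-level
#' map, and the whole-brain maximum t is recorded. Returns the pair with the
#' maximal objective; ties are broken by smallest `k_white + k_csf`, then
#' smallest `k_white`. Note the objective is the statistic being optimized —
#' a deliberately circular criterion inherited from the study design; fix the
#' counts instead if that concerns the analysis.
#'
#' @param runs List of per-run lists with elements `image` (a `run_image` or
#'   n x V matrix), `task` (task regressor matrix), `timestamps`, `wm_pcs`,
#'   `csf_pcs` (matrices holding at least `max(grid)` columns).
#' @param mask Whole-brain logical array (or voxel indices) for the max.
#' @param k_white_grid,k_csf_grid Candidate counts (default 0..8).
#' @param drift_order,ar_order Passed to [fit_run_glm()].
#' @return An object of class `component_count_choice`.
#' @export
select_component_counts <- function(runs, mask, k_white_grid = 0:8,
                                    k_csf_grid = 0:8, drift_order = 3,
                                    ar_order = 1) {
  stopifnot(length(runs) >= 1, length(k_white_grid) >= 1,
            length(k_csf_grid) >= 1)
  grid_df <- expand.grid(k_white = sort(unique(k_white_grid)),
                         k_csf = sort(unique(k_csf_grid)))
  grid_df$objective <- NA_real_
  for (i in seq_len(nrow(grid_df))) {
    kw <- grid_df$k_white[i]; kc <- grid_df$k_csf[i]
    maps <- lapply(runs, function(run) {
      nuis <- cbind(run$wm_pcs[, seq_len(kw), drop = FALSE],
                    run$csf_pcs[, seq_len(kc), drop = FALSE])
      dm <- assemble_design_matrix(run$task, run$timestamps,
                                   drift_order = drift_order,
                                   nuisance = if (ncol(nuis)) nuis else NULL)
      fit <- fit_run_glm(run$image, dm, ar_order = ar_order)
      compute_contrast(fit, sound_vs_silence_weights(dm),
                       name = "sound_vs_silence")
    })
    obj <- try(subject_max_t(maps, mask), silent = TRUE)
    if (!inherits(obj, "try-error")) grid_df$objective[i] <- obj
  }
  if (all(is.na(grid_df$objective)))
    stop("all component-count fits failed")
  best <- max(grid_df$objective, na.rm = TRUE)
  cand <- grid_df[!is.na(grid_df$objective) &
                    grid_df$objective >= best - 1e-12, , drop = FALSE]
  cand <- cand[order(cand$k_white + cand$k_csf, cand$k_white), , drop = FALSE]
  structure(list(k_white = cand$k_white[1], k_csf = cand$k_csf[1],
                 objective = cand$objective[1], search_grid = grid_df),
            class = "component_count_choice")
}

#' @export
print.component_count_choice <- function(x, ...) {
  cat(sprintf(paste0("<component_count_choice> k_white = %d, k_csf = %d ",
                     "(peak Sound-vs-Silence t = %.2f over %d grid points)\n"),
              x$k_white, x$k_csf, x$objective, nrow(x$search_grid)))
  invisible(x)
}
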