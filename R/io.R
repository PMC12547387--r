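# File formats: NIfTI-1 volumes, TSV event tables, manifests, YAML config.

#' Write a volume (3-D or 4-D array) as NIfTI-1
#'
#' The affine encodes the isotropic voxel size and the grid origin.
#'
#' @param data 3-D or 4-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid A [volume_grid()].
#' @export
write_volume <- function(data, path, grid) {
  stopifnot(inherits(grid, "volume_grid"), length(dim(data)) %in% c(3, 4))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(rep(grid$voxel_size_mm, 3),
                           if (length(dim(data)) == 4) 1)
  aff <- diag(c(rep(grid$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Input path (plain or gzipped NIfTI-1).
#' @param expect_4d Require a 4-D image.
#' @return A list with `data` (array) and `grid` ([volume_grid()]).
#' @export
read_volume <- function(path, expect_4d = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (expect_4d && length(d) != 4)
    stop(sprintf("expected a 4-D image, got %d-D: %s", length(d), path))
  pd <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  if (diff(range(pd)) > 1e-6 * mean(pd))
    stop(sprintf("anisotropic voxels (%s) where isotropy is required: %s",
                 paste(signif(pd, 4), collapse = " x "), path))
  aff <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(aff, "try-error")) c(0, 0, 0) else aff[1:3, 4]
  grid <- volume_grid(d[1:3], voxel_size_mm = pd[1], origin = origin)
  list(data = array(as.numeric(img), d), grid = grid)
}

#' Write a per-run event table (tab-separated)
#'
#' Columns: `onset` (s from run start), `duration` (s), `trial_type`
#' (subcategory name or `"silence"`), `main_category`.
#'
#' @param blocks Block data.frame from a [make_run_design()] (`$blocks`) or
#'   a frame with the output columns already named.
#' @param path Output path.
#' @export
write_events <- function(blocks, path) {
  if (all(c("onset_s", "duration_s", "condition") %in% names(blocks)))
    blocks <- data.frame(onset = blocks$onset_s, duration = blocks$duration_s,
                         trial_type = blocks$condition,
                         main_category = blocks$main_category,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(blocks)))
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate a per-run event table
#'
#' @param path Tab-separated file with header `onset`, `duration`,
#'   `trial_type` (and optionally `main_category`).
#' @param catalog Stimulus catalog used to validate labels.
#' @return A validated data.frame of block records.
#' @export
read_events <- function(path, catalog = stimulus_catalog()) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(ev) == 0) stop(sprintf("no events in '%s'", path))
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop(sprintf("'%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  known <- c(unique(catalog$subcategory), "silence")
  bad <- which(!(ev$trial_type %in% known))
  if (length(bad))
    stop(sprintf("unknown trial_type '%s' at line %d of '%s'",
                 ev$trial_type[bad[1]], bad[1] + 1L, path))
  if (is.unsorted(ev$onset, strictly = TRUE))
    stop(sprintf("event onsets must be strictly increasing in '%s'", path))
  if (!"main_category" %in% names(ev)) {
    sub <- subcategory_table()
    ev$main_category <- sub$main_category[match(ev$trial_type,
                                                sub$subcategory)]
    ev$main_category[ev$trial_type == "silence"] <- "silence"
  }
  ev
}

#' Write / read a cohort run manifest (tab-separated)
#'
#' @param manifest Data.frame with columns `subject_id`, `run_id`, `image`,
#'   `events`, `seed` (and optionally `kept`).
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_paths Verify that referenced files exist.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "run_id", "image", "events", "seed")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  if (anyDuplicated(m[c("subject_id", "run_id")]))
    stop("duplicate (subject_id, run_id) in manifest")
  if (check_paths) {
    missing <- c(m$image[!file.exists(m$image)],
                 m$events[!file.exists(m$events)])
    if (length(missing))
      stop(sprintf("manifest references missing file(s): %s",
                   paste(utils::head(missing, 3), collapse = ", ")))
  }
  m
}

#' Pipeline configuration
#'
#' One structured object holding every tunable of the pipeline; defaults
#' reproduce the study's stated settings where stated and this package's
#' documented conventions elsewhere. Serializable to/from YAML.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_subjects = 11L,
    runs_per_subject = NULL,          # NULL: draw 10..14 per subject
    grid_dims = c(24L, 24L, 18L),
    voxel_size_mm = 1.5,
    protocol = unclass(sparse_protocol()),
    rf = list(k = 3, theta = 4, duration_s = 60, normalization = "peak",
              step_s = 0.01),
    smoothing_fwhm_mm = 3.0,
    erosion_kernel_mm = 3.0,
    drift_order = 3L,
    ar_order = 1L,
    nuisance = list(optimize = TRUE, k_white_grid = 0:4, k_csf_grid = 0:4,
                    k_white = 2L, k_csf = 2L),
    jackknife = TRUE,
    thresholds = list(alpha = 0.05, cluster_forming_p = 0.001,
                      connectivity = 6L, gaussian_limit = TRUE),
    roi = list(diameter_mm = 4.5, statistic = "mean"))
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("config overrides must be named")
    cfg <- utils::modifyList(cfg, over)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Semantic hash of a configuration (provenance stamp)
#' @param config A `pipeline_config`.
#' @return An 8-hex-digit string that changes iff a semantic field changes.
#' @export
config_hash <- function(config) {
  # canonicalize storage modes (YAML round trips may turn integers into
  # doubles) so the hash reflects semantic content only
  canon <- rapply(unclass(config), as.numeric, classes = "integer",
                  how = "replace")
  canon <- canon[!vapply(canon, is.null, logical(1))]   # absent == NULL
  string_hash(yaml::as.yaml(canon))
}
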