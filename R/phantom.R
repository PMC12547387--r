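# Tissue/region phantoms for the synthetic cohort generator.

#' Stimulus catalog: 8 subcategories nested in 2 main categories
#'
#' Forty-eight stimulus labels: two main categories (macaque vocalizations and
#' non-vocal sounds), each split into 4 subcategories of 6 stimuli. Stimuli
#' exist only as labels, durations and timings; no audio is handled.
#'
#' @param stimulus_duration_s Duration assigned to every stimulus (seconds).
#' @return A data.frame with columns `stimulus_id`, `subcategory`,
#'   `main_category`, `duration_s`.
#' @export
stimulus_catalog <- function(stimulus_duration_s = 0.5) {
  sub <- subcategory_table()
  out <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    data.frame(stimulus_id = sprintf("%s_%02d", sub$subcategory[i], 1:6),
               subcategory = sub$subcategory[i],
               main_category = sub$main_category[i],
               duration_s = stimulus_duration_s,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# The fixed subcategory -> main-category nesting.
subcategory_table <- function() {
  data.frame(
    subcategory = c("coo", "grunt", "bark", "scream",
                    "natural_living", "natural_nonliving",
                    "artificial_human", "artificial_other"),
    main_category = rep(c("macaque_vocal", "non_vocal"), each = 4),
    stringsAsFactors = FALSE)
}

#' Default phantom region layout
#'
#' Places spherical gray-matter regions emulating the study's anatomy on a
#' given grid: bilateral A1-like auditory cortex, a midline IC-like midbrain
#' blob, bilateral F5-like ventral premotor and pMTG-like temporal regions,
#' and an aTVA-like anterior temporal region, plus white-matter and CSF slabs
#' handled by [make_phantom()]. Centers scale with the grid so the layout
#' works on any grid of at least 16 x 16 x 12 voxels.
#'
#' @param grid A [volume_grid()].
#' @return A data.frame with columns `region_name`, `label_code`, `cx`, `cy`,
#'   `cz` (voxel indices) and `radius_mm`.
#' @export
default_region_spec <- function(grid) {
  d <- grid$dims
  if (any(d < c(16, 16, 12)))
    stop("default region layout needs a grid of at least 16 x 16 x 12 voxels")
  # fractional positions (x: left-right, y: post-ant, z: inf-sup), spaced so
  # 3 mm-radius spheres stay disjoint down to a 16 x 16 x 12 grid
  f <- rbind(
    `A1-like-left`    = c(0.200, 0.400, 0.727),
    `A1-like-right`   = c(0.800, 0.400, 0.727),
    `IC-like`         = c(0.533, 0.133, 0.545),
    `F5-like-left`    = c(0.133, 0.800, 0.636),
    `F5-like-right`   = c(0.867, 0.800, 0.636),
    `pMTG-like-left`  = c(0.133, 0.133, 0.909),
    `pMTG-like-right` = c(0.867, 0.133, 0.909),
    `aTVA-like`       = c(0.533, 0.800, 0.909))
  ctr <- round(sweep(f, 2, d - 1, "*")) + 1
  data.frame(region_name = rownames(f), label_code = 10L + seq_len(nrow(f)),
             cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
             radius_mm = 3.0, row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a tissue/region phantom atlas
#'
#' Constructs an integer label volume with background (0), gray matter (1),
#' a white-matter slab (2), a CSF slab (3) and spherical named gray-matter
#' regions (codes from `region_spec`). Stands in for the segmentation and
#' atlas volumes a real analysis would register to the functional grid.
#'
#' @param grid A [volume_grid()].
#' @param region_spec Data.frame as returned by [default_region_spec()]; may
#'   have zero rows for a plain tissue phantom.
#' @return An object of class `tissue_atlas` with fields `grid`, `labels`
#'   (integer array), `codes` (named tissue codes) and `region_table`.
#' @export
make_phantom <- function(grid, region_spec = default_region_spec(grid)) {
  d <- grid$dims
  lab <- array(1L, d)                        # gray everywhere inside the box
  # 1-voxel background border (keeps regions off the volume edge)
  lab[c(1, d[1]), , ] <- 0L
  lab[, c(1, d[2]), ] <- 0L
  lab[, , c(1, d[3])] <- 0L
  # white-matter and CSF slabs in the inferior part of the volume
  # slabs at least 3 voxels thick so a 3x3x3 erosion retains a core
  zw <- 2:max(4, round(d[3] * 0.25))
  zc <- (max(zw) + 1):(max(zw) + max(3, round(d[3] * 0.1)))
  lab[2:(d[1] - 1), 2:(d[2] - 1), zw] <- 2L
  lab[2:(d[1] - 1), 2:(d[2] - 1), zc] <- 3L

  if (nrow(region_spec) > 0) {
    if (anyDuplicated(region_spec$label_code))
      stop("region label codes must be unique")
    claimed <- array(0L, d)
    ax <- lapply(1:3, function(a) ((seq_len(d[a])) - 1) * grid$voxel_size_mm)
    for (i in seq_len(nrow(region_spec))) {
      ctr <- c(region_spec$cx[i], region_spec$cy[i], region_spec$cz[i])
      if (any(ctr < 1) || any(ctr > d))
        stop(sprintf("region '%s' center lies outside the grid",
                     region_spec$region_name[i]))
      r <- region_spec$radius_mm[i]
      dx <- ax[[1]] - ax[[1]][ctr[1]]
      dy <- ax[[2]] - ax[[2]][ctr[2]]
      dz <- ax[[3]] - ax[[3]][ctr[3]]
      sph <- outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= r^2
      sph <- sph & lab == 1L            # regions live in gray matter only
      hit <- claimed[sph]
      if (any(hit > 0)) {
        other <- region_spec$region_name[match(hit[hit > 0][1],
                                               region_spec$label_code)]
        stop(sprintf("regions '%s' and '%s' overlap",
                     region_spec$region_name[i], other))
      }
      claimed[sph] <- region_spec$label_code[i]
    }
    lab[claimed > 0] <- claimed[claimed > 0]
    missing <- setdiff(region_spec$label_code, unique(as.vector(lab)))
    if (length(missing))
      stop(sprintf("region(s) %s produced no voxels",
                   paste(region_spec$region_name[
                     match(missing, region_spec$label_code)], collapse = ", ")))
  }
  structure(list(grid = grid, labels = lab,
                 codes = c(background = 0L, gray = 1L, white = 2L, csf = 3L),
                 region_table = region_spec),
            class = "tissue_atlas")
}

#' Extract a logical mask from a tissue atlas
#'
#' @param atlas A `tissue_atlas`.
#' @param what One of `"gray"`, `"white"`, `"csf"`, `"background"`,
#'   `"brain"` (gray plus all named regions) or a region name from the
#'   atlas's region table.
#' @return A logical array on the atlas grid.
#' @export
atlas_mask <- function(atlas, what) {
  stopifnot(inherits(atlas, "tissue_atlas"))
  if (what %in% names(atlas$codes))
    return(atlas$labels == atlas$codes[[what]])
  if (what == "brain")
    return(atlas$labels == atlas$codes[["gray"]] |
             array(atlas$labels %in% atlas$region_table$label_code,
                   dim(atlas$labels)))
  i <- match(what, atlas$region_table$region_name)
  if (is.na(i)) stop(sprintf("unknown atlas mask '%s'", what))
  atlas$labels == atlas$region_table$label_code[i]
}

#' @export
print.tissue_atlas <- function(x, ...) {
  cat(sprintf("<tissue_atlas> %d x %d x %d voxels (%.3g mm), %d named regions\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$voxel_size_mm, nrow(x$region_table)))
  if (nrow(x$region_table) > 0) {
    n <- vapply(x$region_table$label_code,
                function(k) sum(x$labels == k), integer(1))
    cat(paste(sprintf("  %-16s %4d voxels", x$region_table$region_name, n),
              collapse = "\n"), "\n")
  }
  invisible(x)
}
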