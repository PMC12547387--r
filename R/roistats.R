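# ROI construction (spheres at peaks, atlas/contrast intersections) and
# per-subcategory t-profile extraction.

#' Build a spherical ROI on the functional grid
#'
#' Voxels whose centers lie within `diameter_mm / 2` of the center voxel's
#' center. At the study's 4.5 mm diameter on a 1.5 mm grid this yields
#' exactly 19 voxels. ROIs clipped at the grid edge raise a warning.
#'
#' @param center Voxel indices (length 3).
#' @param diameter_mm Sphere diameter in mm (> 0).
#' @param grid A [volume_grid()].
#' @param name Optional ROI name.
#' @return An object of class `roi`: `name`, `center`, `voxels` (index
#'   matrix), `lin` (linear indices), `diameter_mm`, `mode`.
#' @export
sphere_roi <- function(center, diameter_mm = 4.5, grid, name = NULL) {
  stopifnot(length(center) == 3, diameter_mm > 0)
  center <- as.integer(round(center))
  if (any(center < 1) || any(center > grid$dims))
    stop("sphere center lies outside the grid")
  vs <- grid$voxel_size_mm
  r <- diameter_mm / 2
  mo <- floor(r / vs)
  off <- as.matrix(expand.grid(x = -mo:mo, y = -mo:mo, z = -mo:mo))
  off <- off[rowSums(off^2) * vs^2 <= r^2 + 1e-9, , drop = FALSE]
  vox <- sweep(off, 2, center, "+")
  inside <- vox[, 1] >= 1 & vox[, 1] <= grid$dims[1] &
            vox[, 2] >= 1 & vox[, 2] <= grid$dims[2] &
            vox[, 3] >= 1 & vox[, 3] <= grid$dims[3]
  if (!all(inside))
    warning(sprintf("ROI%s clipped at grid edge (%d of %d voxels kept)",
                    if (is.null(name)) "" else paste0(" ", name),
                    sum(inside), length(inside)))
  vox <- vox[inside, , drop = FALSE]
  lin <- vox[, 1] + (vox[, 2] - 1) * grid$dims[1] +
    (vox[, 3] - 1) * grid$dims[1] * grid$dims[2]
  structure(list(name = name, center = center, voxels = vox, lin = lin,
                 diameter_mm = diameter_mm, mode = "sphere", grid = grid),
            class = "roi")
}

#' Build an intersection ROI (atlas field x subject significance)
#'
#' @param field_mask Logical array: the atlas-defined field.
#' @param sig_mask Logical array: the subject's significant voxels.
#' @param name ROI name (used in the error when the intersection is empty).
#' @param grid A [volume_grid()].
#' @return An object of class `roi` with mode `"intersection"`.
#' @export
intersection_roi <- function(field_mask, sig_mask, name, grid) {
  both <- field_mask & sig_mask
  if (!any(both))
    stop(sprintf("empty intersection for ROI '%s'", name))
  lin <- which(both)
  structure(list(name = name, center = NULL,
                 voxels = arrayInd(lin, grid$dims), lin = lin,
                 diameter_mm = NA_real_, mode = "intersection", grid = grid),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s (%s): %d voxels%s\n",
              x$name %||% "<unnamed>", x$mode, length(x$lin),
              if (x$mode == "sphere")
                sprintf(", diameter %.2g mm at (%d, %d, %d)", x$diameter_mm,
                        x$center[1], x$center[2], x$center[3]) else ""))
  invisible(x)
}

# Global-maximum voxel of a t map restricted to a label mask.
peak_in_mask <- function(tmap, mask) {
  tvol <- if (is.null(dim(tmap))) array(tmap, dim(mask)) else tmap
  vox <- which(mask)
  if (!length(vox)) stop("peak search mask is empty")
  pk <- vox[which.max(tvol[vox])]
  arrayInd(pk, dim(mask))[1, ]
}

#' Define the study's ROI set
#'
#' Per subject, an A1 intersection ROI (atlas A1-like field x the subject's
#' significant Sound-vs-Silence mask, per hemisphere). At the group level,
#' fixed-diameter spheres centered on peak activations: IC from the
#' random-effects Sound-vs-Silence map, F5 and pMTG (per hemisphere) from
#' the fixed-effects Macaque-vs-NonVocal map, and an aTVA-like sphere at
#' the phantom's configured region center.
#'
#' @param atlas A `tissue_atlas`.
#' @param group_svs Random-effects Sound-vs-Silence `group_result`.
#' @param group_mvn Fixed-effects Macaque-vs-NonVocal `group_result`.
#' @param subject_sig_masks Named list (by subject) of logical arrays of
#'   significant Sound-vs-Silence voxels.
#' @param diameter_mm Sphere diameter (default 4.5 mm).
#' @return List with `group` (named list of sphere `roi`s) and `subject`
#'   (named list of per-subject lists of intersection `roi`s).
#' @export
define_rois <- function(atlas, group_svs, group_mvn, subject_sig_masks,
                        diameter_mm = 4.5) {
  grid <- atlas$grid
  grp <- list()
  grp[["IC-like"]] <- sphere_roi(
    peak_in_mask(map_volume(group_svs), atlas_mask(atlas, "IC-like")),
    diameter_mm, grid, "IC-like")
  for (rn in c("F5-like-left", "F5-like-right",
               "pMTG-like-left", "pMTG-like-right"))
    grp[[rn]] <- sphere_roi(
      peak_in_mask(map_volume(group_mvn), atlas_mask(atlas, rn)),
      diameter_mm, grid, rn)
  at <- atlas$region_table
  av <- match("aTVA-like", at$region_name)
  if (!is.na(av))
    grp[["aTVA-like"]] <- sphere_roi(c(at$cx[av], at$cy[av], at$cz[av]),
                                     diameter_mm, grid, "aTVA-like")
  subj <- lapply(subject_sig_masks, function(sig) {
    out <- list()
    for (hemi in c("A1-like-left", "A1-like-right"))
      out[[hemi]] <- intersection_roi(atlas_mask(atlas, hemi), sig,
                                      paste0("A1:", hemi), grid)
    out
  })
  list(group = grp, subject = subj)
}

#' Extract a per-subject subcategory t profile from an ROI
#'
#' @param subcat_maps Named list of 8 subcategory-vs-silence `contrast_map`s
#'   for one subject.
#' @param roi A `roi`.
#' @param statistic `"mean"` (default) or `"peak"` aggregation over ROI
#'   voxels.
#' @return Named numeric vector of 8 t values.
#' @export
extract_profile <- function(subcat_maps, roi, statistic = c("mean", "peak")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(roi, "roi"))
  vapply(subcat_maps, function(m) {
    if (max(roi$lin) > length(m$t))
      stop("ROI lies outside the map grid")
    v <- m$t[roi$lin]
    if (statistic == "mean") mean(v, na.rm = TRUE) else v[which.max(abs(v))]
  }, numeric(1))
}

#' Group subcategory profile: mean and SEM across subjects
#'
#' @param values Matrix (subjects x 8 subcategories, named columns) or list
#'   of per-subject named vectors from [extract_profile()].
#' @param roi_name Optional label.
#' @return An object of class `subcategory_profile`: `table` (subcategory,
#'   mean, sem), `values` (the subject x subcategory matrix).
#' @export
group_profile <- function(values, roi_name = NULL) {
  if (is.list(values)) values <- do.call(rbind, values)
  values <- as.matrix(values)
  if (nrow(values) < 2)
    stop("group profile needs >= 2 subjects (SEM undefined for one)")
  mu <- colMeans(values)
  sem <- apply(values, 2, stats::sd) / sqrt(nrow(values))
  structure(list(roi = roi_name,
                 table = data.frame(subcategory = colnames(values) %||%
                                      sprintf("c%d", seq_along(mu)),
                                    mean = unname(mu), sem = unname(sem),
                                    stringsAsFactors = FALSE),
                 values = values),
            class = "subcategory_profile")
}

#' @export
print.subcategory_profile <- function(x, ...) {
  cat(sprintf("<subcategory_profile>%s %d subjects\n",
              if (is.null(x$roi)) "" else paste0(" ", x$roi),
              nrow(x$values)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.subcategory_profile <- function(x, ...) {
  tb <- x$table
  bp <- graphics::barplot(tb$mean, names.arg = tb$subcategory, las = 2,
                          ylab = "t value (mean over subjects)",
                          main = x$roi %||% "subcategory profile",
                          ylim = range(0, tb$mean - 1.5 * tb$sem,
                                       tb$mean + 1.5 * tb$sem), ...)
  graphics::arrows(bp, tb$mean - tb$sem, bp, tb$mean + tb$sem,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Write profiles as tab-separated text
#' @param profile A `subcategory_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(cbind(roi = profile$roi %||% NA, profile$table), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
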