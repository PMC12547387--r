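#' Define an isotropic volume grid
#'
#' The sampling lattice of the functional volumes. Isotropy is enforced (a
#' single scalar voxel size), matching the 1.5 mm isotropic functional
#' resolution the pipeline is designed around.
#'
#' @param dims Integer vector of length 3: voxels per axis (each >= 8).
#' @param voxel_size_mm Positive scalar voxel edge length in mm.
#' @param origin Numeric length-3 mm offset of the center of voxel (1,1,1).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size_mm = 1.5, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 8))
    stop("`dims` must be 3 integers, each >= 8 for simulation use")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1 ||
      voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a single positive number")
  stopifnot(length(origin) == 3)
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm,
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g mm isotropic\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_mm))
  invisible(x)
}

# mm coordinates of voxel centers for a matrix of voxel indices (rows = voxels)
voxel_to_mm <- function(idx, grid) {
  idx <- matrix(idx, ncol = 3)
  sweep((idx - 1) * grid$voxel_size_mm, 2, grid$origin, "+")
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) && abs(a$voxel_size_mm - b$voxel_size_mm) < tol
}
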