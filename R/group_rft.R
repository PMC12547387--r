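# Fixed/random-effects group maps and Gaussian-random-field multiple
# comparison control (peak thresholds, cluster-size correction).

#' Fixed-effects group map
#'
#' Inverse-variance combination of subject-level contrast maps (same rule as
#' [combine_runs()], applied across subjects); degrees of freedom are summed.
#'
#' @param maps List of >= 2 subject-level `contrast_map`s on one grid.
#' @return An object of class `group_result` (also a `contrast_map`).
#' @export
fixed_effects_group <- function(maps) {
  if (length(maps) < 2) stop("fixed-effects group map needs >= 2 subjects")
  out <- combine_runs(maps)
  out$model <- "fixed"
  out$n_subjects <- length(maps)
  class(out) <- c("group_result", class(out))
  out
}

#' Random-effects group map
#'
#' One-sample analysis on the subject-level effect maps: `t = mean /
#' (sd / sqrt(n))` with `df = n - 1`, where sd is the between-subject
#' standard deviation. Voxels with zero between-subject variance and nonzero
#' mean are capped at a large finite t with a warning.
#'
#' @param maps List of >= 3 subject-level `contrast_map`s on one grid.
#' @return An object of class `group_result`.
#' @export
random_effects_group <- function(maps) {
  if (length(maps) < 3)
    stop("random-effects group map needs >= 3 subjects (df too small)")
  g0 <- maps[[1]]$grid
  n <- length(maps)
  E <- matrix(vapply(maps, function(m) m$effect,
                     numeric(length(maps[[1]]$effect))), ncol = n)
  mu <- rowMeans(E)
  sdv <- sqrt(rowSums((E - mu)^2) / (n - 1))
  se <- sdv / sqrt(n)
  t <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * 1e6))
  if (any(se == 0 & mu != 0, na.rm = TRUE))
    warning("zero between-subject variance at some voxels; t capped at 1e6")
  structure(list(effect = mu, sd = sdv, t = t, df = n - 1, grid = g0,
                 name = maps[[1]]$name, model = "random", n_subjects = n),
            class = c("group_result", "contrast_map"))
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s effects%s: %d subjects, df = %s, max t = %.2f\n",
              x$model, if (is.null(x$name)) "" else paste0(" (", x$name, ")"),
              x$n_subjects, format(x$df), max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' Estimate field smoothness and resel counts
#'
#' FWHM per axis is estimated from the lag-1 spatial autocorrelation of
#' standardized residual images under a Gaussian autocorrelation model
#' (`r(d) = exp(-d^2 / (4 s^2))` for a field smoothed with a Gaussian of sd
#' `s`), or taken from a declared applied kernel. Resel counts follow the
#' lattice edge/face/cube counting of the mask, with the top-order count
#' taken as `volume / prod(FWHM)`.
#'
#' @param residuals Optional 4-D array (or V x m matrix) of residual images
#'   used for estimation; omit when declaring `fwhm_mm`.
#' @param mask Logical 3-D array defining the search region.
#' @param grid A [volume_grid()].
#' @param fwhm_mm Optional declared FWHM (scalar or per-axis), bypassing
#'   estimation.
#' @return An object of class `smoothness_estimate`: `fwhm_mm` (length 3),
#'   `resels` (R0..R3), `n_voxels`, `volume_mm3`.
#' @export
estimate_smoothness <- function(residuals = NULL, mask, grid,
                                fwhm_mm = NULL) {
  if (!any(mask)) stop("mask is empty")
  vs <- grid$voxel_size_mm
  if (!is.null(fwhm_mm)) {
    fwhm <- rep(fwhm_mm, length.out = 3)
  } else {
    if (is.null(residuals))
      stop("supply `residuals` or a declared `fwhm_mm`")
    R <- if (length(dim(residuals)) == 4)
      matrix(residuals, prod(dim(residuals)[1:3])) else as.matrix(residuals)
    if (ncol(R) < 3) stop("need residual set with df >= 3")
    fwhm <- numeric(3)
    d <- dim(mask)
    for (ax in 1:3) {
      num <- den <- 0
      off <- c(0, 0, 0); off[ax] <- 1
      m2 <- mask & shift_array(mask, -off, FALSE)   # voxel and +1 neighbour
      i1 <- which(m2)
      i2 <- which(shift_array(m2, off, FALSE))
      for (j in seq_len(ncol(R))) {
        z <- R[, j]
        z <- z - mean(z[mask]); z <- z / stats::sd(z[mask])
        num <- num + sum(z[i1] * z[i2])
        den <- den + length(i1)
      }
      r1 <- num / den
      fwhm[ax] <- if (r1 <= 0.05) vs else
        vs * sqrt(8 * log(2)) * sqrt(-1 / (4 * log(r1)))
    }
  }
  if (any(fwhm <= 0)) stop("FWHM must be positive")
  counts <- mask_resel_counts(mask)
  r <- vs / fwhm
  ex <- counts$edges[1]; ey <- counts$edges[2]; ez <- counts$edges[3]
  fxy <- counts$faces[1]; fxz <- counts$faces[2]; fyz <- counts$faces[3]
  cub <- counts$cubes
  resels <- c(R0 = counts$euler,
              R1 = (ex - fxy - fxz + cub) * r[1] +
                   (ey - fxy - fyz + cub) * r[2] +
                   (ez - fxz - fyz + cub) * r[3],
              R2 = (fxy - cub) * r[1] * r[2] + (fxz - cub) * r[1] * r[3] +
                   (fyz - cub) * r[2] * r[3],
              R3 = counts$n * prod(r))
  structure(list(fwhm_mm = fwhm, resels = resels, n_voxels = counts$n,
                 volume_mm3 = counts$n * vs^3),
            class = "smoothness_estimate")
}

# Lattice counts for resel computation: voxels, edges per axis, faces per
# plane (xy, xz, yz), cubes, and the Euler characteristic.
mask_resel_counts <- function(mask) {
  sh <- function(...) shift_array(mask, -c(...), FALSE)
  ex <- sum(mask & sh(1, 0, 0))
  ey <- sum(mask & sh(0, 1, 0))
  ez <- sum(mask & sh(0, 0, 1))
  fxy <- sum(mask & sh(1, 0, 0) & sh(0, 1, 0) & sh(1, 1, 0))
  fxz <- sum(mask & sh(1, 0, 0) & sh(0, 0, 1) & sh(1, 0, 1))
  fyz <- sum(mask & sh(0, 1, 0) & sh(0, 0, 1) & sh(0, 1, 1))
  cub <- sum(mask & sh(1, 0, 0) & sh(0, 1, 0) & sh(0, 0, 1) &
               sh(1, 1, 0) & sh(1, 0, 1) & sh(0, 1, 1) & sh(1, 1, 1))
  n <- sum(mask)
  list(n = n, edges = c(ex, ey, ez), faces = c(fxy, fxz, fyz), cubes = cub,
       euler = n - ex - ey - ez + fxy + fxz + fyz - cub)
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf(paste0("<smoothness_estimate> FWHM = %s mm, %d voxels ",
                     "(%.0f mm^3), resels R0..R3 = %s\n"),
              paste(signif(x$fwhm_mm, 3), collapse = " x "), x$n_voxels,
              x$volume_mm3, paste(signif(x$resels, 4), collapse = ", ")))
  invisible(x)
}

# Euler-characteristic densities of a t field (Gaussian field when
# df = Inf), dimensions 0..3.
ec_density <- function(t, df, dim) {
  gaussian <- !is.finite(df)
  fl <- if (gaussian) exp(-t^2 / 2) else (1 + t^2 / df)^(-(df - 1) / 2)
  l2 <- 4 * log(2)
  switch(as.character(dim),
    "0" = if (gaussian) stats::pnorm(t, lower.tail = FALSE)
          else stats::pt(t, df, lower.tail = FALSE),
    "1" = sqrt(l2) / (2 * pi) * fl,
    "2" = {
      ct <- if (gaussian) 1 else
        exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2)
      l2 / (2 * pi)^1.5 * ct * t * fl
    },
    "3" = l2^1.5 / (2 * pi)^2 * fl *
      (if (gaussian) t^2 - 1 else (df - 1) / df * t^2 - 1),
    stop("dim must be 0..3"))
}

# Expected Euler characteristic of the excursion set above t.
expected_ec <- function(t, df, resels) {
  vapply(t, function(tt)
    sum(vapply(0:3, function(d) resels[d + 1] * ec_density(tt, df, d),
               numeric(1))), numeric(1))
}

#' Family-wise peak threshold from Gaussian random field theory
#'
#' The smallest t at which the expected Euler characteristic of the
#' thresholded t field drops to `alpha`, found by monotone root finding over
#' the EC densities weighted by the search region's resel counts.
#'
#' @param df Degrees of freedom of the t field (`Inf` for a Gaussian field).
#' @param smoothness A [estimate_smoothness()] result (or a length-4 resel
#'   vector R0..R3).
#' @param alpha Family-wise error level in (0, 1).
#' @param cap Upper bound for the root search; exceeding it is an error.
#' @return The peak threshold t*.
#' @export
peak_threshold <- function(df, smoothness, alpha = 0.05, cap = 50) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (is.finite(df) && df <= 4) stop("`df` must exceed 4")
  resels <- if (inherits(smoothness, "smoothness_estimate"))
    smoothness$resels else as.numeric(smoothness)
  stopifnot(length(resels) == 4)
  f <- function(t) expected_ec(t, df, resels) - alpha
  if (f(cap) > 0)
    stop(sprintf("no peak threshold below cap = %g at alpha = %g", cap,
                 alpha))
  # the expected EC is non-monotone at low t; locate the upper-tail
  # crossing (the largest t with EC >= alpha) on a coarse grid, then refine
  ts <- seq(0.5, cap, by = 0.05)
  vals <- f(ts)
  above <- which(vals >= 0)
  if (!length(above)) {
    # search region so small that even low thresholds control alpha; fall
    # back to the pointwise upper-alpha quantile
    return(if (is.finite(df)) stats::qt(1 - alpha, df)
           else stats::qnorm(1 - alpha))
  }
  i <- max(above)
  if (i == length(ts)) return(ts[i])
  stats::uniroot(f, c(ts[i], ts[i + 1]), tol = 1e-8)$root
}

#' Label connected suprathreshold clusters
#'
#' Flood-fill connected-component labeling of a logical 3-D array.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6 (faces; default) or 26 (faces, edges, corners).
#' @return Integer array of cluster labels (0 = background), with labels
#'   ordered by discovery.
#' @export
label_clusters <- function(mask, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 26), length(dim(mask)) == 3)
  d <- dim(mask)
  offs <- if (connectivity == 6)
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  else as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))[
    -14, , drop = FALSE]  # drop the zero offset
  lab <- array(0L, d)
  todo <- which(mask)
  nextlab <- 0L
  for (v in todo) {
    if (lab[v] != 0L) next
    nextlab <- nextlab + 1L
    lab[v] <- nextlab
    frontier <- v
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        sweep(co, 2, offs[i, ], "+")))
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1) * d[1] +
                      (nb[, 3] - 1) * d[1] * d[2])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nextlab
      frontier <- lin
    }
  }
  lab
}

#' Cluster-size multiple-comparison correction
#'
#' Thresholds the t map at the cluster-forming threshold (the upper-tail
#' quantile at `cluster_forming_p`; standard-normal quantile in the Gaussian
#' limit, which at p = 0.001 gives t = 3.09), labels suprathreshold
#' clusters, and computes the minimum significant cluster extent from the
#' GRF expected-cluster-size distribution at family level `alpha`. Clusters
#' survive by extent, or by containing a voxel above the GRF peak threshold.
#'
#' @param tmap Numeric 3-D array (or vector matching the mask grid) of t
#'   values.
#' @param mask Logical 3-D search-region mask.
#' @param smoothness A [estimate_smoothness()] result.
#' @param df Degrees of freedom of the map.
#' @param cluster_forming_p Primary (uncorrected) threshold probability.
#' @param alpha Family-wise level for cluster extent and peak threshold.
#' @param connectivity 6 or 26.
#' @param gaussian_limit Use the standard-normal quantile/tail for the
#'   cluster-forming threshold (the convention when df is large).
#' @return An object of class `threshold_result`: thresholds, minimum
#'   extent, cluster table (label, n_voxels, peak_t, peak voxel and mm
#'   coordinates, significant flag) and the surviving-voxel mask.
#' @export
cluster_correct <- function(tmap, mask, smoothness, df,
                            cluster_forming_p = 0.001, alpha = 0.05,
                            connectivity = 6, gaussian_limit = TRUE) {
  grid_dims <- dim(mask)
  tvol <- if (is.null(dim(tmap))) array(tmap, grid_dims) else tmap
  stopifnot(all(dim(tvol) == grid_dims))
  t_c <- if (gaussian_limit) stats::qnorm(1 - cluster_forming_p)
         else stats::qt(1 - cluster_forming_p, df)
  tail_p <- function(t) if (gaussian_limit)
    stats::pnorm(t, lower.tail = FALSE) else
      stats::pt(t, df, lower.tail = FALSE)
  resels <- smoothness$resels
  ec_df <- if (gaussian_limit) Inf else df
  em <- max(expected_ec(t_c, ec_df, resels), 1e-12)   # expected cluster count
  en <- smoothness$n_voxels * tail_p(t_c)             # expected voxel count
  nbar <- en / em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  lnarg <- em / (-log(1 - alpha))
  k_min <- if (lnarg <= 1) 1L else
    max(1L, as.integer(ceiling((log(lnarg) / beta)^1.5)))
  t_star <- peak_threshold(ec_df, smoothness, alpha)

  supra <- mask & !is.na(tvol) & tvol > t_c
  labs <- label_clusters(supra, connectivity)
  ids <- setdiff(sort(unique(as.vector(labs))), 0L)
  rows <- lapply(ids, function(id) {
    vox <- which(labs == id)
    pk <- vox[which.max(tvol[vox])]
    co <- arrayInd(pk, grid_dims)
    data.frame(label = id, n_voxels = length(vox), peak_t = max(tvol[vox]),
               peak_x = co[1], peak_y = co[2], peak_z = co[3])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_voxels = integer(0),
               peak_t = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0))
  tab$significant <- tab$n_voxels >= k_min | tab$peak_t >= t_star
  surviving <- array(FALSE, grid_dims)
  if (any(tab$significant))
    surviving[labs %in% tab$label[tab$significant]] <- TRUE
  structure(list(alpha = alpha, peak_threshold = t_star,
                 cluster_forming_t = t_c, min_cluster_extent = k_min,
                 clusters = tab, surviving = surviving, labels = labs,
                 smoothness = smoothness, df = df),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(paste0("<threshold_result> alpha = %.3g: cluster-forming ",
                     "t = %.2f, min extent = %d voxels, peak t* = %.2f; ",
                     "%d cluster(s), %d significant\n"),
              x$alpha, x$cluster_forming_t, x$min_cluster_extent,
              x$peak_threshold, nrow(x$clusters), sum(x$clusters$significant)))
  invisible(x)
}

#' Export a cluster table as tab-separated text
#' @param result A `threshold_result`.
#' @param path Output path.
#' @param grid Optional [volume_grid()] to add mm peak coordinates.
#' @export
write_cluster_table <- function(result, path, grid = NULL) {
  tab <- result$clusters
  if (!is.null(grid) && nrow(tab)) {
    mm <- voxel_to_mm(as.matrix(tab[, c("peak_x", "peak_y", "peak_z")]), grid)
    tab$x_mm <- mm[, 1]; tab$y_mm <- mm[, 2]; tab$z_mm <- mm[, 3]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
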