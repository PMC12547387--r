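# Spatial smoothing, per-run prewhitened GLM, contrasts, run combination.

# Bias correction for the residual-based AR(1) estimator. OLS residuals
# r = M y (M the residual-forming matrix) underestimate the lag-1
# autocorrelation because projection removes low-frequency structure. For
# AR(1) noise with covariance V(rho)_{ij} = rho^|i-j|,
#   E[sum r_t r_{t+1}] = tr(M A M V),  E[sum r_t^2] = tr(M V),
# with A the symmetric lag-1 averaging matrix. Both traces are polynomials
# in rho whose coefficients are diagonal sums of M A M and M, so the
# expectation curve f(rho) is cheap to tabulate and invert.
ar1_bias_inverse <- function(X) {
  n <- nrow(X)
  H <- X %*% solve(crossprod(X), t(X))
  M <- diag(n) - H
  A <- matrix(0, n, n)
  A[cbind(1:(n - 1), 2:n)] <- 0.5
  A[cbind(2:n, 1:(n - 1))] <- 0.5
  K <- M %*% A %*% M
  diag_sums <- function(B) {
    vapply(0:(n - 1), function(d) {
      i <- seq_len(n - d)
      s <- sum(B[cbind(i, i + d)])
      if (d == 0) s else 2 * s
    }, numeric(1))
  }
  a <- diag_sums(K)
  b <- diag_sums(M)
  grid <- seq(-0.98, 0.98, by = 0.005)
  pows <- outer(grid, 0:(n - 1), "^")
  f <- as.vector(pows %*% a) / as.vector(pows %*% b)
  function(rho_raw) {
    out <- stats::approx(f, grid, xout = rho_raw, rule = 2)$y
    pmin(pmax(out, -0.99), 0.99)
  }
}

# 1-D Gaussian smoothing operator (d x d matrix) with normalized kernel.
# boundary = "renorm": the truncated symmetric kernel matrix is made doubly
# stochastic by symmetric (Sinkhorn) rescaling, so constants AND the volume
# mean are both preserved exactly. boundary = "wrap": periodic convolution
# (used to generate stationary smooth noise fields).
smoothing_operator <- function(d, sigma_vox, boundary = c("renorm", "wrap")) {
  boundary <- match.arg(boundary)
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(((-r):r)^2) / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, d, d)
  for (i in seq_len(d)) for (o in (-r):r) {
    j <- i + o
    if (boundary == "wrap") {
      j <- ((j - 1) %% d) + 1
      K[j, i] <- K[j, i] + w[o + r + 1]
    } else if (j >= 1 && j <= d) {
      K[j, i] <- K[j, i] + w[o + r + 1]
    }
  }
  if (boundary == "renorm") {
    # symmetric scaling D K D to a doubly stochastic operator
    s <- rep(1, d)
    for (it in seq_len(200)) {
      rs <- as.vector(K %*% s) * s
      if (max(abs(rs - 1)) < 1e-13) break
      s <- s / sqrt(rs)
    }
    K <- K * tcrossprod(s)
  }
  K
}

# Apply separable Gaussian smoothing to one 3-D array.
smooth_volume3d <- function(vol, fwhm_mm, voxel_size_mm,
                            boundary = "renorm") {
  if (fwhm_mm == 0) return(vol)
  d <- dim(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  for (ax in 1:3) {
    K <- smoothing_operator(d[ax], sigma, boundary)
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    v <- array(K %*% matrix(v, d[ax]), d[perm])
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Spatially smooth a 4-D image
#'
#' Convolves each volume with a separable 3-D Gaussian of the given FWHM.
#' The normalized kernel is renormalized at the volume boundary so that both
#' constant images and each volume's mean are preserved exactly. The study
#' convention is a FWHM of twice the functional voxel size (3 mm at 1.5 mm
#' resolution).
#'
#' @param image A `run_image`, or a 3-D/4-D array (then supply `grid`).
#' @param fwhm_mm Full width at half maximum in mm (>= 0; 0 is the identity).
#' @param grid A [volume_grid()] (taken from `image` when it is a
#'   `run_image`).
#' @param boundary `"renorm"` (default: truncated kernel symmetrically renormalized so constants and the volume mean are preserved) or `"wrap"` (periodic; useful for
#'   generating stationary smooth noise fields).
#' @return Same type as the input.
#' @export
smooth_volumes <- function(image, fwhm_mm = 3.0, grid = NULL,
                           boundary = "renorm") {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  is_run <- inherits(image, "run_image")
  arr <- if (is_run) image$data else image
  vs <- if (is_run) image$grid$voxel_size_mm
        else if (!is.null(grid)) grid$voxel_size_mm
        else stop("supply `grid` when `image` is a bare array")
  if (fwhm_mm == 0) return(image)
  nd <- length(dim(arr))
  if (nd == 3) {
    out <- smooth_volume3d(arr, fwhm_mm, vs, boundary)
  } else if (nd == 4) {
    out <- arr
    for (tt in seq_len(dim(arr)[4]))
      out[, , , tt] <- smooth_volume3d(arr[, , , tt], fwhm_mm, vs, boundary)
  } else stop("`image` must be a 3-D or 4-D array")
  if (is_run) { image$data <- out; image } else out
}

#' Fit the per-run voxelwise GLM with AR(1) prewhitening
#'
#' Ordinary least squares first; the AR(1) coefficient is then estimated per
#' voxel from the residuals, optionally regularized by spatial smoothing
#' (3 mm by default, the standard stabilization), data and design are
#' prewhitened, and the model refit. Voxels are grouped into AR-coefficient
#' bins of width 0.01 so the whitened normal equations are solved once per
#' bin. Intensities are converted to percent signal change about each
#' voxel's temporal mean before fitting (`scale = "psc"`), so task
#' coefficients are in percent-signal-change units and, because the task
#' regressors embed the reversed-sign response function, carry *neural*
#' polarity (activation positive).
#'
#' @param image A `run_image` or an n x V matrix (volumes in rows).
#' @param design A [assemble_design_matrix()] result.
#' @param ar_order 0 (plain OLS) or 1 (AR(1) prewhitening).
#' @param smooth_ar_fwhm_mm FWHM for spatial regularization of the AR
#'   coefficient map (0 disables; ignored for bare matrices without a grid).
#' @param scale `"psc"` (percent signal change) or `"none"`.
#' @param ar_bias_correct Correct the downward bias of the residual-based
#'   AR(1) estimate induced by the regression projection (recommended).
#' @return An object of class `glm_fit`: `beta` (p x V), `sigma2`, `rho`,
#'   `df`, per-bin whitened `(X'X)^{-1}` matrices, column metadata, grid.
#' @export
fit_run_glm <- function(image, design, ar_order = 1,
                        smooth_ar_fwhm_mm = 3.0, scale = c("psc", "none"),
                        ar_bias_correct = TRUE) {
  scale <- match.arg(scale)
  stopifnot(inherits(design, "design_matrix"), ar_order %in% c(0, 1))
  grid <- if (inherits(image, "run_image")) image$grid else NULL
  Y <- if (inherits(image, "run_image")) image_matrix(image) else
    as.matrix(image)
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n)
    stop(sprintf("image has %d volumes but design has %d rows", nrow(Y), n))
  if (n <= p) stop("fewer volumes than design columns")
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  V <- ncol(Y)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- n - p

  if (ar_order == 0) {
    rho <- rep(0, V)
  } else {
    den <- colSums(res^2)
    rho <- ifelse(den > 0, colSums(res[-1, , drop = FALSE] *
                                     res[-n, , drop = FALSE]) / den, 0)
    if (ar_bias_correct) rho <- ar1_bias_inverse(X)(rho)
    if (smooth_ar_fwhm_mm > 0 && !is.null(grid))
      rho <- as.vector(smooth_volume3d(array(rho, grid$dims),
                                       smooth_ar_fwhm_mm,
                                       grid$voxel_size_mm))
    rho <- pmin(pmax(rho, -0.99), 0.99)
  }
  bin <- as.integer(round(rho * 100))
  ubin <- sort(unique(bin))
  xtxinv <- vector("list", length(ubin))
  names(xtxinv) <- as.character(ubin)
  sigma2 <- numeric(V)
  for (b in seq_along(ubin)) {
    r <- ubin[b] / 100
    vox <- which(bin == ubin[b])
    if (r == 0) { Xw <- X; Yw <- Y[, vox, drop = FALSE] }
    else {
      w1 <- sqrt(1 - r^2)
      Xw <- rbind(X[1, ] * w1, X[-1, ] - r * X[-n, ])
      Yg <- Y[, vox, drop = FALSE]
      Yw <- rbind(Yg[1, ] * w1, Yg[-1, , drop = FALSE] -
                    r * Yg[-n, , drop = FALSE])
    }
    qw <- qr(Xw)
    beta[, vox] <- qr.coef(qw, Yw)
    rw <- Yw - Xw %*% beta[, vox, drop = FALSE]
    sigma2[vox] <- colSums(rw^2) / df
    xtxinv[[b]] <- if (identical(qw$pivot, seq_len(p)))
      chol2inv(qr.R(qw)) else solve(crossprod(Xw))
  }
  psc_scale <- rep(1, V)
  if (scale == "psc") {
    # percent signal change relative to the GLM's own baseline estimate
    # (the constant coefficient = silence baseline), which unlike the raw
    # temporal mean is not depressed by the task response itself
    b0 <- beta[match("constant", design$meta$name), ]
    psc_scale <- ifelse(is.finite(b0) & b0 > 0, 100 / b0, NA_real_)
    beta <- sweep(beta, 2, psc_scale, "*")
  }
  structure(list(beta = beta, sigma2 = sigma2, rho = rho, df = df,
                 xtxinv = xtxinv, voxel_bin = bin, psc_scale = psc_scale,
                 meta = design$meta, grid = grid, n = n, residual_df = df),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf(paste0("<glm_fit> %d volumes, %d regressors, %d voxels, ",
                     "df = %d, AR(1) range [%.2f, %.2f]\n"),
              x$n, nrow(x$beta), ncol(x$beta), x$df,
              min(x$rho), max(x$rho)))
  invisible(x)
}

#' @export
coef.glm_fit <- function(object, ...) object$beta

#' Contrast weight helpers
#'
#' `sound_vs_silence_weights()` averages all task columns against the
#' implicit silence baseline; `macaque_vs_nonvocal_weights()` contrasts the
#' mean of the macaque-vocalization columns with the mean of the non-vocal
#' columns (requires category metadata on the design).
#'
#' @param design A `design_matrix` (or a `glm_fit`, whose metadata is used).
#' @return Numeric weight vector over the task columns.
#' @export
sound_vs_silence_weights <- function(design) {
  meta <- if (inherits(design, "glm_fit")) design$meta else design$meta
  k <- sum(meta$kind == "task")
  rep(1 / k, k)
}

#' @rdname sound_vs_silence_weights
#' @export
macaque_vs_nonvocal_weights <- function(design) {
  meta <- if (inherits(design, "glm_fit")) design$meta else design$meta
  cat_task <- meta$category[meta$kind == "task"]
  if (anyNA(cat_task))
    stop("design lacks main-category metadata for its task columns")
  w <- ifelse(cat_task == "macaque_vocal", 1 / sum(cat_task == "macaque_vocal"),
              -1 / sum(cat_task == "non_vocal"))
  w
}

#' Compute a contrast map from a fitted GLM
#'
#' `effect = w' beta` per voxel; the standard deviation comes from the
#' whitened covariance, `t = effect / sd`. Weights apply to the task columns
#' only (drift and nuisance weights are zero by construction).
#'
#' @param fit A [fit_run_glm()] result.
#' @param weights Numeric vector, one weight per task column.
#' @param name Optional contrast name.
#' @return An object of class `contrast_map`: `effect`, `sd`, `t` (vectors
#'   over voxels), `df`, `grid`, `name`.
#' @export
compute_contrast <- function(fit, weights, name = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  task_idx <- which(fit$meta$kind == "task")
  if (length(weights) != length(task_idx))
    stop(sprintf("`weights` must have one entry per task column (%d)",
                 length(task_idx)))
  if (all(weights == 0)) stop("all-zero contrast weights")
  w <- numeric(nrow(fit$beta))
  w[task_idx] <- weights
  effect <- as.vector(crossprod(w, fit$beta))
  var_scale <- vapply(fit$xtxinv, function(M) drop(t(w) %*% M %*% w),
                      numeric(1))
  sd <- sqrt(fit$sigma2 *
               var_scale[match(as.character(fit$voxel_bin),
                               names(fit$xtxinv))]) *
    (fit$psc_scale %||% 1)
  t <- ifelse(is.finite(sd) & sd > 0, effect / sd, NA_real_)
  structure(list(effect = effect, sd = sd, t = t, df = fit$df,
                 grid = fit$grid, name = name, weights = weights),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map>%s %d voxels, df = %s, max |t| = %.2f\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$t), format(x$df),
              max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

# 3-D array view of a contrast-map field
map_volume <- function(map, field = "t") {
  if (is.null(map$grid)) stop("contrast map carries no grid")
  array(map[[field]], map$grid$dims)
}

#' Combine a subject's run-level contrast maps (fixed effects)
#'
#' Inverse-variance (precision-weighted) combination:
#' `effect = sum(e_i / s_i^2) / sum(1 / s_i^2)`,
#' `sd = (sum(1 / s_i^2))^(-1/2)`; degrees of freedom are summed.
#'
#' @param maps List of `contrast_map`s on identical grids.
#' @return A subject-level `contrast_map`.
#' @export
combine_runs <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "contrast_map")))
  g0 <- maps[[1]]$grid
  for (m in maps)
    if (!is.null(g0) && !is.null(m$grid) && !same_grid(g0, m$grid))
      stop("contrast maps are on different grids")
  W <- vapply(maps, function(m) ifelse(is.finite(m$sd) & m$sd > 0,
                                       1 / m$sd^2, 0),
              numeric(length(maps[[1]]$effect)))
  E <- vapply(maps, function(m) m$effect, numeric(length(maps[[1]]$effect)))
  W <- matrix(W, ncol = length(maps)); E <- matrix(E, ncol = length(maps))
  sw <- rowSums(W)
  effect <- ifelse(sw > 0, rowSums(W * E) / sw, NA_real_)
  sd <- ifelse(sw > 0, 1 / sqrt(sw), NA_real_)
  structure(list(effect = effect, sd = sd,
                 t = ifelse(sd > 0, effect / sd, NA_real_),
                 df = sum(vapply(maps, function(m) m$df, numeric(1))),
                 grid = g0, name = maps[[1]]$name,
                 n_combined = length(maps)),
            class = "contrast_map")
}
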