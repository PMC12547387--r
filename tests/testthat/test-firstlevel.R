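# Smoothing, GLM fitting, contrasts, run combination.

test_that("smoothing preserves means, is the identity at FWHM 0, and has
          the nominal kernel width", {
  g <- tiny_grid()
  arr <- array(rnorm(prod(g$dims) * 3), c(g$dims, 3))
  expect_identical(smooth_volumes(arr, 0, g), arr)
  sm <- smooth_volumes(arr, 3, g)
  for (tt in 1:3)
    expect_equal(mean(sm[, , , tt]), mean(arr[, , , tt]), tolerance = 1e-6)
  # constant image is unchanged
  const <- array(7, c(g$dims, 2))
  expect_equal(smooth_volumes(const, 3, g), const, tolerance = 1e-6)
  # delta image: measured FWHM of the kernel = 2 voxels +/- 5% at 3 mm
  delta <- array(0, g$dims); delta[8, 8, 7] <- 1
  k <- smooth_volumes(delta, 3, g)
  prof <- k[, 8, 7] / max(k[, 8, 7])
  half <- which(prof >= 0.5)
  # linear interpolation at the half-maximum crossings
  lo <- min(half); hi <- max(half)
  f_lo <- lo - 1 + (0.5 - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f_hi <- hi + (prof[hi] - 0.5) / (prof[hi] - prof[hi + 1])
  expect_equal(f_hi - f_lo, 2, tolerance = 0.05)
  expect_error(smooth_volumes(arr, -1, g), "fwhm")
})

test_that("noise-free runs recover planted coefficients exactly", {
  img <- simulate_run(tiny_atlas(), tiny_design(), clean_truth(), tiny_rf(),
                      seed = 2)
  dm <- tiny_design_matrix()
  fit <- fit_run_glm(img, dm, ar_order = 0)
  a1 <- which(atlas_mask(tiny_atlas(), "A1-like-left"))
  f5 <- which(atlas_mask(tiny_atlas(), "F5-like-left"))
  expect_lt(max(abs(fit$beta["coo", a1] - 1)), 1e-8)
  expect_lt(max(abs(fit$beta["bark", f5] - 0.5)), 1e-8)
  expect_lt(max(abs(fit$beta["natural_living", f5] + 0.5)), 1e-8)
})

test_that("ar_order = 0 fits equal the direct normal-equations oracle", {
  img <- simulate_run(tiny_atlas(), tiny_design(), ground_truth(), tiny_rf(),
                      seed = 3)
  dm <- tiny_design_matrix()
  fit <- fit_run_glm(img, dm, ar_order = 0, scale = "none")
  d4 <- dim(img$data)
  Y <- t(matrix(img$data, prod(d4[1:3]), d4[4]))
  X <- dm$X
  keep <- sample(ncol(Y), 50)   # oracle on a 50-voxel subset
  B <- solve(t(X) %*% X) %*% t(X) %*% Y[, keep]
  expect_lt(max(abs(B - fit$beta[, keep])), 1e-8)
  # residual variance oracle
  res <- Y[, keep] - X %*% B
  s2 <- colSums(res^2) / (nrow(X) - ncol(X))
  expect_lt(max(abs(s2 - fit$sigma2[keep]) / s2), 1e-8)
})

test_that("planted AR(1) coefficients are recovered", {
  img <- simulate_run(tiny_atlas(), tiny_design(), noise_truth(ar1 = 0.4),
                      tiny_rf(), seed = 4)
  dm <- tiny_design_matrix()
  fit <- fit_run_glm(img, dm, ar_order = 1, smooth_ar_fwhm_mm = 0)
  expect_lt(abs(mean(fit$rho) - 0.4), 0.05)
})

test_that("dimension and rank errors are raised", {
  img <- simulate_run(tiny_atlas(), tiny_design(), clean_truth(), tiny_rf(),
                      seed = 5)
  dm <- tiny_design_matrix()
  short <- img; short$data <- img$data[, , , 1:100]
  expect_error(fit_run_glm(short, dm), "volumes")
  few <- matrix(rnorm(5 * 12), 5)
  dm2 <- dm; dm2$X <- dm$X[1:5, ]
  expect_error(fit_run_glm(few, dm2), "fewer volumes")
})

test_that("single-column contrasts match the per-coefficient t oracle", {
  img <- simulate_run(tiny_atlas(), tiny_design(), ground_truth(), tiny_rf(),
                      seed = 6)
  dm <- tiny_design_matrix()
  fit <- fit_run_glm(img, dm, ar_order = 0, scale = "none")
  cm <- compute_contrast(fit, as.numeric(seq_len(8) == 1))
  # oracle: classical per-coefficient t from the normal equations
  d4 <- dim(img$data)
  Y <- t(matrix(img$data, prod(d4[1:3]), d4[4]))
  X <- dm$X
  XtXinv <- solve(crossprod(X))
  keep <- sample(ncol(Y), 30)
  B <- XtXinv %*% t(X) %*% Y[, keep]
  res <- Y[, keep] - X %*% B
  s2 <- colSums(res^2) / (nrow(X) - ncol(X))
  t_or <- B[1, ] / sqrt(s2 * XtXinv[1, 1])
  expect_lt(max(abs(t_or - cm$t[keep])), 1e-8)
})

test_that("contrast maps negate under weight negation and reject bad
          weights", {
  img <- simulate_run(tiny_atlas(), tiny_design(), ground_truth(), tiny_rf(),
                      seed = 7)
  dm <- tiny_design_matrix()
  fit <- fit_run_glm(img, dm)
  w <- macaque_vs_nonvocal_weights(dm)
  cm <- compute_contrast(fit, w)
  cm_neg <- compute_contrast(fit, -w)
  expect_equal(cm_neg$t, -cm$t, tolerance = 1e-12)
  expect_equal(cm_neg$effect, -cm$effect, tolerance = 1e-12)
  expect_error(compute_contrast(fit, rep(0, 8)), "all-zero")
  expect_error(compute_contrast(fit, rep(1, 3)), "task column")
})

test_that("equal-amplitude categories give a null Macaque-vs-NonVocal
          contrast in A1", {
  a1 <- which(atlas_mask(tiny_atlas(), "A1-like-left"))
  zs <- numeric(6)
  dm <- tiny_design_matrix()
  for (i in seq_along(zs)) {
    img <- simulate_run(tiny_atlas(), tiny_design(), ground_truth(),
                        tiny_rf(), seed = derive_seed(700, i))
    fit <- fit_run_glm(img, dm)
    cm <- compute_contrast(fit, macaque_vs_nonvocal_weights(dm))
    zs[i] <- mean(cm$t[a1])
  }
  # A1 responds equally to both categories: mean t within 3 SE of zero
  expect_lt(abs(mean(zs)), 3 * stats::sd(zs) / sqrt(length(zs)) + 0.5)
})

test_that("effects are invariant to rf rescaling with inverse-rescaled
          weights", {
  d <- tiny_design()
  img <- simulate_run(tiny_atlas(), d, ground_truth(), tiny_rf(), seed = 8)
  rf2 <- tiny_rf(); rf2$h <- rf2$h * 2   # doubled response function
  dm1 <- tiny_design_matrix()
  dm2 <- assemble_design_matrix(build_task_regressors(d, rf2, "subcategory"),
                                drift_order = 3)
  f1 <- fit_run_glm(img, dm1, ar_order = 0)
  f2 <- fit_run_glm(img, dm2, ar_order = 0)
  c1 <- compute_contrast(f1, rep(1 / 8, 8))
  c2 <- compute_contrast(f2, rep(2 / 8, 8))   # inverse-rescaled weights
  expect_equal(c1$effect, c2$effect, tolerance = 1e-6)
})

test_that("combine_runs: identity, sqrt(n) shrinkage, and 4:1 weighting", {
  m <- toy_map(c(2, -1, 0.5), sd = c(1, 2, 4))
  one <- combine_runs(list(m))
  expect_equal(one$effect, m$effect)
  expect_equal(one$sd, m$sd)
  three <- combine_runs(list(m, m, m))
  expect_equal(three$effect, m$effect)
  expect_equal(three$sd, m$sd / sqrt(3), tolerance = 1e-12)
  expect_equal(three$df, 300)
  # sd ratio 1:2 -> precision weights 4:1 (hand-computed oracle)
  a <- toy_map(1, sd = 1); b <- toy_map(2, sd = 2)
  ab <- combine_runs(list(a, b))
  expect_equal(ab$effect, (4 * 1 + 1 * 2) / 5, tolerance = 1e-12)
  expect_equal(ab$sd, 1 / sqrt(1 + 1 / 4), tolerance = 1e-12)
  # grid mismatch
  g1 <- toy_map(1); g1$grid <- volume_grid(c(8, 8, 8))
  g2 <- toy_map(1); g2$grid <- volume_grid(c(9, 9, 9))
  expect_error(combine_runs(list(g1, g2)), "grid")
})

test_that("null-simulation t quantiles match the reference distribution", {
  # voxelwise t of a pure-noise run should follow a t distribution with the
  # fit's df; check the upper 5% quantile over many voxels
  img <- simulate_run(tiny_atlas(), tiny_design(), noise_truth(ar1 = 0),
                      tiny_rf(), seed = 12)
  dm <- tiny_design_matrix()
  fit <- fit_run_glm(img, dm, ar_order = 0)
  cm <- compute_contrast(fit, sound_vs_silence_weights(dm))
  q95 <- stats::quantile(cm$t, 0.95, na.rm = TRUE, names = FALSE)
  expect_lt(abs(q95 - stats::qt(0.95, fit$df)), 0.15)
})
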