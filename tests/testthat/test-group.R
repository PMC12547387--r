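# Group maps and random-field-theory inference.

test_that("fixed-effects group combination matches the closed form", {
  m <- toy_map(c(1, 2), sd = c(1, 2))
  expect_error(fixed_effects_group(list(m)), ">= 2")
  gg <- fixed_effects_group(list(m, m, m, m))
  expect_equal(gg$effect, m$effect)
  expect_equal(gg$sd, m$sd / 2, tolerance = 1e-12)
  expect_equal(gg$model, "fixed")
  # hand-set two-subject oracle
  a <- toy_map(3, sd = 1); b <- toy_map(0, sd = 3)
  ab <- fixed_effects_group(list(a, b))
  expect_equal(ab$effect, (9 * 3 + 1 * 0) / (9 + 1) * (9 / 9), # 2.7
               tolerance = 1e-10)
  expect_equal(ab$sd, 1 / sqrt(1 + 1 / 9), tolerance = 1e-10)
  # n identical subjects: group t = single t * sqrt(n)
  tmap <- toy_map(c(1.5, -2), sd = 1)
  g9 <- fixed_effects_group(rep(list(tmap), 9))
  expect_equal(g9$t, tmap$t * 3, tolerance = 1e-6)
})

test_that("random-effects group analysis: df, degenerate variance, n = 11", {
  m1 <- toy_map(1); m2 <- toy_map(2); m3 <- toy_map(3)
  expect_error(random_effects_group(list(m1, m2)), ">= 3")
  g <- random_effects_group(list(m1, m2, m3))
  expect_equal(g$df, 2)
  expect_equal(g$effect, 2)
  expect_equal(g$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  # identical nonzero subjects: capped t with warning
  expect_warning(gid <- random_effects_group(rep(list(toy_map(1)), 5)),
                 "capped")
  expect_equal(gid$t, 1e6)
  # n = 11 subjects -> df = 10
  maps <- lapply(1:11, function(i) toy_map(i / 10))
  expect_equal(random_effects_group(maps)$df, 10)
})

test_that("random-effects type-I error is calibrated at nominal p = 0.05", {
  set.seed(501)
  n_sub <- 11; V <- 600; n_rep <- 120
  rej <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    maps <- lapply(seq_len(n_sub), function(i) toy_map(rnorm(V)))
    g <- random_effects_group(maps)
    rej[r] <- mean(g$t > stats::qt(0.95, g$df))
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("declared-kernel resel arithmetic and scaling law", {
  mask <- array(FALSE, c(14, 14, 14)); mask[3:12, 3:12, 3:12] <- TRUE
  g <- volume_grid(c(14, 14, 14))
  sm <- estimate_smoothness(mask = mask, grid = g, fwhm_mm = 3)
  expect_equal(unname(sm$resels["R3"]), 1000 * 3.375 / 27, tolerance = 1e-12)
  expect_equal(unname(sm$resels["R0"]), 1)
  sm6 <- estimate_smoothness(mask = mask, grid = g, fwhm_mm = 6)
  expect_equal(unname(sm6$resels["R3"]), unname(sm$resels["R3"]) / 8,
               tolerance = 1e-12)
  expect_error(estimate_smoothness(mask = array(FALSE, c(8, 8, 8)),
                                   grid = volume_grid(c(8, 8, 8)),
                                   fwhm_mm = 3), "empty")
})

test_that("smoothness is estimated correctly from smooth residuals", {
  set.seed(31)
  d <- c(24, 24, 24)
  res <- array(rnorm(prod(d) * 30), c(d, 30))
  g <- volume_grid(d)
  for (i in 1:30)
    res[, , , i] <- smooth_volumes(res[, , , i], 3, g, boundary = "wrap")
  sm <- estimate_smoothness(res, array(TRUE, d), g)
  expect_true(all(sm$fwhm_mm > 2.6 & sm$fwhm_mm < 3.4))
})

test_that("peak thresholds: point-search limit, monotonicity", {
  expect_equal(peak_threshold(Inf, c(1, 0, 0, 0), 0.05),
               stats::qnorm(0.95), tolerance = 1e-3)
  mask <- array(TRUE, c(20, 20, 20))
  g <- volume_grid(c(20, 20, 20))
  sm <- estimate_smoothness(mask = mask, grid = g, fwhm_mm = 3)
  t1 <- peak_threshold(Inf, sm, 0.05)
  # increasing resels raises the threshold
  sm_big <- sm; sm_big$resels <- sm$resels * 4
  expect_gt(peak_threshold(Inf, sm_big, 0.05), t1)
  # decreasing alpha raises the threshold
  expect_gt(peak_threshold(Inf, sm, 0.01), t1)
  # finite df raises it relative to the Gaussian limit
  expect_gt(peak_threshold(10, sm, 0.05), t1)
  expect_error(peak_threshold(3, sm, 0.05), "df")
  expect_error(peak_threshold(Inf, sm, 1.2), "alpha")
})

test_that("cluster labeling equals an igraph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (conn in c(6, 26)) {
    for (rep in 1:4) {
      m <- array(runif(10 * 9 * 8) > 0.6, c(10, 9, 8))
      lab <- label_clusters(m, conn)
      # oracle: graph over suprathreshold voxels, edges between neighbours
      vox <- which(m)
      co <- arrayInd(vox, dim(m))
      idx <- stats::setNames(seq_along(vox), vox)
      edges <- NULL
      for (i in seq_along(vox)) {
        dd <- sweep(co, 2, co[i, ], "-")
        ad <- abs(dd)
        nb <- if (conn == 6) rowSums(ad) == 1
              else rowSums(ad >= 1) >= 1 & apply(ad, 1, max) == 1
        nb <- which(nb & seq_along(vox) > i)
        if (length(nb)) edges <- rbind(edges, cbind(i, nb))
      }
      gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
      gr <- igraph::add_vertices(gr, length(vox) - igraph::vcount(gr))
      comp <- igraph::components(gr)$membership
      # same partition: labels agree up to renaming
      ours <- lab[vox]
      expect_equal(length(unique(ours)), max(comp))
      expect_true(all(tapply(comp, ours, function(x) length(unique(x))) == 1))
      expect_true(all(tapply(ours, comp, function(x) length(unique(x))) == 1))
    }
  }
})

test_that("cluster correction: threshold constant, empty maps, planted
          activation", {
  d <- c(24, 24, 24)
  g <- volume_grid(d)
  mask <- array(TRUE, d)
  sm <- estimate_smoothness(mask = mask, grid = g, fwhm_mm = 3)
  # Gaussian-limit cluster-forming threshold at p = 0.001 is 3.09 (2 d.p.)
  tc <- cluster_correct(array(0, d), mask, sm, df = 100)
  expect_equal(round(tc$cluster_forming_t, 2), 3.09)
  expect_equal(nrow(tc$clusters), 0)
  expect_false(any(tc$surviving))
  # planted activation in smooth null background survives as one cluster
  set.seed(51)
  detected <- 0; single <- 0
  for (i in 1:10) {
    f <- smooth_null_field(d)
    blob <- array(0, d); blob[12, 12, 12] <- 1
    blob <- smooth_volumes(blob, 4.5, g); blob <- blob / max(blob) * 8
    res <- cluster_correct(f + blob, mask, sm, df = 100)
    sig <- res$clusters[res$clusters$significant, ]
    near <- abs(sig$peak_x - 12) <= 3 & abs(sig$peak_y - 12) <= 3 &
      abs(sig$peak_z - 12) <= 3
    if (any(near)) detected <- detected + 1
    if (nrow(sig) == 1 && any(near)) single <- single + 1
  }
  # the planted activation is always found; spurious extra clusters are
  # bounded separately by the family-wise error test below
  expect_gte(detected, 9)
  expect_gte(single, 8)
})

test_that("combined peak-or-cluster decision controls family-wise error", {
  set.seed(61)
  d <- c(24, 24, 24)
  g <- volume_grid(d)
  mask <- array(TRUE, d)
  sm <- estimate_smoothness(mask = mask, grid = g, fwhm_mm = 3)
  fp <- 0; n_rep <- 150
  for (i in seq_len(n_rep)) {
    f <- smooth_null_field(d)
    res <- cluster_correct(f, mask, sm, df = 100)
    if (any(res$clusters$significant)) fp <- fp + 1
  }
  expect_lte(fp / n_rep, 1.5 * 0.05)
})
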