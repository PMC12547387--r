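# Synthetic-data generator: atlas, stimulus catalog, run designs, simulation.

test_that("stimulus catalog has the nested category structure", {
  cat48 <- stimulus_catalog()
  expect_equal(nrow(cat48), 48)
  expect_equal(length(unique(cat48$subcategory)), 8)
  expect_equal(as.vector(table(cat48$subcategory)), rep(6L, 8))
  # each subcategory maps to exactly one main category, 4 per main category
  map <- unique(cat48[c("subcategory", "main_category")])
  expect_equal(nrow(map), 8)
  expect_equal(as.vector(table(map$main_category)), c(4L, 4L))
})

test_that("default phantom contains the named regions and tissue classes", {
  atlas <- make_phantom(volume_grid(c(24, 24, 18)))
  expect_s3_class(atlas, "tissue_atlas")
  expect_gte(nrow(atlas$region_table), 6)
  expect_true(all(c("A1-like-left", "A1-like-right", "IC-like") %in%
                    atlas$region_table$region_name))
  expect_gt(sum(atlas_mask(atlas, "white")), 0)
  expect_gt(sum(atlas_mask(atlas, "csf")), 0)
  # every named region code appears, tissue codes mutually exclusive by
  # construction of a single label volume
  for (code in atlas$region_table$label_code)
    expect_gt(sum(atlas$labels == code), 0)
})

test_that("overlapping regions are rejected with both names", {
  g <- volume_grid(c(16, 16, 14))
  spec <- data.frame(region_name = c("blob-a", "blob-b"),
                     label_code = c(11L, 12L),
                     cx = c(8, 9), cy = c(8, 8), cz = c(9, 9),
                     radius_mm = 3)
  expect_error(make_phantom(g, spec), "blob-a.*blob-b|blob-b.*blob-a")
})

test_that("empty region spec yields a plain tissue phantom", {
  atlas <- make_phantom(tiny_grid(), default_region_spec(tiny_grid())[0, ])
  expect_equal(sort(unique(as.vector(atlas$labels))), 0:3)
  expect_equal(nrow(atlas$region_table), 0)
})

test_that("run designs honour the protocol counts and jitter bounds", {
  for (seed in c(1, 77, 31415)) {
    d <- make_run_design(seed)
    expect_equal(sum(d$blocks$condition != "silence"), 32)
    expect_equal(sum(d$blocks$condition == "silence"), 16)
    counts <- table(d$blocks$condition[d$blocks$condition != "silence"])
    expect_equal(as.vector(counts), rep(4L, 8))
    stim <- d$blocks$condition != "silence"
    expect_true(all(d$blocks$jitter_s[stim] >= 0.100 - 1e-12))
    expect_true(all(d$blocks$jitter_s[stim] <= 0.250 + 1e-12))
    expect_equal(d$n_volumes, 48 * 7)
  }
})

test_that("same seed gives identical designs; zero jitter is degenerate", {
  expect_identical(make_run_design(42), make_run_design(42))
  p0 <- sparse_protocol(jitter_range_s = c(0, 0))
  d0 <- make_run_design(5, p0)
  stim <- d0$blocks$condition != "silence"
  gap_start <- (which(stim) - 1) * (p0$gap_s + 7 * p0$volume_spacing_s)
  expect_equal(d0$blocks$onset_s[stim], gap_start)
})

test_that("block schedules that cannot fit the silent gap are rejected", {
  expect_error(make_run_design(1, sparse_protocol(stimulus_duration_s = 1)),
               "does not fit")
})

test_that("designs satisfy timing invariants across many seeds", {
  p <- sparse_protocol()
  cluster_len <- p$cluster_volumes * p$volume_spacing_s
  for (seed in seq_len(300)) {
    d <- make_run_design(seed, p)
    # acquisition clusters strictly increasing, non-overlapping
    expect_true(all(diff(d$schedule$start_time_s) >= cluster_len))
    # every stimulus block lies inside its scanner-silent gap
    stim <- which(d$blocks$condition != "silence")
    gap_start <- (stim - 1) * (p$gap_s + cluster_len)
    expect_true(all(d$blocks$onset_s[stim] >= gap_start))
    expect_true(all(d$blocks$onset_s[stim] + d$blocks$duration_s[stim] <=
                      gap_start + p$gap_s + 1e-9))
    # volume timestamps strictly increasing
    expect_true(all(diff(d$volume_times_s) > 0))
  }
})

test_that("null-signal simulation is constant at baseline", {
  img <- simulate_run(tiny_atlas(), tiny_design(),
                      ground_truth(
                        amplitude_table = default_amplitudes()[0, ],
                        noise = list(ar1 = 0, sd = 0, drift_sd = 0),
                        nuisance = list(amplitude = 0)),
                      tiny_rf(), seed = 1)
  expect_true(all(img$data == 1000))
})

test_that("positive neural amplitude with reversed-sign rf lowers intensity", {
  img <- simulate_run(tiny_atlas(), tiny_design(), clean_truth(), tiny_rf(),
                      seed = 1)
  a1 <- which(atlas_mask(tiny_atlas(), "A1-like-left"))
  Y <- t(matrix(img$data, prod(dim(img$data)[1:3]), dim(img$data)[4]))
  expect_lte(max(Y[, a1]), 1000 + 1e-9)
  expect_lt(min(Y[, a1]), 1000 - 1)
})

test_that("simulation is bit-reproducible and rejects unknown regions", {
  i1 <- simulate_run(tiny_atlas(), tiny_design(), ground_truth(), tiny_rf(),
                     seed = 9)
  i2 <- simulate_run(tiny_atlas(), tiny_design(), ground_truth(), tiny_rf(),
                     seed = 9)
  expect_identical(i1$data, i2$data)
  bad <- ground_truth(amplitude_table = data.frame(
    region_name = "no-such-region", subcategory = "coo",
    amplitude_pct = 1))
  expect_error(simulate_run(tiny_atlas(), tiny_design(), bad, tiny_rf()),
               "no-such-region")
})

test_that("pure-noise runs have temporal means near baseline and the
          configured lag-1 autocorrelation", {
  # long pure-noise series: simulate a run's worth of AR(1) noise voxels
  img <- simulate_run(tiny_atlas(), tiny_design(), noise_truth(ar1 = 0.4),
                      tiny_rf(), seed = 21)
  Y <- t(matrix(img$data, prod(dim(img$data)[1:3]), dim(img$data)[4]))
  n <- nrow(Y)
  # per-voxel mean within 3 standard errors for ~99% of voxels (AR(1)
  # variance inflation factor (1+rho)/(1-rho) on the SE of the mean)
  se <- 20 / sqrt(n) * sqrt((1 + 0.4) / (1 - 0.4))
  z <- abs(colMeans(Y) - 1000) / se
  expect_gt(mean(z < 3), 0.985)
  # empirical lag-1 autocorrelation near the configured value
  Yc <- sweep(Y, 2, colMeans(Y))
  r1 <- colSums(Yc[-1, ] * Yc[-n, ]) / colSums(Yc^2)
  expect_lt(abs(mean(r1) - 0.4), 0.05)
})

test_that("cohorts are written completely and reproducibly", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  m1 <- simulate_cohort(2, 3, tiny_atlas(), seed = 5, out_dir = td1)
  expect_equal(nrow(m1), 6)
  expect_true(all(file.exists(m1$image)))
  expect_true(all(file.exists(m1$events)))
  expect_true(file.exists(file.path(td1, "atlas.nii.gz")))
  expect_true(file.exists(file.path(td1, "truth.yaml")))
  m2 <- simulate_cohort(2, 3, tiny_atlas(), seed = 5, out_dir = td2)
  expect_identical(unname(tools::md5sum(m1$image)),
                   unname(tools::md5sum(m2$image)))
  expect_error(simulate_cohort(0, 3, tiny_atlas(), seed = 1,
                               out_dir = withr::local_tempdir()),
               "n_subjects")
})
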