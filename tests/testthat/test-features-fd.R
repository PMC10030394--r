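test_that("band layout covers [0.015, 2] Hz with 60 contiguous bands", {
  b <- wcoh_bands()
  expect_equal(nrow(b), 60)
  expect_equal(b$f_low[1], 0.015)
  expect_equal(b$f_high[60], 2)
  expect_equal(b$f_low[-1], b$f_high[-60], tolerance = 1e-12)
  expect_true(all(b$f_low < b$f_center & b$f_center < b$f_high))
  lin <- wcoh_bands(spacing = "linear")
  expect_lt(diff(range(diff(lin$f_low))), 1e-9)
})

test_that("self-coherence is one at every band outside the cone", {
  set.seed(2)
  x <- rnorm(600)
  wc <- wavelet_coherence(x, x, fs = 5)
  expect_true(all(abs(wc$coh[wc$coi_ok] - 1) < 1e-6))
})

test_that("coherence is symmetric and invariant to affine rescaling", {
  set.seed(4)
  x <- rnorm(500); y <- rnorm(500)
  a <- wavelet_coherence(x, y, fs = 5)
  b <- wavelet_coherence(y, x, fs = 5)
  expect_lt(max(abs(a$coh - b$coh), na.rm = TRUE), 1e-9)
  d <- wavelet_coherence(3 * x + 2, y, fs = 5)
  expect_lt(max(abs(a$coh - d$coh), na.rm = TRUE), 1e-6)
})

test_that("independent noise stays below the shared-tone coherence", {
  set.seed(6)
  null_means <- vapply(1:5, function(i) {
    x <- rnorm(900); y <- rnorm(900)
    wc <- wavelet_coherence(x, y, fs = 5)
    mean(band_average(wc$coh, 1:900, wc$coi_ok), na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(null_means), 0.5)

  tt <- seq(0, by = 0.2, length.out = 900)
  s <- sin(2 * pi * 0.7 * tt)
  x <- s + rnorm(900, 0, 0.5)
  y <- s + rnorm(900, 0, 0.5)
  wc <- wavelet_coherence(x, y, fs = 5)
  bm <- band_average(wc$coh, 1:900, wc$coi_ok)
  b <- wcoh_bands()
  k <- which(b$f_low <= 0.7 & b$f_high > 0.7)
  expect_gt(bm[k], max(bm[b$f_center > 1.5]))
})

test_that("coherence values stay inside [0, 1] on random trace pairs", {
  set.seed(8)
  for (i in 1:20) {
    x <- cumsum(rnorm(300)); y <- rnorm(300) + sin(1:300 / 7)
    wc <- wavelet_coherence(x, y, fs = 5)
    v <- wc$coh[is.finite(wc$coh)]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("constant traces yield flagged, undefined coherence", {
  x <- rep(3, 400)
  wc <- wavelet_coherence(x, rnorm(400), fs = 5)
  expect_true(all(is.nan(wc$coh) | !wc$coi_ok | is.na(wc$coh)))
})

test_that("band averaging matches a loop-based oracle", {
  set.seed(10)
  coh <- matrix(runif(200 * 60), 200, 60)
  coi <- matrix(sample(c(TRUE, FALSE), 200 * 60, TRUE, c(0.8, 0.2)),
                200, 60)
  win <- 41:160
  got <- band_average(coh, win, coi)
  for (s in c(1, 7, 33, 60)) {
    keep <- c()
    for (t in win) if (coi[t, s]) keep <- c(keep, coh[t, s])
    expect_equal(got[s], mean(keep))
  }
})

test_that("the tumor reference is the subset mean and is seeded", {
  sim <- simulate_thermal_video(mini_cfg())
  X <- thermoseg:::video_traces(sim$video)
  full <- make_reference(sim$video, sim$mask, fraction = 1)
  expect_equal(as.numeric(full),
               rowMeans(X[, as.vector(sim$mask), drop = FALSE]),
               tolerance = 1e-12)
  r1 <- make_reference(sim$video, sim$mask, fraction = 0.3, seed = 1)
  r2 <- make_reference(sim$video, sim$mask, fraction = 0.3, seed = 1)
  r3 <- make_reference(sim$video, sim$mask, fraction = 0.3, seed = 2)
  expect_identical(r1, r2)
  expect_false(identical(attr(r1, "pixels"), attr(r3, "pixels")))
  # different subsets still estimate the same underlying mean course,
  # within the sampling error implied by the within-class spread
  tum <- X[, as.vector(sim$mask), drop = FALSE]
  sigma_px <- sqrt(mean(apply(tum, 1, var)))
  k <- length(attr(r1, "pixels"))
  expect_lt(sqrt(mean((r1 - r3)^2)), 3 * sqrt(2) * sigma_px / sqrt(k))
  expect_error(make_reference(sim$video, sim$mask & FALSE, 0.2), "empty")
})

test_that("noiseless identical tumor pixels are fully coherent with it", {
  sim <- simulate_thermal_video(quiet_cfg(base_sd = 0))
  fd <- extract_fd_features(sim$video, sim$mask, scope = "bl",
                            fraction = 0.5, seed = 3)
  refpix <- fd$in_reference & fd$label == 1
  vals <- unlist(fd[refpix, grep("^wcoh_bl_", names(fd))])
  vals <- vals[is.finite(vals)]
  expect_true(all(vals > 1 - 1e-6))
})

test_that("feature table shape and flags follow the scope", {
  sim <- simulate_thermal_video(mini_cfg())
  bl <- extract_fd_features(sim$video, sim$mask, scope = "bl", seed = 5)
  expect_equal(sum(grepl("^wcoh_", names(bl))), 60)
  expect_equal(nrow(bl), 256)
  expect_equal(sum(bl$in_reference),
               ceiling(0.2 * sum(sim$mask)))
  both <- extract_fd_features(sim$video, sim$mask, scope = "bl_rec",
                              seed = 5)
  expect_equal(sum(grepl("^wcoh_", names(both))), 120)
})

test_that("strong mixing-weight contrast appears in the cardiac band", {
  cfg <- scenario_config(n_rows = 24, n_cols = 24, t_bl = 60, t_gap = 10,
                         t_rec = 120, seed = 19)
  sim <- simulate_thermal_video(cfg)
  fd <- extract_fd_features(sim$video, sim$mask, scope = "bl_rec",
                            seed = 23)
  b <- wcoh_bands()
  k <- which(b$f_low <= 0.71 & b$f_high > 0.71)
  cn <- sprintf("wcoh_rec_%02d", k)
  expect_gt(mean(fd[fd$label == 1, cn]), mean(fd[fd$label == 0, cn]) + 0.1)
})
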