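test_that("noiseless exponential recovery is recovered to 1e-6", {
  t <- seq(0, 120, by = 0.2)
  y <- 2.0 * (1 - exp(-0.05 * t)) + 31.0
  f <- fit_recovery(y, t)
  expect_true(f$accepted)
  expect_equal(f$a, 2.0, tolerance = 1e-6)
  expect_equal(f$b, -0.05, tolerance = 1e-6)
  expect_equal(f$c, 31.0, tolerance = 1e-6)
  expect_gt(f$R, 0.999)
})

test_that("flat and noise-only traces are rejected by the R > 0.8 gate", {
  t <- seq(0, 60, by = 0.2)
  flat <- fit_recovery(rep(31, length(t)), t)
  expect_false(flat$accepted)
  expect_true(is.na(flat$a))

  set.seed(5)
  noise <- fit_recovery(rnorm(length(t)), t)
  expect_false(noise$accepted)
})

test_that("recovery fit is scale-consistent in its amplitude", {
  t <- seq(0, 100, by = 0.2)
  y <- 1.5 * (1 - exp(-0.03 * t)) + 30
  k <- 2.5
  f1 <- fit_recovery(y, t)
  f2 <- fit_recovery(k * (y - 30) + 30, t)
  expect_equal(f2$a, k * f1$a, tolerance = 1e-5)
  expect_equal(f2$b, f1$b, tolerance = 1e-5)
  expect_equal(f2$c, f1$c, tolerance = 1e-5)
})

test_that("temperature variation uses first/last 10 s windows", {
  ts <- seq(0, 179.8, by = 0.2)
  expect_equal(temperature_variation(rep(30, length(ts)), ts), 0)
  expect_equal(temperature_variation(ts, ts), 170.1, tolerance = 1e-9)
  step <- ifelse(ts < 90, 30, 31)
  expect_equal(temperature_variation(step, ts), 1.0)
  expect_error(temperature_variation(1:50, seq(0, 9.8, by = 0.2)),
               "20 s")
})

test_that("initial temperature averages the 30 s before the stress", {
  ts <- seq(0, 59.8, by = 0.2)
  expect_equal(initial_temperature(rep(33, length(ts)), ts, 60), 33)
  ramp <- 0.1 * ts
  w <- ts >= 30 & ts < 60
  expect_equal(initial_temperature(ramp, ts, 60), mean(ramp[w]))
  expect_error(initial_temperature(ramp, ts, 5), "30 s")
})

test_that("moment features match known distributions and conventions", {
  set.seed(9)
  x <- rnorm(1e5)
  m <- moment_features(x)
  expect_equal(m$kurtosis, 3, tolerance = 0.05)
  expect_equal(m$skewness, 0, tolerance = 0.05)
  expect_equal(m$std, 1, tolerance = 0.02)

  w <- 1:10
  mw <- moment_features(w)
  expect_equal(mw$p90, 1 + 0.9 * 9)       # type-7 interpolation by hand
  expect_equal(mw$p90, unname(quantile(w, 0.9, type = 7)))

  mc <- moment_features(rep(5, 10))
  expect_equal(mc$std, 0)
  expect_true(mc$degenerate)
  expect_true(is.nan(mc$kurtosis))
})

test_that("sample entropy matches the exhaustive oracle and its limits", {
  cst <- sample_entropy(rep(2, 50))
  expect_equal(as.numeric(cst), 0)
  expect_true(attr(cst, "degenerate"))

  x <- rep(c(1, 2), 5)
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x), sampen_oracle(x, 2, r))

  set.seed(31)
  for (i in 1:10) {
    z <- rnorm(60)
    expect_equal(sample_entropy(z), sampen_oracle(z, 2, 0.2 * sd(z)),
                 tolerance = 1e-12)
  }
})

test_that("sample entropy is invariant under affine trace rescaling", {
  set.seed(13)
  for (i in 1:20) {
    z <- rnorm(80)
    expect_equal(sample_entropy(2 * z + 5), sample_entropy(z),
                 tolerance = 1e-12)
  }
})

test_that("irregular noise carries more entropy than a smooth oscillation", {
  set.seed(17)
  n <- 600
  wins <- vapply(1:10, function(i) {
    u <- runif(n)
    s <- sin(2 * pi * 0.7 * seq(0, by = 0.2, length.out = n))
    sample_entropy(u) > sample_entropy(s)
  }, logical(1))
  expect_true(all(wins))
})

test_that("feature table bookkeeping matches the mask and scope", {
  sim <- simulate_thermal_video(quiet_cfg(base_sd = 0))
  tab <- extract_td_features(sim$video, sim$mask, scope = "bl_rec")
  expect_equal(nrow(tab), 16 * 16)
  expect_equal(sum(tab$label), sum(sim$mask))
  expect_setequal(
    setdiff(names(tab),
            c("pixel_row", "pixel_col", "label", "fit_R")),
    thermoseg:::td_feature_names("bl_rec"))

  # deterministic generator with identical class parameters per pixel:
  # all tumor rows identical, all healthy rows identical
  for (f in c("t_ini", "c", "b", "std_rec", "sampen_bl")) {
    expect_lt(diff(range(tab[[f]][tab$label == 1])), 1e-6)
    expect_lt(diff(range(tab[[f]][tab$label == 0])), 1e-6)
  }

  bl <- extract_td_features(sim$video, sim$mask, scope = "bl")
  expect_setequal(setdiff(names(bl),
                          c("pixel_row", "pixel_col", "label")),
                  thermoseg:::td_feature_names("bl"))
})
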