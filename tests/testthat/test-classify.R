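# labeled feature table with tunable class separation
sep_table <- function(n0 = 450, n1 = 50, d = 6, seed = 1) {
  set.seed(seed)
  data.frame(pixel_row = rep(0:(ceiling((n0 + n1) / 20) - 1),
                             length.out = n0 + n1),
             pixel_col = rep(0:19, length.out = n0 + n1),
             label = rep(c(0L, 1L), c(n0, n1)),
             t_ini = c(rnorm(n0), rnorm(n1) + d),
             std_bl = c(rnorm(n0), rnorm(n1) - d / 2),
             k_bl = rnorm(n0 + n1),
             sk_bl = rnorm(n0 + n1),
             p90_bl = rnorm(n0 + n1),
             sampen_bl = rnorm(n0 + n1))
}

test_that("split sets partition the pixels and balance the classes", {
  set.seed(2)
  labels <- rep(c(0, 1), c(900, 100))[sample(1000)]
  sp <- make_split(labels, seed = 5)
  all_idx <- sort(c(sp$train_idx, sp$test_idx, sp$validation_idx,
                    sp$dropped_idx))
  expect_identical(all_idx, 1:1000)
  expect_equal(sum(labels[sp$train_idx] == 0),
               sum(labels[sp$train_idx] == 1))
  expect_equal(sum(labels[sp$test_idx] == 0),
               sum(labels[sp$test_idx] == 1))
  # pre-balance train pool holds 20% of the pixels
  expect_equal(sum(unlist(sp$balance_record$train$before)), 200)
  expect_equal(length(sp$train_idx),
               2 * min(sp$balance_record$train$before))
})

test_that("balanced input loses nothing; bad fractions are refused", {
  labels <- rep(c(0, 1), each = 500)
  sp <- make_split(labels, seed = 3)
  expect_lt(length(sp$dropped_idx), 0.1 * 1000)  # only pool imbalance
  expect_error(make_split(labels, 0.6, 0.6), "below 1")
})

test_that("a linearly separable table is learned perfectly", {
  tab <- sep_table(d = 8)
  sp <- make_split(tab$label, seed = 7)
  m <- thermoseg(tab, family = "td_bl", split = sp)
  pred <- predict(m, tab)
  expect_equal(mean(pred[sp$train_idx] == tab$label[sp$train_idx]), 1)
  ev <- evaluate_segmentation(m, tab)
  expect_gt(ev$accuracy, 95)
  expect_equal(length(ev$cv_scores), 10)
})

test_that("confusion-matrix metrics follow their definitions", {
  truth <- rep(c(1, 0), c(10, 90))
  all0 <- rep(0, 100)
  m <- thermoseg:::confusion_metrics(truth, all0)
  expect_equal(m$accuracy, 90)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 100)
  perfect <- thermoseg:::confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
})

test_that("cross-validation refits preprocessing inside each fold", {
  tab <- sep_table(d = 3)
  sp <- make_split(tab$label, seed = 9)
  m <- thermoseg(tab, family = "td_bl", split = sp)
  ev <- evaluate_segmentation(m, tab)
  ctrs <- do.call(rbind, ev$fold_centers)
  # fold-level training means must differ across folds (no leakage of a
  # single global standardization)
  expect_gt(max(apply(ctrs, 2, sd)), 0)
})

test_that("shuffled labels give chance-level cross-validation accuracy", {
  cvs <- vapply(1:20, function(s) {
    tab <- sep_table(n0 = 150, n1 = 150, d = 0, seed = s)
    tab$label <- sample(tab$label)
    sp <- make_split(tab$label, seed = s)
    m <- thermoseg(tab, family = "td_bl", split = sp)
    evaluate_segmentation(m, tab)$cv_mean
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 50), 5)
})

test_that("an extra constant feature column does not change predictions", {
  set.seed(11)
  n <- 400
  tab <- data.frame(label = rep(c(0L, 1L), each = n / 2))
  for (k in 1:5) {
    tab[[sprintf("wcoh_bl_%02d", k)]] <- rnorm(n) + 2 * tab$label
  }
  sp <- make_split(tab$label, seed = 11)
  m1 <- thermoseg(tab, family = "fd_bl", split = sp)
  tab2 <- tab
  tab2$wcoh_bl_06 <- 0.7                   # constant band, dropped at fit
  m2 <- thermoseg(tab2, family = "fd_bl", split = sp)
  expect_identical(m2$core$features, m1$core$features)
  expect_equal(predict(m2, tab2), predict(m1, tab))
})

test_that("missing fit coefficients are imputed with train medians", {
  tab <- sep_table(d = 5)
  tab$a <- c(rnorm(450), rnorm(50) + 3)
  tab$b <- rnorm(500); tab$c <- rnorm(500); tab$delta <- rnorm(500)
  tab$std_rec <- rnorm(500); tab$k_rec <- rnorm(500)
  tab$sk_rec <- rnorm(500); tab$p90_rec <- rnorm(500)
  tab$sampen_rec <- rnorm(500)
  tab$a[sample(500, 60)] <- NA
  sp <- make_split(tab$label, seed = 13)
  m <- thermoseg(tab, family = "td_blrec", split = sp)
  expect_true(is.finite(m$core$medians["a"]))
  expect_equal(length(predict(m, tab)), 500)
})

test_that("the whole pipeline is reproducible under fixed seeds", {
  cfg <- mini_cfg(seed = 3L)
  run_once <- function() {
    sim <- simulate_thermal_video(cfg)
    td <- extract_td_features(sim$video, sim$mask)
    sp <- make_split(td$label, seed = 21)
    m <- thermoseg(td, family = "td_blrec", split = sp)
    ev <- evaluate_segmentation(m, td)
    c(ev$accuracy, ev$sensitivity, ev$specificity, ev$cv_scores)
  }
  expect_identical(run_once(), run_once())
})
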