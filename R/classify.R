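#' Balanced train/test/validation split of labeled pixels
#'
#' Assigns every labeled pixel to exactly one of train (`train_frac`),
#' test (`test_frac`) or validation (the remainder) uniformly at random,
#' then balances the train and the test sets separately by randomly
#' down-sampling the larger class. Down-sampled pixels are dropped (they
#' join no set) and recorded.
#'
#' @param labels integer vector of 0/1 class labels, one per pixel.
#' @param train_frac,test_frac fractions of pixels for train and test;
#'   must sum to less than 1.
#' @param seed RNG seed.
#' @return An object of class `split_plan` with `train_idx`, `test_idx`,
#'   `validation_idx`, `dropped_idx`, `seed` and `balance_record`.
#' @export
make_split <- function(labels, train_frac = 0.2, test_frac = 0.2,
                       seed = 1L) {
  if (train_frac + test_frac >= 1) {
    stop("train_frac + test_frac must be below 1")
  }
  if (!any(labels == 0) || !any(labels == 1)) {
    stop("both classes must be present")
  }
  n <- length(labels)
  with_seed(seed, {
    perm <- sample.int(n)
    n_tr <- round(train_frac * n)
    n_te <- round(test_frac * n)
    train_pool <- perm[seq_len(n_tr)]
    test_pool <- perm[n_tr + seq_len(n_te)]
    validation <- perm[-seq_len(n_tr + n_te)]

    balance <- function(idx) {
      l <- labels[idx]
      n0 <- sum(l == 0); n1 <- sum(l == 1)
      if (n0 == 0 || n1 == 0) {
        stop("a class is absent from the train or test pool; reseed")
      }
      m <- min(n0, n1)
      keep0 <- sample(idx[l == 0], m)
      keep1 <- sample(idx[l == 1], m)
      list(keep = sort(c(keep0, keep1)), before = c(n0 = n0, n1 = n1),
           after = c(n0 = m, n1 = m))
    }
    btr <- balance(train_pool)
    bte <- balance(test_pool)
    dropped <- sort(c(setdiff(train_pool, btr$keep),
                      setdiff(test_pool, bte$keep)))
    structure(list(train_idx = btr$keep, test_idx = bte$keep,
                   validation_idx = sort(validation),
                   dropped_idx = dropped, seed = as.integer(seed),
                   balance_record = list(train = btr[c("before", "after")],
                                         test = bte[c("before", "after")])),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan (seed", x$seed, ")\n")
  cat(sprintf("  train %d | test %d | validation %d | dropped %d px\n",
              length(x$train_idx), length(x$test_idx),
              length(x$validation_idx), length(x$dropped_idx)))
  b <- x$balance_record$train
  cat(sprintf("  train balance: %d/%d -> %d/%d (class 0/1)\n",
              b$before["n0"], b$before["n1"], b$after["n0"],
              b$after["n1"]))
  invisible(x)
}

family_features <- function(family, table) {
  feats <- switch(family,
    td_bl = td_feature_names("bl"),
    td_blrec = td_feature_names("bl_rec"),
    fd_bl = grep("^wcoh_bl_", names(table), value = TRUE),
    fd_blrec = grep("^wcoh_(bl|rec)_", names(table), value = TRUE),
    stop("unknown model family: ", family))
  missing <- setdiff(feats, names(table))
  if (length(feats) == 0 || length(missing) > 0) {
    stop("table lacks the feature columns of family '", family, "'",
         if (length(missing)) paste0(": ", paste(missing, collapse = ", ")))
  }
  feats
}

# Imputation + standardization + RBF-SVM, with all preprocessing
# statistics taken from the training rows only.
fit_svm_core <- function(X, y, cost, gamma) {
  keep <- apply(X, 2, function(v) any(is.finite(v)))
  if (!all(keep)) {
    warning("dropping all-missing feature column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  medians <- apply(X, 2, function(v) median(v[is.finite(v)]))
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- medians[j]
  }
  scale_ <- apply(X, 2, sd)
  const <- scale_ <= 0
  if (any(const)) {
    # constant columns carry no information; drop them so the kernel
    # width heuristic sees only informative dimensions
    if (all(const)) stop("all feature columns are constant")
    X <- X[, !const, drop = FALSE]
    medians <- medians[!const]
    scale_ <- scale_[!const]
  }
  center <- colMeans(X)
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  model <- e1071::svm(Xs, factor(y, levels = c(0, 1)),
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
  list(model = model, features = colnames(X), medians = medians,
       center = center, scale = scale_, gamma = gamma, cost = cost)
}

predict_svm_core <- function(core, X) {
  X <- X[, core$features, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- core$medians[j]
  }
  Xs <- sweep(sweep(X, 2, core$center), 2, core$scale, "/")
  as.integer(as.character(predict(core$model, Xs)))
}

#' Fit a per-patient thermal segmentation model
#'
#' Trains the radial-basis-function support vector machine that
#' classifies tumor (class 1) against healthy (class 0) pixels from one
#' of the four feature families: time-domain or wavelet-coherence
#' features, from the baseline phase only or from baseline plus
#' recovery. Features are standardized with training-set statistics;
#' missing recovery-fit coefficients are imputed with the training-set
#' median; both sets of preprocessing parameters are stored in the model
#' and re-applied at prediction time.
#'
#' @param table a per-pixel feature table ([extract_td_features()] or
#'   [extract_fd_features()]).
#' @param family one of `"td_bl"`, `"td_blrec"`, `"fd_bl"`,
#'   `"fd_blrec"`.
#' @param split a [make_split()] plan over the table rows.
#' @param cost SVM regularization parameter C.
#' @param gamma RBF kernel width; default `1 / n_features` on the
#'   standardized features.
#' @param exclude_reference drop reference-subset pixels (FD tables)
#'   from the training rows, guarding against circularity.
#' @return An object of class `thermoseg`.
#' @seealso [evaluate_segmentation()], [run_cohort()]
#' @export
thermoseg <- function(table, family = c("fd_blrec", "fd_bl", "td_blrec",
                                        "td_bl"),
                      split, cost = 1, gamma = NULL,
                      exclude_reference = FALSE) {
  family <- match.arg(family)
  stopifnot(inherits(split, "split_plan"))
  feats <- family_features(family, table)
  tr <- split$train_idx
  if (exclude_reference && "in_reference" %in% names(table)) {
    tr <- tr[!table$in_reference[tr]]
  }
  X <- as.matrix(table[tr, feats, drop = FALSE])
  core <- fit_svm_core(X, table$label[tr], cost, gamma)
  structure(list(core = core, family = family, split = split,
                 n_train = length(tr),
                 exclude_reference = exclude_reference,
                 call = match.call()),
            class = "thermoseg")
}

#' @export
print.thermoseg <- function(x, ...) {
  cat(sprintf("thermoseg %s model (RBF-SVM)\n", toupper(x$family)))
  cat(sprintf("  %d features, %d balanced training pixels\n",
              length(x$core$features), x$n_train))
  cat(sprintf("  C = %g, gamma = %.4g, %d support vectors\n",
              x$core$cost, x$core$gamma, x$core$model$tot.nSV))
  invisible(x)
}

#' @export
summary.thermoseg <- function(object, ...) {
  print(object)
  b <- object$split$balance_record$train
  cat(sprintf("  split seed %d; train balance %d/%d per class\n",
              object$split$seed, b$after["n0"], b$after["n1"]))
  invisible(object)
}

#' Predict pixel classes from a fitted segmentation model
#'
#' @param object a [thermoseg()] model.
#' @param table a feature table with the model's feature columns.
#' @param ... unused.
#' @return Integer vector of predicted classes (0 healthy, 1 tumor).
#' @export
predict.thermoseg <- function(object, table, ...) {
  predict_svm_core(object$core, as.matrix(
    table[, object$core$features, drop = FALSE]))
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  list(confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
       accuracy = 100 * (tp + tn) / max(1, tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Evaluate a segmentation model
#'
#' Headline metrics (accuracy, sensitivity, specificity, in percent) are
#' computed on the untouched, unbalanced validation set. Generalization
#' is additionally estimated by k-fold cross-validation over the
#' balanced train-plus-test pool, refitting the imputation and
#' standardization inside every fold. A full-frame prediction map is
#' rendered over all pixels.
#'
#' @param object a [thermoseg()] model.
#' @param table the feature table the model was fit on.
#' @param cv_folds number of cross-validation folds.
#' @param cv_seed seed for the fold assignment; defaults to the split
#'   seed plus one.
#' @return An object of class `segmentation_result`.
#' @export
evaluate_segmentation <- function(object, table, cv_folds = 10,
                                  cv_seed = NULL) {
  split <- object$split
  if (is.null(cv_seed)) cv_seed <- split$seed + 1L
  feats <- object$core$features
  pred_all <- predict(object, table)
  vi <- split$validation_idx
  vm <- confusion_metrics(table$label[vi], pred_all[vi])
  tm <- confusion_metrics(table$label[split$test_idx],
                          pred_all[split$test_idx])

  pool <- c(split$train_idx, split$test_idx)
  Xp <- as.matrix(table[pool, feats, drop = FALSE])
  yp <- table$label[pool]
  folds <- with_seed(cv_seed,
                     sample(rep(seq_len(cv_folds),
                                length.out = length(pool))))
  cv_scores <- rep(NA_real_, cv_folds)
  fold_centers <- vector("list", cv_folds)
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    if (length(unique(yp[tr])) < 2 || sum(!tr) == 0) next
    core_k <- suppressWarnings(
      fit_svm_core(Xp[tr, , drop = FALSE], yp[tr],
                   object$core$cost, object$core$gamma))
    pk <- predict_svm_core(core_k, Xp[!tr, , drop = FALSE])
    cv_scores[k] <- 100 * mean(pk == yp[!tr])
    fold_centers[[k]] <- core_k$center
  }

  map <- NULL
  if (all(c("pixel_row", "pixel_col") %in% names(table))) {
    nr <- max(table$pixel_row) + 1
    nc <- max(table$pixel_col) + 1
    map <- matrix(NA_integer_, nr, nc)
    map[cbind(table$pixel_row + 1, table$pixel_col + 1)] <- pred_all
  }

  structure(list(family = object$family,
                 accuracy = vm$accuracy, sensitivity = vm$sensitivity,
                 specificity = vm$specificity, confusion = vm$confusion,
                 test_metrics = tm,
                 cv_scores = cv_scores,
                 cv_mean = mean(cv_scores, na.rm = TRUE),
                 cv_sd = sd(cv_scores, na.rm = TRUE),
                 fold_centers = fold_centers,
                 prediction_map = map,
                 hyperparams = c(C = object$core$cost,
                                 gamma = object$core$gamma)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation result (%s)\n", toupper(x$family)))
  cat(sprintf(
    "  validation: accuracy %.2f%% | sensitivity %.2f%% | specificity %.2f%%\n",
    x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  10-fold CV accuracy: %.2f%% +/- %.2f%%\n",
              x$cv_mean, x$cv_sd))
  invisible(x)
}

#' @export
plot.segmentation_result <- function(x, mask = NULL, ...) {
  map <- x$prediction_map
  image(t(map)[, nrow(map):1], col = gray.colors(2, 0.2, 0.9),
        axes = FALSE, main = sprintf("%s prediction map",
                                     toupper(x$family)), ...)
  invisible(x)
}

#' Run the full per-patient pipeline over a cohort
#'
#' For each patient (a `video` + `mask` pair, e.g. from
#' [simulate_cohort()]): extracts the time-domain and wavelet-coherence
#' feature tables, draws one split plan, then fits and evaluates one
#' model per requested family. Optionally records the per-patient
#' feature t-statistics used for the discriminability analysis.
#'
#' @param patients list of lists with elements `video` and `mask`.
#' @param families model families to fit.
#' @param seed master seed; per-patient split and reference seeds are
#'   derived from it.
#' @param fraction tumor-reference fraction for the FD features.
#' @param include_stats also compute per-patient feature t-tests.
#' @param cost,gamma SVM hyperparameters, see [thermoseg()].
#' @return List with `results` (one row per patient x family),
#'   `summary` (per-family mean and SD, shaped like a performance
#'   table), and if requested `stats` (per-patient t-statistics).
#' @export
run_cohort <- function(patients,
                       families = c("td_bl", "td_blrec", "fd_bl",
                                    "fd_blrec"),
                       seed = 1L, fraction = 0.2, include_stats = TRUE,
                       cost = 1, gamma = NULL) {
  rows <- list()
  stats <- list()
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    td <- extract_td_features(p$video, p$mask, scope = "bl_rec")
    fd <- extract_fd_features(p$video, p$mask, scope = "bl_rec",
                              fraction = fraction,
                              seed = seed + 101L * i)
    split <- make_split(td$label, seed = seed + 17L * i)
    for (fam in families) {
      tab <- if (grepl("^fd", fam)) fd else td
      model <- thermoseg(tab, family = fam, split = split, cost = cost,
                         gamma = gamma)
      ev <- evaluate_segmentation(model, tab)
      rows[[length(rows) + 1]] <- data.frame(
        patient = i, family = fam, accuracy = ev$accuracy,
        sensitivity = ev$sensitivity, specificity = ev$specificity,
        cv_mean = ev$cv_mean, cv_sd = ev$cv_sd)
    }
    if (include_stats) {
      stats[[i]] <- list(
        td = test_features(td, orientation = "class0-class1"),
        fd_bl_t = band_t_values(fd, "bl"),
        fd_rec_t = band_t_values(fd, "rec"))
    }
  }
  results <- do.call(rbind, rows)
  out <- list(results = results, summary = cohort_summary(results))
  if (include_stats) out$stats <- stats
  out
}

#' Summarize cohort results per model family
#'
#' @param results the `results` data.frame from [run_cohort()].
#' @return A `data.frame` with one row per family: mean and SD of
#'   accuracy, sensitivity and specificity over patients.
#' @export
cohort_summary <- function(results) {
  fams <- unique(results$family)
  do.call(rbind, lapply(fams, function(f) {
    r <- results[results$family == f, ]
    data.frame(family = f,
               accuracy_mean = mean(r$accuracy),
               accuracy_sd = sd(r$accuracy),
               sensitivity_mean = mean(r$sensitivity),
               sensitivity_sd = sd(r$sensitivity),
               specificity_mean = mean(r$specificity),
               specificity_sd = sd(r$specificity))
  }))
}

#' Write a cohort report to CSV
#'
#' Writes the per-patient results and the per-family summary as two CSV
#' files under `dir`.
#'
#' @param cohort result of [run_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_report <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "results.csv")
  p2 <- file.path(dir, "summary.csv")
  utils::write.csv(cohort$results, p1, row.names = FALSE)
  utils::write.csv(cohort$summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
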