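#' Feature columns of a per-pixel feature table
#'
#' Everything except the pixel coordinates, the class label, the
#' reference flag and the diagnostic `fit_R` column.
#'
#' @param table a feature `data.frame`.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table),
          c("pixel_row", "pixel_col", "label", "in_reference", "fit_R"))
}

#' Per-feature two-sample t-tests between tumor and healthy pixels
#'
#' Welch's two-sample t-test (pooled-variance optionally) for every
#' feature, comparing class 0 (healthy) against class 1 (tumor), with
#' Bonferroni correction over the features tested. Rows with missing
#' values are dropped per feature (complete rows). The `orientation`
#' controls the sign of `t`: `"class0-class1"` tests healthy minus
#' tumor; `"class1-class0"` the reverse.
#'
#' @param table a feature `data.frame` with a `label` column.
#' @param features feature columns to test; defaults to
#'   [feature_columns()].
#' @param orientation sign convention for `t`.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param alpha family-wise significance level after correction.
#' @return A `data.frame` with `feature_id`, `t_value`, `p_raw`,
#'   `p_bonferroni`, `significant`, `n0`, `n1`.
#' @export
test_features <- function(table, features = feature_columns(table),
                          orientation = c("class0-class1",
                                          "class1-class0"),
                          var_equal = FALSE, alpha = 0.05) {
  orientation <- match.arg(orientation)
  lab <- table$label
  if (!any(lab == 0) || !any(lab == 1)) {
    stop("both classes must be present in the table")
  }
  n_tests <- length(features)
  rows <- lapply(features, function(f) {
    v <- table[[f]]
    ok <- is.finite(v)
    x0 <- v[ok & lab == 0]
    x1 <- v[ok & lab == 1]
    if (length(x0) < 2 || length(x1) < 2 ||
        (var(x0) == 0 && var(x1) == 0)) {
      return(data.frame(feature_id = f, t_value = NA_real_,
                        p_raw = NA_real_, p_bonferroni = NA_real_,
                        significant = NA, n0 = length(x0),
                        n1 = length(x1)))
    }
    tt <- if (orientation == "class0-class1") {
      t.test(x0, x1, var.equal = var_equal)
    } else {
      t.test(x1, x0, var.equal = var_equal)
    }
    pb <- min(1, tt$p.value * n_tests)
    data.frame(feature_id = f, t_value = unname(tt$statistic),
               p_raw = tt$p.value, p_bonferroni = pb,
               significant = pb < alpha, n0 = length(x0),
               n1 = length(x1))
  })
  out <- do.call(rbind, rows)
  attr(out, "orientation") <- orientation
  attr(out, "n_tests") <- n_tests
  out
}

#' Most discriminative wavelet-coherence band across patients
#'
#' Averages per-band t-values (tumor-minus-healthy orientation) across
#' patients and returns the band with the maximal mean t. Ties break to
#' the lower-frequency band.
#'
#' @param t_matrix numeric matrix, patients in rows, bands in columns, of
#'   per-band t-values; or a single t-vector.
#' @param bands band layout from [wcoh_bands()] matching the columns.
#' @return List with `band`, `f_low`, `f_center`, `f_high` and `mean_t`
#'   (the per-band cross-patient means).
#' @export
max_discriminative_band <- function(t_matrix, bands = wcoh_bands()) {
  t_matrix <- rbind(t_matrix)
  if (ncol(t_matrix) != nrow(bands)) {
    stop("band layouts do not match: ", ncol(t_matrix), " t-values vs ",
         nrow(bands), " bands")
  }
  mean_t <- colMeans(t_matrix)
  k <- which(mean_t >= max(mean_t, na.rm = TRUE) - 1e-12)[1]
  list(band = bands$band[k], f_low = bands$f_low[k],
       f_center = bands$f_center[k], f_high = bands$f_high[k],
       mean_t = mean_t)
}

#' Per-band t-values of a wavelet-coherence feature table
#'
#' Convenience wrapper: runs [test_features()] on the band features of
#' one phase and returns the t-vector in band order.
#'
#' @param table an FD feature table from [extract_fd_features()].
#' @param phase `"bl"` or `"rec"`.
#' @param orientation passed to [test_features()].
#' @return Numeric vector of t-values, one per band.
#' @export
band_t_values <- function(table, phase = c("rec", "bl"),
                          orientation = "class1-class0") {
  phase <- match.arg(phase)
  feats <- grep(paste0("^wcoh_", phase, "_"), names(table), value = TRUE)
  if (length(feats) == 0) stop("table has no ", phase, " band features")
  res <- test_features(table, features = feats, orientation = orientation)
  res$t_value
}
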