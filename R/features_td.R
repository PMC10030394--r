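#' Fit the exponential thermal-recovery model to a recovery-phase trace
#'
#' Fits `y = a (1 - exp(b x)) + c` by nonlinear least squares, where `x`
#' is time from recovery onset, `a` is the asymptotic re-warming
#' amplitude, `b < 0` the (negative) inverse time constant and `c` the
#' temperature right after the cold perturbation. The fit is accepted
#' only when the goodness of fit `R = sqrt(max(R^2, 0))` — the
#' correlation form of the coefficient of determination — exceeds 0.8
#' strictly; otherwise the coefficients are reported as rejected.
#'
#' The optimisation is separable: for fixed `b` the model is linear in
#' `(a, c)`, so the profile residual sum of squares is minimised over a
#' log-spaced grid of `b` values and refined by golden-section search.
#' This is deterministic and needs no starting values. A flat trace
#' (`a = 0`, `b` unidentifiable) is rejected.
#'
#' @param signal recovery-phase temperatures, deg C (at least 10 samples).
#' @param t times in seconds from recovery onset, starting at 0,
#'   increasing.
#' @param r_threshold acceptance threshold on `R` (strict).
#' @return List with `a`, `b`, `c`, `R`, `accepted`; coefficients are
#'   `NA` when the fit is rejected (the raw estimates stay available in
#'   `raw`).
#' @export
fit_recovery <- function(signal, t, r_threshold = 0.8) {
  if (length(signal) < 10) stop("need at least 10 recovery samples")
  if (abs(t[1]) > 1e-9 || any(diff(t) <= 0)) {
    stop("t must start at 0 and be increasing")
  }
  f <- fit_recovery_matrix(matrix(signal, ncol = 1), t,
                           r_threshold = r_threshold, tol = 1e-10)
  list(a = f$a[1], b = f$b[1], c = f$c[1], R = f$R[1],
       accepted = f$accepted[1],
       raw = list(a = f$a_raw[1], b = f$b_raw[1], c = f$c_raw[1]))
}

# Batched separable least squares for y = a(1-exp(bt)) + c over the
# columns of Y. Grid over b with vectorized profile RSS, then per-column
# golden-section refinement.
fit_recovery_matrix <- function(Y, t, r_threshold = 0.8,
                                b_grid = NULL, tol = 1e-8) {
  n <- nrow(Y); P <- ncol(Y)
  if (is.null(b_grid)) {
    b_grid <- -exp(seq(log(2), log(5e-4), length.out = 80))
  }
  b_grid <- sort(b_grid)                       # ascending (most negative first)
  ybar <- colMeans(Y)
  TSS <- colSums(Y^2) - n * ybar^2
  K <- length(b_grid)
  best_rss <- rep(Inf, P)
  best_k <- rep(1L, P)
  for (k in seq_len(K)) {
    u <- 1 - exp(b_grid[k] * t)
    uc <- u - mean(u)
    suu <- sum(uc^2)
    if (suu < 1e-12) next
    suy <- as.numeric(crossprod(uc, Y))
    rss <- pmax(TSS - suy^2 / suu, 0)
    better <- rss < best_rss
    best_rss[better] <- rss[better]
    best_k[better] <- k
  }

  profile_rss <- function(b, y) {
    u <- 1 - exp(b * t)
    uc <- u - mean(u)
    suu <- sum(uc^2)
    if (suu < 1e-12) return(sum((y - mean(y))^2))
    max(sum(y^2) - n * mean(y)^2 - sum(uc * y)^2 / suu, 0)
  }

  b_hat <- numeric(P)
  for (j in seq_len(P)) {
    k <- best_k[j]
    lo <- b_grid[max(1, k - 1)]
    hi <- b_grid[min(K, k + 1)]
    if (lo == hi) {
      b_hat[j] <- lo
    } else {
      b_hat[j] <- optimize(profile_rss, c(lo, hi), y = Y[, j],
                           tol = tol)$minimum
    }
  }

  a <- cvec <- rss <- numeric(P)
  for (j in seq_len(P)) {
    u <- 1 - exp(b_hat[j] * t)
    uc <- u - mean(u)
    suu <- sum(uc^2)
    if (suu < 1e-12) {
      a[j] <- 0; cvec[j] <- ybar[j]; rss[j] <- TSS[j]
    } else {
      a[j] <- sum(uc * Y[, j]) / suu
      cvec[j] <- ybar[j] - a[j] * mean(u)
      rss[j] <- max(TSS[j] - sum(uc * Y[, j])^2 / suu, 0)
    }
  }
  R2 <- ifelse(TSS > 1e-12, 1 - rss / TSS, NA_real_)
  R <- sqrt(pmax(R2, 0))
  accepted <- !is.na(R) & R > r_threshold
  list(a = ifelse(accepted, a, NA_real_),
       b = ifelse(accepted, b_hat, NA_real_),
       c = ifelse(accepted, cvec, NA_real_),
       R = R, accepted = accepted,
       a_raw = a, b_raw = b_hat, c_raw = cvec)
}

#' Temperature variation over the whole procedure
#'
#' Difference between the average temperature in the last 10 s and in the
#' first 10 s of the recording (positive = net warming). Windows are
#' time-based: `[t0, t0 + 10)` and `(t_end - 10, t_end]` where `t_end`
#' is the exclusive end of sampling (`last timestamp + dt`).
#'
#' @param signal full temperature trace, deg C.
#' @param timestamps per-sample times, s.
#' @return Mean(last 10 s) - mean(first 10 s), deg C.
#' @export
temperature_variation <- function(signal, timestamps) {
  dt <- mean(diff(timestamps))
  t_end <- timestamps[length(timestamps)] + dt
  if (t_end - timestamps[1] < 20) {
    stop("trace must span at least 20 s")
  }
  first <- timestamps < timestamps[1] + 10
  last <- timestamps > t_end - 10
  mean(signal[last]) - mean(signal[first])
}

#' Pre-stress initial temperature
#'
#' Average temperature over the 30 s immediately preceding the cold
#' stress, `[t_injection - 30, t_injection)`.
#'
#' @param signal temperature trace, deg C.
#' @param timestamps per-sample times, s.
#' @param t_injection injection instant, s.
#' @return Mean temperature in the window, deg C.
#' @export
initial_temperature <- function(signal, timestamps, t_injection) {
  if (t_injection - timestamps[1] < 30 - 1e-9) {
    stop("need at least 30 s of data before the cold stress")
  }
  w <- timestamps >= t_injection - 30 & timestamps < t_injection
  mean(signal[w])
}

#' Distributional moments of a windowed trace
#'
#' Sample standard deviation (n-1 denominator), kurtosis (non-excess:
#' a normal distribution gives 3), skewness (third standardized moment)
#' and the empirical 90th percentile (linear interpolation between order
#' statistics, R quantile type 7). A zero-variance window yields
#' `std = 0` with skewness and kurtosis flagged undefined (`NaN`).
#'
#' @param x windowed trace values.
#' @return List with `std`, `kurtosis`, `skewness`, `p90`, `degenerate`.
#' @export
moment_features <- function(x) {
  if (length(x) < 4) stop("need at least 4 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) {
    return(list(std = 0, kurtosis = NaN, skewness = NaN,
                p90 = unname(quantile(x, 0.9, type = 7)),
                degenerate = TRUE))
  }
  list(std = sd(x),
       kurtosis = mean((x - m)^4) / m2^2,
       skewness = mean((x - m)^3) / m2^1.5,
       p90 = unname(quantile(x, 0.9, type = 7)),
       degenerate = FALSE)
}

#' Sample entropy of a trace
#'
#' `SampEn(m, r, N) = -ln(U^{m+1}(r) / U^m(r))` where `U^k(r)` counts
#' pairs of distinct length-`k` subseries matching within Chebyshev
#' distance `<= r` (self-matches excluded); the tolerance is
#' `r = r_factor * SD(trace)`. Returns `+Inf` when no `(m+1)`-length pair
#' matches and `0` (flagged degenerate) for a constant trace, where all
#' templates match at every length.
#'
#' @param x trace values (`N >= m + 2`).
#' @param m pattern length (default 2).
#' @param r_factor tolerance as a fraction of the trace SD (default 0.2).
#' @return Sample entropy in nats; attribute `degenerate` is `TRUE` for a
#'   constant trace.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  if (length(x) < m + 2) stop("need at least m + 2 samples")
  s <- sd(x)
  if (s == 0) return(structure(0, degenerate = TRUE))
  as.numeric(sampen_cpp(matrix(x, ncol = 1), as.integer(m), r_factor * s))
}

td_feature_names <- function(scope) {
  bl <- c("t_ini", "std_bl", "k_bl", "sk_bl", "p90_bl", "sampen_bl")
  if (scope == "bl") bl
  else c("a", "b", "c", "delta", bl,
         "std_rec", "k_rec", "sk_rec", "p90_rec", "sampen_rec")
}

col_moments <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  Xc <- sweep(X, 2, m)
  m2 <- colMeans(Xc^2)
  m3 <- colMeans(Xc^3)
  m4 <- colMeans(Xc^4)
  std <- sqrt(m2 * n / (n - 1))
  k <- ifelse(m2 > 0, m4 / m2^2, NaN)
  sk <- ifelse(m2 > 0, m3 / m2^1.5, NaN)
  p90 <- apply(X, 2, quantile, probs = 0.9, type = 7, names = FALSE)
  list(std = std, k = k, sk = sk, p90 = p90)
}

col_sampen <- function(X, m = 2, r_factor = 0.2) {
  n <- nrow(X)
  s <- sqrt(pmax(colMeans(X^2) - colMeans(X)^2, 0) * n / (n - 1))
  out <- numeric(ncol(X))
  pos <- s > 0
  if (any(pos)) {
    out[pos] <- sampen_cpp(X[, pos, drop = FALSE], as.integer(m),
                           r_factor * s[pos])
  }
  out[!pos] <- 0
  out
}

#' Extract the per-pixel time-domain feature table
#'
#' Computes, for every pixel, the time-domain features of the cold-stress
#' protocol. With `scope = "bl"` only baseline-window features are
#' produced (`t_ini`, `std_bl`, `k_bl`, `sk_bl`, `p90_bl`, `sampen_bl`);
#' with `scope = "bl_rec"` the recovery-phase exponential-fit
#' coefficients (`a`, `b`, `c`, gated on `fit_R > 0.8`), the whole-trace
#' temperature variation `delta` and the recovery-window features are
#' added. Pixels whose recovery fit is rejected carry `NA` fit
#' coefficients; imputation is the classifier's responsibility.
#'
#' @param video a [thermal_video()] with phase annotations.
#' @param mask logical tumor mask matching the frame size.
#' @param scope `"bl"` or `"bl_rec"`.
#' @return A `data.frame` with `pixel_row`, `pixel_col` (0-based),
#'   `label` (1 inside the mask) and the feature columns; for
#'   `scope = "bl_rec"` also the diagnostic `fit_R` column (not a
#'   classification feature).
#' @export
extract_td_features <- function(video, mask, scope = c("bl_rec", "bl")) {
  scope <- match.arg(scope)
  d <- dim(video$frames)
  stopifnot(nrow(mask) == d[2], ncol(mask) == d[3])
  X <- video_traces(video)
  tt <- video$timestamps
  ib <- phase_frames(video, "bl")
  if (length(ib) == 0) stop("baseline phase contains no frames")

  tab <- data.frame(pixel_row = rep(0:(d[2] - 1), times = d[3]),
                    pixel_col = rep(0:(d[3] - 1), each = d[2]),
                    label = as.integer(as.vector(mask)))

  BL <- X[ib, , drop = FALSE]
  mom <- col_moments(BL)
  tab$t_ini <- {
    w <- tt >= video$phases$injection - 30 & tt < video$phases$injection
    if (sum(w) == 0) stop("no frames in the 30 s pre-injection window")
    colMeans(X[w, , drop = FALSE])
  }
  tab$std_bl <- mom$std; tab$k_bl <- mom$k
  tab$sk_bl <- mom$sk; tab$p90_bl <- mom$p90
  tab$sampen_bl <- col_sampen(BL)

  if (scope == "bl_rec") {
    ir <- phase_frames(video, "rec")
    if (length(ir) == 0) stop("recovery phase requested but not annotated")
    REC <- X[ir, , drop = FALSE]
    fit <- fit_recovery_matrix(REC, tt[ir] - tt[ir[1]])
    tab$a <- fit$a; tab$b <- fit$b; tab$c <- fit$c; tab$fit_R <- fit$R
    dt <- mean(diff(tt))
    t_end <- tt[length(tt)] + dt
    tab$delta <- colMeans(X[tt > t_end - 10, , drop = FALSE]) -
      colMeans(X[tt < tt[1] + 10, , drop = FALSE])
    mom <- col_moments(REC)
    tab$std_rec <- mom$std; tab$k_rec <- mom$k
    tab$sk_rec <- mom$sk; tab$p90_rec <- mom$p90
    tab$sampen_rec <- col_sampen(REC)
  }
  attr(tab, "scope") <- scope
  attr(tab, "domain") <- "td"
  tab
}
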