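#' Frequency-band layout for wavelet-coherence features
#'
#' Defines the 60 analysis bands spanning `[0.015, 2]` Hz. Band edges are
#' log-spaced by default (wavelet scale resolution is multiplicative);
#' centers are the geometric (log) or arithmetic (linear) midpoints.
#'
#' @param n_bands number of bands.
#' @param f_range frequency range covered, Hz.
#' @param spacing `"log"` or `"linear"` edge spacing.
#' @return A `data.frame` with `band`, `f_low`, `f_center`, `f_high`
#'   (Hz), ascending in frequency.
#' @export
wcoh_bands <- function(n_bands = 60, f_range = c(0.015, 2),
                       spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(n_bands >= 2, f_range[1] > 0, f_range[2] > f_range[1])
  if (spacing == "log") {
    edges <- exp(seq(log(f_range[1]), log(f_range[2]),
                     length.out = n_bands + 1))
    centers <- sqrt(edges[-1] * edges[-(n_bands + 1)])
  } else {
    edges <- seq(f_range[1], f_range[2], length.out = n_bands + 1)
    centers <- (edges[-1] + edges[-(n_bands + 1)]) / 2
  }
  data.frame(band = seq_len(n_bands), f_low = edges[-(n_bands + 1)],
             f_center = centers, f_high = edges[-1])
}

# Morlet scale for a given Fourier frequency (centre frequency omega0).
morlet_scale <- function(f, omega0 = 6) {
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  1 / (ff * f)
}

#' Randomized tumor-region reference trace
#'
#' Mean temperature time course over a uniformly sampled
#' without-replacement subset of tumor pixels of size
#' `ceiling(fraction * n_tumor)`. This is the reference signal against
#' which every pixel's wavelet coherence is computed.
#'
#' @param video a [thermal_video()].
#' @param mask logical tumor mask.
#' @param fraction fraction of tumor pixels to draw, in `(0, 1]`.
#' @param seed RNG seed for the subset draw.
#' @return Numeric reference trace with attribute `pixels` (column-major
#'   pixel indices of the subset).
#' @export
make_reference <- function(video, mask, fraction = 0.2, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  idx <- which(as.vector(mask))
  if (length(idx) == 0) stop("tumor mask is empty")
  k <- ceiling(fraction * length(idx))
  pick <- with_seed(seed, sort(sample(idx, k)))
  X <- video_traces(video)
  structure(rowMeans(X[, pick, drop = FALSE]), pixels = pick)
}

#' Wavelet coherence between two traces
#'
#' Magnitude-squared wavelet coherence
#' `|S(Wx Wy*)|^2 / (S(|Wx|^2) S(|Wy|^2))` on the band layout of
#' [wcoh_bands()], using an analytic Morlet continuous wavelet transform
#' and a smoothing operator `S` that is a boxcar over time of span
#' `tsf * scale` seconds plus a 3-point boxcar across scales. Values lie
#' in `[0, 1]`; samples inside the cone of influence (`sqrt(2) * scale`
#' from either edge) are marked in `coi_ok`. Bands where a trace has no
#' power (e.g. constant input) come out `NaN`.
#'
#' @param x,y equal-length traces.
#' @param fs sampling frequency, Hz; must satisfy
#'   `fs / 2 >= max(bands$f_high)`.
#' @param bands band layout from [wcoh_bands()].
#' @param omega0 Morlet centre frequency parameter.
#' @param tsf time-smoothing span in units of the wavelet scale.
#' @return List with `coh` (`N x n_bands` coherence map), `coi_ok`
#'   (logical matrix, `TRUE` outside the cone of influence) and `bands`.
#' @export
wavelet_coherence <- function(x, y, fs, bands = wcoh_bands(),
                              omega0 = 6, tsf = 3) {
  if (length(x) != length(y)) stop("traces must have equal length")
  if (max(bands$f_high) > fs / 2 + 1e-12) {
    stop("band range exceeds the Nyquist frequency fs/2")
  }
  scales <- morlet_scale(bands$f_center, omega0)
  res <- wcoh_cpp(matrix(x, ncol = 1), y, 1 / fs, scales, omega0, tsf,
                  list(0:(length(x) - 1)), TRUE)
  list(coh = res$map, coi_ok = res$coi_ok > 0, bands = bands)
}

#' Time-average a coherence map over a phase window, per band
#'
#' Averages the coherence amplitude over the time samples of the window,
#' excluding samples inside the cone of influence at each band's scale.
#' Bands whose window retains no usable sample (or is shorter than one
#' period of the band's lowest frequency) are still reported, as `NaN`
#' and flagged in the `unreliable` attribute.
#'
#' @param coh `N x n_bands` coherence map from [wavelet_coherence()].
#' @param window_idx integer vector of time-sample indices (1-based) of
#'   the phase window.
#' @param coi_ok logical matrix from [wavelet_coherence()].
#' @param bands band layout; used with `fs` for the reliability flag.
#' @param fs sampling frequency, Hz.
#' @return Numeric vector of per-band means with attribute `unreliable`.
#' @export
band_average <- function(coh, window_idx, coi_ok = NULL, bands = NULL,
                         fs = NULL) {
  S <- ncol(coh)
  out <- numeric(S)
  for (s in seq_len(S)) {
    idx <- window_idx
    if (!is.null(coi_ok)) idx <- idx[coi_ok[idx, s]]
    v <- coh[idx, s]
    v <- v[is.finite(v)]
    out[s] <- if (length(v)) mean(v) else NaN
  }
  unreliable <- !is.finite(out)
  if (!is.null(bands) && !is.null(fs)) {
    win_len <- length(window_idx) / fs
    unreliable <- unreliable | (1 / bands$f_low > win_len)
  }
  structure(out, unreliable = unreliable)
}

fd_feature_names <- function(scope, n_bands = 60) {
  bl <- sprintf("wcoh_bl_%02d", seq_len(n_bands))
  if (scope == "bl") bl
  else c(bl, sprintf("wcoh_rec_%02d", seq_len(n_bands)))
}

#' Extract the per-pixel wavelet-coherence feature table
#'
#' For every pixel, computes the time-averaged wavelet coherence against
#' the randomized tumor reference in each of the 60 frequency bands, for
#' the baseline window (`scope = "bl"`, 60 features) or both baseline and
#' recovery windows (`scope = "bl_rec"`, 120 features). One transform of
#' the full trace is windowed afterwards, so phase boundaries introduce
#' no extra edge effects; cone-of-influence samples are excluded from
#' the averages. Reference-subset pixels stay in the table, flagged in
#' `in_reference`.
#'
#' @param video a [thermal_video()].
#' @param mask logical tumor mask.
#' @param scope `"bl"` or `"bl_rec"`.
#' @param fraction,seed reference-subset parameters, see
#'   [make_reference()].
#' @param bands band layout from [wcoh_bands()].
#' @param omega0,tsf wavelet parameters, see [wavelet_coherence()].
#' @return A `data.frame` with `pixel_row`, `pixel_col`, `label`,
#'   `in_reference` and the band features; attribute `bands` holds the
#'   layout.
#' @export
extract_fd_features <- function(video, mask, scope = c("bl_rec", "bl"),
                                fraction = 0.2, seed = 1L,
                                bands = wcoh_bands(), omega0 = 6,
                                tsf = 3) {
  scope <- match.arg(scope)
  d <- dim(video$frames)
  stopifnot(nrow(mask) == d[2], ncol(mask) == d[3])
  fs <- 1 / mean(diff(video$timestamps))
  if (max(bands$f_high) > fs / 2 + 1e-12) {
    stop("band range exceeds the Nyquist frequency fs/2")
  }
  X <- video_traces(video)
  ref <- make_reference(video, mask, fraction, seed)
  windows <- list(phase_frames(video, "bl") - 1L)
  if (scope == "bl_rec") {
    windows <- c(windows, list(phase_frames(video, "rec") - 1L))
  }
  scales <- morlet_scale(bands$f_center, omega0)
  res <- wcoh_cpp(X, as.numeric(ref), 1 / fs, scales, omega0, tsf,
                  windows, FALSE)

  tab <- data.frame(pixel_row = rep(0:(d[2] - 1), times = d[3]),
                    pixel_col = rep(0:(d[3] - 1), each = d[2]),
                    label = as.integer(as.vector(mask)),
                    in_reference = seq_len(ncol(X)) %in%
                      attr(ref, "pixels"))
  nb <- nrow(bands)
  A <- res$band_avg[[1]]
  colnames(A) <- sprintf("wcoh_bl_%02d", seq_len(nb))
  tab <- cbind(tab, as.data.frame(A))
  if (scope == "bl_rec") {
    B <- res$band_avg[[2]]
    colnames(B) <- sprintf("wcoh_rec_%02d", seq_len(nb))
    tab <- cbind(tab, as.data.frame(B))
  }
  attr(tab, "scope") <- scope
  attr(tab, "domain") <- "fd"
  attr(tab, "bands") <- bands
  attr(tab, "reference_pixels") <- attr(ref, "pixels")
  attr(tab, "seed") <- seed
  tab
}
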