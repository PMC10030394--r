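#' Default per-class generative parameters for the cold-stress simulator
#'
#' Returns the generative parameters of one tissue class in the synthetic
#' cold-stress scenario. Defaults encode the contrast between healthy
#' cortex and tumor tissue that the segmentation pipeline exploits:
#' tumor tissue is slightly cooler at baseline, re-warms more slowly after
#' the cold-saline wash (smaller `|b_true|`, i.e. longer time constant),
#' and its cardiac-band temperature oscillation is strongly coherent
#' across the lesion while healthy-pixel oscillations are mostly
#' independent of each other.
#'
#' @param base_mean mean baseline temperature, deg C.
#' @param base_sd spatial SD of the per-pixel baseline temperature, deg C.
#' @param drop cold-stress temperature drop at injection, deg C.
#' @param a_true asymptotic recovery amplitude, deg C.
#' @param b_true recovery rate (negative), 1/s; `-1/b_true` is the thermal
#'   recovery time constant.
#' @param f_c cardiac oscillation frequency, Hz.
#' @param cardiac_amp cardiac oscillation amplitude, deg C.
#' @param coh_weight mixing weight in `[0,1]` of the shared cardiac source;
#'   the remainder is an independent per-pixel source.
#' @param param_jitter relative SD of per-pixel variation of `a_true` and
#'   `b_true` (biological heterogeneity within a class).
#' @return A named list of class parameters.
#' @export
class_params <- function(base_mean = 33.5, base_sd = 1.0, drop = 3.5,
                         a_true = 3.3, b_true = -1 / 35, f_c = 0.71,
                         cardiac_amp = 0.03, coh_weight = 0.1,
                         param_jitter = 0.3) {
  stopifnot(b_true < 0, coh_weight >= 0, coh_weight <= 1,
            base_sd >= 0, cardiac_amp >= 0, f_c > 0, param_jitter >= 0)
  list(base_mean = base_mean, base_sd = base_sd, drop = drop,
       a_true = a_true, b_true = b_true, f_c = f_c,
       cardiac_amp = cardiac_amp, coh_weight = coh_weight,
       param_jitter = param_jitter)
}

default_tumor_polygon <- function(n_rows, n_cols, radius_frac = 0.19,
                                  n_vertices = 12) {
  r0 <- (n_rows - 1) / 2
  c0 <- (n_cols - 1) / 2
  rad <- radius_frac * min(n_rows, n_cols)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  # slight ellipticity so the lesion is not perfectly round
  cbind(row = r0 + rad * 1.15 * sin(th), col = c0 + rad * cos(th))
}

#' Scenario configuration for the synthetic thermal-video simulator
#'
#' Bundles and validates everything [simulate_thermal_video()] needs: frame
#' geometry, acquisition rate, protocol phase durations (baseline, excluded
#' post-injection transient, recovery), the tumor polygon, per-class
#' generative parameters, sensor noise and the RNG seed.
#'
#' The protocol defaults follow the intraoperative cold-stress design the
#' pipeline targets: 60 s of baseline, an instantaneous cold-saline
#' perturbation followed by a 10 s transient that no feature window
#' touches, then 120 s of recovery, sampled at 5 Hz.
#'
#' @param n_rows,n_cols frame size in pixels.
#' @param fs sampling frequency, Hz.
#' @param t_bl,t_rec baseline and recovery durations, s.
#' @param t_gap excluded post-injection transient, s.
#' @param tumor_polygon `k x 2` matrix of polygon vertices, 0-based
#'   `(row, col)` pixel coordinates with pixel centers at integers.
#' @param healthy,tumor per-class parameter lists from [class_params()].
#' @param noise_sd sensor noise SD, deg C.
#' @param cardiac_bw bandwidth of the narrowband cardiac source, Hz;
#'   independent per-pixel sources decorrelate on the `1/cardiac_bw`
#'   timescale.
#' @param drift_sd SD of the shared slow global drift of the exposed
#'   cortex (irrigation/ambient thermal drift), deg C; identical in every
#'   pixel, so it adds no class contrast.
#' @param drift_f,drift_bw centre and bandwidth of the drift spectrum, Hz.
#' @param seed integer RNG seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_rows = 64, n_cols = 64, fs = 5,
                            t_bl = 60, t_gap = 10, t_rec = 120,
                            tumor_polygon = NULL,
                            healthy = class_params(),
                            tumor = class_params(base_mean = 32.7,
                                                 drop = 4.5,
                                                 a_true = 4.2,
                                                 b_true = -1 / 80,
                                                 coh_weight = 0.9),
                            noise_sd = 0.05, cardiac_bw = 0.15,
                            drift_sd = 0.3, drift_f = 0.02,
                            drift_bw = 0.025, seed = 1L) {
  stopifnot(fs > 0, t_bl > 0, t_rec > 0, t_gap >= 0, noise_sd >= 0,
            n_rows >= 2, n_cols >= 2)
  if (is.null(tumor_polygon)) {
    tumor_polygon <- default_tumor_polygon(n_rows, n_cols)
  }
  tumor_polygon <- as.matrix(tumor_polygon)
  if (ncol(tumor_polygon) != 2 || nrow(tumor_polygon) < 3) {
    stop("tumor_polygon must be a k x 2 matrix with k >= 3")
  }
  if (abs(polygon_area(tumor_polygon)) < 1e-9) {
    stop("degenerate tumor polygon: area is zero")
  }
  if (min(tumor_polygon[, 1]) < 0 || max(tumor_polygon[, 1]) > n_rows - 1 ||
      min(tumor_polygon[, 2]) < 0 || max(tumor_polygon[, 2]) > n_cols - 1) {
    stop("tumor_polygon must lie inside the frame")
  }
  for (cl in list(healthy, tumor)) {
    if (cl$f_c >= fs / 2) {
      stop(sprintf(paste0("Nyquist violation: cardiac frequency %.3f Hz ",
                          "is not below fs/2 = %.3f Hz"), cl$f_c, fs / 2))
    }
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, fs = fs, t_bl = t_bl,
                 t_gap = t_gap, t_rec = t_rec,
                 tumor_polygon = tumor_polygon, healthy = healthy,
                 tumor = tumor, noise_sd = noise_sd,
                 cardiac_bw = cardiac_bw, drift_sd = drift_sd,
                 drift_f = drift_f, drift_bw = drift_bw,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Cold-stress thermal scenario\n")
  cat(sprintf("  frame: %d x %d px at %.4g Hz\n", x$n_rows, x$n_cols, x$fs))
  cat(sprintf("  phases: BL %gs | transient %gs | REC %gs\n",
              x$t_bl, x$t_gap, x$t_rec))
  cat(sprintf("  tumor polygon: %d vertices; noise SD %.3g degC; seed %d\n",
              nrow(x$tumor_polygon), x$noise_sd, x$seed))
  invisible(x)
}

# Shoelace area; vertices (row, col).
polygon_area <- function(poly) {
  r <- poly[, 1]; c <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(c * r[j] - c[j] * r) / 2
}
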