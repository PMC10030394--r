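#' Construct a thermal video object
#'
#' A `thermal_video` holds a temperature movie (deg C) with its timebase
#' and the protocol phase annotation. `frames` is indexed
#' `[frame, row, col]`; `timestamps` are seconds from acquisition start;
#' `phases` names the baseline interval, the injection instant and the
#' recovery interval.
#'
#' @param frames 3-D numeric array, `n_frames x n_rows x n_cols`, deg C.
#' @param timestamps numeric vector of per-frame times, s, strictly
#'   increasing.
#' @param phases list with elements `bl = c(t0, t1)`, `injection = t`,
#'   `rec = c(t2, t3)`; `t1 <= t <= t2`.
#' @param meta free-form provenance list.
#' @return An object of class `thermal_video`.
#' @export
thermal_video <- function(frames, timestamps, phases, meta = list()) {
  frames <- as.array(frames)
  stopifnot(length(dim(frames)) == 3,
            length(timestamps) == dim(frames)[1])
  if (any(!is.finite(frames))) stop("all temperatures must be finite")
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (!all(c("bl", "injection", "rec") %in% names(phases))) {
    stop("phases must name 'bl', 'injection' and 'rec'")
  }
  if (phases$bl[2] > phases$injection + 1e-12) {
    stop("baseline must end at or before the injection instant")
  }
  if (phases$rec[1] < phases$injection - 1e-12) {
    stop("recovery must begin at or after the injection instant")
  }
  structure(list(frames = frames, timestamps = timestamps,
                 phases = phases, meta = meta), class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Thermal video: %d frames of %d x %d px\n", d[1], d[2], d[3]))
  cat(sprintf("  time: %.2f..%.2f s (fs ~ %.4g Hz)\n",
              x$timestamps[1], x$timestamps[d[1]],
              1 / mean(diff(x$timestamps))))
  cat(sprintf("  BL [%g, %g) s | injection %g s | REC [%g, %g] s\n",
              x$phases$bl[1], x$phases$bl[2], x$phases$injection,
              x$phases$rec[1], x$phases$rec[2]))
  cat(sprintf("  temperature range: %.2f..%.2f degC\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Frame indices of a protocol phase
#'
#' @param video a [thermal_video()].
#' @param phase `"bl"` or `"rec"`.
#' @return Integer vector of frame indices whose timestamp lies in the
#'   half-open phase interval `[t0, t1)` for BL, `[t2, t3]` for REC.
#' @export
phase_frames <- function(video, phase = c("bl", "rec")) {
  phase <- match.arg(phase)
  tt <- video$timestamps
  iv <- video$phases[[phase]]
  if (phase == "bl") which(tt >= iv[1] & tt < iv[2])
  else which(tt >= iv[1] & tt <= iv[2] + 1e-9)
}

# n_frames x (n_rows*n_cols) trace matrix; pixel order is column-major
# over (row, col), matching as.vector(mask).
video_traces <- function(video) {
  d <- dim(video$frames)
  matrix(video$frames, nrow = d[1], ncol = d[2] * d[3])
}

#' Simulate a cold-stress thermal video
#'
#' Generates a thermal movie with the statistical structure the
#' segmentation pipeline assumes. Each pixel's trace is a constant
#' baseline level (spatially heterogeneous), a step drop of `drop` deg C at
#' the injection instant, an exponential re-warming
#' `a (1 - exp(b t))` whose clock starts at recovery onset, a narrowband
#' cardiac oscillation, and white sensor noise. Within the tumor polygon
#' the cardiac oscillation is `w * shared + (1 - w) * independent` with the
#' tumor mixing weight `w`; outside, the healthy-class weight applies. The
#' post-injection transient (`t_gap`) holds at the dropped level and is
#' excluded from every feature window downstream.
#'
#' Identical configurations (including the seed) yield bit-identical
#' output.
#'
#' @param cfg a [scenario_config()].
#' @return A list with elements `video` (a [thermal_video()]) and `mask`
#'   (logical `n_rows x n_cols` ground-truth tumor image).
#' @export
simulate_thermal_video <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  fs <- cfg$fs
  n <- round(fs * (cfg$t_bl + cfg$t_gap + cfg$t_rec))
  tt <- seq(0, by = 1 / fs, length.out = n)
  t_inj <- cfg$t_bl
  t_rec0 <- cfg$t_bl + cfg$t_gap
  mask <- rasterize_polygon(cfg$tumor_polygon, c(cfg$n_rows, cfg$n_cols))
  if (!any(mask)) stop("tumor polygon rasterizes to an empty mask")
  P <- cfg$n_rows * cfg$n_cols
  mvec <- as.vector(mask)

  with_seed(cfg$seed, {
    w_class <- ifelse(mvec, cfg$tumor$coh_weight, cfg$healthy$coh_weight)
    # draw per-pixel parameters class by class so healthy pixels do not
    # consume draws meant for tumor pixels and vice versa
    draw <- function(par, n_px) {
      list(base = rnorm(n_px, par$base_mean, par$base_sd),
           a = par$a_true * (1 + par$param_jitter * rnorm(n_px)),
           b = pmin(par$b_true * (1 + par$param_jitter * rnorm(n_px)),
                    -1e-6))
    }
    n_tum <- sum(mvec)
    ph <- draw(cfg$healthy, P - n_tum)
    pt_ <- draw(cfg$tumor, n_tum)
    base <- a_px <- b_px <- numeric(P)
    base[!mvec] <- ph$base; base[mvec] <- pt_$base
    a_px[!mvec] <- ph$a;    a_px[mvec] <- pt_$a
    b_px[!mvec] <- ph$b;    b_px[mvec] <- pt_$b
    drop_px <- ifelse(mvec, cfg$tumor$drop, cfg$healthy$drop)
    amp_px <- ifelse(mvec, cfg$tumor$cardiac_amp, cfg$healthy$cardiac_amp)
    f_px <- ifelse(mvec, cfg$tumor$f_c, cfg$healthy$f_c)

    # deterministic slow-recovery skeleton
    rec <- tt >= t_rec0
    trel <- pmax(tt - t_rec0, 0)
    # n x P trace matrix
    Tr <- matrix(rep(base, each = n), nrow = n)
    stepdown <- outer(as.numeric(tt >= t_inj), drop_px)
    Tr <- Tr - stepdown
    Erec <- 1 - exp(outer(trel, b_px))
    Erec[!rec, ] <- 0
    Tr <- Tr + Erec * matrix(rep(a_px, each = n), nrow = n)

    # narrowband cardiac sources: one shared process plus independent
    # per-pixel processes, all band-passed Gaussian noise centred at f_c
    s_shared <- bandpass_noise(n, 1, fs, cfg$tumor$f_c, cfg$cardiac_bw)[, 1]
    s_own <- matrix(0, n, P)
    s_own[, !mvec] <- bandpass_noise(n, P - n_tum, fs, cfg$healthy$f_c,
                                     cfg$cardiac_bw)
    s_own[, mvec] <- bandpass_noise(n, n_tum, fs, cfg$tumor$f_c,
                                    cfg$cardiac_bw)
    cardiac <- s_shared %o% (amp_px * w_class) +
      s_own * matrix(rep(amp_px * (1 - w_class), each = n), nrow = n)
    Tr <- Tr + cardiac

    # shared slow global drift of the exposed cortex: identical in every
    # pixel, hence no class contrast, but it anchors the low-frequency
    # coherence of all pixels to the reference
    if (cfg$drift_sd > 0) {
      Tr <- Tr + cfg$drift_sd *
        bandpass_noise(n, 1, fs, cfg$drift_f, cfg$drift_bw)[, 1]
    }

    if (cfg$noise_sd > 0) {
      Tr <- Tr + matrix(rnorm(n * P, 0, cfg$noise_sd), nrow = n)
    }

    video <- thermal_video(
      frames = array(Tr, dim = c(n, cfg$n_rows, cfg$n_cols)),
      timestamps = tt,
      phases = list(bl = c(0, t_inj), injection = t_inj,
                    rec = c(t_rec0, tt[n])),
      meta = list(generator = "simulate_thermal_video", seed = cfg$seed,
                  fs = fs, n_tumor = n_tum))
    list(video = video, mask = mask)
  })
}

#' Simulate a cohort of synthetic patients
#'
#' Repeats [simulate_thermal_video()] with per-patient seeds and a
#' patient-level baseline temperature offset (inter-patient cortical
#' temperature variability), keeping the within-patient class structure
#' fixed.
#'
#' @param n_patients number of synthetic patients.
#' @param cfg base [scenario_config()]; per-patient seeds are derived from
#'   `seed`.
#' @param seed cohort-level seed.
#' @param patient_sd SD of the patient-level baseline offset, deg C.
#' @return A list of `n_patients` elements, each with `video`, `mask` and
#'   `patient_id`.
#' @export
simulate_cohort <- function(n_patients = 5, cfg = scenario_config(),
                            seed = 1L, patient_sd = 1.5) {
  stopifnot(n_patients >= 1)
  offsets <- with_seed(seed, rnorm(n_patients, 0, patient_sd))
  lapply(seq_len(n_patients), function(i) {
    ci <- cfg
    ci$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    ci$healthy$base_mean <- cfg$healthy$base_mean + offsets[i]
    ci$tumor$base_mean <- cfg$tumor$base_mean + offsets[i]
    sim <- simulate_thermal_video(ci)
    sim$patient_id <- i
    sim
  })
}

#' Generate paired control points under a known affine map
#'
#' Fixture generator for the co-registration stage: samples `n_points`
#' well-spread points on the visible image and maps them through
#' `true_affine`, adding Gaussian jitter of SD `jitter_sd` to the thermal
#' side (landmark placement error).
#'
#' @param cfg a [scenario_config()] (frame geometry).
#' @param true_affine an [affine_map()].
#' @param n_points number of point pairs, at least 3.
#' @param jitter_sd landmark jitter SD, px.
#' @param seed RNG seed.
#' @return List with matrices `src` and `dst` (`n_points x 2`, 0-based
#'   `(row, col)`).
#' @export
make_control_points <- function(cfg, true_affine, n_points = 6,
                                jitter_sd = 0, seed = 1L) {
  if (n_points < 3) stop("at least 3 control points are required")
  stopifnot(inherits(true_affine, "affine_map"))
  with_seed(seed, {
    for (attempt in 1:50) {
      src <- cbind(runif(n_points, 0, cfg$n_rows - 1),
                   runif(n_points, 0, cfg$n_cols - 1))
      if (!points_collinear(src)) break
      if (attempt == 50) stop("could not sample non-collinear points")
    }
    dst <- apply_affine(true_affine, src) +
      matrix(rnorm(2 * n_points, 0, jitter_sd), ncol = 2)
    list(src = src, dst = dst)
  })
}

# Unit-variance Gaussian noise band-passed with a Gaussian frequency
# window centred at f_c (bandwidth bw, Hz). Independent columns
# decorrelate on the 1/bw timescale, so coherence between them reflects
# only the smoothing-induced estimator floor.
bandpass_noise <- function(n, P, fs, f_c, bw) {
  if (P == 0) return(matrix(0, n, 0))
  W <- matrix(rnorm(n * P), n, P)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  H <- exp(-0.5 * ((f - f_c) / bw)^2)
  X <- Re(stats::mvfft(stats::mvfft(W) * H, inverse = TRUE)) / n
  s <- sqrt(pmax(colMeans(X^2) - colMeans(X)^2, 1e-300))
  sweep(X, 2, s, "/")
}

points_collinear <- function(pts, tol = 1e-8) {
  if (nrow(pts) < 3) return(TRUE)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  sv[2] <= tol * max(sv[1], 1)
}
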