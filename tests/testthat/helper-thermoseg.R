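# Desk-scale scenario used by most unit tests: 16x16 px, shortened
# protocol (40 s BL / 4 s transient / 60 s REC at 5 Hz). Full-scale
# cohort runs live in the acceptance tests only.
mini_cfg <- function(..., seed = 42L) {
  scenario_config(n_rows = 16, n_cols = 16, t_bl = 40, t_gap = 4,
                  t_rec = 60, seed = seed, ...)
}

# Deterministic variant: every stochastic generator component off, and no
# within-class parameter spread, so per-class traces are analytic.
quiet_cfg <- function(..., base_sd = 0, seed = 42L) {
  mini_cfg(
    healthy = class_params(base_sd = base_sd, cardiac_amp = 0,
                           param_jitter = 0),
    tumor = class_params(base_mean = 32.7, drop = 4.5, a_true = 4.2,
                         b_true = -1 / 80, base_sd = base_sd,
                         cardiac_amp = 0, coh_weight = 0.9,
                         param_jitter = 0),
    noise_sd = 0, drift_sd = 0, seed = seed, ...)
}

# Exhaustive O(N^2) pair-counting sample entropy, independent of the
# compiled implementation.
sampen_oracle <- function(x, m = 2, r) {
  N <- length(x)
  nt <- N - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(NaN)
  if (A == 0) return(Inf)
  -log(A / B)
}

# Normal-equations affine estimate by explicit matrix inversion.
affine_oracle <- function(src, dst) {
  X <- cbind(src, 1)
  beta <- solve(t(X) %*% X) %*% t(X) %*% dst
  list(A = t(beta[1:2, , drop = FALSE]), offset = as.numeric(beta[3, ]))
}
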