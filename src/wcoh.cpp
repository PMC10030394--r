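#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Morlet wavelet coherence, batched over pixels.
//
// The CWT is computed in the frequency domain with an analytic Morlet
// wavelet (centre frequency omega0); the constant amplitude factor is
// dropped because it cancels in the coherence ratio. Smoothing is a
// truncated boxcar over time of span tsf*scale seconds plus a 3-point
// boxcar across adjacent scales; coherence is the magnitude-squared
// smoothed cross-spectrum over the product of smoothed auto-spectra.
// Samples inside the cone of influence (sqrt(2)*scale e-folding from
// either edge) are excluded from the per-window band averages.

template <typename MT>
static MT movavg_rows(const MT& M, int L) {
  const int N = M.n_rows;
  if (L <= 1) return M;
  const int h = L / 2;
  MT CS = cumsum(M, 0);
  MT out(M.n_rows, M.n_cols);
  // interior rows in one block operation; truncated windows at the edges
  if (N > 2 * h + 1) {
    out.rows(h + 1, N - 1 - h) =
        (CS.rows(2 * h + 1, N - 1) - CS.rows(0, N - 2 * h - 2)) /
        double(2 * h + 1);
    out.row(h) = CS.row(2 * h) / double(2 * h + 1);
  }
  const int lo_end = std::min(N - 1, h - 1);
  for (int t = 0; t <= lo_end; ++t) {
    int hi = std::min(N - 1, t + h);
    out.row(t) = CS.row(hi) / double(hi + 1);
  }
  for (int t = std::max(h + 1, N - 1 - h + 1); t < N; ++t) {
    int lo = std::max(0, t - h);
    if (lo == 0) out.row(t) = CS.row(N - 1) / double(N);
    else out.row(t) = (CS.row(N - 1) - CS.row(lo - 1)) / double(N - lo);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List wcoh_cpp(const arma::mat& X, const arma::vec& y, double dt,
                    const arma::vec& scales, double omega0, double tsf,
                    const Rcpp::List& windows, bool return_map) {
  const int N = X.n_rows, P = X.n_cols, S = scales.n_elem;
  const int W = windows.size();
  if ((int)y.n_elem != N) Rcpp::stop("length(y) must equal nrow(X)");

  int Npad = 1;
  while (Npad < N) Npad <<= 1;

  mat Xp(Npad, P, fill::zeros);
  for (int j = 0; j < P; ++j) Xp.col(j).head(N) = X.col(j) - mean(X.col(j));
  vec yp(Npad, fill::zeros);
  yp.head(N) = y - mean(y);

  cx_mat Fx = fft(Xp);
  cx_vec Fy = fft(yp);

  // positive angular frequencies of the padded grid
  vec wk(Npad, fill::zeros);
  for (int k = 1; k <= Npad / 2; ++k) wk(k) = 2.0 * M_PI * k / (Npad * dt);

  // ring buffers of time-smoothed quantities for 3-point scale smoothing
  std::vector<cx_mat> cr(3);
  std::vector<mat> px(3);
  std::vector<vec> py(3);

  std::vector<mat> out(W);
  for (int w = 0; w < W; ++w) out[w] = mat(P, S, fill::value(datum::nan));
  std::vector<uvec> widx(W);
  for (int w = 0; w < W; ++w) {
    Rcpp::IntegerVector iv = windows[w];
    widx[w] = conv_to<uvec>::from(
        std::vector<unsigned long long>(iv.begin(), iv.end()));
  }

  mat map;
  umat coi_ok;
  if (return_map) {
    if (P != 1) Rcpp::stop("return_map requires a single trace pair");
    map = mat(N, S, fill::value(datum::nan));
    coi_ok = umat(N, S, fill::zeros);
  }

  auto compute_scale = [&](int si) {
    const double s = scales(si);
    vec h(Npad, fill::zeros);
    for (int k = 1; k <= Npad / 2; ++k) {
      double u = s * wk(k) - omega0;
      h(k) = std::exp(-0.5 * u * u);
    }
    cx_vec hc = conv_to<cx_vec>::from(h);
    cx_mat Wx = ifft(Fx.each_col() % hc);
    cx_vec wy = ifft(Fy % hc);
    Wx = Wx.head_rows(N);
    wy = wy.head(N);

    int L = std::max(1, (int)std::lround(tsf * s / dt));
    if (L % 2 == 0) ++L;
    if (L > N) L = (N % 2 == 1) ? N : N - 1;

    const int slot = si % 3;
    cx_vec wyc = conj(wy);
    cr[slot] = movavg_rows(cx_mat(Wx.each_col() % wyc), L);
    px[slot] = movavg_rows(mat(square(abs(Wx))), L);
    py[slot] = movavg_rows(mat(square(abs(wy))), L).col(0);
  };

  auto emit_scale = [&](int e, int computed_up_to) {
    const int lo = std::max(0, e - 1), hi = std::min({S - 1, e + 1,
                                                      computed_up_to});
    cx_mat C(N, P, fill::zeros);
    mat PX(N, P, fill::zeros);
    vec PY(N, fill::zeros);
    for (int k = lo; k <= hi; ++k) {
      const int slot = k % 3;
      C += cr[slot];
      PX += px[slot];
      PY += py[slot];
    }
    const double nn = double(hi - lo + 1);
    C /= nn; PX /= nn; PY /= nn;

    mat denom = PX.each_col() % PY;
    mat coh = square(abs(C));
    for (uword i = 0; i < coh.n_elem; ++i) {
      double d = denom(i);
      if (d <= 1e-300 || !std::isfinite(d)) coh(i) = datum::nan;
      else {
        coh(i) /= d;
        if (coh(i) < 0.0) coh(i) = 0.0;
        if (coh(i) > 1.0) coh(i) = 1.0;
      }
    }

    const double coi_t = std::sqrt(2.0) * scales(e);
    std::vector<unsigned long long> ok;
    ok.reserve(N);
    for (int t = 0; t < N; ++t) {
      if (std::min(t, N - 1 - t) * dt >= coi_t) ok.push_back(t);
    }
    uvec okv = conv_to<uvec>::from(ok);

    for (int w = 0; w < W; ++w) {
      uvec idx = intersect(widx[w], okv);
      if (idx.n_elem == 0) continue;
      mat sub = coh.rows(idx);
      rowvec mn(P);
      for (int j = 0; j < P; ++j) {
        vec cj = sub.col(j);
        uvec fin = find_finite(cj);
        mn(j) = fin.n_elem ? mean(cj.elem(fin)) : datum::nan;
      }
      out[w].col(e) = mn.t();
    }

    if (return_map) {
      map.col(e) = coh.col(0);
      for (uword t = 0; t < okv.n_elem; ++t) coi_ok(okv(t), e) = 1;
    }
  };

  for (int si = 0; si < S; ++si) {
    compute_scale(si);
    if (si >= 1) emit_scale(si - 1, si);
  }
  if (S >= 1) emit_scale(S - 1, S - 1);

  Rcpp::List avg(W);
  for (int w = 0; w < W; ++w) avg[w] = out[w];
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("band_avg") = avg);
  if (return_map) {
    res["map"] = map;
    res["coi_ok"] = coi_ok;
  }
  return res;
}
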