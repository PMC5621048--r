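#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Discrete quadratic (Cohen-class) time-frequency machinery.
//
// Conventions, shared with the R-level direct-summation oracle:
//  * s is the analytic signal, length W.
//  * The instantaneous autocorrelation K(n, k) = s[n + ceil(k/2)] *
//    conj(s[n - floor(k/2)]) is evaluated on integer lags k =
//    -(W-1)..(W-1) without interpolation; samples outside the segment
//    are zero (no periodic extension). This indexing keeps K Hermitian
//    in k, so the final distribution is real up to FFT round-off.
//  * The lag axis is stored with length L = 2N (k wrapped mod L, with
//    L >= 2W-1 there is no collision), so the final lag DFT yields 2N
//    frequency bins of which the N non-negative ones are retained:
//    freq bin f corresponds to f * fs / (2N) Hz, covering [0, fs/2).
//  * Doppler phi is in cycles/sample (DFT index m over W time points,
//    signed as m/W for m <= W/2, (m-W)/W above); lag tau in samples.
//    The Choi-Williams kernel is evaluated on this unitless grid.
//  * The distribution is scaled by 1/fs so that the full-axis time
//    marginal sum_f Gamma(t,f) * df equals |s(t)|^2 exactly.

static inline int lag_up(int k)   { return (k >= 0) ?  (k + 1) / 2 : -((-k) / 2); }
static inline int lag_down(int k) { return (k >= 0) ?  k / 2       : -(((-k) + 1) / 2); }

// Build the W x L instantaneous autocorrelation with wrapped lag axis.
static cx_mat inst_autocorr(const cx_vec& s, const int L) {
  const int W = s.n_elem;
  cx_mat K(W, L, fill::zeros);
  for (int k = -(W - 1); k <= W - 1; ++k) {
    const int c  = ((k % L) + L) % L;
    const int up = lag_up(k), dn = lag_down(k);
    const int n0 = std::max(0, std::max(-up, dn));
    const int n1 = std::min(W - 1, std::min(W - 1 - up, W - 1 + dn));
    for (int n = n0; n <= n1; ++n)
      K(n, c) = s[n + up] * std::conj(s[n - dn]);
  }
  return K;
}

static inline double doppler_cps(const int m, const int W) {
  return (m <= W / 2) ? m / (double)W : (m - W) / (double)W;
}

static inline double signed_lag(const int c, const int N) {
  return (c < N) ? (double)c : (double)(c - 2 * N);
}

// [[Rcpp::export]]
arma::cx_mat cpp_ambiguity(const arma::cx_vec& s, const int N) {
  // AF(m, k) = sum_n K(n, k) exp(+j 2 pi m n / W): Doppler transform of
  // the instantaneous autocorrelation (positive-exponent convention).
  const int L = 2 * N;
  cx_mat K = inst_autocorr(s, L);
  return ifft(K) * (double)s.n_elem;
}

// [[Rcpp::export]]
Rcpp::List cpp_tfd(const arma::cx_vec& s, const int N, const int family,
                   const double gamma_par, const int mult_form,
                   const double fs) {
  const int W = s.n_elem;
  const int L = 2 * N;

  // compact autocorrelation: only the 2W-1 populated lags, column j
  // holding lag k = j - (W-1)
  cx_mat K(W, 2 * W - 1, fill::zeros);
  for (int k = -(W - 1); k <= W - 1; ++k) {
    const int j  = k + W - 1;
    const int up = lag_up(k), dn = lag_down(k);
    const int n0 = std::max(0, std::max(-up, dn));
    const int n1 = std::min(W - 1, std::min(W - 1 - up, W - 1 + dn));
    for (int n = n0; n <= n1; ++n)
      K(n, j) = s[n + up] * std::conj(s[n - dn]);
  }

  if (family == 1) { // Choi-Williams: filter in the ambiguity domain
    cx_mat A = fft(K); // columnwise over n -> Doppler index m
    for (int j = 0; j < (int)K.n_cols; ++j) {
      const double tau = j - (W - 1);
      for (int m = 0; m < W; ++m) {
        const double phi = doppler_cps(m, W);
        const double pt  = phi * tau;
        const double arg = mult_form ? pt * pt * gamma_par * gamma_par
                                     : pt * pt / (gamma_par * gamma_par);
        A(m, j) *= std::exp(-arg);
      }
    }
    K = ifft(A);
  }

  // lag -> frequency: scatter the populated lags onto the wrapped
  // 2N-point lag axis, DFT each time row, keep the N
  // non-negative-frequency bins
  cx_mat P(L, W, fill::zeros);
  for (int j = 0; j < (int)K.n_cols; ++j) {
    const int k = j - (W - 1);
    const int r = ((k % L) + L) % L;
    P.row(r) = K.col(j).st();
  }
  cx_mat G = fft(P);                // columnwise over lag, length L
  cx_mat Gpos = G.rows(0, N - 1).st() / fs; // W x N

  const double tot = norm(Gpos, "fro");
  const double imr = (tot > 0) ? norm(imag(Gpos), "fro") / tot : 0.0;
  mat out = real(Gpos);
  return Rcpp::List::create(Rcpp::Named("gamma") = out,
                            Rcpp::Named("im_ratio") = imr);
}

// Column-wise lower/upper quartile spread by order statistics: for each
// column sort the W values and take ranks round((W+1)/4), round(3(W+1)/4)
// (1-based); returns mean over columns of (Q3 - Q1).
// [[Rcpp::export]]
double cpp_iqr_mean(const arma::mat& G) {
  const int W = G.n_rows, N = G.n_cols;
  const int r1 = (int)std::lround((W + 1) / 4.0);
  const int r3 = (int)std::lround(3.0 * (W + 1) / 4.0);
  const int i1 = std::min(std::max(r1, 1), W) - 1;
  const int i3 = std::min(std::max(r3, 1), W) - 1;
  double acc = 0.0;
  vec col(W);
  for (int j = 0; j < N; ++j) {
    col = sort(G.col(j));
    acc += col[i3] - col[i1];
  }
  return acc / N;
}

// All twelve features of one time-frequency matrix in a few passes.
// Mirrors the R per-feature definitions exactly (shared floor policy:
// magnitudes floored at floor_rel * max|G| before log / geometric
// mean). Returns the 12 values plus a degeneracy flag for the
// skewness/kurtosis guard (variance <= 1e-12 * mean^2).
// [[Rcpp::export]]
Rcpp::List cpp_tf_features(const arma::mat& G, const double floor_rel,
                           const int tf3_literal, const int renyi_order) {
  const int W = G.n_rows, N = G.n_cols;
  const double n = (double)W * N;
  const double maxabs = std::max(abs(G).max(),
                                 std::numeric_limits<double>::min());
  const double eps = floor_rel * maxabs;

  double sum = 0, sum2 = 0, sum3 = 0, sumabs = 0, sumlog = 0;
  for (int j = 0; j < N; ++j) for (int i = 0; i < W; ++i) {
    const double x = G(i, j);
    sum += x; sum2 += x * x; sum3 += x * x * x;
    const double a = std::max(std::fabs(x), eps);
    sumabs += a; sumlog += std::log(a);
  }
  const double m = sum / n;
  double c2 = 0, c3 = 0, c4 = 0, adev = 0;
  for (int j = 0; j < N; ++j) for (int i = 0; i < W; ++i) {
    const double d = G(i, j) - m;
    const double d2 = d * d;
    c2 += d2; c3 += d2 * d; c4 += d2 * d2; adev += std::fabs(d);
  }
  const double v = c2 / n;
  const bool degen = v <= 1e-12 * std::max(m * m,
                                 std::numeric_limits<double>::min());

  Rcpp::NumericVector tf(12);
  tf[0] = sumlog;                                        // TF1
  tf[1] = adev / n;                                      // TF2
  tf[2] = tf3_literal ? m : std::sqrt(sum2 / n);         // TF3
  tf[3] = cpp_iqr_mean(G);                               // TF4
  tf[4] = m;                                             // TF5
  tf[5] = v;                                             // TF6
  tf[6] = degen ? 0.0 : (c3 / n) / std::pow(v, 1.5);     // TF7
  tf[7] = degen ? 0.0 : (c4 / n) / (v * v);              // TF8
  tf[8] = std::exp(sumlog / n) / (sumabs / n);           // TF9
  double flux = 0;                                       // TF10
  for (int j = 0; j < N - 1; ++j) for (int i = 0; i < W - 1; ++i)
    flux += G(i + 1, j + 1) - G(i, j);
  tf[9] = flux;
  if (sum == 0) {                                        // TF11
    tf[10] = NA_REAL;
  } else if (renyi_order == 3) {
    tf[10] = -0.5 * std::log2(sum3 / (sum * sum * sum));
  } else {
    tf[10] = -std::log2(sum2 / (sum * sum));
  }
  tf[11] = sum2;                                         // TF12
  return Rcpp::List::create(Rcpp::Named("tf") = tf,
                            Rcpp::Named("degenerate") = degen,
                            Rcpp::Named("zero_sum") = (sum == 0));
}
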