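#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Drift of the firing-rate network: tau * dx/dt = -x + s*phi(x) + g*W*phi(x) + I,
// phi = tanh, W[i,j] = synaptic weight of the edge j -> i (receiver rows).
static inline arma::vec drift(const arma::mat& W, const arma::vec& x,
                              double s, double g, double tau,
                              const arma::vec& I, const arma::vec& row_sums,
                              bool balance) {
  arma::vec ph = arma::tanh(x);
  arma::vec coup = W * ph;
  if (balance) coup -= row_sums * arma::mean(ph);
  return (-x + s * ph + g * coup + I) / tau;
}

// Explicit midpoint (RK2) integration with piecewise-constant external input:
// one Gaussian noise draw per node per outer step, held fixed across the two
// stage evaluations. Uses R's RNG so set.seed() governs reproducibility.
//
// stim_cond: per-step condition index (0 = no stimulation), may be length 0.
// stim_nodes: one column of 1-based node indices per condition.
// ext_input: optional dense n_nodes x n_steps input (0 x 0 when unused).
// record_from: number of leading (burn-in) steps to discard from the output.
// [[Rcpp::export]]
arma::mat rk2_integrate(const arma::mat& W, arma::vec x, double s, double g,
                        double tau, double dt, int n_steps, double noise_sd,
                        Rcpp::IntegerVector stim_cond,
                        Rcpp::IntegerMatrix stim_nodes, double stim_amp,
                        Rcpp::NumericMatrix ext_input, int record_from,
                        bool balance) {
  const int n = W.n_rows;
  const bool has_sched = stim_cond.size() > 0;
  const bool has_ext = ext_input.nrow() > 0;
  const int n_rec = n_steps - record_from;
  arma::mat out(n, n_rec);
  arma::vec I(n);
  const arma::vec row_sums = arma::sum(W, 1);
  for (int t = 0; t < n_steps; ++t) {
    if (noise_sd > 0.0) {
      for (int i = 0; i < n; ++i) I[i] = noise_sd * R::norm_rand();
    } else {
      I.zeros();
    }
    if (has_ext)
      for (int i = 0; i < n; ++i) I[i] += ext_input(i, t);
    if (has_sched && stim_cond[t] > 0) {
      const int c = stim_cond[t] - 1;
      for (int k = 0; k < stim_nodes.nrow(); ++k)
        I[stim_nodes(k, c) - 1] += stim_amp;
    }
    const arma::vec k1 = drift(W, x, s, g, tau, I, row_sums, balance);
    const arma::vec k2 = drift(W, x + 0.5 * dt * k1, s, g, tau, I, row_sums, balance);
    x += dt * k2;
    if (!x.is_finite())
      Rcpp::stop("state became non-finite at integration step %d", t + 1);
    if (t >= record_from) out.col(t - record_from) = x;
  }
  return out;
}

// Heun (trapezoidal RK2) variant, used only to verify insensitivity of the
// simulated statistics to the choice of second-order scheme.
// [[Rcpp::export]]
arma::mat rk2_integrate_heun(const arma::mat& W, arma::vec x, double s,
                             double g, double tau, double dt, int n_steps,
                             double noise_sd, Rcpp::IntegerVector stim_cond,
                             Rcpp::IntegerMatrix stim_nodes, double stim_amp,
                             Rcpp::NumericMatrix ext_input, int record_from,
                             bool balance) {
  const int n = W.n_rows;
  const bool has_sched = stim_cond.size() > 0;
  const bool has_ext = ext_input.nrow() > 0;
  arma::mat out(n, n_steps - record_from);
  arma::vec I(n);
  const arma::vec row_sums = arma::sum(W, 1);
  for (int t = 0; t < n_steps; ++t) {
    if (noise_sd > 0.0) {
      for (int i = 0; i < n; ++i) I[i] = noise_sd * R::norm_rand();
    } else {
      I.zeros();
    }
    if (has_ext)
      for (int i = 0; i < n; ++i) I[i] += ext_input(i, t);
    if (has_sched && stim_cond[t] > 0) {
      const int c = stim_cond[t] - 1;
      for (int k = 0; k < stim_nodes.nrow(); ++k)
        I[stim_nodes(k, c) - 1] += stim_amp;
    }
    const arma::vec k1 = drift(W, x, s, g, tau, I, row_sums, balance);
    const arma::vec k2 = drift(W, x + dt * k1, s, g, tau, I, row_sums, balance);
    x += 0.5 * dt * (k1 + k2);
    if (!x.is_finite())
      Rcpp::stop("state became non-finite at integration step %d", t + 1);
    if (t >= record_from) out.col(t - record_from) = x;
  }
  return out;
}

// Causal FIR convolution with kernel h followed by decimation: output sample
// m (0-based) is the full convolution evaluated at input index
// (m+1)*factor - 1, i.e. the last sample of each output interval.
// [[Rcpp::export]]
arma::mat convolve_decimate(const arma::mat& X, const arma::vec& h,
                            int factor) {
  const int T = X.n_cols, L = h.n_elem;
  const int n_out = T / factor;
  arma::mat out(X.n_rows, n_out, arma::fill::zeros);
  for (int m = 0; m < n_out; ++m) {
    const int t_end = (m + 1) * factor - 1;
    const int lmax = std::min<int>(L - 1, t_end);
    for (int l = 0; l <= lmax; ++l)
      out.col(m) += h[l] * X.col(t_end - l);
  }
  return out;
}

// Per-target least squares for multiple-regression FC. X is T x n with
// demeaned columns; for each target i the remaining columns are regressors
// and the QR-based solver (no normal equations) supplies the coefficients.
// Returns the n x n source-by-target coefficient matrix, zero diagonal.
// [[Rcpp::export]]
arma::mat multreg_coefficients(const arma::mat& X) {
  const int n = X.n_cols;
  arma::mat B(n, n, arma::fill::zeros);
  const arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    const arma::uvec others = arma::find(all != (unsigned) i);
    arma::vec b;
    const bool ok = arma::solve(b, X.cols(others), X.col(i),
                                arma::solve_opts::no_approx);
    if (!ok)
      Rcpp::stop("least-squares solve failed for target node %d "
                 "(rank-deficient regressor matrix)", i + 1);
    for (arma::uword k = 0; k < others.n_elem; ++k) B(others(k), i) = b(k);
  }
  return B;
}
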