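// Reservoir simulation and readout training. This is the package's only hot
// loop: the per-timestep recurrence cannot be vectorized in R, and the
// density sweep multiplies it by subjects x densities x trials.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Pearson correlation with the degenerate-case policy: zero variance in
// either argument gives 0, not NaN.
static double safe_cor(const vec& a, const vec& b) {
  double sa = stddev(a), sb = stddev(b);
  if (sa <= 0.0 || sb <= 0.0) return 0.0;
  double c = as_scalar(cor(a, b));
  if (!std::isfinite(c)) return 0.0;
  return c;
}

// Iterate r(t+1) = tanh(W_in u(t) + W r(t)) from r(1) = 0 and return the
// post-washout states: column j holds r(washout + j), j = 1..T-washout.
// State r(t) has seen inputs u(1..t-1), so the delay-tau target for column j
// is u(washout + j - tau).
// [[Rcpp::export(name = ".sim_states_cpp")]]
arma::mat sim_states_cpp(const arma::mat& W, const arma::vec& win,
                         const arma::vec& u, const int washout) {
  const int T = u.n_elem;
  const int N = W.n_rows;
  const int nsig = T - washout;
  mat R(N, nsig);
  vec r(N, fill::zeros);
  for (int t = 1; t <= T; ++t) {
    if (t > washout) R.col(t - washout - 1) = r;
    if (t < T) r = tanh(win * u[t - 1] + W * r);
  }
  if (!R.is_finite()) Rcpp::stop("non-finite reservoir state");
  return R;
}

// Forgetting curve(s) for one trial. Global readout: W_out = y R^T X_R with
// X_R the Moore-Penrose pseudoinverse of R R^T (singular values below
// 1e-12 * s_max dropped -> minimum-norm least squares). Regional readout:
// scalar least squares on a single node's activation row.
// [[Rcpp::export(name = ".trial_curves_cpp")]]
Rcpp::List trial_curves_cpp(const arma::mat& W, const arma::vec& win,
                            const arma::vec& u, const int washout,
                            const arma::ivec& taus, const bool do_global,
                            const bool do_regional) {
  mat R = sim_states_cpp(W, win, u, washout);
  const int N = R.n_rows;
  const int nsig = R.n_cols;
  const int ntau = taus.n_elem;

  vec rho_global(ntau, fill::zeros);
  mat rho_regional;
  mat P;
  if (do_global) {
    mat G = R * R.t();
    double smax = norm(G, 2);
    P = pinv(G, 1e-12 * smax);
  }
  if (do_regional) rho_regional.zeros(N, ntau);

  // per-node second moments for the regional scalar readouts
  vec node_ss(N);
  if (do_regional) {
    for (int i = 0; i < N; ++i) node_ss[i] = dot(R.row(i), R.row(i));
  }

  for (int k = 0; k < ntau; ++k) {
    const int tau = taus[k];
    vec y(nsig);
    for (int j = 0; j < nsig; ++j) y[j] = u[washout + j - tau];
    if (do_global) {
      vec a = R * y;          // (y R^T)^T
      vec wout = P * a;       // minimum-norm readout weights
      vec pred = R.t() * wout;
      rho_global[k] = safe_cor(pred, y);
    }
    if (do_regional) {
      for (int i = 0; i < N; ++i) {
        if (node_ss[i] <= 0.0) { rho_regional(i, k) = 0.0; continue; }
        rowvec ri = R.row(i);
        double w1 = dot(ri, y) / node_ss[i];
        vec pred = w1 * ri.t();
        rho_regional(i, k) = safe_cor(pred, y);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("global") = rho_global,
                            Rcpp::Named("regional") = rho_regional);
}
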