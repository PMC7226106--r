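// Compiled core for the linear compartmental systems: matrix-exponential
// propagation of state amounts for multi-dose regimens and steady-state
// dosing.  All doses are oral boluses into compartment 1 (the gut); lag
// times are handled by the R callers, which shift dose times before calling
// in here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;

// State amounts at `times` for bolus doses `amts` into compartment 1 at
// `dose_times` (already lag-shifted), starting from zero amounts.
// Sequential propagation: one expmat per inter-event step.
// [[Rcpp::export]]
arma::mat cpp_profile_states(const arma::mat& A, const arma::vec& dose_times,
                             const arma::vec& amts, const arma::vec& times) {
  const arma::uword K = A.n_rows;
  arma::mat out(times.n_elem, K);
  // merge events (doses) and outputs in time order
  arma::uvec ord = arma::sort_index(times);
  vec x(K, arma::fill::zeros);
  double t_cur = 0.0;
  arma::uword j = 0;  // next dose
  for (arma::uword oi = 0; oi < ord.n_elem; ++oi) {
    double t_out = times(ord(oi));
    while (j < dose_times.n_elem && dose_times(j) <= t_out) {
      double dt = dose_times(j) - t_cur;
      if (dt > 0) x = arma::expmat(A * dt) * x;
      t_cur = dose_times(j);
      x(0) += amts(j);
      ++j;
    }
    double dt = t_out - t_cur;
    vec xo = x;
    if (dt > 0) {
      xo = arma::expmat(A * dt) * x;
      x = xo;
      t_cur = t_out;
    }
    out.row(ord(oi)) = xo.t();
  }
  return out;
}

// Steady-state amounts under uniform dosing (dose into compartment 1 at
// tlag after each interval start) evaluated at times after dose `tad`,
// which may exceed the interval (intervening doses are included).
// Pre-dose state solves x0 = E(tau) x0 + E(tau - tlag) d.
// [[Rcpp::export]]
arma::mat cpp_ss_states(const arma::mat& A, double amt, double interval,
                        double tlag, const arma::vec& tad) {
  const arma::uword K = A.n_rows;
  vec d(K, arma::fill::zeros);
  d(0) = amt;
  mat Etau = arma::expmat(A * interval);
  vec dlag = arma::expmat(A * (interval - tlag)) * d;
  vec x0 = arma::solve(arma::eye(K, K) - Etau, dlag);
  arma::mat out(tad.n_elem, K);
  for (arma::uword i = 0; i < tad.n_elem; ++i) {
    double t = tad(i);
    vec x = arma::expmat(A * t) * x0;
    for (int k = 0; k * interval + tlag <= t; ++k)
      x += arma::expmat(A * (t - k * interval - tlag)) * d;
    out.row(i) = x.t();
  }
  return out;
}

// State amounts within one dosing interval starting from pre-dose state x0,
// with the interval's dose entering compartment 1 at tlag.
// [[Rcpp::export]]
arma::mat cpp_interval_states(const arma::mat& A, const arma::vec& x0,
                              double amt, double tlag,
                              const arma::vec& times) {
  const arma::uword K = A.n_rows;
  vec d(K, arma::fill::zeros);
  d(0) = amt;
  arma::mat out(times.n_elem, K);
  for (arma::uword i = 0; i < times.n_elem; ++i) {
    double t = times(i);
    vec x = arma::expmat(A * t) * x0;
    if (t >= tlag) x += arma::expmat(A * (t - tlag)) * d;
    out.row(i) = x.t();
  }
  return out;
}

// Matrix exponential (exposed for the steady-state accumulation loop).
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& A) { return arma::expmat(A); }
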