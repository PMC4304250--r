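#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// KL-divergence NMF multiplicative-update loop.
//
// Per sweep: W update first, then H using the updated W (Lee-Seung
// convention).  Convergence follows the Brunet consensus criterion: every
// `check_interval` sweeps the sample connectivity pattern (argmax metagene
// per column of H) is inspected; when it is unchanged for `stop_conv`
// consecutive checks the loop stops.  `eps` floors every denominator so a
// zero row/column sum never produces 0/0.
//
// W0 and H0 are drawn on the R side so that seeding stays in R's RNG.
// [[Rcpp::export]]
Rcpp::List nmf_kl_engine(const arma::mat& A, arma::mat W, arma::mat H,
                         int max_iter, int check_interval, int stop_conv,
                         double eps) {
  const uword m = A.n_cols;

  urowvec conn_old(m, fill::zeros);
  bool have_conn = false;
  bool converged = false;
  int stable = 0;
  int iter = 0;

  mat WH = W * H;
  mat R;

  for (iter = 1; iter <= max_iter; ++iter) {
    // W_ia <- W_ia * sum_u H_au A_iu/(WH)_iu / sum_v H_av
    R = A / (WH + eps);
    W %= (R * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);

    // H_au <- H_au * sum_i W_ia A_iu/(WH)_iu / sum_k W_ka  (updated W)
    WH = W * H;
    R = A / (WH + eps);
    H %= (W.t() * R);
    H.each_col() /= (sum(W, 0).t() + eps);
    WH = W * H;

    if (check_interval > 0 && iter % check_interval == 0) {
      urowvec conn = index_max(H, 0);  // first max wins ties (lowest index)
      if (have_conn && all(conn == conn_old)) {
        if (++stable >= stop_conv) { converged = true; break; }
      } else {
        stable = 0;
        conn_old = conn;
        have_conn = true;
      }
    }
  }
  if (iter > max_iter) iter = max_iter;

  // D(A||WH) with the 0*log0 := 0 convention; eps floors the log argument.
  double div = accu(WH) - accu(A);
  uvec pos = find(A > 0);
  vec a = A.elem(pos);
  div += accu(a % log(a / (WH.elem(pos) + eps)));

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("divergence") = div,
                            Rcpp::Named("n_iter") = iter,
                            Rcpp::Named("converged") = converged);
}
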