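#include <Rcpp.h>
using namespace Rcpp;

// Per-trial negative log-probabilities of a choice sequence under the
// attention-gated RL model. Replays the sequence deterministically: softmax
// probabilities from the current action values, then an update using the
// actually-chosen option. Mirrors the R reference implementation exactly.
//
// chosen:       0-based chosen compartment (location) per trial
// session:      1-based session index per trial (nondecreasing)
// item_at_loc:  sessions x n_options, 0-based item index per compartment
// x:            K x n_levels normalized attribute values (levels = items or
//               locations depending on is_item)
// w:            attention weight per attribute
// q0:           K x n_levels initial action values
// [[Rcpp::export]]
NumericVector nll_trials_cpp(IntegerVector chosen,
                             IntegerVector session,
                             IntegerMatrix item_at_loc,
                             NumericMatrix x,
                             LogicalVector is_item,
                             NumericVector w,
                             double alpha_c, double mu, double beta,
                             double gamma, double reward_norm,
                             double q_floor, double prob_floor,
                             NumericMatrix q0,
                             bool decay_unchosen,
                             bool reset_sessions) {
  const int T = chosen.size();
  const int K = x.nrow();
  const int n = x.ncol();
  NumericMatrix q = clone(q0);
  NumericMatrix r(K, n);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i)
      r(k, i) = reward_norm * std::pow(x(k, i), gamma);

  NumericVector out(T);
  std::vector<double> qi(n), p(n);
  int prev_session = session.size() ? session[0] : 1;

  for (int t = 0; t < T; ++t) {
    int s = session[t] - 1;
    if (reset_sessions && session[t] != prev_session) {
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < n; ++i) q(k, i) = q0(k, i);
    }
    prev_session = session[t];

    double zmax = R_NegInf;
    for (int l = 0; l < n; ++l) {
      double v = 0.0;
      for (int k = 0; k < K; ++k) {
        int lev = is_item[k] ? item_at_loc(s, l) : l;
        v += w[k] * q(k, lev);
      }
      qi[l] = beta * v;
      if (qi[l] > zmax) zmax = qi[l];
    }
    double zsum = 0.0;
    for (int l = 0; l < n; ++l) { p[l] = std::exp(qi[l] - zmax); zsum += p[l]; }
    double pc = p[chosen[t]] / zsum;
    if (pc < prob_floor) pc = prob_floor;
    out[t] = -std::log(pc);

    for (int k = 0; k < K; ++k) {
      int ck = is_item[k] ? item_at_loc(s, chosen[t]) : chosen[t];
      q(k, ck) += alpha_c * (r(k, ck) - q(k, ck));
      if (q(k, ck) < 0) q(k, ck) = 0;
      if (decay_unchosen) {
        for (int i = 0; i < n; ++i) {
          if (i == ck) continue;
          double qv = q(k, i);
          double a_u;
          if (mu == 1.0) {
            a_u = alpha_c;
          } else if (qv == 0.0 && mu > 1.0) {
            a_u = 0.0;
          } else {
            double base = qv > q_floor ? qv : q_floor;
            a_u = alpha_c * std::pow(base, mu - 1.0);
            if (a_u > 1.0) a_u = 1.0;
            if (a_u < 0.0) a_u = 0.0;
          }
          q(k, i) -= a_u * qv;
          if (q(k, i) < 0) q(k, i) = 0;
        }
      }
    }
  }
  return out;
}
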