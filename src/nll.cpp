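#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a trial table under the Beta-Bernoulli
// learner with depletion factor, forgetting, and the structured softmax
// choice model. Mirrors the R reference implementation in value_trace();
// kept in C++ because model fitting evaluates it thousands of times.
//
// par order: gamma, depletion_factor, decay, beta_stay, beta_go,
//            beta_port, b_stay, b_turn (natural space).
// [[Rcpp::export]]
double nll_trials_cpp(IntegerVector origin_port, IntegerVector dest_port,
                      IntegerVector origin_patch, IntegerVector dest_patch,
                      IntegerVector reward, IntegerVector session_id,
                      NumericVector par, IntegerVector patch_of_port,
                      IntegerVector left_neighbor) {
  const int n = origin_port.size();
  const double gamma = par[0], f = par[1], decay = par[2];
  const double beta_stay = par[3], beta_go = par[4], beta_port = par[5];
  const double b_stay = par[6], b_turn = par[7];

  double alpha[6], beta[6], d[6];
  int visits[6];
  int prev_sess = NA_INTEGER;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (t == 0 || session_id[t] != prev_sess) {
      for (int j = 0; j < 6; ++j) {
        alpha[j] = 1.0; beta[j] = 1.0; d[j] = 1.0; visits[j] = 0;
      }
      visits[origin_port[t] - 1] = 1;  // session start counts as a visit
      prev_sess = session_id[t];
    }
    const int cur_port = origin_port[t] - 1;
    const int cur_patch = origin_patch[t] - 1;

    double qp[6];
    for (int j = 0; j < 6; ++j) qp[j] = alpha[j] / (alpha[j] + beta[j]);

    const int partner = (cur_port % 2 == 0) ? cur_port + 1 : cur_port - 1;
    const double d_next = (visits[partner] >= 1) ? d[partner] * f : 1.0;
    const double q_up = qp[partner] * d_next;
    const double q_past = qp[cur_port];

    double q_patch[3];
    for (int p = 0; p < 3; ++p) {
      if (p == cur_patch) {
        q_patch[p] = gamma * q_up + (1.0 - gamma) * q_past;
      } else {
        q_patch[p] = 0.5 * (qp[2 * p] + qp[2 * p + 1]);
      }
    }

    double v[3];
    for (int p = 0; p < 3; ++p) v[p] = beta_go * q_patch[p];
    v[cur_patch] = beta_stay * q_patch[cur_patch] + b_stay;
    v[left_neighbor[cur_patch] - 1] += b_turn;

    double vmax = std::max(v[0], std::max(v[1], v[2]));
    double lse = std::log(std::exp(v[0] - vmax) + std::exp(v[1] - vmax) +
                          std::exp(v[2] - vmax)) + vmax;
    const int chosen_patch = dest_patch[t] - 1;
    ll += v[chosen_patch] - lse;

    const bool switched = chosen_patch != cur_patch;
    const int chosen = dest_port[t] - 1;
    if (switched) {
      const int pa = 2 * chosen_patch, pb = 2 * chosen_patch + 1;
      const double va = beta_port * qp[pa], vb = beta_port * qp[pb];
      const double m = std::max(va, vb);
      const double lsep = std::log(std::exp(va - m) + std::exp(vb - m)) + m;
      ll += (chosen == pa ? va : vb) - lsep;
    }

    // belief update (same order as belief_update in R)
    if (switched) {
      for (int j = 0; j < 6; ++j) { d[j] = 1.0; visits[j] = 0; }
    }
    if (visits[chosen] >= 1) d[chosen] *= f;
    if (reward[t] == 1) {
      alpha[chosen] += 1.0;
    } else {
      const double mu = (alpha[chosen] + 1.0) / (alpha[chosen] + beta[chosen] + 2.0);
      beta[chosen] += (1.0 - mu) / (1.0 / d[chosen] - mu);
    }
    for (int j = 0; j < 6; ++j) {
      if (j == chosen) continue;
      alpha[j] = (alpha[j] - 1.0) * (1.0 - decay) + 1.0;
      beta[j] = (beta[j] - 1.0) * (1.0 - decay) + 1.0;
    }
    visits[chosen] += 1;
  }
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}
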