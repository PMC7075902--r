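#include <Rcpp.h>
using namespace Rcpp;

// Sequential Rescorla-Wagner value recursion over one or more sessions.
//
// cue: 1-based cue index per trial (1 = CS_High, 2 = CS_Low)
// reward: 0/1 outcome per trial
// alpha_eff: effective learning rate per trial (alpha * beta_sound, already
//   clipped to (0, 1]); depends on the trial's sound and, when learning rates
//   are split, on the trial's outcome -- precomputed vectorised in R
// v0: starting value per cue (length 2)
//
// Returns v_pre (value of the presented cue before the update, the V(t-1)
// regressor), v_post (after the update) and the final per-cue values so a
// caller can chain sessions.
// [[Rcpp::export]]
List rw_value_path_cpp(IntegerVector cue, NumericVector reward,
                       NumericVector alpha_eff, NumericVector v0) {
  int n = cue.size();
  if (reward.size() != n || alpha_eff.size() != n)
    stop("cue, reward and alpha_eff must have equal length");
  if (v0.size() != 2) stop("v0 must have length 2");
  NumericVector v_pre(n), v_post(n);
  double v[2] = {v0[0], v0[1]};
  for (int t = 0; t < n; ++t) {
    int c = cue[t] - 1;
    if (c < 0 || c > 1) stop("cue indices must be 1 or 2");
    v_pre[t] = v[c];
    v[c] += alpha_eff[t] * (reward[t] - v[c]);
    v_post[t] = v[c];
  }
  return List::create(_["v_pre"] = v_pre, _["v_post"] = v_post,
                      _["v_final"] = NumericVector::create(v[0], v[1]));
}
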