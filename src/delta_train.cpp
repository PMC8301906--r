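#include <Rcpp.h>
using namespace Rcpp;

// Delta-rule training loop over a presentation schedule.
//
// W         : out_dim x in_dim weight matrix, modified in place on a copy.
// act_in    : n_slots x n_items integer matrix of active input columns
//             (1-based), one column per lexicon item.  Slot coding is
//             one-hot, so every slot contributes exactly one active unit
//             (a grapheme unit or the slot's empty unit).
// act_out   : n_slots x n_items integer matrix of active target rows
//             (1-based), aligned with act_in.
// schedule  : 1-based item indices, one per presentation, already sampled
//             by frequency.
// eta       : learning rate.
// dead_band : output units whose absolute error is below this threshold
//             are not updated (error-gated learning); 0 recovers the pure
//             delta rule.
//
// Update for one presentation of item j with active columns C and active
// target rows T:  o = sum_{c in C} W[, c];  err = t - o  (t one-hot on T);
// W[, c] += eta * err for every c in C.  This is exactly
// W <- W + eta * (t - W x) x^T for a binary x supported on C (with errors
// inside the dead band zeroed).
// [[Rcpp::export(name = ".delta_train_cpp")]]
NumericMatrix delta_train_cpp(NumericMatrix W,
                              IntegerMatrix act_in,
                              IntegerMatrix act_out,
                              IntegerVector schedule,
                              double eta,
                              double dead_band) {
  NumericMatrix Wc = clone(W);
  const int out_dim = Wc.nrow();
  const int n_slots = act_in.nrow();
  const int n_pres = schedule.size();
  std::vector<double> err(out_dim);
  std::vector<int> live;
  live.reserve(out_dim);
  double *w = REAL(Wc);

  for (int p = 0; p < n_pres; ++p) {
    const int item = schedule[p] - 1;
    // net output restricted to the active columns
    for (int r = 0; r < out_dim; ++r) err[r] = 0.0;
    for (int s = 0; s < n_slots; ++s) {
      const double *col = w + (size_t)(act_in(s, item) - 1) * out_dim;
      for (int r = 0; r < out_dim; ++r) err[r] -= col[r];
    }
    for (int s = 0; s < n_slots; ++s) err[act_out(s, item) - 1] += 1.0;
    live.clear();
    for (int r = 0; r < out_dim; ++r)
      if (err[r] > dead_band || err[r] < -dead_band) live.push_back(r);
    for (int s = 0; s < n_slots; ++s) {
      double *col = w + (size_t)(act_in(s, item) - 1) * out_dim;
      for (int r : live) col[r] += eta * err[r];
    }
  }
  return Wc;
}
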