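#include <Rcpp.h>
using namespace Rcpp;

// Trial loop for one run of the learning models.
//
// model: 1..5. Coarse models (2, 3) keep one value per factor, fine models
// (4, 5) one value per item; model 1 is the reference-point regression and
// keeps no state. The reference-point models (3, 5) blend the reference
// point into the emitted prediction, P = gamma*RP + (1-gamma)*state, while
// the stored state accumulates pure Rescorla-Wagner increments; the
// prediction error uses the emitted (blended) prediction. a_pos is used
// when PE >= 0, a_neg when PE < 0 (equal for single-learning-rate models).
// State values are never clipped.
//
// items / factor_of are 0-based indices; feedback is aligned to trials.
// Returns the model's prediction on every trial.
// [[Rcpp::export]]
NumericVector run_core_cpp(int model, double a_pos, double a_neg,
                           double gamma, double start, double b0, double b1,
                           IntegerVector items, NumericVector feedback,
                           IntegerVector factor_of, NumericVector rp,
                           NumericMatrix sim, int n_items, int n_factors) {
  int nt = items.size();
  NumericVector pred(nt);
  double g = (model == 3 || model == 5) ? gamma : 0.0;

  if (model == 1) {
    for (int t = 0; t < nt; ++t) pred[t] = rp[items[t]] * b1 + b0;
    return pred;
  }

  if (model <= 3) {
    std::vector<double> state(n_factors, start);
    for (int t = 0; t < nt; ++t) {
      int it = items[t];
      int f = factor_of[it];
      double p = g * rp[it] + (1.0 - g) * state[f];
      pred[t] = p;
      double pe = feedback[t] - p;
      double a = (pe < 0) ? a_neg : a_pos;
      state[f] += a * pe;
    }
    return pred;
  }

  std::vector<double> state(n_items, start);
  for (int t = 0; t < nt; ++t) {
    int it = items[t];
    double p = g * rp[it] + (1.0 - g) * state[it];
    pred[t] = p;
    double pe = feedback[t] - p;
    double a = (pe < 0) ? a_neg : a_pos;
    double ape = a * pe;
    for (int j = 0; j < n_items; ++j) state[j] += ape * sim(j, it);
  }
  return pred;
}

// Sum of squared errors of model predictions against responses over a set
// of runs (state resets per run). items_runs / feedback_runs / response_runs
// are parallel lists, one element per run; NA responses are skipped.
// [[Rcpp::export]]
double sse_core_cpp(int model, double a_pos, double a_neg, double gamma,
                    double start, double b0, double b1, List items_runs,
                    List feedback_runs, List response_runs,
                    IntegerVector factor_of, NumericVector rp,
                    NumericMatrix sim, int n_items, int n_factors) {
  double sse = 0.0;
  int nr = items_runs.size();
  for (int r = 0; r < nr; ++r) {
    IntegerVector items = items_runs[r];
    NumericVector fb = feedback_runs[r];
    NumericVector resp = response_runs[r];
    NumericVector pred = run_core_cpp(model, a_pos, a_neg, gamma, start, b0,
                                      b1, items, fb, factor_of, rp, sim,
                                      n_items, n_factors);
    for (int t = 0; t < items.size(); ++t) {
      if (NumericVector::is_na(resp[t])) continue;
      double e = resp[t] - pred[t];
      sse += e * e;
    }
  }
  return sse;
}
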