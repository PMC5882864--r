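#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial training of the layered tanh network with chosen-unit-gated
// backpropagation.  All randomness is pre-drawn in R (gamble grids, tie-break
// and outcome uniforms), so this loop is a pure deterministic function of its
// inputs; the sequential dependence of weights on earlier trials is why it
// lives in C++ rather than vectorised R.
//
// derivative: 0 = analytic 3(1 - tanh^2(3x)), 1 = printed 1 - tanh^2(3x)
// normalization: 0 = max_bound (divide layer by max |w| only when > 1),
//                1 = absmax, 2 = signed_max, 3 = none
// record_from: 1-based trial index from which hidden+output activities are kept.

static inline double act_deriv(double x, double slope, int mode) {
  double t = std::tanh(slope * x);
  double d = 1.0 - t * t;
  return mode == 0 ? slope * d : d;
}

// [[Rcpp::export]]
List cpp_train_loop(List init_weights,
                    NumericMatrix inputs,
                    NumericVector tie_u,
                    NumericVector outcome_u,
                    double eta,
                    double slope,
                    int derivative,
                    int normalization,
                    int record_from,
                    bool learn) {
  int n_layers = init_weights.size();          // weight matrices w^1 .. w^N
  int n_trials = inputs.nrow();

  std::vector<NumericMatrix> W(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    NumericMatrix src = init_weights[l];
    W[l] = clone(src);
  }

  std::vector<int> sizes(n_layers + 1);
  sizes[0] = W[0].ncol();
  for (int l = 0; l < n_layers; ++l) sizes[l + 1] = W[l].nrow();
  if (sizes[n_layers] != 2) stop("output layer must have exactly 2 units");
  if (sizes[0] != inputs.ncol()) stop("input width does not match first weight matrix");

  // per-layer activity and net-input buffers (y[0] is the input vector)
  std::vector<std::vector<double> > y(n_layers + 1), net(n_layers + 1),
                                    delta(n_layers + 1);
  for (int l = 0; l <= n_layers; ++l) {
    y[l].assign(sizes[l], 0.0);
    net[l].assign(sizes[l], 0.0);
    delta[l].assign(sizes[l], 0.0);
  }

  int n_hidden_units = 0;
  for (int l = 1; l < n_layers; ++l) n_hidden_units += sizes[l];
  int n_rec = std::max(0, n_trials - (record_from - 1));
  NumericMatrix acts(n_rec, n_hidden_units + 2);

  IntegerVector choose_left(n_trials);
  NumericVector outcome(n_trials), y_chosen(n_trials), err(n_trials);

  for (int t = 0; t < n_trials; ++t) {
    for (int j = 0; j < sizes[0]; ++j) y[0][j] = inputs(t, j);

    // forward pass, Eq. 4
    for (int l = 1; l <= n_layers; ++l) {
      NumericMatrix &w = W[l - 1];
      for (int i = 0; i < sizes[l]; ++i) {
        double s = 0.0;
        for (int j = 0; j < sizes[l - 1]; ++j) s += w(i, j) * y[l - 1][j];
        net[l][i] = s;
        y[l][i] = std::tanh(slope * s);
      }
    }

    // choice readout, Eq. 2: unit 1 -> right, unit 2 -> left; exact ties random
    int chosen;                                 // 0 = right (unit 1), 1 = left (unit 2)
    double y1 = y[n_layers][0], y2 = y[n_layers][1];
    if (y1 > y2)      chosen = 0;
    else if (y2 > y1) chosen = 1;
    else              chosen = (tie_u[t] < 0.5) ? 0 : 1;
    choose_left[t] = chosen;

    // Bernoulli outcome of the chosen gamble
    double r_ch = (chosen == 0) ? inputs(t, 0) : inputs(t, 2);
    double p_ch = (chosen == 0) ? inputs(t, 1) : inputs(t, 3);
    double R = (outcome_u[t] < p_ch) ? r_ch : 0.0;
    outcome[t] = R;
    y_chosen[t] = y[n_layers][chosen];
    double e = R - y[n_layers][chosen];
    err[t] = e;

    if (record_from - 1 <= t) {
      int row = t - (record_from - 1), col = 0;
      for (int l = 1; l < n_layers; ++l)
        for (int i = 0; i < sizes[l]; ++i) acts(row, col++) = y[l][i];
      acts(row, col)     = y[n_layers][0];
      acts(row, col + 1) = y[n_layers][1];
    }

    if (!learn) continue;

    // gated output deltas, Eq. 5: unchosen unit's delta is exactly 0
    delta[n_layers][0] = delta[n_layers][1] = 0.0;
    delta[n_layers][chosen] = e * act_deriv(net[n_layers][chosen], slope, derivative);

    // hidden deltas, Eq. 6
    for (int l = n_layers - 1; l >= 1; --l) {
      NumericMatrix &w = W[l];                  // weights from layer l to l+1
      for (int j = 0; j < sizes[l]; ++j) {
        double s = 0.0;
        for (int i = 0; i < sizes[l + 1]; ++i) s += delta[l + 1][i] * w(i, j);
        delta[l][j] = s * act_deriv(net[l][j], slope, derivative);
      }
    }

    // weight update, Eq. 7, then per-layer normalization, Eq. 8
    for (int l = 1; l <= n_layers; ++l) {
      NumericMatrix &w = W[l - 1];
      for (int i = 0; i < sizes[l]; ++i) {
        double d = delta[l][i];
        if (d != 0.0)
          for (int j = 0; j < sizes[l - 1]; ++j) w(i, j) += eta * d * y[l - 1][j];
      }
      if (normalization == 3) continue;
      double mabs = 0.0, msigned = -std::numeric_limits<double>::infinity();
      for (int i = 0; i < sizes[l]; ++i)
        for (int j = 0; j < sizes[l - 1]; ++j) {
          double v = w(i, j);
          if (std::fabs(v) > mabs) mabs = std::fabs(v);
          if (v > msigned) msigned = v;
        }
      double denom = 0.0;
      if (normalization == 0)      denom = (mabs > 1.0) ? mabs : 0.0;
      else if (normalization == 1) denom = (mabs > 0.0) ? mabs : 0.0;
      else                         denom = (msigned != 0.0) ? msigned : 0.0;
      if (denom != 0.0)
        for (int i = 0; i < sizes[l]; ++i)
          for (int j = 0; j < sizes[l - 1]; ++j) w(i, j) /= denom;
    }
  }

  List wout(n_layers);
  for (int l = 0; l < n_layers; ++l) wout[l] = W[l];
  return List::create(_["weights"] = wout,
                      _["choose_left"] = choose_left,
                      _["outcome"] = outcome,
                      _["y_chosen"] = y_chosen,
                      _["error"] = err,
                      _["activities"] = acts);
}
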