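#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Flattened curve representation produced by curve_to_cspec() on the R side.
// Components: kind 1 = step (a=low, b=mid, c=high), 2 = logistic (a=d, b=slope),
// 3 = piecewise constant (edges, values), 4 = constant (a=p), 5 = identity.
// A mixture is a list of components with weights summing to 1.
struct CurveC {
  std::vector<int> kind;
  std::vector<double> a, b, c, w;
  std::vector<std::vector<double> > edges, values;
};

static CurveC parse_cspec(const List& s) {
  CurveC cv;
  IntegerVector kind = s["kind"];
  NumericVector a = s["a"], b = s["b"], c = s["c"], w = s["w"];
  List edges = s["edges"], values = s["values"];
  int m = kind.size();
  for (int i = 0; i < m; ++i) {
    cv.kind.push_back(kind[i]);
    cv.a.push_back(a[i]);
    cv.b.push_back(b[i]);
    cv.c.push_back(c[i]);
    cv.w.push_back(w[i]);
    std::vector<double> e, v;
    if (kind[i] == 3) {
      NumericVector ee = edges[i], vv = values[i];
      e.assign(ee.begin(), ee.end());
      v.assign(vv.begin(), vv.end());
    }
    cv.edges.push_back(e);
    cv.values.push_back(v);
  }
  return cv;
}

static double eval_piecewise(const std::vector<double>& e,
                             const std::vector<double>& v, double x) {
  int nb = (int) v.size();
  // interior edge: value is the mean of the adjacent bins (one-sided limits exist)
  for (int j = 1; j < nb; ++j) {
    if (x == e[j]) return 0.5 * (v[j - 1] + v[j]);
  }
  int j = nb - 1;
  for (int k = 0; k < nb; ++k) {
    if (x < e[k + 1]) { j = k; break; }
  }
  return v[j];
}

static double eval_comp(const CurveC& cv, int i, double x) {
  switch (cv.kind[i]) {
  case 1:
    if (x < 0.5) return cv.a[i];
    if (x > 0.5) return cv.c[i];
    return cv.b[i];
  case 2: {
    double d = cv.a[i], bb = cv.b[i];
    return 1.0 / (1.0 + (1.0 + d) / (1.0 - d) * std::exp(bb * (1.0 - 2.0 * x)));
  }
  case 3:
    return eval_piecewise(cv.edges[i], cv.values[i], x);
  case 4:
    return cv.a[i];
  default:
    return x;
  }
}

static double eval_curve(const CurveC& cv, double x) {
  double s = 0.0;
  for (size_t i = 0; i < cv.kind.size(); ++i) s += cv.w[i] * eval_comp(cv, i, x);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_eval_curve(List cspec, NumericVector x) {
  CurveC cv = parse_cspec(cspec);
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = eval_curve(cv, x[i]);
  return out;
}

// One trial of the sequential binary choice process. Returns the choices
// (1 = A), the popularity x_t seen by each participant, the end popularity,
// and whether popularity stayed >= 1/2 at every step (including the end).
// [[Rcpp::export]]
List cpp_simulate_trial(List cspec, double init_a, double init_b, int horizon) {
  CurveC cv = parse_cspec(cspec);
  IntegerVector choice(horizon);
  NumericVector xs(horizon);
  double na = init_a, nb = init_b;
  bool survived = true;
  for (int t = 0; t < horizon; ++t) {
    double x = na / (na + nb);
    xs[t] = x;
    if (x < 0.5) survived = false;
    double p = eval_curve(cv, x);
    int ch = (unif_rand() < p) ? 1 : 0;
    choice[t] = ch;
    if (ch == 1) na += 1.0; else nb += 1.0;
  }
  double endpop = na / (na + nb);
  if (endpop < 0.5) survived = false;
  return List::create(_["choice"] = choice, _["x"] = xs,
                      _["end_popularity"] = endpop, _["survived"] = survived);
}

// Ensemble of independent trials; only end popularities and the survival
// indicator are kept. When the curve value hits exactly 0 below popularity
// 1/2 (e.g. the auxiliary step process with low = 0), the remainder of the
// trial is deterministic and is completed in closed form.
// [[Rcpp::export]]
List cpp_simulate_ensemble(List cspec, double init_a, double init_b,
                           int horizon, int n_trials) {
  CurveC cv = parse_cspec(cspec);
  NumericVector endpop(n_trials);
  LogicalVector survived(n_trials);
  for (int r = 0; r < n_trials; ++r) {
    double na = init_a, nb = init_b;
    bool surv = true;
    for (int t = 0; t < horizon; ++t) {
      double x = na / (na + nb);
      if (x < 0.5) surv = false;
      double p = eval_curve(cv, x);
      if (p == 0.0 && x < 0.5) { nb += (double)(horizon - t); break; }
      if (unif_rand() < p) na += 1.0; else nb += 1.0;
    }
    double ep = na / (na + nb);
    if (ep < 0.5) surv = false;
    endpop[r] = ep;
    survived[r] = surv;
  }
  return List::create(_["end_popularity"] = endpop, _["survived"] = survived);
}

// Biased-walk survival Monte Carlo: walk starts at 0, steps +1 with
// probability q0 at state 0 and q_plus at states > 0; a trial fails as soon
// as the state becomes negative. Returns the number of walks that stay >= 0
// for the whole horizon.
// [[Rcpp::export]]
int cpp_walk_survival(double q0, double q_plus, int horizon, int reps) {
  int surv = 0;
  for (int r = 0; r < reps; ++r) {
    long k = 0;
    bool ok = true;
    for (int n = 0; n < horizon; ++n) {
      double q = (k > 0) ? q_plus : q0;
      if (unif_rand() < q) ++k; else --k;
      if (k < 0) { ok = false; break; }
    }
    if (ok) ++surv;
  }
  return surv;
}

// Party-signal variant: participant of party P (0 = A, 1 = B) supports the
// statement with probability p_plus_P when current party-A support leads
// (x = x_A - x_B > 0), p_minus_P when it trails, and the mean of the two when
// x = 0 or undefined (fewer than one prior participant in either party).
// Returns per-record support, the signal x seen (NA when undefined), and the
// end-of-trial per-party support shares.
// [[Rcpp::export]]
List cpp_simulate_party(double pp_a, double pm_a, double pp_b, double pm_b,
                        IntegerVector party) {
  int horizon = party.size();
  IntegerVector support(horizon);
  NumericVector xs(horizon);
  double nA = 0, sA = 0, nB = 0, sB = 0;
  for (int t = 0; t < horizon; ++t) {
    double x = NA_REAL;
    if (nA > 0 && nB > 0) x = sA / nA - sB / nB;
    double pp = (party[t] == 0) ? pp_a : pp_b;
    double pm = (party[t] == 0) ? pm_a : pm_b;
    double p;
    if (!ISNA(x) && x > 0) p = pp;
    else if (!ISNA(x) && x < 0) p = pm;
    else p = 0.5 * (pp + pm);
    int s = (unif_rand() < p) ? 1 : 0;
    support[t] = s;
    xs[t] = x;
    if (party[t] == 0) { nA += 1; sA += s; } else { nB += 1; sB += s; }
  }
  double yA = (nA > 0) ? sA / nA : NA_REAL;
  double yB = (nB > 0) ? sB / nB : NA_REAL;
  return List::create(_["support"] = support, _["x"] = xs,
                      _["ybar_a"] = yA, _["ybar_b"] = yB);
}
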