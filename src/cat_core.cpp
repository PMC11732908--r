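#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Numerically stable logistic; safe for |x| > 30.
static inline double sigmf(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// Fisher information of one item under the fixed-guessing 1PL:
// I = s^2 (1 - s) / (1 + s) with s = logistic(theta - b).
static inline double iteminfo(double theta, double b) {
  double s = sigmf(theta - b);
  return s * s * (1.0 - s) / (1.0 + s);
}

// Bernoulli log-likelihood of theta given responses x and difficulties b,
// with P = 0.5 + 0.5 * logistic(theta - b).
static double loglik(double th, const std::vector<double>& b,
                     const std::vector<int>& x) {
  double ll = 0.0;
  for (size_t i = 0; i < b.size(); ++i) {
    double s = sigmf(th - b[i]);
    ll += x[i] ? std::log(0.5 * (1.0 + s)) : std::log(0.5 * (1.0 - s));
  }
  return ll;
}

// Score function d/dtheta log-likelihood.
static double score(double th, const std::vector<double>& b,
                    const std::vector<int>& x) {
  double g = 0.0;
  for (size_t i = 0; i < b.size(); ++i) {
    double s = sigmf(th - b[i]);
    if (x[i]) g += 0.5 * s * (1.0 - s) / (0.5 * (1.0 + s));
    else      g -= s;
  }
  return g;
}

// Golden-section maximisation on [a, c], then Newton polish on the score so
// that independently seeded optimisations of the same likelihood agree to
// ~1e-12 (golden section alone stalls ~1e-8 from the flat maximum). The
// likelihood is unimodal so the bracket from the grid scan always contains
// the maximum.
static double golden_max(double a, double c, const std::vector<double>& b,
                         const std::vector<int>& x,
                         double lo, double hi) {
  const double r = 0.3819660112501051;
  double a0 = a, c0 = c;
  double x1 = a + r * (c - a), x2 = c - r * (c - a);
  double f1 = loglik(x1, b, x), f2 = loglik(x2, b, x);
  for (int it = 0; it < 40 && (c - a) > 1e-8; ++it) {
    if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = c - r * (c - a); f2 = loglik(x2, b, x); }
    else         { c = x2; x2 = x1; f2 = f1; x1 = a + r * (c - a); f1 = loglik(x1, b, x); }
  }
  double th = 0.5 * (a + c);
  if (th > a0 + 1e-9 && th < c0 - 1e-9) {  // interior: polish to the score root
    const double h = 1e-5;
    for (int it = 0; it < 30; ++it) {
      double g = score(th, b, x);
      double d2 = (score(th + h, b, x) - score(th - h, b, x)) / (2.0 * h);
      if (!(d2 < 0)) break;
      double step = g / d2;
      double thn = th - step;
      if (thn < lo) thn = lo; else if (thn > hi) thn = hi;
      double moved = std::fabs(thn - th);
      th = thn;
      if (moved < 1e-12) break;
    }
  }
  return th;
}

static const double GRID_STEP = 0.05;

static inline int grid_size(double lo, double hi) {
  int G = (int)std::floor((hi - lo) / GRID_STEP + 1.5);
  return G < 9 ? 9 : G;
}

// [[Rcpp::export]]
double mle_theta_cpp(IntegerVector correct, NumericVector difficulty,
                     double lo, double hi) {
  int n = correct.size();
  std::vector<int> x(correct.begin(), correct.end());
  std::vector<double> b(difficulty.begin(), difficulty.end());
  bool all1 = true, all0 = true;
  for (int i = 0; i < n; ++i) { if (x[i]) all0 = false; else all1 = false; }
  if (all1) return hi;  // monotone increasing likelihood: clamp at bound
  if (all0) return lo;
  int G = grid_size(lo, hi);
  double h = (hi - lo) / (G - 1);
  double bestll = R_NegInf; int bj = 0;
  for (int j = 0; j < G; ++j) {
    double ll = loglik(lo + j * h, b, x);
    if (ll > bestll) { bestll = ll; bj = j; }
  }
  double a = std::max(lo, lo + (bj - 1) * h);
  double c = std::min(hi, lo + (bj + 1) * h);
  return golden_max(a, c, b, x, lo, hi);
}

// [[Rcpp::export]]
double test_info_cpp(double theta, NumericVector difficulty) {
  double s = 0.0;
  for (int i = 0; i < difficulty.size(); ++i) s += iteminfo(theta, difficulty[i]);
  return s;
}

// Adaptive (or random-order) session loop.
//
// difficulty / is_pseudo / calibrated describe the bank; scored_sched marks
// which trials are scored CAT trials (TRUE) versus interleaved uncalibrated
// validation trials (FALSE). selector: 0 = maximum Fisher information,
// 1 = difficulty closest to theta, 2 = random. responder is either a 0/1
// vector over the whole bank (fast path for simulation/replay) or an R
// function called with the 1-based bank row of the selected item.
//
// Theta is refit by MLE after every scored trial using an incrementally
// updated log-likelihood grid (step 0.05) plus golden-section refinement,
// so the trajectory agrees with a from-scratch MLE on each prefix.
// [[Rcpp::export]]
List run_cat_cpp(NumericVector difficulty, IntegerVector is_pseudo,
                 LogicalVector calibrated, LogicalVector scored_sched,
                 int selector, bool counterbalance,
                 double lo, double hi, double theta0, SEXP responder) {
  int nbank = difficulty.size();
  int ntrial = scored_sched.size();

  std::vector<int> pool[2];   // unadministered calibrated items by category
  std::vector<int> vpool;     // unadministered uncalibrated items
  for (int i = 0; i < nbank; ++i) {
    if (calibrated[i]) pool[is_pseudo[i] ? 1 : 0].push_back(i);
    else vpool.push_back(i);
  }
  for (int k = 0; k < 2; ++k)
    std::stable_sort(pool[k].begin(), pool[k].end(),
                     [&](int a, int b2) { return difficulty[a] < difficulty[b2]; });

  bool use_vec = (TYPEOF(responder) == REALSXP || TYPEOF(responder) == INTSXP);
  NumericVector respvec;
  Function respfun("identity");  // placeholder when the vector path is used
  if (use_vec) respvec = as<NumericVector>(responder);
  else respfun = as<Function>(responder);

  std::vector<int> xs; std::vector<double> bs;  // scored administration record
  int G = grid_size(lo, hi);
  double h = (hi - lo) / (G - 1);
  std::vector<double> llgrid(G, 0.0);
  int n_correct = 0, n_fallback = 0;
  double theta = theta0, sem = NA_REAL;
  bool first_scored = true;

  IntegerVector out_item(ntrial), out_resp(ntrial);
  NumericVector out_theta(ntrial), out_sem(ntrial);
  std::vector<int> cand;

  for (int t = 0; t < ntrial; ++t) {
    int chosen = -1;
    if (scored_sched[t]) {
      int cat = -1;
      if (counterbalance) {
        cat = (unif_rand() < 0.5) ? 0 : 1;
        if (pool[cat].empty()) {
          if (pool[1 - cat].empty())
            stop("no unadministered calibrated items remain at trial %d", t + 1);
          cat = 1 - cat;  // silent fallback; the bank ran out of this category
          ++n_fallback;
        }
      }
      if (cat >= 0) {
        cand = pool[cat];
      } else {
        // merge the two difficulty-sorted pools, preserving order
        cand.clear();
        cand.reserve(pool[0].size() + pool[1].size());
        std::merge(pool[0].begin(), pool[0].end(), pool[1].begin(), pool[1].end(),
                   std::back_inserter(cand),
                   [&](int a, int b2) { return difficulty[a] < difficulty[b2]; });
        if (cand.empty())
          stop("no unadministered calibrated items remain at trial %d", t + 1);
      }
      int ncand = (int)cand.size();
      if (first_scored) {
        // median-difficulty start (lower middle for even counts)
        chosen = cand[(ncand - 1) / 2];
        first_scored = false;
      } else if (selector == 0 || selector == 1) {
        double best = R_NegInf;
        std::vector<int> ties;
        for (int j = 0; j < ncand; ++j) {
          double crit = (selector == 0)
            ? iteminfo(theta, difficulty[cand[j]])
            : -std::fabs(theta - difficulty[cand[j]]);
          if (crit > best + 1e-12) { best = crit; ties.clear(); ties.push_back(cand[j]); }
          else if (crit > best - 1e-12) ties.push_back(cand[j]);
        }
        if (ties.size() == 1) chosen = ties[0];
        else {
          int j = (int)(unif_rand() * ties.size());
          if (j >= (int)ties.size()) j = (int)ties.size() - 1;
          chosen = ties[j];
        }
      } else {
        int j = (int)(unif_rand() * ncand);
        if (j >= ncand) j = ncand - 1;
        chosen = cand[j];
      }
      int cc = is_pseudo[chosen] ? 1 : 0;
      pool[cc].erase(std::find(pool[cc].begin(), pool[cc].end(), chosen));
    } else {
      if (vpool.empty())
        stop("no unadministered uncalibrated items remain at trial %d", t + 1);
      int j = (int)(unif_rand() * vpool.size());
      if (j >= (int)vpool.size()) j = (int)vpool.size() - 1;
      chosen = vpool[j];
      vpool.erase(vpool.begin() + j);
    }

    int r;
    if (use_vec) {
      double rv = respvec[chosen];
      if (rv != 0.0 && rv != 1.0) stop("responder vector must contain only 0/1");
      r = (int)rv;
    } else {
      r = as<int>(respfun(chosen + 1));
      if (r != 0 && r != 1) stop("responder callback must return 0 or 1");
    }

    if (scored_sched[t]) {
      xs.push_back(r);
      bs.push_back(difficulty[chosen]);
      n_correct += r;
      double bi = difficulty[chosen];
      for (int j = 0; j < G; ++j) {
        double s = sigmf(lo + j * h - bi);
        llgrid[j] += r ? std::log(0.5 * (1.0 + s)) : std::log(0.5 * (1.0 - s));
      }
      int nsc = (int)xs.size();
      if (n_correct == nsc) theta = hi;
      else if (n_correct == 0) theta = lo;
      else {
        int bj = 0; double bestll = R_NegInf;
        for (int j = 0; j < G; ++j)
          if (llgrid[j] > bestll) { bestll = llgrid[j]; bj = j; }
        double a = std::max(lo, lo + (bj - 1) * h);
        double c = std::min(hi, lo + (bj + 1) * h);
        theta = golden_max(a, c, bs, xs, lo, hi);
      }
      NumericVector bvec(bs.begin(), bs.end());
      double info = test_info_cpp(theta, bvec);
      sem = info > 0 ? 1.0 / std::sqrt(info) : NA_REAL;
    }
    out_item[t] = chosen + 1;
    out_resp[t] = r;
    out_theta[t] = theta;
    out_sem[t] = sem;
  }

  return List::create(_["item"] = out_item, _["response"] = out_resp,
                      _["theta_after"] = out_theta, _["sem_after"] = out_sem,
                      _["n_fallback"] = n_fallback);
}
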