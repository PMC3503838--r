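// GMYC likelihood kernel and Metropolis-Hastings chain.
//
// Conventions (matching the R-level interval_table()):
//   - ranked branching events t_1 > ... > t_m (m = n_tips - 1);
//   - interval i = [t_{i+1}, t_i], i = 1..m-1, holds i+1 lineages and is
//     terminated (backward in time) by event rank i;
//   - threshold rank T in [2, n_tips]: events 1..T-1 are speciations, so
//     there are E_y = min(T-1, m-1) Yule events and E_c = m-1-E_y
//     coalescent events among the terminated intervals;
//   - each event contributes the hazard of its own process, survival uses
//     the combined hazard, and the per-process lambdas are profiled at
//     their closed-form conditional MLEs.
#include <Rcpp.h>
using namespace Rcpp;

struct TreeData {
  int n;                              // tips
  int m;                              // events
  int nint;                           // waiting intervals = m - 1
  std::vector<double> t;              // ranked ages, length m
  std::vector<double> x;              // waiting times, length m - 1
  std::vector<int> parent_rank;       // per event rank (1-based), 0 = root
  std::vector<std::vector<int>> desc; // per rank: ranks inside subtree, asc.
};

static TreeData unpack_tree(const List& pre) {
  TreeData td;
  NumericVector t = pre["t"], x = pre["x"];
  IntegerVector pr = pre["parent_rank"];
  List dr = pre["desc_ranks"];
  td.n = as<int>(pre["n_tips"]);
  td.m = t.size();
  td.nint = td.m - 1;
  td.t.assign(t.begin(), t.end());
  td.x.assign(x.begin(), x.end());
  td.parent_rank.assign(pr.begin(), pr.end());
  td.desc.resize(td.m);
  for (int r = 0; r < td.m; ++r) {
    IntegerVector v = dr[r];
    td.desc[r].assign(v.begin(), v.end());
  }
  return td;
}

struct EvalResult {
  double loglik, lambda_y, lambda_c;
  int ey, ec;
};

// A[i], C[i] for intervals i = 1..nint (0-based storage) given threshold T.
static void fill_rates(const TreeData& td, int T, double p_yule, double p_coal,
                       std::vector<double>& A, std::vector<double>& C) {
  const int nint = td.nint, n = td.n;
  std::vector<double> scoal(nint, 0.0);
  std::fill(C.begin(), C.end(), 0.0);
  std::vector<double> powc(n + 1, 0.0), powy(n + 1, 0.0);
  for (int s = 2; s <= n; ++s)
    powc[s] = std::pow((double)s * (s - 1), p_coal);
  powy[0] = 0.0;  // no lineages, no hazard (even at p = 0)
  for (int k = 1; k <= n; ++k) powy[k] = std::pow((double)k, p_yule);
  // cluster roots: rank r >= T whose parent event is a speciation
  for (int r = T; r <= td.m; ++r) {
    if (td.parent_rank[r - 1] > T - 1) continue;
    if (r > nint) continue;            // youngest cherries never span an interval
    const std::vector<int>& dr = td.desc[r - 1];
    int s = 2, ptr = 0, len = dr.size();
    for (int i = r; i <= nint; ++i) {
      while (ptr < len && dr[ptr] <= i) { ++s; ++ptr; }
      C[i - 1] += powc[s];
      scoal[i - 1] += s;
    }
  }
  for (int i = 1; i <= nint; ++i) {
    int ny = (i + 1) - (int)std::lround(scoal[i - 1]);
    A[i - 1] = powy[ny];
  }
}

static EvalResult eval_loglik(const TreeData& td, int T, double p_yule,
                              double p_coal) {
  const int nint = td.nint;
  std::vector<double> A(nint), C(nint);
  fill_rates(td, T, p_yule, p_coal, A, C);
  int ey = std::min(T - 1, nint), ec = nint - ey;
  double sumAx = 0.0, sumCx = 0.0, sumlog = 0.0;
  for (int i = 0; i < nint; ++i) {
    sumAx += A[i] * td.x[i];
    sumCx += C[i] * td.x[i];
    sumlog += std::log(i < ey ? A[i] : C[i]);  // event rank i+1: Yule iff <= ey
  }
  double lam_y = ey > 0 ? ey / sumAx : 0.0;
  double lam_c = ec > 0 ? ec / sumCx : 0.0;
  double ll = sumlog;
  if (ey > 0) ll += ey * (std::log(lam_y) - 1.0);
  if (ec > 0) ll += ec * (std::log(lam_c) - 1.0);
  EvalResult res = {ll, lam_y, lam_c, ey, ec};
  return res;
}

// [[Rcpp::export]]
List gmyc_eval_cpp(List pre, int threshold, double p_yule, double p_coal,
                   bool return_rates = false) {
  TreeData td = unpack_tree(pre);
  if (threshold < 2 || threshold > td.n)
    stop("threshold out of range [2, n_tips]");
  EvalResult r = eval_loglik(td, threshold, p_yule, p_coal);
  List out = List::create(
    _["loglik"] = r.loglik, _["lambda_yule"] = r.lambda_y,
    _["lambda_coal"] = r.lambda_c, _["n_events_yule"] = r.ey,
    _["n_events_coal"] = r.ec);
  if (return_rates) {
    std::vector<double> A(td.nint), C(td.nint);
    fill_rates(td, threshold, p_yule, p_coal, A, C);
    out["A"] = NumericVector(A.begin(), A.end());
    out["C"] = NumericVector(C.begin(), C.end());
  }
  return out;
}

// Threshold move: mostly a small random walk; with probability `jump_prob`
// an independence draw from the uniform prior. Both components have
// symmetric proposal densities, so the Metropolis ratio is the plain
// posterior ratio. Random-walk proposals that leave the support are
// rejected in place (returning the current value keeps the kernel
// symmetric; reflecting a *discrete* walk at the bounds would not). The
// independence component lets the chain cross the likelihood barrier that
// separates the all-singletons corner (a weak local mode) from the main
// mode, which a bounded walk cannot do.
static int propose_T(int T, int Tmin, int Tmax, int step, double jump_prob) {
  if (unif_rand() < jump_prob) {
    int nT = Tmin + (int)std::floor(unif_rand() * (Tmax - Tmin + 1));
    if (nT > Tmax) nT = Tmax;
    return nT;
  }
  int d = (int)std::floor(unif_rand() * (2 * step)) - step;
  if (d >= 0) ++d;                     // uniform on {-step..-1, 1..step}
  int nT = T + d;
  if (nT < Tmin || nT > Tmax) return T;
  return nT;
}

static double propose_p(double p, double lo, double hi, double w) {
  double np = p + w * (unif_rand() - 0.5);
  while (np < lo || np > hi) {
    if (np < lo) np = 2 * lo - np;
    if (np > hi) np = 2 * hi - np;
  }
  return np;
}

// Metropolis-Hastings over (T, p_yule, p_coal); lambdas profiled each step.
// Uniform priors: flat within support, enforced by reflecting proposals.
// [[Rcpp::export]]
List gmyc_chain_cpp(List pre, int n_steps, int burnin, int thin,
                    int Tmin, int Tmax,
                    double py_lo, double py_hi, double pc_lo, double pc_hi,
                    int t_step, double p_window, double t_jump_prob,
                    bool likelihood_on,
                    int init_T, double init_py, double init_pc) {
  TreeData td = unpack_tree(pre);
  if (Tmin < 2) Tmin = 2;
  if (Tmax > td.n) Tmax = td.n;
  int T = init_T;
  double py = init_py, pc = init_pc;
  EvalResult zero = {0.0, 0.0, 0.0, 0, 0};
  EvalResult cur = likelihood_on ? eval_loglik(td, T, py, pc) : zero;
  double cur_ll = likelihood_on ? cur.loglik : 0.0;

  int n_keep = 0;
  for (int s = 1; s <= n_steps; ++s)
    if (s > burnin && (s - burnin) % thin == 0) ++n_keep;
  NumericMatrix samples(n_keep, 7);
  IntegerVector proposed(3), accepted(3);
  int row = 0;
  for (int s = 1; s <= n_steps; ++s) {
    int which = (int)std::floor(unif_rand() * 3.0);
    if (which > 2) which = 2;
    int nT = T;
    double npy = py, npc = pc;
    if (which == 0) nT = propose_T(T, Tmin, Tmax, t_step, t_jump_prob);
    else if (which == 1) npy = propose_p(py, py_lo, py_hi, p_window);
    else npc = propose_p(pc, pc_lo, pc_hi, p_window);
    EvalResult prop = likelihood_on ? eval_loglik(td, nT, npy, npc) : zero;
    double prop_ll = likelihood_on ? prop.loglik : 0.0;
    ++proposed[which];
    if (std::log(unif_rand()) < prop_ll - cur_ll) {
      T = nT; py = npy; pc = npc; cur = prop; cur_ll = prop_ll;
      ++accepted[which];
    }
    if (s > burnin && (s - burnin) % thin == 0) {
      samples(row, 0) = s;
      samples(row, 1) = T;
      samples(row, 2) = py;
      samples(row, 3) = pc;
      samples(row, 4) = cur.lambda_y;
      samples(row, 5) = cur.lambda_c;
      samples(row, 6) = cur_ll;
      ++row;
    }
  }
  colnames(samples) = CharacterVector::create(
    "step", "threshold", "p_yule", "p_coal", "lambda_yule", "lambda_coal",
    "log_posterior");
  return List::create(_["samples"] = samples, _["proposed"] = proposed,
                      _["accepted"] = accepted);
}
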