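// Tabular Q-learning inner loop over the cached reward graph.
//
// The graph is passed CSR-style: pairs (state-action edges) are sorted by
// state then by the fixed lexicographic action order; state_off (0-based,
// length S+1) delimits each state's pairs.  Greedy ties break to the first
// (lexicographically smallest) action.  All randomness comes from R's RNG so
// runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static int argmax_pair(const std::vector<double> &q, int lo, int hi) {
  int best = lo;
  for (int e = lo + 1; e < hi; ++e)
    if (q[e] > q[best]) best = e;
  return best;
}

// greedy limit cycle mean reward from a start state (NaN on dead end)
static double greedy_speed(const std::vector<double> &q,
                           const IntegerVector &edge_next,
                           const NumericVector &edge_reward,
                           const IntegerVector &state_off,
                           int start, std::vector<int> &visit,
                           std::vector<int> &path) {
  std::fill(visit.begin(), visit.end(), -1);
  path.clear();
  int s = start;
  for (int t = 0;; ++t) {
    if (visit[s] >= 0) {
      double sum = 0.0;
      int t0 = visit[s];
      for (int k = t0; k < t; ++k) sum += edge_reward[path[k]];
      return sum / (t - t0);
    }
    visit[s] = t;
    int lo = state_off[s], hi = state_off[s + 1];
    if (lo == hi) return NA_REAL;
    int e = argmax_pair(q, lo, hi);
    path.push_back(e);
    s = edge_next[e];
  }
}

// [[Rcpp::export]]
List train_cpp(const IntegerVector &edge_next,
               const NumericVector &edge_reward,
               const IntegerVector &state_off,
               const NumericVector &q0,
               const IntegerVector &reset_states,
               int rollout_start,
               int episodes, int steps, double gamma,
               double alpha0, double eps0,
               double alpha_decay, double eps_decay,
               bool alpha_geometric, bool eps_geometric,
               bool reset_each_episode) {
  const int S = state_off.size() - 1;
  const int nreset = reset_states.size();
  if (nreset == 0) stop("no states with available actions");
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<int> visit(S), path;
  NumericVector h_speed(episodes), h_alpha(episodes), h_eps(episodes),
      h_behav(episodes);
  double alpha = alpha0, eps = eps0;
  int s = reset_states[runif_int(nreset)];

  for (int ep = 0; ep < episodes; ++ep) {
    if (reset_each_episode || state_off[s] == state_off[s + 1])
      s = reset_states[runif_int(nreset)];
    double disp = 0.0;
    for (int step = 0; step < steps; ++step) {
      int lo = state_off[s], hi = state_off[s + 1];
      if (lo == hi) { s = reset_states[runif_int(nreset)]; continue; }
      int e = (unif_rand() < eps) ? lo + runif_int(hi - lo)
                                  : argmax_pair(q, lo, hi);
      int sn = edge_next[e];
      int lo2 = state_off[sn], hi2 = state_off[sn + 1];
      double maxn = 0.0;
      if (hi2 > lo2) {
        maxn = q[lo2];
        for (int e2 = lo2 + 1; e2 < hi2; ++e2)
          if (q[e2] > maxn) maxn = q[e2];
      }
      q[e] = (1.0 - alpha) * q[e] + alpha * (edge_reward[e] + gamma * maxn);
      disp += edge_reward[e];
      s = sn;
    }
    h_behav[ep] = disp / steps;
    h_alpha[ep] = alpha;
    h_eps[ep] = eps;
    h_speed[ep] = greedy_speed(q, edge_next, edge_reward, state_off,
                               rollout_start, visit, path);
    if (alpha_geometric) alpha *= alpha_decay;
    if (eps_geometric) eps *= eps_decay;
  }
  return List::create(_["q"] = NumericVector(q.begin(), q.end()),
                      _["greedy_speed"] = h_speed,
                      _["behavior_speed"] = h_behav,
                      _["alpha"] = h_alpha, _["epsilon"] = h_eps);
}
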