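// Batch TD(lambda) training engine.  Mirrors the R reference run_trial()
// exactly: same update rule, same order of uniform draws, long-double
// accumulation in inner products to match R's sum().
#include <Rcpp.h>
using namespace Rcpp;

static inline double dot_col(const NumericMatrix& PhiT, int state,
                             const std::vector<double>& w) {
  long double acc = 0.0L;
  const int N = PhiT.nrow();
  const double* col = &PhiT(0, state);
  for (int i = 0; i < N; ++i) acc += w[i] * col[i];
  return (double)acc;
}

// PhiT: N x M basis (transposed, one column per state); nb: M x 4 neighbor
// table, 0-based, -1 for unavailable, columns in action order N,S,E,W;
// starts: 0-based candidate start states.
// [[Rcpp::export]]
List td_train_cpp(NumericMatrix PhiT, IntegerMatrix nb, int goal,
                  double reward, IntegerVector starts, int n_runs,
                  int n_trials, double alpha, double lambda, double gamma,
                  double beta, int max_steps) {
  const int N = PhiT.nrow();
  const int n_starts = starts.size();
  IntegerMatrix steps_out(n_runs, n_trials);
  NumericMatrix W_out(n_runs, N);
  std::vector<double> w(N), e(N);
  double q[4], ex[4];
  int acts[4];

  for (int run = 0; run < n_runs; ++run) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int trial = 0; trial < n_trials; ++trial) {
      double u = unif_rand();
      int s = starts[(int)(u * n_starts)];
      std::fill(e.begin(), e.end(), 0.0);
      int steps = 0;
      while (steps < max_steps) {
        // one-step-lookahead Q over available actions
        int na = 0;
        double qmax = R_NegInf;
        for (int a = 0; a < 4; ++a) {
          int t = nb(s, a);
          if (t < 0) continue;
          q[na] = dot_col(PhiT, t, w);
          if (q[na] > qmax) qmax = q[na];
          acts[na] = t;
          ++na;
        }
        long double tot = 0.0L;
        for (int a = 0; a < na; ++a) { ex[a] = std::exp(beta * (q[a] - qmax)); tot += ex[a]; }
        double u2 = unif_rand() * (double)tot;
        int pick = na - 1;
        double accp = 0.0;
        for (int a = 0; a < na; ++a) {
          accp += ex[a];
          if (u2 <= accp) { pick = a; break; }
        }
        int s_next = acts[pick];
        ++steps;
        // TD update for the visited state (r = 0 off the goal)
        double v_s = dot_col(PhiT, s, w);
        double v_n = dot_col(PhiT, s_next, w);
        double delta = gamma * v_n - v_s;
        const double* phi_s = &PhiT(0, s);
        double gl = gamma * lambda;
        for (int i = 0; i < N; ++i) {
          e[i] = gl * e[i] + phi_s[i];
          w[i] += alpha * delta * e[i];
        }
        s = s_next;
        if (s == goal) {
          // final terminal update at the absorbing goal
          double v_g = dot_col(PhiT, s, w);
          double dg = reward - v_g;
          const double* phi_g = &PhiT(0, s);
          for (int i = 0; i < N; ++i) {
            e[i] = gl * e[i] + phi_g[i];
            w[i] += alpha * dg * e[i];
          }
          break;
        }
      }
      steps_out(run, trial) = steps;
    }
    for (int i = 0; i < N; ++i) W_out(run, i) = w[i];
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["steps"] = steps_out, _["weights"] = W_out);
}
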