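#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout used by both entry points:
//   par[0] alpha_rl, par[1] gamma, par[2] phi, par[3] rho,
//   par[4] nu, par[5] wm_cap, par[6] beta
// Trials must be time-ordered with contiguous blocks; stim_local is the
// 0-based index of the stimulus within its block; global stimulus index is
// offset[block] + stim_local with offset = cumsum(block_ns).

namespace {

inline void softmax(const std::vector<double>& v, int n, double beta,
                    std::vector<double>& out) {
  double m = v[0];
  for (int j = 1; j < n; ++j) if (v[j] > m) m = v[j];
  double z = 0.0;
  for (int j = 0; j < n; ++j) { out[j] = std::exp(beta * (v[j] - m)); z += out[j]; }
  for (int j = 0; j < n; ++j) out[j] /= z;
}

// probability of choosing the first of two values under softmax(beta)
inline double softmax2_first(double va, double vb, double beta) {
  double d = beta * (va - vb);
  if (d > 0) return 1.0 / (1.0 + std::exp(-d));
  double e = std::exp(d);
  return e / (1.0 + e);
}

struct SessionState {
  int ns, na;
  double q0;
  std::vector<double> Q, WM, V;      // ns*na, ns*na, ns
  std::vector<int> delay;            // ns: intervening count carried over
                                     //     from completed presentation gaps
  std::vector<int> pending;          // ns: count within the current gap
  std::vector<char> seen;            // ns*ns: seen[k*ns + s] in current gap
  void reset(int ns_, int na_) {
    ns = ns_; na = na_; q0 = 1.0 / na_;
    Q.assign(ns * na, q0);
    WM.assign(ns * na, q0);
    V.assign(ns, q0);
    delay.assign(ns, 0);
    pending.assign(ns, 0);
    seen.assign(ns * ns, 0);
  }
};

// delay_mode 0 ("gap"): unique intervening stimuli per inter-presentation
//   gap, accumulated across gaps since the last correct response
// delay_mode 1 ("window"): unique intervening stimuli over the whole window
//   since the last correct response (bounded by set size - 1)
// delay_mode 2 ("trials"): all intervening trials since the last correct
inline void delay_advance(SessionState& st, int s, int r, int delay_mode) {
  int ns = st.ns;
  if (delay_mode == 2) {
    // reset before incrementing so that at the next presentation the counter
    // equals the trial distance to the last correct response (the same clock
    // as the behavioural delay regressor)
    if (r == 1) st.delay[s] = 0;
    for (int k = 0; k < ns; ++k) st.delay[k]++;
    return;
  }
  // close the current stimulus's gap: fold its pending count into the
  // carried delay (gap mode) or keep the since-correct uniqueness (window)
  if (delay_mode == 0) {
    st.delay[s] += st.pending[s];
    st.pending[s] = 0;
    for (int j = 0; j < ns; ++j) st.seen[s * ns + j] = 0;
  }
  if (r == 1) {
    st.delay[s] = 0;
    st.pending[s] = 0;
    for (int j = 0; j < ns; ++j) st.seen[s * ns + j] = 0;
  }
  for (int k = 0; k < ns; ++k) {
    if (k == s) continue;
    if (!st.seen[k * ns + s]) { st.seen[k * ns + s] = 1; st.pending[k]++; }
  }
}

inline double omega_of(const SessionState& st, int s, double rho, double cap) {
  int nd = st.delay[s] + st.pending[s];
  double m = (nd <= cap) ? 1.0 : cap / (double)nd;
  return rho * m;
}

// post-choice bookkeeping shared by likelihood and simulation:
// delay counters, then RL/WM/critic updates, then WM decay
inline void step_update(SessionState& st, int s, int a, int r, double rc,
                        double alpha, double gamma, double phi,
                        bool pair_level_decay, int delay_mode) {
  int na = st.na, ns = st.ns;
  delay_advance(st, s, r, delay_mode);
  double q = st.Q[s * na + a];
  st.Q[s * na + a] = (r == 1) ? q + alpha * (1.0 - q) : q + alpha * gamma * (0.0 - q);
  st.WM[s * na + a] = (r == 1) ? 1.0 : (1.0 - gamma) * st.WM[s * na + a];
  double v = st.V[s];
  st.V[s] = (r == 1) ? v + alpha * (rc - v) : v + alpha * gamma * (0.0 - v);
  for (int k = 0; k < ns; ++k) {
    for (int j = 0; j < na; ++j) {
      if (pair_level_decay ? (k == s && j == a) : (k == s)) continue;
      double w = st.WM[k * na + j];
      st.WM[k * na + j] = w + phi * (st.q0 - w);
    }
  }
}

} // namespace

// [[Rcpp::export]]
double cpp_session_loglik(IntegerVector block, IntegerVector stim_local,
                          IntegerVector action, IntegerVector reward,
                          NumericVector critic_reward,
                          IntegerVector block_ns, int n_actions,
                          IntegerVector test_i, IntegerVector test_j,
                          IntegerVector test_choice,
                          NumericVector par, bool pair_level_decay,
                          int delay_mode) {
  const double alpha = par[0], gamma = par[1], phi = par[2], rho = par[3],
               nu = par[4], cap = par[5], beta = par[6];
  const int nT = block.size(), nB = block_ns.size();
  std::vector<int> offset(nB, 0);
  for (int b = 1; b < nB; ++b) offset[b] = offset[b - 1] + block_ns[b - 1];
  const int nS = nB ? offset[nB - 1] + block_ns[nB - 1] : 0;
  std::vector<double> Vglob(nS, 1.0 / n_actions);

  SessionState st;
  std::vector<double> prl(n_actions), pwm(n_actions), qv(n_actions), wv(n_actions);
  int cur = -1;
  double ll = 0.0;
  for (int t = 0; t < nT; ++t) {
    int b = block[t];
    if (b != cur) { st.reset(block_ns[b], n_actions); cur = b; }
    int s = stim_local[t], a = action[t], r = reward[t];
    double w = omega_of(st, s, rho, cap);
    for (int j = 0; j < n_actions; ++j) {
      qv[j] = st.Q[s * n_actions + j];
      wv[j] = st.WM[s * n_actions + j];
    }
    softmax(qv, n_actions, beta, prl);
    softmax(wv, n_actions, beta, pwm);
    ll += std::log((1.0 - w) * prl[a] + w * pwm[a]);
    step_update(st, s, a, r, critic_reward[t], alpha, gamma, phi,
                pair_level_decay, delay_mode);
    Vglob[offset[b] + s] = st.V[s];
  }
  for (int t = 0; t < test_i.size(); ++t) {
    double pa = 0.5 * nu +
      (1.0 - nu) * softmax2_first(Vglob[test_i[t]], Vglob[test_j[t]], beta);
    ll += std::log(test_choice[t] == 0 ? pa : 1.0 - pa);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_simulate_session(IntegerVector block, IntegerVector stim_local,
                          IntegerVector correct_action,
                          IntegerVector block_ns, int n_actions,
                          NumericVector par, double p_two,
                          IntegerVector test_i, IntegerVector test_j,
                          NumericVector test_ns_i, NumericVector test_ns_j,
                          double kappa, bool pair_level_decay,
                          bool critic_points, int delay_mode) {
  const double alpha = par[0], gamma = par[1], phi = par[2], rho = par[3],
               nu = par[4], cap = par[5], beta = par[6];
  const int nT = block.size(), nB = block_ns.size();
  std::vector<int> offset(nB, 0);
  for (int b = 1; b < nB; ++b) offset[b] = offset[b - 1] + block_ns[b - 1];
  const int nS = nB ? offset[nB - 1] + block_ns[nB - 1] : 0;
  std::vector<double> Vglob(nS, 1.0 / n_actions);

  IntegerVector act(nT), corr(nT), pts(nT);
  SessionState st;
  std::vector<double> prl(n_actions), pwm(n_actions), qv(n_actions), wv(n_actions);
  int cur = -1;
  for (int t = 0; t < nT; ++t) {
    int b = block[t];
    if (b != cur) { st.reset(block_ns[b], n_actions); cur = b; }
    int s = stim_local[t];
    double w = omega_of(st, s, rho, cap);
    for (int j = 0; j < n_actions; ++j) {
      qv[j] = st.Q[s * n_actions + j];
      wv[j] = st.WM[s * n_actions + j];
    }
    softmax(qv, n_actions, beta, prl);
    softmax(wv, n_actions, beta, pwm);
    double u = R::runif(0.0, 1.0), acc = 0.0;
    int a = n_actions - 1;
    for (int j = 0; j < n_actions; ++j) {
      acc += (1.0 - w) * prl[j] + w * pwm[j];
      if (u < acc) { a = j; break; }
    }
    int r = (a == correct_action[t]) ? 1 : 0;
    int p = r ? ((R::runif(0.0, 1.0) < p_two) ? 2 : 1) : 0;
    act[t] = a; corr[t] = r; pts[t] = p;
    double rc = critic_points ? (double)p : (double)r;
    step_update(st, s, a, r, rc, alpha, gamma, phi, pair_level_decay, delay_mode);
    Vglob[offset[b] + s] = st.V[s];
  }
  const int nP = test_i.size();
  IntegerVector choice(nP);
  for (int t = 0; t < nP; ++t) {
    double ua = Vglob[test_i[t]] - kappa * test_ns_i[t];
    double ub = Vglob[test_j[t]] - kappa * test_ns_j[t];
    double pa = 0.5 * nu + (1.0 - nu) * softmax2_first(ua, ub, beta);
    choice[t] = (R::runif(0.0, 1.0) < pa) ? 0 : 1;
  }
  return List::create(_["action"] = act, _["correct"] = corr,
                      _["points"] = pts, _["test_choice"] = choice);
}
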