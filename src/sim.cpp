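#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Geometry of the circular world. Angles live in [-pi, pi); arcs are
// half-open [center - len/2, center + len/2), wrap-aware.
static const double PI_ = 3.14159265358979323846;

static inline double norm_angle(double x) {
  return x - 2.0 * PI_ * std::floor((x + PI_) / (2.0 * PI_));
}

static inline bool in_arc(double pos, double center, double len) {
  double d = norm_angle(pos - center);
  return d >= -len / 2.0 && d < len / 2.0;
}

static const double NEST_LEN = PI_ / 2.0;
static const double SITE_LEN = PI_ / 4.0;
static const double SITE_CENTERS[5] = {PI_ / 2.0, 3.0 * PI_ / 4.0, PI_,
                                       -3.0 * PI_ / 4.0, -PI_ / 2.0};

static inline bool in_nest(double pos) { return in_arc(pos, 0.0, NEST_LEN); }

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Fixed-topology CTRNN: 3 inputs, 5 fully recurrent hidden, 2 or 3 outputs.
struct Net {
  int nin, nh, nout, n;
  std::vector<double> Wih;   // nh x nin, column-major (by input)
  std::vector<double> Whh;   // nh x nh, column-major (by presynaptic hidden)
  std::vector<double> Who;   // nout x nh, column-major (by presynaptic hidden)
  std::vector<double> theta; // n biases, order: inputs, hidden, outputs
  std::vector<double> tau;   // n time constants, same order
};

static Net decode(const double* g, int len, int nout) {
  Net net;
  net.nin = 3; net.nh = 5; net.nout = nout;
  net.n = net.nin + net.nh + net.nout;
  int expected = net.nin * net.nh + net.nh * net.nh + net.nh * net.nout +
                 2 * net.n;
  if (len != expected) stop("genome length %d does not match architecture (%d)",
                            len, expected);
  int k = 0;
  net.Wih.resize(net.nh * net.nin);
  for (int i = 0; i < net.nh * net.nin; ++i) net.Wih[i] = 8.0 * g[k++] - 4.0;
  net.Whh.resize(net.nh * net.nh);
  for (int i = 0; i < net.nh * net.nh; ++i) net.Whh[i] = 8.0 * g[k++] - 4.0;
  net.Who.resize(net.nout * net.nh);
  for (int i = 0; i < net.nout * net.nh; ++i) net.Who[i] = 8.0 * g[k++] - 4.0;
  net.theta.resize(net.n);
  for (int i = 0; i < net.n; ++i) net.theta[i] = 4.0 * g[k++] - 2.0;
  net.tau.resize(net.n);
  for (int i = 0; i < net.n; ++i) net.tau[i] = 0.1 + 0.9 * g[k++];
  return net;
}

struct NetState {
  std::vector<double> s; // internal states, all neurons
  std::vector<double> y; // activations, all neurons
};

static void reset_state(const Net& net, NetState& st) {
  st.s.assign(net.n, 0.0);
  st.y.resize(net.n);
  for (int i = 0; i < net.n; ++i) st.y[i] = sigmoid(net.theta[i]);
}

struct SimOpts {
  double alpha;          // integration step size
  double max_speed;      // radians per step
  int input_mode;        // 0 = integrate, 1 = direct pass-through
  int tau_form;          // 0 = tau multiplies bracket (as printed), 1 = alpha/tau
  int treatment;         // 0 = communication, 1 = no_communication, 2 = constrained_sender
  double fixed_amp;      // NaN = off; else emitted amplitude override
  bool duration_lock;    // freeze sender on first nest re-entry
  double constrained_speed;
  double constrained_dir;
  double onset_thr;      // perceived amplitude counting as signal onset
};

static SimOpts parse_opts(const List& opts) {
  SimOpts o;
  o.alpha = as<double>(opts["alpha"]);
  o.max_speed = as<double>(opts["max_speed"]);
  o.input_mode = as<int>(opts["input_mode"]);
  o.tau_form = as<int>(opts["tau_form"]);
  o.treatment = as<int>(opts["treatment"]);
  o.fixed_amp = as<double>(opts["fixed_amp"]);
  o.duration_lock = as<bool>(opts["duration_lock"]);
  o.constrained_speed = as<double>(opts["constrained_speed"]);
  o.constrained_dir = as<double>(opts["constrained_dir"]);
  o.onset_thr = as<double>(opts["onset_thr"]);
  return o;
}

// One synchronous network update: input neurons first (driven by the raw
// sensory value in place of the weighted sum), then hidden (fed by the fresh
// input activations and the previous hidden activations), then outputs.
static void net_step(const Net& net, NetState& st, const double* inputs,
                     const SimOpts& o) {
  const int nin = net.nin, nh = net.nh, nout = net.nout;
  double yin[3];
  for (int i = 0; i < nin; ++i) {
    if (o.input_mode == 1) {
      yin[i] = inputs[i];
      st.y[i] = yin[i];
    } else {
      double rate = (o.tau_form == 0) ? o.alpha * net.tau[i]
                                      : o.alpha / net.tau[i];
      st.s[i] += rate * (inputs[i] - st.s[i]);
      yin[i] = sigmoid(st.s[i] + net.theta[i]);
      st.y[i] = yin[i];
    }
  }
  double yh_prev[5];
  for (int h = 0; h < nh; ++h) yh_prev[h] = st.y[nin + h];
  double yh_new[5];
  for (int h = 0; h < nh; ++h) {
    double sum = 0.0;
    for (int i = 0; i < nin; ++i) sum += net.Wih[h + nh * i] * yin[i];
    for (int j = 0; j < nh; ++j) sum += net.Whh[h + nh * j] * yh_prev[j];
    int idx = nin + h;
    double rate = (o.tau_form == 0) ? o.alpha * net.tau[idx]
                                    : o.alpha / net.tau[idx];
    st.s[idx] += rate * (sum - st.s[idx]);
    yh_new[h] = sigmoid(st.s[idx] + net.theta[idx]);
  }
  for (int h = 0; h < nh; ++h) st.y[nin + h] = yh_new[h];
  for (int oN = 0; oN < nout; ++oN) {
    double sum = 0.0;
    for (int h = 0; h < nh; ++h) sum += net.Who[oN + nout * h] * yh_new[h];
    int idx = nin + nh + oN;
    double rate = (o.tau_form == 0) ? o.alpha * net.tau[idx]
                                    : o.alpha / net.tau[idx];
    st.s[idx] += rate * (sum - st.s[idx]);
    st.y[idx] = sigmoid(st.s[idx] + net.theta[idx]);
  }
}

static inline void motor(const double y1, const double y2, double max_speed,
                         double& speed, double& dir) {
  double d = y1 - y2;
  speed = std::fabs(d) * max_speed;
  dir = (d >= 0.0) ? 1.0 : -1.0;
}

// Simulate one 100-step trial for one pair. Logged positions are the ones
// used for sensing/gating at each step (pre-move); scoring uses the same.
// If `log` is non-null it must point at 100 rows x 6 cols storage
// (sender_pos, receiver_pos, emitted, perceived, food_sensor, on_food),
// filled column-major with leading dimension ld and row offset row0.
static double run_one_trial(const Net& S, const Net& R, int food_site,
                            const SimOpts& o, int n_steps,
                            double* log, int ld, int row0,
                            int* onset /* first step perceived > thr, -1 */) {
  NetState stS, stR;
  reset_state(S, stS);
  reset_state(R, stR);
  double posS = 0.0, posR = 0.0;
  bool frozen = false, was_outside = false;
  double perf = 0.0;
  int first_onset = -1;
  const bool no_comm = (o.treatment == 1);
  const bool constrained = (o.treatment == 2);
  const bool fix_amp = !ISNAN(o.fixed_amp);
  const double fc = SITE_CENTERS[food_site];
  for (int t = 1; t <= n_steps; ++t) {
    double food = in_arc(posS, fc, SITE_LEN) ? 1.0 : 0.0;
    double inS[3] = {std::sin(posS), std::cos(posS), food};
    net_step(S, stS, inS, o);
    double emitted = fix_amp ? o.fixed_amp : stS.y[S.nin + S.nh + 2];
    double avail = in_nest(posS) ? emitted : 0.0;
    double perceived = no_comm ? 0.0 : (in_nest(posR) ? avail : 0.0);
    double inR[3] = {std::sin(posR), std::cos(posR), perceived};
    net_step(R, stR, inR, o);
    bool on_food = in_arc(posR, fc, SITE_LEN);
    if (t >= n_steps - 19 && on_food) perf += 0.01;
    if (first_onset < 0 && perceived > o.onset_thr) first_onset = t;
    if (log) {
      int r = row0 + (t - 1);
      log[r + ld * 0] = posS;
      log[r + ld * 1] = posR;
      log[r + ld * 2] = emitted;
      log[r + ld * 3] = perceived;
      log[r + ld * 4] = food;
      log[r + ld * 5] = on_food ? 1.0 : 0.0;
    }
    // movement
    if (constrained) {
      posS = norm_angle(posS + o.constrained_dir * o.constrained_speed);
    } else {
      if (o.duration_lock && !frozen) {
        bool in = in_nest(posS);
        if (!in) was_outside = true;
        else if (was_outside) frozen = true;
      }
      if (!frozen) {
        double sp, dir;
        motor(stS.y[S.nin + S.nh + 0], stS.y[S.nin + S.nh + 1], o.max_speed,
              sp, dir);
        posS = norm_angle(posS + dir * sp);
      }
    }
    double spR, dirR;
    motor(stR.y[R.nin + R.nh + 0], stR.y[R.nin + R.nh + 1], o.max_speed,
          spR, dirR);
    posR = norm_angle(posR + dirR * spR);
  }
  if (onset) *onset = first_onset;
  return perf;
}

// Evaluate a whole population of pairs: per-pair, per-trial performance and
// signal-onset step. Genome matrices are n_pairs x genome_length; food is
// n_pairs x 5 (0-based site indices, each row a permutation).
// [[Rcpp::export]]
List cpp_eval_population(NumericMatrix sender_g, NumericMatrix receiver_g,
                         IntegerMatrix food, List opts_, int n_steps) {
  SimOpts o = parse_opts(opts_);
  int n = sender_g.nrow();
  if (receiver_g.nrow() != n || food.nrow() != n)
    stop("sender, receiver and food-order row counts differ");
  if (food.ncol() != 5) stop("food order must have 5 columns");
  NumericMatrix perf(n, 5);
  IntegerMatrix onset(n, 5);
  int slen = sender_g.ncol(), rlen = receiver_g.ncol();
  std::vector<double> sg(slen), rg(rlen);
  for (int p = 0; p < n; ++p) {
    for (int j = 0; j < slen; ++j) sg[j] = sender_g(p, j);
    for (int j = 0; j < rlen; ++j) rg[j] = receiver_g(p, j);
    Net S = decode(sg.data(), slen, 3);
    Net R = decode(rg.data(), rlen, 2);
    for (int k = 0; k < 5; ++k) {
      int f = food(p, k);
      if (f < 0 || f > 4) stop("food site index out of range");
      int on;
      perf(p, k) = run_one_trial(S, R, f, o, n_steps, nullptr, 0, 0, &on);
      onset(p, k) = (on < 0) ? NA_INTEGER : on;
    }
  }
  return List::create(_["perf"] = perf, _["onset"] = onset);
}

// Run the five trials of one pair with full step-level logging.
// [[Rcpp::export]]
List cpp_run_pair(NumericVector sender_g, NumericVector receiver_g,
                  IntegerVector food_order, List opts_, int n_steps) {
  SimOpts o = parse_opts(opts_);
  int m = food_order.size();
  if (m < 1) stop("food_order must not be empty");
  Net S = decode(REAL(sender_g), sender_g.size(), 3);
  Net R = decode(REAL(receiver_g), receiver_g.size(), 2);
  NumericMatrix log(m * n_steps, 6);
  NumericVector perf(m);
  IntegerVector onset(m);
  for (int k = 0; k < m; ++k) {
    int f = food_order[k];
    if (f < 0 || f > 4) stop("food site index out of range");
    int on;
    perf[k] = run_one_trial(S, R, f, o, n_steps, REAL(log), m * n_steps,
                            k * n_steps, &on);
    onset[k] = (on < 0) ? NA_INTEGER : on;
  }
  return List::create(_["perf"] = perf, _["onset"] = onset, _["log"] = log);
}

// Re-run only the receiver against a prescribed available-signal schedule
// (already gated by the logged sender nest presence); perception remains
// gated by the live receiver nest presence.
// [[Rcpp::export]]
List cpp_replay_receiver(NumericVector receiver_g, NumericMatrix avail,
                         IntegerVector food_order, List opts_, int n_steps) {
  SimOpts o = parse_opts(opts_);
  int m = food_order.size();
  if (m < 1) stop("food_order must not be empty");
  if (avail.nrow() != n_steps || avail.ncol() != m)
    stop("avail must be n_steps x length(food_order)");
  Net R = decode(REAL(receiver_g), receiver_g.size(), 2);
  NumericVector perf(m);
  NumericMatrix log(m * n_steps, 3); // receiver_pos, perceived, on_food
  const int ld = m * n_steps;
  for (int k = 0; k < m; ++k) {
    int f = food_order[k];
    if (f < 0 || f > 4) stop("food site index out of range");
    const double fc = SITE_CENTERS[f];
    NetState st;
    reset_state(R, st);
    double posR = 0.0, p = 0.0;
    for (int t = 1; t <= n_steps; ++t) {
      double perceived = in_nest(posR) ? avail(t - 1, k) : 0.0;
      double inR[3] = {std::sin(posR), std::cos(posR), perceived};
      net_step(R, st, inR, o);
      bool on_food = in_arc(posR, fc, SITE_LEN);
      if (t >= n_steps - 19 && on_food) p += 0.01;
      int r = k * n_steps + (t - 1);
      log[r + ld * 0] = posR;
      log[r + ld * 1] = perceived;
      log[r + ld * 2] = on_food ? 1.0 : 0.0;
      double sp, dir;
      motor(st.y[R.nin + R.nh + 0], st.y[R.nin + R.nh + 1], o.max_speed,
            sp, dir);
      posR = norm_angle(posR + dir * sp);
    }
    perf[k] = p;
  }
  return List::create(_["perf"] = perf, _["log"] = log);
}
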