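// Event-driven simulation of the dual-pathway AV-node network.
//
// The network is two parallel linear chains (fast pathway FP, slow pathway
// SP) of `n_chain` nodes each, converging on a single coupling node.  Every
// atrial impulse enters node 0 of both chains simultaneously.  A node that
// receives an impulse while refractory blocks it; otherwise it forwards the
// impulse after a diastolic-interval-dependent conduction delay and issues
// itself a new refractory period.  The coupling node has a fixed 60 ms delay
// and a fixed refractory period equal to RR_min; each of its conductions is
// one ventricular activation.

#include <Rcpp.h>
#include <queue>
#include <random>
#include <vector>
#include <cmath>

namespace {

struct Event {
  double t;
  int pathway;  // 0 = FP, 1 = SP, 2 = coupling
  int node;     // index within pathway chain
};

// ties broken (time, FP before SP before coupling, node index)
struct EventLater {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.pathway != b.pathway) return a.pathway > b.pathway;
    return a.node > b.node;
  }
};

struct Pathway {
  double r_min, delta_r, tau_r, d_min, delta_d, tau_d;
};

class AVNetwork {
 public:
  AVNetwork(const Pathway& fp, const Pathway& sp, double rr_min,
            int n_chain)
      : fp_(fp), sp_(sp), rr_min_(rr_min), n_chain_(n_chain),
        t_last_(2 * n_chain, 0.0), r_last_(2 * n_chain, 0.0),
        active_(2 * n_chain, false), coupling_active_(false),
        coupling_t_last_(0.0) {}

  void impulse(double t) {
    queue_.push(Event{t, 0, 0});
    queue_.push(Event{t, 1, 0});
  }

  bool empty() const { return queue_.empty(); }
  double next_time() const { return queue_.top().t; }

  // process the earliest event; returns ventricular activation time or NaN
  double step() {
    Event ev = queue_.top();
    queue_.pop();
    if (ev.pathway == 2) return coupling(ev.t);
    const Pathway& p = (ev.pathway == 0) ? fp_ : sp_;
    int idx = ev.pathway * n_chain_ + ev.node;
    double delay;
    if (!active_[idx]) {
      // never activated: full-recovery convention (diastolic interval -> inf)
      delay = p.d_min;
      r_last_[idx] = p.r_min + p.delta_r;
    } else {
      double t_dia = ev.t - t_last_[idx] - r_last_[idx];
      if (t_dia < 0) return NA_REAL;  // refractory: impulse dies here
      delay = p.d_min + p.delta_d * std::exp(-t_dia / p.tau_d);
      r_last_[idx] = p.r_min + p.delta_r * (1.0 - std::exp(-t_dia / p.tau_r));
    }
    active_[idx] = true;
    t_last_[idx] = ev.t;
    if (ev.node + 1 < n_chain_)
      queue_.push(Event{ev.t + delay, ev.pathway, ev.node + 1});
    else
      queue_.push(Event{ev.t + delay, 2, 0});
    return NA_REAL;
  }

 private:
  double coupling(double t) {
    if (coupling_active_) {
      double t_dia = t - coupling_t_last_ - rr_min_;
      if (t_dia < 0) return NA_REAL;
    }
    coupling_active_ = true;
    coupling_t_last_ = t;
    return t + 60.0;  // fixed coupling-node delay
  }

  Pathway fp_, sp_;
  double rr_min_;
  int n_chain_;
  std::vector<double> t_last_, r_last_;
  std::vector<bool> active_;
  bool coupling_active_;
  double coupling_t_last_;
  std::priority_queue<Event, std::vector<Event>, EventLater> queue_;
};

Pathway pathway_from(const Rcpp::NumericVector& theta, int offset_r,
                     int offset_d) {
  Pathway p;
  p.r_min = theta[offset_r];
  p.delta_r = theta[offset_r + 1];
  p.tau_r = theta[offset_r + 2];
  p.d_min = theta[offset_d];
  p.delta_d = theta[offset_d + 1];
  p.tau_d = theta[offset_d + 2];
  return p;
}

}  // namespace

// theta layout (fixed order used throughout the package):
// [R_min^FP, dR^FP, tauR^FP, R_min^SP, dR^SP, tauR^SP,
//  D_min^FP, dD^FP, tauD^FP, D_min^SP, dD^SP, tauD^SP]

// [[Rcpp::export]]
Rcpp::NumericVector cpp_simulate_train(Rcpp::NumericVector theta,
                                       Rcpp::NumericVector arrivals,
                                       double rr_min, int n_chain) {
  AVNetwork net(pathway_from(theta, 0, 6), pathway_from(theta, 3, 9),
                rr_min, n_chain);
  std::vector<double> out;
  std::size_t next = 0;
  while (next < (std::size_t)arrivals.size() || !net.empty()) {
    if (next < (std::size_t)arrivals.size() &&
        (net.empty() || arrivals[next] <= net.next_time())) {
      net.impulse(arrivals[next]);
      ++next;
    } else {
      double v = net.step();
      if (!ISNA(v)) out.push_back(v);
    }
  }
  return Rcpp::wrap(out);
}

// Poisson-driven simulation with lazily generated impulses.  Runs until
// n_rr RR intervals are emitted (n_rr + 1 activations) or t_max_ms is
// reached, whichever applies (<= 0 disables that stop rule).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_simulate_poisson(Rcpp::NumericVector theta,
                                         double lambda_hz, double rr_min,
                                         int n_chain, double seed,
                                         int n_rr, double t_max_ms) {
  AVNetwork net(pathway_from(theta, 0, 6), pathway_from(theta, 3, 9),
                rr_min, n_chain);
  std::mt19937_64 rng((uint64_t)seed);
  // inter-arrival times in ms; exponential with mean 1000 / lambda
  const double mean_ms = 1000.0 / lambda_hz;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto rexp_ms = [&]() {
    double u;
    do { u = unif(rng); } while (u <= 0.0);
    return -std::log(u) * mean_ms;
  };

  double next_arrival = rexp_ms();
  std::vector<double> out;
  const long max_impulses =
      1000000L + (n_rr > 0 ? 2000L * (long)n_rr : 0L);
  long n_impulses = 0;
  while (true) {
    if (n_rr > 0 && (int)out.size() >= n_rr + 1) break;
    if (t_max_ms > 0 && next_arrival > t_max_ms && net.empty()) break;
    if (n_impulses > max_impulses) break;  // pathological parameters
    if (net.empty() || next_arrival <= net.next_time()) {
      if (t_max_ms > 0 && next_arrival > t_max_ms) {
        // drain remaining events, no new impulses
        if (net.empty()) break;
        double v = net.step();
        if (!ISNA(v)) out.push_back(v);
        continue;
      }
      net.impulse(next_arrival);
      next_arrival += rexp_ms();
      ++n_impulses;
    } else {
      double v = net.step();
      if (!ISNA(v)) out.push_back(v);
    }
  }
  return Rcpp::wrap(out);
}
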