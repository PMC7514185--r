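// Event-handling integrator for conductance-based integrate-and-fire
// networks.  Voltage follows
//   dx_i/dt = -x_i/tau - (g_bg + g_ex)(x_i - x_ex) - g_in(x_i - x_in)
// with conductances that jump at event times (background Poisson arrivals
// and recurrent spikes) and decay exponentially between them.  Voltage is
// advanced by midpoint Runge-Kutta on sub-intervals delimited by events;
// conductance decay is applied analytically, so only the voltage is
// integrated numerically.

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Deterministic per-node RNG stream: 64-bit mix of (seed, node), uniform
// doubles derived from raw mt19937_64 output so results do not depend on
// library distribution internals.
struct NodeRng {
  std::mt19937_64 eng;
  NodeRng(int seed, int node) {
    std::uint64_t s = static_cast<std::uint64_t>(seed) * 0x9E3779B97F4A7C15ULL
        ^ (static_cast<std::uint64_t>(node) + 1ULL) * 0xBF58476D1CE4E5B9ULL;
    // splitmix64 scramble to decorrelate nearby (seed, node) pairs
    s += 0x9E3779B97F4A7C15ULL;
    s = (s ^ (s >> 30)) * 0xBF58476D1CE4E5B9ULL;
    s = (s ^ (s >> 27)) * 0x94D049BB133111EBULL;
    eng.seed(s ^ (s >> 31));
  }
  // uniform on (0, 1]
  double unif() {
    return (static_cast<double>(eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
};

std::vector<double> poisson_times(double mu, double duration, int seed,
                                  int node) {
  std::vector<double> out;
  if (mu <= 0.0 || duration <= 0.0) return out;
  NodeRng rng(seed, node);
  double t = 0.0;
  for (;;) {
    t += -std::log(rng.unif()) / mu;
    if (t >= duration) break;
    out.push_back(t);
  }
  return out;
}

struct IFP {
  double tau, x_ex, x_in, sigma_ex, sigma_in, x_th, x_r, tau_ref, f, mu, dt;
};

inline double dvdt(const IFP& p, double x, double gbg, double gex,
                   double gin) {
  return -x / p.tau - (gbg + gex) * (x - p.x_ex) - gin * (x - p.x_in);
}

struct NodeState {
  double x, g_bg, g_ex, g_in;
  double ref_end;   // refractory clamp active while t < ref_end
  std::size_t bg_ptr;
};

}  // namespace

// [[Rcpp::export(name = ".cpp_background_events")]]
NumericVector cpp_background_events(double mu, double duration, int seed,
                                    int node) {
  std::vector<double> ev = poisson_times(mu, duration, seed, node);
  return NumericVector(ev.begin(), ev.end());
}

// [[Rcpp::export(name = ".cpp_simulate_ifnet")]]
List cpp_simulate_ifnet(int n, IntegerVector edge_from, IntegerVector edge_to,
                        NumericVector edge_strength, IntegerVector node_sign,
                        List params, double duration, double transient,
                        int seed, bool constant_bg, bool check_bounds) {
  IFP p;
  p.tau = params["tau"];       p.x_ex = params["x_ex"];
  p.x_in = params["x_in"];     p.sigma_ex = params["sigma_ex"];
  p.sigma_in = params["sigma_in"]; p.x_th = params["x_th"];
  p.x_r = params["x_r"];       p.tau_ref = params["tau_ref"];
  p.f = params["f"];           p.mu = params["mu"];
  p.dt = params["dt"];

  const double t_end = transient + duration;

  // adjacency: children of each node with their strengths
  std::vector<std::vector<std::pair<int, double>>> kids(n);
  for (int e = 0; e < edge_from.size(); ++e) {
    kids[edge_from[e] - 1].push_back({edge_to[e] - 1, edge_strength[e]});
  }

  // per-node background arrival times over the whole run
  std::vector<std::vector<double>> bg(n);
  if (!constant_bg) {
    for (int i = 0; i < n; ++i) bg[i] = poisson_times(p.mu, t_end, seed, i + 1);
  }

  std::vector<NodeState> st(n);
  for (int i = 0; i < n; ++i) {
    st[i] = {p.x_r, constant_bg ? p.f : 0.0, 0.0, 0.0, -1.0, 0};
  }

  std::vector<int> spike_node;
  std::vector<double> spike_time;
  // deliveries scheduled for the start of the next step: (node, dg_ex, dg_in)
  std::vector<double> pend_ex(n, 0.0), pend_in(n, 0.0);

  long nsteps = static_cast<long>(std::ceil(t_end / p.dt - 1e-12));

  // advance one node's voltage over [a, b] with conductances fixed at their
  // value at `a` for evaluation via analytic decay; returns crossing flag
  auto advance_segment = [&](NodeState& s, double a, double b,
                             bool& crossed, double& t_cross) {
    crossed = false;
    double h = b - a;
    if (h <= 0) return;
    double start = a;
    double x0 = s.x;
    if (s.ref_end > a) {
      if (s.ref_end >= b) {
        // clamped throughout: only decay conductances
        double de = std::exp(-h / p.sigma_ex), di = std::exp(-h / p.sigma_in);
        if (!constant_bg) s.g_bg *= de;
        s.g_ex *= de; s.g_in *= di;
        s.x = p.x_r;
        return;
      }
      // decay conductances to ref_end, then integrate the remainder
      double h1 = s.ref_end - a;
      double de = std::exp(-h1 / p.sigma_ex), di = std::exp(-h1 / p.sigma_in);
      if (!constant_bg) s.g_bg *= de;
      s.g_ex *= de; s.g_in *= di;
      start = s.ref_end;
      x0 = p.x_r;
      h = b - start;
    }
    // midpoint RK2 with conductances evaluated analytically
    double de2 = std::exp(-0.5 * h / p.sigma_ex);
    double di2 = std::exp(-0.5 * h / p.sigma_in);
    double gbg0 = s.g_bg, gex0 = s.g_ex, gin0 = s.g_in;
    double gbg_m = constant_bg ? gbg0 : gbg0 * de2;
    double k1 = dvdt(p, x0, gbg0, gex0, gin0);
    double xm = x0 + 0.5 * h * k1;
    double k2 = dvdt(p, xm, gbg_m, gex0 * de2, gin0 * di2);
    double x1 = x0 + h * k2;
    if (!std::isfinite(x1)) {
      stop("non-finite state variable during integration "
           "(check parameters and step size)");
    }
    // decay conductances across the full sub-interval
    if (!constant_bg) s.g_bg *= de2 * de2;
    s.g_ex *= de2 * de2;
    s.g_in *= di2 * di2;
    if (x1 >= p.x_th) {
      // locate the crossing by linear interpolation inside the segment
      double frac = (x1 > x0) ? (p.x_th - x0) / (x1 - x0) : 1.0;
      if (frac < 0) frac = 0; if (frac > 1) frac = 1;
      t_cross = start + frac * h;
      crossed = true;
      s.x = p.x_r;
      s.ref_end = t_cross + p.tau_ref;
    } else {
      s.x = x1;
    }
    if (check_bounds) {
      double lo = p.x_in - 1e-9, hi = p.x_ex + 1e-9;
      if (s.x < lo || s.x > hi) {
        stop("voltage left the [x_in, x_ex] interval during integration");
      }
    }
  };

  for (long step = 0; step < nsteps; ++step) {
    double t0 = step * p.dt;
    double t1 = std::min(t_end, t0 + p.dt);
    for (int i = 0; i < n; ++i) {
      NodeState& s = st[i];
      // recurrent spikes from the previous step take effect now
      s.g_ex += pend_ex[i]; s.g_in += pend_in[i];
      pend_ex[i] = 0.0; pend_in[i] = 0.0;
      double cur = t0;
      bool crossed = false;
      double t_cross = 0.0, t_spike = -1.0;
      if (!constant_bg) {
        const std::vector<double>& ev = bg[i];
        while (s.bg_ptr < ev.size() && ev[s.bg_ptr] < t1) {
          double te = ev[s.bg_ptr];
          advance_segment(s, cur, te, crossed, t_cross);
          if (crossed && t_spike < 0) t_spike = t_cross;
          s.g_bg += p.f;
          cur = te;
          ++s.bg_ptr;
        }
      }
      advance_segment(s, cur, t1, crossed, t_cross);
      if (crossed && t_spike < 0) t_spike = t_cross;
      if (t_spike >= 0) {
        if (t_spike >= transient) {
          spike_node.push_back(i + 1);
          spike_time.push_back(t_spike - transient);
        }
        // deliver to children at the start of the next step
        for (const auto& kv : kids[i]) {
          if (node_sign[i] > 0) pend_ex[kv.first] += kv.second;
          else                  pend_in[kv.first] += kv.second;
        }
      }
    }
  }
  return List::create(_["node"] = IntegerVector(spike_node.begin(),
                                                spike_node.end()),
                      _["time"] = NumericVector(spike_time.begin(),
                                                spike_time.end()));
}
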