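// Event-grid simulator for a purely excitatory culture: leaky
// integrate-and-fire neurons, current-based exponential synapses and
// Tsodyks-Markram short-term depression.  All linear subsystems are
// propagated with exact exponential updates on a fixed grid; spikes are
// resolved at grid resolution.  The per-step work is split into simple
// branchless passes over neurons so the compiler can vectorize them;
// rare events (drive arrivals, threshold crossings) sit in separate
// lightweight passes.
//
// The three-state synaptic resource (effective E, recovered R, inactive I)
// is tracked once per *presynaptic* neuron: synapse parameters are
// homogeneous, so every outgoing synapse of a neuron shares the same
// presynaptic spike history and hence the same state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
List simulate_lif_tm_cpp(List targets,        // per-neuron 0-based postsynaptic index vectors
                         int n_neurons,
                         double tau_m, double g_leak, double v_th,
                         double t_ref, double delay, double dt,
                         double g_int, double u_frac,
                         double tau_inact, double tau_rec, double tau_syn,
                         double nu, double g_noise,
                         double duration_ms, int seed,
                         List forced,          // per-neuron forced spike times (ms); empty list = none
                         int record_neuron)    // 1-based index, 0 = no state recording
{
  const int N = n_neurons;
  const long n_steps = (long)std::llround(duration_ms / dt);
  const int delay_steps = std::max(1, (int)std::llround(delay / dt));
  const int ref_steps = std::max(1, (int)std::llround(t_ref / dt));

  // exact per-step propagators
  const double a_m = std::exp(-dt / tau_m);
  const double a_s = std::exp(-dt / tau_syn);
  const double a_e = std::exp(-dt / tau_inact);
  const double a_r = std::exp(-dt / tau_rec);
  // membrane response to the synaptic state s over one step:
  // dV/dt = -V/tau_m + s/(g_leak*tau_m), ds/dt = -s/tau_syn
  const double c_vs = (a_s - a_m) / ((1.0 / tau_m - 1.0 / tau_syn) * g_leak * tau_m);
  // inactive-pool feed from the effective pool over one step:
  // dI/dt = E/tau_inact - I/tau_rec
  const double c_ie = (a_e - a_r) / (tau_inact * (1.0 / tau_rec - 1.0 / tau_inact));

  std::vector<double> V(N, 0.0), S(N, 0.0), E(N, 0.0), Ipool(N, 0.0);
  std::vector<int> ref(N, 0);

  // pending synaptic arrivals; ring one slot longer than the delay so a
  // spike emitted while its slot is being consumed lands delay_steps ahead
  const int ring = delay_steps + 1;
  std::vector< std::vector<double> > pending(ring, std::vector<double>(N, 0.0));

  // adjacency as raw vectors for speed
  std::vector< std::vector<int> > out(N);
  for (int j = 0; j < N; ++j) out[j] = as< std::vector<int> >(targets[j]);

  // forced presynaptic spikes (sorted per neuron), converted to step indices
  std::vector< std::vector<long> > forced_steps(N);
  std::vector<size_t> forced_pos(N, 0);
  bool any_forced = false;
  if (forced.size() == N) {
    for (int j = 0; j < N; ++j) {
      NumericVector ft = forced[j];
      for (int q = 0; q < ft.size(); ++q) {
        forced_steps[j].push_back((long)std::llround(ft[q] / dt));
        any_forced = true;
      }
    }
  }

  std::mt19937_64 rng((unsigned long long)seed * 2654435761ULL + 1ULL);
  std::exponential_distribution<double> rexp1(1.0);

  // per-neuron next Poisson drive arrival (in steps)
  const double rate_per_step = nu * dt * 1e-3;  // nu in Hz, dt in ms
  std::vector<long> next_drive(N, std::numeric_limits<long>::max());
  if (nu > 0.0) {
    for (int i = 0; i < N; ++i)
      next_drive[i] = 1 + (long)std::ceil(rexp1(rng) / rate_per_step);
  }

  std::vector<double> spike_times;
  std::vector<int> spike_ids;
  spike_times.reserve(1 << 16);
  spike_ids.reserve(1 << 16);

  const bool rec = record_neuron >= 1 && record_neuron <= N;
  const int ri = record_neuron - 1;
  std::vector<double> rec_E, rec_R, rec_I, rec_V;
  if (rec) {
    rec_E.reserve(n_steps); rec_R.reserve(n_steps);
    rec_I.reserve(n_steps); rec_V.reserve(n_steps);
  }

  double* Vp = V.data();
  double* Sp = S.data();
  double* Ep = E.data();
  double* Ip = Ipool.data();
  int* refp = ref.data();
  long* ndp = next_drive.data();

  for (long n = 0; n < n_steps; ++n) {
    // deliver delayed recurrent input scheduled for this step
    double* slot = pending[n % ring].data();
    for (int i = 0; i < N; ++i) { Sp[i] += slot[i]; slot[i] = 0.0; }

    // Poisson drive (static coupling, no depression)
    if (nu > 0.0) {
      for (int i = 0; i < N; ++i) {
        if (ndp[i] == n) {
          Sp[i] += g_noise;
          ndp[i] = n + 1 + (long)std::ceil(rexp1(rng) / rate_per_step);
        }
      }
    }

    // exact exponential propagation; V clamped to 0 while refractory.
    // Decaying states are flushed to zero below 1e-20 -- physically
    // irrelevant, and it keeps the exponentials out of the denormal
    // range where SSE arithmetic is an order of magnitude slower.
    for (int i = 0; i < N; ++i) {
      const double m = (refp[i] == 0) ? 1.0 : 0.0;
      const double v = (Vp[i] * a_m + Sp[i] * c_vs) * m;
      Vp[i] = (v > 1e-20) ? v : 0.0;
      const double s = Sp[i] * a_s;
      Sp[i] = (s > 1e-20) ? s : 0.0;
      const double Enew = Ep[i] * a_e;
      const double ip = Ip[i] * a_r + Ep[i] * c_ie;
      Ip[i] = (ip > 1e-20) ? ip : 0.0;
      Ep[i] = (Enew > 1e-20) ? Enew : 0.0;
    }
    for (int i = 0; i < N; ++i) refp[i] -= (refp[i] > 0);

    // threshold crossings (and forced presynaptic spikes)
    for (int i = 0; i < N; ++i) {
      bool fire = (refp[i] == 0 && Vp[i] >= v_th);
      if (any_forced && forced_pos[i] < forced_steps[i].size() &&
          forced_steps[i][forced_pos[i]] == n) {
        fire = true;
        ++forced_pos[i];
      }
      if (!fire) continue;
      spike_times.push_back(n * dt * 1e-3);  // seconds, within [0, duration)
      spike_ids.push_back(i + 1);
      Vp[i] = 0.0;
      refp[i] = ref_steps;
      const double dE = u_frac * (1.0 - Ep[i] - Ip[i]);  // U * R
      Ep[i] += dE;
      const double amount = g_int * dE;
      double* dest = pending[(n + delay_steps) % ring].data();
      const std::vector<int>& tg = out[i];
      for (size_t q = 0; q < tg.size(); ++q) dest[tg[q]] += amount;
    }

    if ((n & 1023) == 0) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(Vp[i]) || std::fabs(Vp[i]) > 1e9)
          stop("membrane potential diverged (neuron %d, t = %.3f ms); "
               "check neuron/synapse parameter set", i + 1, n * dt);
    }

    if (rec) {
      rec_E.push_back(Ep[ri]);
      rec_I.push_back(Ip[ri]);
      rec_R.push_back(1.0 - Ep[ri] - Ip[ri]);
      rec_V.push_back(Vp[ri]);
    }
  }

  List res = List::create(_["times"] = wrap(spike_times),
                          _["ids"] = wrap(spike_ids));
  if (rec)
    res["state"] = List::create(_["E"] = wrap(rec_E), _["R"] = wrap(rec_R),
                                _["I"] = wrap(rec_I), _["V"] = wrap(rec_V));
  return res;
}
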