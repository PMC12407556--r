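// Fast integrators for ring / torus rate networks and LIF spiking networks.
// All rate kernels work with a constant external drive vector h = W_ff %*% r;
// time is in units of the membrane time constant tau for rate models and in
// milliseconds for the spiking model.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double l1_dev(const std::vector<double> &x, const NumericVector &t) {
  double s = 0.0;
  for (int i = 0; i < (int)x.size(); ++i) s += std::fabs(x[i] - t[i]);
  return s;
}

// Nearest-neighbour sum on a ring.
static inline void ring_neigh(const std::vector<double> &x, std::vector<double> &out) {
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    const int ip = (i + 1 == n) ? 0 : i + 1;
    const int im = (i == 0) ? n - 1 : i - 1;
    out[i] = x[ip] + x[im];
  }
}

// [[Rcpp::export]]
List ring_rate_sim_cpp(NumericVector x0, NumericVector h, double w_rec,
                       double tau, double dt, int n_steps, bool midpoint,
                       NumericVector x_target, int record_stride) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), nb(n), xm(n), k1(n);
  NumericVector loss(n_steps + 1);
  const double l0 = l1_dev(x, x_target);
  loss[0] = l0;
  const double guard = (l0 > 0 ? 1e3 * l0 : 1e12);
  bool diverged = false;
  int n_rec = record_stride > 0 ? n_steps / record_stride + 1 : 0;
  NumericMatrix states(record_stride > 0 ? n : 0, n_rec);
  if (record_stride > 0) for (int i = 0; i < n; ++i) states(i, 0) = x[i];
  int done = 0;
  for (int s = 1; s <= n_steps; ++s) {
    ring_neigh(x, nb);
    for (int i = 0; i < n; ++i) k1[i] = (-x[i] + w_rec * nb[i] + h[i]) / tau;
    if (midpoint) {
      for (int i = 0; i < n; ++i) xm[i] = x[i] + 0.5 * dt * k1[i];
      ring_neigh(xm, nb);
      for (int i = 0; i < n; ++i) x[i] += dt * (-xm[i] + w_rec * nb[i] + h[i]) / tau;
    } else {
      for (int i = 0; i < n; ++i) x[i] += dt * k1[i];
    }
    const double l = l1_dev(x, x_target);
    loss[s] = l;
    done = s;
    if (record_stride > 0 && s % record_stride == 0)
      for (int i = 0; i < n; ++i) states(i, s / record_stride) = x[i];
    if (!std::isfinite(l) || l > guard) { diverged = true; break; }
  }
  if (diverged) for (int s = done + 1; s <= n_steps; ++s) loss[s] = R_PosInf;
  return List::create(_["loss"] = loss, _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["diverged"] = diverged, _["n_done"] = done,
                      _["states"] = states);
}

// Euler integration of the ring with spike-frequency adaptation.  The weights
// and drive are expected to be pre-scaled by (1 + a_sfa); the adaptation
// current -a_sfa * u is added on top.
// [[Rcpp::export]]
List ring_sfa_sim_cpp(NumericVector x0, NumericVector u0, NumericVector h,
                      double w_rec_eff, double a_sfa, double tau, double tau_sfa,
                      double dt, int n_steps, NumericVector x_target,
                      int record_stride) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), u(u0.begin(), u0.end()), nb(n);
  NumericVector loss(n_steps + 1);
  const double l0 = l1_dev(x, x_target);
  loss[0] = l0;
  double tnorm = 0.0;
  for (int i = 0; i < n; ++i) tnorm += std::fabs(x_target[i]);
  const double guard = (l0 > 0 ? 1e3 * l0 : 1e12);
  bool diverged = false;
  int n_rec = record_stride > 0 ? n_steps / record_stride + 1 : 0;
  NumericMatrix states(record_stride > 0 ? 2 * n : 0, n_rec);
  if (record_stride > 0) for (int i = 0; i < n; ++i) {
    states(i, 0) = x[i]; states(n + i, 0) = u[i];
  }
  double acc = l0;
  int done = 0;
  for (int s = 1; s <= n_steps; ++s) {
    ring_neigh(x, nb);
    for (int i = 0; i < n; ++i) {
      const double dx = (-x[i] + w_rec_eff * nb[i] + h[i] - a_sfa * u[i]) / tau;
      const double du = (-u[i] + x[i]) / tau_sfa;
      x[i] += dt * dx;
      u[i] += dt * du;
    }
    const double l = l1_dev(x, x_target);
    loss[s] = l;
    acc += l;
    done = s;
    if (record_stride > 0 && s % record_stride == 0)
      for (int i = 0; i < n; ++i) {
        states(i, s / record_stride) = x[i];
        states(n + i, s / record_stride) = u[i];
      }
    if (!std::isfinite(l) || l > guard) { diverged = true; break; }
  }
  if (diverged) for (int s = done + 1; s <= n_steps; ++s) loss[s] = R_PosInf;
  const double mean_norm_loss =
      diverged ? R_PosInf : acc / ((n_steps + 1) * (tnorm > 0 ? tnorm : 1.0));
  return List::create(_["loss"] = loss,
                      _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["u_final"] = NumericVector(u.begin(), u.end()),
                      _["mean_norm_loss"] = mean_norm_loss,
                      _["diverged"] = diverged, _["n_done"] = done,
                      _["states"] = states);
}

// Midpoint integration of the ring with delayed balancing inhibition.  The
// delayed activity enters through Delta x_i(t) = x_i(t) - x_i(t - tau_lag);
// midpoint values of the delayed activity are copies of the midpoint values
// of the non-delayed activity lag_steps earlier.  History is x(t) = x0 for
// t <= 0.
// [[Rcpp::export]]
List ring_delay_sim_cpp(NumericVector x0, NumericVector h, double w_net,
                        double w_bal, double tau, double dt, int lag_steps,
                        int n_steps, NumericVector x_target, int record_stride) {
  const int n = x0.size();
  const int L = lag_steps;
  std::vector<double> x(x0.begin(), x0.end()), nb(n), nbd(n), xm(n), k1(n);
  // ring buffers of past full-step and past midpoint states
  std::vector<std::vector<double>> buf_full(L, std::vector<double>(x0.begin(), x0.end()));
  std::vector<std::vector<double>> buf_mid(L, std::vector<double>(x0.begin(), x0.end()));
  NumericVector loss(n_steps + 1);
  const double l0 = l1_dev(x, x_target);
  loss[0] = l0;
  const double guard = (l0 > 0 ? 1e3 * l0 : 1e12);
  bool diverged = false;
  int n_rec = record_stride > 0 ? n_steps / record_stride + 1 : 0;
  NumericMatrix states(record_stride > 0 ? n : 0, n_rec);
  if (record_stride > 0) for (int i = 0; i < n; ++i) states(i, 0) = x[i];
  int done = 0;
  for (int s = 1; s <= n_steps; ++s) {
    const int slot = (s - 1) % L;           // holds state / midpoint from s-1-L... wrap
    const std::vector<double> &xd = buf_full[slot];
    const std::vector<double> &xdm = buf_mid[slot];
    ring_neigh(x, nb);
    ring_neigh(xd, nbd);
    for (int i = 0; i < n; ++i)
      k1[i] = (-x[i] + w_net * nb[i] + w_bal * (nb[i] - nbd[i]) + h[i]) / tau;
    for (int i = 0; i < n; ++i) xm[i] = x[i] + 0.5 * dt * k1[i];
    // stash current full state before overwriting buffers
    buf_full[slot] = x;
    ring_neigh(xm, nb);
    ring_neigh(xdm, nbd);
    for (int i = 0; i < n; ++i)
      x[i] += dt * (-xm[i] + w_net * nb[i] + w_bal * (nb[i] - nbd[i]) + h[i]) / tau;
    buf_mid[slot] = xm;
    const double l = l1_dev(x, x_target);
    loss[s] = l;
    done = s;
    if (record_stride > 0 && s % record_stride == 0)
      for (int i = 0; i < n; ++i) states(i, s / record_stride) = x[i];
    if (!std::isfinite(l) || l > guard) { diverged = true; break; }
  }
  if (diverged) for (int s = done + 1; s <= n_steps; ++s) loss[s] = R_PosInf;
  return List::create(_["loss"] = loss, _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["diverged"] = diverged, _["n_done"] = done,
                      _["states"] = states);
}

// Four-neighbour sum on an nx-by-ny torus (column-major indexing i + nx*j).
static inline void torus_neigh(const std::vector<double> &x, std::vector<double> &out,
                               int nx, int ny) {
  for (int j = 0; j < ny; ++j) {
    const int jp = (j + 1 == ny) ? 0 : j + 1, jm = (j == 0) ? ny - 1 : j - 1;
    for (int i = 0; i < nx; ++i) {
      const int ip = (i + 1 == nx) ? 0 : i + 1, im = (i == 0) ? nx - 1 : i - 1;
      out[i + nx * j] = x[ip + nx * j] + x[im + nx * j] +
                        x[i + nx * jp] + x[i + nx * jm];
    }
  }
}

// Midpoint integration on the torus; covers the 2D-stimulus network and the
// mixed-selectivity grid (both have four nearest-neighbour recurrent synapses),
// with optional delayed balancing inhibition (w_bal > 0, lag_steps > 0).
// [[Rcpp::export]]
List torus_sim_cpp(NumericVector x0, NumericVector h, int nx, int ny,
                   double w_rec, double w_bal, double tau, double dt,
                   int lag_steps, int n_steps, NumericVector x_target,
                   int record_stride) {
  const int n = nx * ny;
  const bool delayed = (w_bal != 0.0 && lag_steps > 0);
  const int L = delayed ? lag_steps : 1;
  std::vector<double> x(x0.begin(), x0.end()), nb(n), nbd(n), xm(n), k1(n);
  std::vector<std::vector<double>> buf_full, buf_mid;
  if (delayed) {
    buf_full.assign(L, std::vector<double>(x0.begin(), x0.end()));
    buf_mid.assign(L, std::vector<double>(x0.begin(), x0.end()));
  }
  NumericVector loss(n_steps + 1);
  const double l0 = l1_dev(x, x_target);
  loss[0] = l0;
  const double guard = (l0 > 0 ? 1e3 * l0 : 1e12);
  bool diverged = false;
  int n_rec = record_stride > 0 ? n_steps / record_stride + 1 : 0;
  NumericMatrix states(record_stride > 0 ? n : 0, n_rec);
  if (record_stride > 0) for (int i = 0; i < n; ++i) states(i, 0) = x[i];
  int done = 0;
  for (int s = 1; s <= n_steps; ++s) {
    const int slot = (s - 1) % L;
    torus_neigh(x, nb, nx, ny);
    if (delayed) {
      torus_neigh(buf_full[slot], nbd, nx, ny);
      for (int i = 0; i < n; ++i)
        k1[i] = (-x[i] + w_rec * nb[i] + w_bal * (nb[i] - nbd[i]) + h[i]) / tau;
    } else {
      for (int i = 0; i < n; ++i) k1[i] = (-x[i] + w_rec * nb[i] + h[i]) / tau;
    }
    for (int i = 0; i < n; ++i) xm[i] = x[i] + 0.5 * dt * k1[i];
    if (delayed) buf_full[slot] = x;
    torus_neigh(xm, nb, nx, ny);
    if (delayed) {
      torus_neigh(buf_mid[slot], nbd, nx, ny);
      for (int i = 0; i < n; ++i)
        x[i] += dt * (-xm[i] + w_rec * nb[i] + w_bal * (nb[i] - nbd[i]) + h[i]) / tau;
      buf_mid[slot] = xm;
    } else {
      for (int i = 0; i < n; ++i) x[i] += dt * (-xm[i] + w_rec * nb[i] + h[i]) / tau;
    }
    const double l = l1_dev(x, x_target);
    loss[s] = l;
    done = s;
    if (record_stride > 0 && s % record_stride == 0)
      for (int i = 0; i < n; ++i) states(i, s / record_stride) = x[i];
    if (!std::isfinite(l) || l > guard) { diverged = true; break; }
  }
  if (diverged) for (int s = done + 1; s <= n_steps; ++s) loss[s] = R_PosInf;
  return List::create(_["loss"] = loss, _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["diverged"] = diverged, _["n_done"] = done,
                      _["states"] = states);
}

// ---------------------------------------------------------------------------
// LIF spiking network: Euler-Maruyama with grid-constrained spike times and
// per-synapse integer-step delays.  Noise uses a dedicated xoshiro256++
// stream so that billions of normals per run stay cheap; the stream is seeded
// explicitly from R.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_cached = false;
  double cached = 0.0;
  inline double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    have_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

} // namespace

// [[Rcpp::export]]
List lif_sim_cpp(NumericVector v0, NumericVector i_pre, NumericVector i_post,
                 int stim_step, double tau_m, double sigma, double v_thr,
                 double v_reset, double dt,
                 IntegerVector syn_ptr, IntegerVector syn_post,
                 IntegerVector syn_delay, NumericVector syn_w,
                 IntegerVector pop_id, int n_pops, IntegerVector pop_size,
                 NumericVector x_target, LogicalVector loss_pop,
                 int n_steps, int stat_start_step, int bin_steps,
                 LogicalVector record_neuron, double seed1, double seed2) {
  const int n = v0.size();
  std::vector<double> v(v0.begin(), v0.end());
  Xoshiro rng((uint64_t)seed1 * 2654435761ULL + (uint64_t)seed2);
  int max_delay = 1;
  for (int k = 0; k < syn_delay.size(); ++k)
    if (syn_delay[k] + 1 > max_delay) max_delay = syn_delay[k] + 1;
  const int L = max_delay + 1;
  std::vector<double> pending((size_t)L * n, 0.0);
  const double a = dt / tau_m;
  const double noise_sd = sigma * std::sqrt(2.0 * dt / tau_m);
  const double dt_s = dt * 1e-3; // ms -> s, for rates in Hz
  const int n_loss = n_steps - stim_step;
  NumericVector loss(n_loss > 0 ? n_loss : 0);
  const int n_bins = n_steps / bin_steps;
  NumericMatrix binned(n_pops, n_bins);
  std::vector<long long> stat_counts(n_pops, 0), pop_step(n_pops, 0);
  std::vector<double> rec_t; std::vector<int> rec_id;
  long long total_spikes = 0;
  for (int s = 0; s < n_steps; ++s) {
    const int slot = s % L;
    double *pend = &pending[(size_t)slot * n];
    const NumericVector &Iext = (s >= stim_step) ? i_post : i_pre;
    std::fill(pop_step.begin(), pop_step.end(), 0LL);
    for (int i = 0; i < n; ++i) {
      double vi = v[i] + pend[i];
      pend[i] = 0.0;
      vi += a * (-vi + Iext[i]) + noise_sd * rng.norm();
      if (vi >= v_thr) {
        vi = v_reset;
        const int p = pop_id[i];
        ++pop_step[p];
        ++total_spikes;
        if (record_neuron[i]) { rec_id.push_back(i + 1); rec_t.push_back((s + 1) * dt); }
        for (int k = syn_ptr[i]; k < syn_ptr[i + 1]; ++k) {
          const int when = (s + syn_delay[k]) % L;
          pending[(size_t)when * n + syn_post[k]] += syn_w[k];
        }
      }
      v[i] = vi;
    }
    for (int p = 0; p < n_pops; ++p) {
      if (s / bin_steps < n_bins)
        binned(p, s / bin_steps) += (double)pop_step[p];
      if (s >= stat_start_step) stat_counts[p] += pop_step[p];
    }
    if (s >= stim_step) {
      double l = 0.0;
      for (int p = 0; p < n_pops; ++p)
        if (loss_pop[p])
          l += std::fabs(pop_step[p] / (pop_size[p] * dt_s) - x_target[p]);
      loss[s - stim_step] = l;
    }
  }
  // binned spike counts -> Hz
  for (int p = 0; p < n_pops; ++p)
    for (int b = 0; b < n_bins; ++b)
      binned(p, b) /= pop_size[p] * (bin_steps * dt_s);
  NumericVector stat_rates(n_pops);
  const double stat_dur = (n_steps - stat_start_step) * dt_s;
  for (int p = 0; p < n_pops; ++p)
    stat_rates[p] = stat_counts[p] / (pop_size[p] * stat_dur);
  return List::create(_["loss"] = loss, _["binned_rates"] = binned,
                      _["stat_rates"] = stat_rates,
                      _["total_spikes"] = (double)total_spikes,
                      _["spike_id"] = IntegerVector(rec_id.begin(), rec_id.end()),
                      _["spike_t"] = NumericVector(rec_t.begin(), rec_t.end()));
}
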