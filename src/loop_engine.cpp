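// Compiled cores for the discrete-time loop emulator. The per-tick math
// (plant step, chain filters, FIR convolution, gating) mirrors the R
// reference implementations exactly; cross-checked in the test suite.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Direct-form II transposed recursive filter with streaming state.
struct Df2t {
  std::vector<double> b, a, z;
  // warm-start at the DC steady state for a constant input u0
  void init(const NumericVector &bb, const NumericVector &aa, double u0) {
    size_t n = std::max(bb.size(), aa.size());
    b.assign(n, 0.0);
    a.assign(n, 0.0);
    for (int i = 0; i < bb.size(); ++i) b[i] = bb[i];
    for (int i = 0; i < aa.size(); ++i) a[i] = aa[i];
    z.assign(n - 1, 0.0);
    if (u0 != 0.0) {
      double sb = 0.0, sa = 0.0;
      for (size_t i = 0; i < n; ++i) { sb += b[i]; sa += a[i]; }
      double y0 = u0 * sb / sa;
      double acc = 0.0;
      for (size_t i = n - 1; i >= 1; --i) {
        acc += b[i] * u0 - a[i] * y0;
        z[i - 1] = acc;
      }
    }
  }
  double step(double x) {
    size_t n = b.size();
    double y = b[0] * x + z[0];
    for (size_t i = 0; i + 1 < n - 1; ++i) {
      z[i] = b[i + 1] * x + z[i + 1] - a[i + 1] * y;
    }
    z[n - 2] = b[n - 1] * x - a[n - 1] * y;
    return y;
  }
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// Open-loop plant integration (semi-implicit Euler-Maruyama).
// [[Rcpp::export]]
List plant_run_core(int n_ticks, double x0, double v0, double omega0,
                    double zeta, double sigma, double coupling,
                    double meas_sd, double dt, NumericVector light,
                    NumericVector xi, NumericVector eta) {
  NumericVector xs(n_ticks), vs(n_ticks), lfp(n_ticks);
  double x = x0, v = v0;
  const double sdt = std::sqrt(dt);
  for (int t = 0; t < n_ticks; ++t) {
    double acc = -omega0 * omega0 * x - 2.0 * zeta * omega0 * v + coupling * light[t];
    v = v + dt * acc + sigma * sdt * xi[t];
    x = x + dt * v;
    xs[t] = x;
    vs[t] = v;
    lfp[t] = x + meas_sd * eta[t];
  }
  return List::create(_["x"] = xs, _["v"] = vs, _["lfp"] = lfp);
}

// Full closed-loop session at the loop tick.
//
// Per tick t: (1) advance the plant with the stimulation computed
// loop_delay ticks earlier; (2) clock the analog chain with the new LFP
// sample and read it for the channel scheduled this tick; (3) on the
// control channel, update the FIR and compute the stimulation command,
// gated to zero during control epochs; (4) log the packet fields.
// Stage coding in stage_type: 0 = recursive filter (index in chain_b/a),
// 1 = gain, 2 = level shifter, 3 = ADC.
// [[Rcpp::export]]
List run_session_core(int n_ticks, int n_channels, int loop_delay, double dt,
                      double omega0, double zeta, double sigma,
                      double coupling, double meas_sd,
                      NumericVector xi, NumericVector eta,
                      IntegerVector stage_type, IntegerVector stage_idx,
                      List chain_b, List chain_a, NumericVector stage_dc,
                      double chain_gain,
                      double ls_in_min, double ls_in_max,
                      double ls_out_min, double ls_out_max,
                      int adc_bits, double adc_vmin, double adc_vmax,
                      double dc_offset,
                      NumericMatrix taps, NumericVector cond_gain,
                      double output_max,
                      IntegerVector cond_at_tick) {
  const int n_stages = stage_type.size();
  std::vector<Df2t> filters;
  for (int i = 0; i < n_stages; ++i) {
    if (stage_type[i] == 0) {
      Df2t f;
      f.init(chain_b[stage_idx[i]], chain_a[stage_idx[i]],
             stage_dc[stage_idx[i]]);
      filters.push_back(f);
    }
  }

  const int n_taps = taps.nrow();
  std::vector<double> ring(n_taps, 0.0);
  int ring_pos = 0; // index of the newest sample

  const double ls_slope = (ls_out_max - ls_out_min) / (ls_in_max - ls_in_min);
  const double n_codes = std::pow(2.0, adc_bits);
  const double adc_step = (adc_vmax - adc_vmin) / n_codes;
  const double sdt = std::sqrt(dt);

  std::vector<double> stim_hist(n_ticks, 0.0);
  NumericVector raw(n_ticks), algo_log(n_ticks), stim_log(n_ticks),
      plant_x(n_ticks);
  IntegerVector chan(n_ticks);

  double x = 0.0, v = 0.0;
  double cur_stim = 0.0, cur_algo = 0.0;
  int prev_cond = -1;

  for (int t = 0; t < n_ticks; ++t) {
    // 1. actuate plant with the delayed stimulation value
    double light = (t - loop_delay >= 0) ? stim_hist[t - loop_delay] : 0.0;
    double acc = -omega0 * omega0 * x - 2.0 * zeta * omega0 * v + coupling * light;
    v = v + dt * acc + sigma * sdt * xi[t];
    x = x + dt * v;
    double lfp = x + meas_sd * eta[t];

    // 2. clock the analog chain; the scheduled channel reads its output
    double s = lfp;
    int fi = 0;
    for (int i = 0; i < n_stages; ++i) {
      switch (stage_type[i]) {
      case 0:
        s = filters[fi++].step(s);
        break;
      case 1:
        s *= chain_gain;
        break;
      case 2:
        s = ls_out_min + (s - ls_in_min) * ls_slope;
        s = clampd(s, ls_out_min, ls_out_max);
        break;
      case 3: {
        double code = std::floor((s - adc_vmin) / adc_step);
        code = clampd(code, 0.0, n_codes - 1.0);
        s = adc_vmin + (code + 0.5) * adc_step;
        break;
      }
      }
    }

    int channel = t % n_channels;
    int cond = cond_at_tick[t]; // 0 = control / off

    // 3. controller on the control channel (channel 0)
    if (channel == 0) {
      if (cond != prev_cond) {
        std::fill(ring.begin(), ring.end(), 0.0);
        ring_pos = 0;
        prev_cond = cond;
      }
      if (cond > 0) {
        ring_pos = (ring_pos + n_taps - 1) % n_taps;
        ring[ring_pos] = s - dc_offset;
        double acc_out = 0.0;
        for (int i = 0; i < n_taps; ++i) {
          acc_out += taps(i, cond - 1) * ring[(ring_pos + i) % n_taps];
        }
        cur_algo = acc_out;
        cur_stim = clampd(cond_gain[cond - 1] * acc_out, 0.0, output_max);
      } else {
        cur_algo = 0.0;
        cur_stim = 0.0;
      }
    }

    // 4. the stimulation command of this tick (zero-order hold between
    // controller updates) is applied to the plant loop_delay ticks later
    stim_hist[t] = cur_stim;

    raw[t] = s;
    algo_log[t] = cur_algo;
    stim_log[t] = cur_stim;
    plant_x[t] = x;
    chan[t] = channel;
  }

  return List::create(_["raw"] = raw, _["algo_out"] = algo_log,
                      _["stim"] = stim_log, _["plant_x"] = plant_x,
                      _["channel"] = chan);
}
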