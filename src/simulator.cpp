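#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Self-contained noise stream: PCG32 uniforms feeding a Box-Muller pair.
// The stream is a pure function of the 32-bit seed handed down from R, so
// recordings are reproducible from (params, seed) without touching R's RNG.
namespace {

struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t initstate, uint64_t initseq) {
    state = 0u; inc = (initseq << 1u) | 1u;
    next(); state += initstate; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double runif() { // uniform on (0, 1]
    return (next() + 1.0) * (1.0 / 4294967296.0);
  }
};

struct GaussStream {
  Pcg32 rng;
  double spare;
  bool has_spare;
  explicit GaussStream(uint64_t seed) : rng(seed, 54u), has_spare(false) {}
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = rng.runif(), u2 = rng.runif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
};

} // namespace

// Time-stepped integration of the sensory network plus read-out neuron.
//
// Update order within one Euler step of length dt (all right-hand sides are
// evaluated at start-of-step state; spikes take effect at the end of the
// step, so a spike emitted in step k first drives other neurons in step
// k+1 through I_rec):
//   1. external currents (mean + white noise) and I_syn = I_ext + I_rec
//   2. parallel Euler update of V (all neurons) and I_adp (E neurons)
//   3. exact exponential relaxation of u, x (E) and decay of I_rec, I_E, I_I
//   4. threshold test; spiking neurons reset to E_L; spike-triggered jumps
//      (I_adp += A_s; facilitate-transmit-depress on u, x; recurrent jumps
//      J * transmitted into targets; unit jumps into the read-out filters)
//   5. read-out membrane update from start-of-step filter values
// Traces (s_i = I_syn - I_adp for E neurons, population mean u*x, V_O and
// the read-out drive) are averaged over each trace_dt frame.
//
// noise_in, when supplied (testing), is a (n_steps x (n_e + n_i)) matrix of
// standard normal draws; otherwise the internal Gaussian stream seeded by
// noise_seed is consumed in neuron order within each step.

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(List par,
                     IntegerVector ee_ptr, IntegerVector ee_idx,
                     IntegerVector ei_ptr, IntegerVector ei_idx,
                     IntegerVector ie_ptr, IntegerVector ie_idx,
                     double t_start, double t_end,
                     double stim_on, double stim_off,
                     Nullable<NumericMatrix> noise_in,
                     int noise_seed,
                     bool static_synapses,
                     bool record_s) {
  const int n_e = as<int>(par["n_e"]);
  const int n_i = as<int>(par["n_i"]);
  const int n = n_e + n_i;
  const double dt = as<double>(par["dt"]);
  const double trace_dt = as<double>(par["trace_dt"]);
  const double tau_m = as<double>(par["tau_m"]);
  const double tau_a = as<double>(par["tau_a"]);
  const double tau_s = as<double>(par["tau_s"]);
  const double tau_f = as<double>(par["tau_f"]);
  const double tau_d = as<double>(par["tau_d"]);
  const double tau_o = as<double>(par["tau_o"]);
  const double e_l = as<double>(par["e_l"]);
  const double v_th_e = as<double>(par["v_th_e"]);
  const double v_th_i = as<double>(par["v_th_i"]);
  const double r_m = as<double>(par["r_m"]);
  const double a_s = as<double>(par["a_s"]);
  const double a_p = as<double>(par["a_p"]);
  const double j_ee = as<double>(par["j_ee"]);
  const double j_ei = as<double>(par["j_ei"]);
  const double j_ie = as<double>(par["j_ie"]);
  const double j_s = as<double>(par["j_s"]);
  const double j_eo = as<double>(par["j_eo"]);
  const double j_io = as<double>(par["j_io"]);
  const double U = as<double>(par["U"]);
  const double mu_ext = as<double>(par["mu_ext"]);
  const double mu_b = as<double>(par["mu_b"]);
  const double sigma_ext = as<double>(par["sigma_ext"]);
  const std::string conv = as<std::string>(par["delta_convention"]);
  const std::string nunit = as<std::string>(par["noise_delta_unit"]);
  const std::string smode = as<std::string>(par["stimulus_mode"]);
  const std::string rdrive = as<std::string>(par["readout_drive"]);

  const bool strict = (conv == "jump-equals-coefficient-over-tau");
  const double adp_jump = strict ? a_s / tau_a : a_s;
  const double rec_scale = strict ? 1.0 / tau_s : 1.0;
  const double u_jump = strict ? U / tau_f : U;
  const double x_rel = strict ? 1.0 / tau_d : 1.0; // fraction scale of u'x release
  const double nscale = (nunit == "s") ? std::sqrt(1000.0 / dt)
                                       : std::sqrt(1.0 / dt);
  const bool filtered_readout = (rdrive == "filtered");
  const bool additive_stim = (smode == "add");

  const long n_steps = (long)std::lround((t_end - t_start) / dt);
  const int frame_len = (int)std::lround(trace_dt / dt);
  const long n_frames = n_steps / frame_len;

  const double es = std::exp(-dt / tau_s);
  const double ef = std::exp(-dt / tau_f);
  const double ed = std::exp(-dt / tau_d);

  bool have_noise = noise_in.isNotNull();
  NumericMatrix noise;
  if (have_noise) {
    noise = NumericMatrix(noise_in);
    if (noise.nrow() != n_steps || noise.ncol() != n)
      stop("noise matrix must be n_steps x (n_e + n_i)");
  }
  GaussStream gauss((uint64_t)(uint32_t)noise_seed);

  // state
  std::vector<double> V(n, e_l), Irec(n, 0.0);
  std::vector<double> Iadp(n_e, 0.0), u(n_e, 0.0), x(n_e, 1.0);
  std::vector<double> buf(n, 0.0), s_now(n_e, 0.0);
  double IEf = 0.0, IIf = 0.0, Vo = e_l;

  // recordings
  std::vector<double> spike_t; std::vector<int> spike_id, spike_cl;
  NumericMatrix s_trace(record_s ? n_frames : 0, record_s ? n_e : 0);
  NumericVector ux_trace(n_frames), vo_trace(n_frames), drive_trace(n_frames);
  NumericVector frame_time(n_frames);
  std::vector<double> s_acc(n_e, 0.0);
  double ux_acc = 0.0, vo_acc = 0.0, drive_acc = 0.0;

  for (long step = 0; step < n_steps; ++step) {
    const double t0 = t_start + step * dt;
    const double t_spk = t0 + dt;
    const bool in_stim = (t0 >= stim_on && t0 < stim_off);
    const double mu_e = in_stim ? (additive_stim ? mu_b + mu_ext : mu_ext)
                                : mu_b;

    // 1-2: currents + parallel membrane / adaptation update
    for (int i = 0; i < n; ++i) {
      const bool isE = i < n_e;
      const double z = have_noise ? noise(step, i) : gauss.next();
      const double i_ext = (isE ? mu_e : mu_b) + sigma_ext * nscale * z;
      const double i_syn = i_ext + Irec[i];
      const double v_old = V[i];
      if (isE) {
        const double s_i = i_syn - Iadp[i];
        s_now[i] = s_i;
        V[i] = v_old + dt / tau_m * (-(v_old - e_l) + r_m * s_i);
        Iadp[i] += dt / tau_a * (-Iadp[i] + a_p * (v_old - e_l));
      } else {
        V[i] = v_old + dt / tau_m * (-(v_old - e_l) + r_m * i_syn);
      }
      if (!R_finite(V[i]))
        stop("membrane potential diverged at t = %f ms (neuron %d)",
             t_spk, i + 1);
    }

    // 3: exponential relaxations
    for (int i = 0; i < n_e; ++i) {
      u[i] *= ef;
      x[i] = 1.0 - (1.0 - x[i]) * ed;
    }

    // 4: threshold, reset, spike effects
    std::fill(buf.begin(), buf.end(), 0.0);
    int ne_sp = 0, ni_sp = 0;
    for (int i = 0; i < n_e; ++i) {
      if (V[i] >= v_th_e) {
        V[i] = e_l;
        Iadp[i] += adp_jump;
        double q_drive;
        if (static_synapses) {
          q_drive = j_s;
        } else {
          const double u_new = u[i] + u_jump * (1.0 - u[i]);
          const double q = u_new * x[i];      // facilitate, then transmit
          x[i] -= x_rel * q;                  // then deplete
          u[i] = u_new;
          q_drive = j_ee * q;
        }
        for (int k = ee_ptr[i]; k < ee_ptr[i + 1]; ++k)
          buf[ee_idx[k] - 1] += q_drive;
        for (int k = ei_ptr[i]; k < ei_ptr[i + 1]; ++k)
          buf[n_e + ei_idx[k] - 1] += j_ei;
        spike_t.push_back(t_spk); spike_id.push_back(i + 1);
        spike_cl.push_back(0); ++ne_sp;
      }
    }
    for (int i = 0; i < n_i; ++i) {
      if (V[n_e + i] >= v_th_i) {
        V[n_e + i] = e_l;
        for (int k = ie_ptr[i]; k < ie_ptr[i + 1]; ++k)
          buf[ie_idx[k] - 1] -= j_ie;
        spike_t.push_back(t_spk); spike_id.push_back(i + 1);
        spike_cl.push_back(1); ++ni_sp;
      }
    }
    for (int i = 0; i < n; ++i)
      Irec[i] = Irec[i] * es + rec_scale * buf[i];

    // 5: read-out neuron
    const double drive = r_m * (j_eo * IEf - j_io * IIf);
    Vo += dt / tau_o * (-(Vo - e_l) + drive);
    if (filtered_readout) {
      IEf = IEf * es + ne_sp;
      IIf = IIf * es + ni_sp;
    } else {
      Vo += r_m * (j_eo * ne_sp - j_io * ni_sp);
    }
    if (Vo >= v_th_e) {
      Vo = e_l;
      spike_t.push_back(t_spk); spike_id.push_back(1); spike_cl.push_back(2);
    }

    // traces: frame averages
    double ux_sum = 0.0;
    for (int i = 0; i < n_e; ++i) ux_sum += u[i] * x[i];
    ux_acc += ux_sum / (n_e > 0 ? n_e : 1);
    vo_acc += Vo;
    drive_acc += drive;
    if (record_s)
      for (int i = 0; i < n_e; ++i) s_acc[i] += s_now[i];
    if ((step + 1) % frame_len == 0) {
      const long fr = (step + 1) / frame_len - 1;
      frame_time[fr] = t0 + dt - trace_dt / 2.0; // frame midpoint
      ux_trace[fr] = ux_acc / frame_len;
      vo_trace[fr] = vo_acc / frame_len;
      drive_trace[fr] = drive_acc / frame_len;
      ux_acc = vo_acc = drive_acc = 0.0;
      if (record_s) {
        for (int i = 0; i < n_e; ++i) {
          s_trace(fr, i) = s_acc[i] / frame_len;
          s_acc[i] = 0.0;
        }
      }
    }
  }

  return List::create(
    _["spike_t"] = wrap(spike_t),
    _["spike_id"] = wrap(spike_id),
    _["spike_class"] = wrap(spike_cl),
    _["s"] = s_trace,
    _["ux"] = ux_trace,
    _["vo"] = vo_trace,
    _["drive"] = drive_trace,
    _["time"] = frame_time);
}
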