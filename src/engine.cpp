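// Clock-driven network engine.
//
// Neurons are single-compartment models integrated with exponential-Euler /
// forward-Euler hybrid steps at fixed dt: adaptive-exponential
// integrate-and-fire (cortical cells) and integrate-and-fire augmented with a
// low-threshold T-type calcium current (thalamic cells). Synapses are
// dual-exponential conductances grouped into shared kinetic kernels per
// (receptor, tau_rise, tau_decay) class, with deterministic Tsodyks-Markram
// short-term plasticity evaluated per synapse on presynaptic spikes. Spikes
// are delivered through a ring buffer binned by dt. All randomness (Poisson
// background) draws from R's RNG, so runs are reproducible given set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Delivery {
  int slot;
  double amount;
};

// [[Rcpp::export]]
List run_network_cpp(List neurons, List synapses, List kernels, List slots,
                     List background, List replay, List inject, List record,
                     double dt, int n_steps) {
  // --- neurons ---------------------------------------------------------
  IntegerVector model = neurons["model"];       // 0 = adex, 1 = tif
  NumericVector C = neurons["C"], gL = neurons["gL"], EL = neurons["EL"];
  NumericVector VT = neurons["VT"], DeltaT = neurons["DeltaT"];
  NumericVector Vreset = neurons["Vreset"], Vpeak = neurons["Vpeak"];
  NumericVector a = neurons["a"], b = neurons["b"], tau_w = neurons["tau_w"];
  NumericVector t_ref = neurons["t_ref"];
  NumericVector gT = neurons["gT"], ECa = neurons["ECa"];
  NumericVector tvm = neurons["tvm"], tkm = neurons["tkm"];
  NumericVector tvh = neurons["tvh"], tkh = neurons["tkh"];
  NumericVector tau1 = neurons["tau1"], tau2 = neurons["tau2"];
  NumericVector tauvmid = neurons["tauvmid"], tauk = neurons["tauk"];
  NumericVector v0 = neurons["v0"];
  const int ncell = model.size();

  // --- synapses (CSR by presynaptic cell) ------------------------------
  IntegerVector out_start = synapses["out_start"];   // ncell + 1
  IntegerVector syn_slot = synapses["slot"];         // 0-based slot index
  NumericVector syn_wnorm = synapses["wnorm"];       // g * kernel norm (nS)
  NumericVector syn_U = synapses["U"], syn_D = synapses["D"], syn_F = synapses["F"];
  IntegerVector syn_delay = synapses["delay_steps"];
  const int nsyn = syn_slot.size();

  // --- kernels ----------------------------------------------------------
  NumericVector k_tau_r = kernels["tau_rise"], k_tau_d = kernels["tau_decay"];
  NumericVector k_erev = kernels["erev"];
  const int nk = k_tau_r.size();
  std::vector<double> fr(nk), fd(nk);
  for (int k = 0; k < nk; ++k) {
    fr[k] = std::exp(-dt / k_tau_r[k]);
    fd[k] = std::exp(-dt / k_tau_d[k]);
  }

  // --- conductance slots (cell-major) -----------------------------------
  IntegerVector slot_cell = slots["cell"];     // 0-based, sorted
  IntegerVector slot_kernel = slots["kernel"]; // 0-based
  IntegerVector cell_slot_start = slots["cell_start"]; // ncell + 1
  const int nslot = slot_cell.size();
  std::vector<double> xr(nslot, 0.0), xd(nslot, 0.0);

  // --- background -------------------------------------------------------
  NumericVector bg_rate_exc = background["rate_exc"];  // events per ms, per cell
  NumericVector bg_rate_inh = background["rate_inh"];
  NumericVector bg_w_exc = background["w_exc"];        // norm-multiplied (nS)
  NumericVector bg_w_inh = background["w_inh"];
  IntegerVector bg_slot_exc = background["slot_exc"];  // -1 if none
  IntegerVector bg_slot_inh = background["slot_inh"];

  // --- replay -----------------------------------------------------------
  IntegerVector is_replay = replay["is_replay"];       // per cell 0/1
  IntegerVector rep_step = replay["step"];             // sorted ascending
  IntegerVector rep_cell = replay["cell"];             // 0-based

  // --- injection --------------------------------------------------------
  NumericVector I_const = inject["I_const"];
  NumericVector pulse_amp = inject["pulse_amp"];
  IntegerVector pulse_on = inject["pulse_on"], pulse_off = inject["pulse_off"];

  // --- recording --------------------------------------------------------
  IntegerVector rec_v_idx = record["v_idx"];   // 0-based
  IntegerVector rec_i_idx = record["i_idx"];
  int rec_every = as<int>(record["every"]);
  if (rec_every < 1) rec_every = 1;
  const int n_rec_t = n_steps / rec_every + 1;
  NumericMatrix v_out(n_rec_t, rec_v_idx.size());
  NumericMatrix i_out(n_rec_t, rec_i_idx.size());
  NumericVector rec_times(n_rec_t);

  // --- state ------------------------------------------------------------
  std::vector<double> V(ncell), w(ncell, 0.0), h(ncell);
  std::vector<double> refrac_until(ncell, -1.0);
  for (int c = 0; c < ncell; ++c) {
    V[c] = v0[c];
    if (model[c] == 1) {
      h[c] = 1.0 / (1.0 + std::exp((V[c] - tvh[c]) / tkh[c]));
    }
  }
  std::vector<double> tm_u(nsyn, 0.0), tm_R(nsyn, 1.0), tm_t(nsyn, -1e18);
  std::vector<double> Isyn(ncell, 0.0);

  int max_delay = 1;
  for (int i = 0; i < nsyn; ++i)
    if (syn_delay[i] > max_delay) max_delay = syn_delay[i];
  const int ring_len = max_delay + 1;
  std::vector<std::vector<Delivery> > ring(ring_len);

  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  spike_cell.reserve(1 << 16);
  spike_time.reserve(1 << 16);

  // background next-event times (ms)
  std::vector<double> next_exc(ncell), next_inh(ncell);
  RNGScope rng;
  for (int c = 0; c < ncell; ++c) {
    next_exc[c] = bg_rate_exc[c] > 0 ? R::exp_rand() / bg_rate_exc[c] : R_PosInf;
    next_inh[c] = bg_rate_inh[c] > 0 ? R::exp_rand() / bg_rate_inh[c] : R_PosInf;
  }

  int rep_ptr = 0;
  const int nrep = rep_step.size();
  int rec_row = 0;

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // 1. deliveries scheduled for this step
    std::vector<Delivery>& due = ring[s % ring_len];
    for (size_t i = 0; i < due.size(); ++i) {
      xr[due[i].slot] += due[i].amount;
      xd[due[i].slot] += due[i].amount;
    }
    due.clear();

    // 2. background events (immediate, no delay)
    for (int c = 0; c < ncell; ++c) {
      while (next_exc[c] <= t) {
        int sl = bg_slot_exc[c];
        if (sl >= 0) { xr[sl] += bg_w_exc[c]; xd[sl] += bg_w_exc[c]; }
        next_exc[c] += R::exp_rand() / bg_rate_exc[c];
      }
      while (next_inh[c] <= t) {
        int sl = bg_slot_inh[c];
        if (sl >= 0) { xr[sl] += bg_w_inh[c]; xd[sl] += bg_w_inh[c]; }
        next_inh[c] += R::exp_rand() / bg_rate_inh[c];
      }
    }

    // 3. decay conductances and accumulate synaptic currents
    for (int c = 0; c < ncell; ++c) Isyn[c] = 0.0;
    for (int sl = 0; sl < nslot; ++sl) {
      if (xd[sl] < 1e-12 && xr[sl] < 1e-12) { xr[sl] = 0.0; xd[sl] = 0.0; continue; }
      xr[sl] *= fr[slot_kernel[sl]];
      xd[sl] *= fd[slot_kernel[sl]];
      const double g = xd[sl] - xr[sl];
      const int c = slot_cell[sl];
      Isyn[c] += g * (k_erev[slot_kernel[sl]] - V[c]);
    }

    // 4. replay spikes due this step
    while (rep_ptr < nrep && rep_step[rep_ptr] == s) {
      const int c = rep_cell[rep_ptr];
      spike_cell.push_back(c);
      spike_time.push_back(t);
      for (int i = out_start[c]; i < out_start[c + 1]; ++i) {
        double delta = t - tm_t[i];
        double u = syn_F[i] > 0
          ? syn_U[i] + tm_u[i] * (1.0 - syn_U[i]) * std::exp(-delta / syn_F[i])
          : syn_U[i];
        double Rr = syn_D[i] > 0
          ? 1.0 + (tm_R[i] - 1.0) * std::exp(-delta / syn_D[i])
          : 1.0;
        double release = u * Rr;
        tm_u[i] = u; tm_R[i] = Rr * (1.0 - u); tm_t[i] = t;
        ring[(s + syn_delay[i]) % ring_len].push_back(
          Delivery{syn_slot[i], syn_wnorm[i] * release});
      }
      ++rep_ptr;
    }

    // 5. integrate cells and detect threshold crossings
    for (int c = 0; c < ncell; ++c) {
      if (is_replay[c]) continue;
      double I_in = I_const[c];
      if (s >= pulse_on[c] && s < pulse_off[c]) I_in += pulse_amp[c];
      const double Itot = Isyn[c] + I_in;
      bool spiked = false;

      if (model[c] == 0) { // AdEx
        // adaptation: exact exponential update toward a*(V-EL)
        const double winf = a[c] * (V[c] - EL[c]);
        w[c] = winf + (w[c] - winf) * std::exp(-dt / tau_w[c]);
        if (t >= refrac_until[c]) {
          double ex = 0.0;
          if (DeltaT[c] > 0) {
            double arg = (V[c] - VT[c]) / DeltaT[c];
            if (arg > 16.0) arg = 16.0;
            ex = gL[c] * DeltaT[c] * std::exp(arg);
          }
          V[c] += dt / C[c] * (gL[c] * (EL[c] - V[c]) + ex - w[c] + Itot);
          if (!std::isfinite(V[c]))
            stop("membrane potential diverged for cell %d at t = %.2f ms",
                 c + 1, t);
          if (V[c] >= Vpeak[c]) spiked = true;
        } else {
          V[c] = Vreset[c];
        }
        if (spiked) {
          V[c] = Vreset[c];
          w[c] += b[c];
          refrac_until[c] = t + t_ref[c];
        }
      } else { // thalamic IF with T-type calcium current
        const double hinf = 1.0 / (1.0 + std::exp((V[c] - tvh[c]) / tkh[c]));
        const double th = tau1[c] + (tau2[c] - tau1[c]) /
          (1.0 + std::exp((V[c] - tauvmid[c]) / tauk[c]));
        h[c] = hinf + (h[c] - hinf) * std::exp(-dt / th);
        if (t >= refrac_until[c]) {
          const double minf = 1.0 / (1.0 + std::exp(-(V[c] - tvm[c]) / tkm[c]));
          const double IT = gT[c] * minf * minf * h[c] * (ECa[c] - V[c]);
          V[c] += dt / C[c] * (gL[c] * (EL[c] - V[c]) + IT + Itot);
          if (!std::isfinite(V[c]))
            stop("membrane potential diverged for cell %d at t = %.2f ms",
                 c + 1, t);
          if (V[c] >= VT[c]) spiked = true;
        } else {
          V[c] = Vreset[c];
        }
        if (spiked) {
          V[c] = Vreset[c];
          refrac_until[c] = t + t_ref[c];
        }
      }

      if (!std::isfinite(V[c]))
        stop("membrane potential diverged for cell %d at t = %.2f ms",
             c + 1, t);

      if (spiked) {
        spike_cell.push_back(c);
        spike_time.push_back(t);
        for (int i = out_start[c]; i < out_start[c + 1]; ++i) {
          double delta = t - tm_t[i];
          double u = syn_F[i] > 0
            ? syn_U[i] + tm_u[i] * (1.0 - syn_U[i]) * std::exp(-delta / syn_F[i])
            : syn_U[i];
          double Rr = syn_D[i] > 0
            ? 1.0 + (tm_R[i] - 1.0) * std::exp(-delta / syn_D[i])
            : 1.0;
          double release = u * Rr;
          tm_u[i] = u; tm_R[i] = Rr * (1.0 - u); tm_t[i] = t;
          ring[(s + syn_delay[i]) % ring_len].push_back(
            Delivery{syn_slot[i], syn_wnorm[i] * release});
        }
      }
    }

    // 6. recording
    if (s % rec_every == 0) {
      rec_times[rec_row] = t;
      for (int j = 0; j < rec_v_idx.size(); ++j)
        v_out(rec_row, j) = V[rec_v_idx[j]];
      for (int j = 0; j < rec_i_idx.size(); ++j)
        i_out(rec_row, j) = Isyn[rec_i_idx[j]];
      ++rec_row;
    }

    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["spike_cell"] = wrap(spike_cell),
    _["spike_time"] = wrap(spike_time),
    _["v"] = v_out,
    _["i_syn"] = i_out,
    _["rec_times"] = rec_times,
    _["n_rec"] = rec_row);
}
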