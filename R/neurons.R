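#' Point-neuron parameter sets
#'
#' Reduced single-compartment conductance-based models stand in for the
#' morpho-electrical cell types. Cortical cells are two-variable
#' adaptive-exponential integrate-and-fire models (an adapting excitatory set
#' and a fast-spiking inhibitory set); thalamic cells are integrate-and-fire
#' models augmented with a low-threshold T-type calcium current
#' (Destexhe-style instantaneous activation `m_inf(V)^2` and first-order
#' inactivation `h`), which produces rebound bursts after hyperpolarization
#' and tonic firing at depolarized potentials.
#'
#' Units: capacitance pF, conductance nS, voltage mV, time ms, current pA.
#'
#' @param C Capacitance (pF).
#' @param gL Leak conductance (nS).
#' @param EL Leak reversal / resting target (mV).
#' @param VT Spike threshold (mV): AdEx soft threshold, hard threshold for the
#'   thalamic model.
#' @param DeltaT AdEx slope factor (mV); 0 disables the exponential term.
#' @param Vreset Post-spike reset (mV).
#' @param Vpeak AdEx spike-detection ceiling (mV).
#' @param a,b,tau_w AdEx subthreshold coupling (nS), spike-triggered adaptation
#'   increment (pA) and adaptation time constant (ms).
#' @param t_ref Absolute refractory period (ms).
#' @param gT,ECa T-current maximal conductance (nS) and calcium reversal (mV).
#' @param tvm,tkm Activation half-voltage and slope (mV).
#' @param tvh,tkh Inactivation half-voltage and slope (mV).
#' @param tau1,tau2,tauvmid,tauk Inactivation time constant (ms): logistic
#'   interpolation from `tau1` (depolarized) to `tau2` (hyperpolarized) around
#'   `tauvmid` with slope `tauk`.
#' @param model `"adex"` or `"tif"`.
#' @return A named list of class `tc_neuron_params`.
#' @export
neuron_params <- function(model = c("adex", "tif"), C = 200, gL = 10, EL = -70,
                          VT = -50, DeltaT = 2, Vreset = -58, Vpeak = 0,
                          a = 2, b = 40, tau_w = 300, t_ref = 2.5,
                          gT = 0, ECa = 120, tvm = -57, tkm = 6.2,
                          tvh = -81, tkh = 4, tau1 = 15, tau2 = 80,
                          tauvmid = -78, tauk = 4) {
  model <- match.arg(model)
  structure(list(model = model, C = C, gL = gL, EL = EL, VT = VT,
                 DeltaT = DeltaT, Vreset = Vreset, Vpeak = Vpeak, a = a, b = b,
                 tau_w = tau_w, t_ref = t_ref, gT = gT, ECa = ECa, tvm = tvm,
                 tkm = tkm, tvh = tvh, tkh = tkh, tau1 = tau1, tau2 = tau2,
                 tauvmid = tauvmid, tauk = tauk),
            class = "tc_neuron_params")
}

#' @rdname neuron_params
#' @param layer Cortical layer (accepted for symmetry; the default sets are
#'   shared across layers).
#' @export
cortical_exc_params <- function(layer = "L5") {
  neuron_params("adex", C = 200, gL = 10, EL = -70, VT = -50, DeltaT = 2,
                Vreset = -58, Vpeak = 0, a = 2, b = 40, tau_w = 300,
                t_ref = 2.5)
}

#' @rdname neuron_params
#' @export
cortical_inh_params <- function(layer = "L5") {
  neuron_params("adex", C = 100, gL = 10, EL = -70, VT = -48, DeltaT = 1,
                Vreset = -62, Vpeak = 0, a = 0, b = 0, tau_w = 100,
                t_ref = 1.5)
}

#' @rdname neuron_params
#' @export
relay_cell_params <- function() {
  neuron_params("tif", C = 200, gL = 10, EL = -60, VT = -50, Vreset = -54,
                t_ref = 2.5, gT = 50, ECa = 120, tvm = -57, tkm = 6.2,
                tvh = -81, tkh = 4, tau1 = 15, tau2 = 90, tauvmid = -78,
                tauk = 4)
}

#' @rdname neuron_params
#' @export
reticular_cell_params <- function() {
  neuron_params("tif", C = 200, gL = 10, EL = -80, VT = -50, Vreset = -54,
                t_ref = 2.5, gT = 80, ECa = 120, tvm = -57, tkm = 6.2,
                tvh = -78, tkh = 4, tau1 = 20, tau2 = 110, tauvmid = -76,
                tauk = 4)
}

neuron_param_fields <- c("C", "gL", "EL", "VT", "DeltaT", "Vreset", "Vpeak",
                         "a", "b", "tau_w", "t_ref", "gT", "ECa", "tvm", "tkm",
                         "tvh", "tkh", "tau1", "tau2", "tauvmid", "tauk")

# stack parameter sets into the engine's column-list representation
neurons_for_engine <- function(param_list) {
  out <- list(model = vapply(param_list, function(p)
    if (p$model == "adex") 0L else 1L, integer(1)))
  for (f in neuron_param_fields)
    out[[f]] <- vapply(param_list, function(p) as.numeric(p[[f]]), numeric(1))
  out$v0 <- out$EL
  out
}

#' Simulate a single cell with current injection
#'
#' Integrates one neuron with no synaptic input, an optional constant holding
#' current and an optional square current pulse, recording the membrane
#' potential.
#'
#' @param params A [neuron_params()] set.
#' @param duration Duration (ms).
#' @param dt Step (ms).
#' @param I_const Constant injected current (pA).
#' @param pulse `c(start, end, amplitude)`: square pulse window (ms) and
#'   amplitude (pA), or NULL.
#' @param record_dt Recording interval (ms).
#' @return List with `trace` (tibble `time`, `v`) and `spikes` (times in ms).
#' @export
simulate_cell <- function(params, duration = 1000, dt = 0.1, I_const = 0,
                          pulse = NULL, record_dt = 1) {
  n_steps <- as.integer(round(duration / dt))
  pulse_on <- if (is.null(pulse)) n_steps + 1L else as.integer(round(pulse[1] / dt))
  pulse_off <- if (is.null(pulse)) n_steps + 1L else as.integer(round(pulse[2] / dt))
  pulse_amp <- if (is.null(pulse)) 0 else pulse[3]
  res <- run_network_cpp(
    neurons = neurons_for_engine(list(params)),
    synapses = list(out_start = c(0L, 0L), slot = integer(0),
                    wnorm = numeric(0), U = numeric(0), D = numeric(0),
                    F = numeric(0), delay_steps = integer(0)),
    kernels = list(tau_rise = 0.2, tau_decay = 2, erev = 0),
    slots = list(cell = integer(0), kernel = integer(0), cell_start = c(0L, 0L)),
    background = list(rate_exc = 0, rate_inh = 0, w_exc = 0, w_inh = 0,
                      slot_exc = -1L, slot_inh = -1L),
    replay = list(is_replay = 0L, step = integer(0), cell = integer(0)),
    inject = list(I_const = I_const, pulse_amp = pulse_amp,
                  pulse_on = pulse_on, pulse_off = pulse_off),
    record = list(v_idx = 0L, i_idx = integer(0),
                  every = max(1L, as.integer(round(record_dt / dt)))),
    dt = dt, n_steps = n_steps)
  n <- res$n_rec
  list(trace = tibble(time = res$rec_times[seq_len(n)],
                      v = res$v[seq_len(n), 1]),
       spikes = res$spike_time)
}

#' Steady-state membrane potential with zero input
#'
#' Integrates the model for 1 s with no input and reports the final membrane
#' potential. The calibrated relay and reticular sets rest near -60 and -80 mV
#' respectively.
#'
#' @param params A [neuron_params()] set.
#' @param duration Settling time (ms).
#' @return Resting potential (mV). If the cell spikes spontaneously the value
#'   is returned with a warning attribute.
#' @export
resting_potential <- function(params, duration = 1000) {
  sim <- simulate_cell(params, duration = duration)
  if (length(sim$spikes) > 0)
    warn("cell spikes spontaneously with zero input; resting potential ill-defined")
  tail(sim$trace$v, 1)
}

#' Rebound-burst protocol
#'
#' Applies a hyperpolarizing current pulse and counts spikes within a window
#' after release. Thalamic models with an intact T current burst on release;
#' zeroing the T conductance abolishes the rebound.
#'
#' @param params A [neuron_params()] set.
#' @param pulse_amp Pulse amplitude (pA; negative = hyperpolarizing).
#' @param pulse_dur Pulse duration (ms).
#' @param window Post-release window for counting rebound spikes (ms).
#' @return List: `n_rebound` (spikes within the window after release),
#'   `spikes`, `trace`.
#' @export
rebound_burst_test <- function(params, pulse_amp = -200, pulse_dur = 500,
                               window = 50) {
  t0 <- 200
  sim <- simulate_cell(params, duration = t0 + pulse_dur + 300,
                       pulse = c(t0, t0 + pulse_dur, pulse_amp))
  release <- t0 + pulse_dur
  n_reb <- sum(sim$spikes >= release & sim$spikes < release + window)
  list(n_rebound = n_reb, spikes = sim$spikes, trace = sim$trace)
}

#' Frequency-current curve
#'
#' @param params A [neuron_params()] set.
#' @param currents Injected currents (pA).
#' @param duration Duration per point (ms); the first 200 ms are discarded.
#' @return Tibble with `current`, `rate` (Hz).
#' @export
fi_curve <- function(params, currents, duration = 1200) {
  rates <- vapply(currents, function(I) {
    sim <- simulate_cell(params, duration = duration, I_const = I)
    sum(sim$spikes >= 200) / ((duration - 200) / 1000)
  }, numeric(1))
  tibble(current = currents, rate = rates)
}
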