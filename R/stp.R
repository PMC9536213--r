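#' Initial Tsodyks-Markram synapse state
#'
#' Utilization `u` starts at 0 and resources `R` at 1, so the first spike of a
#' train releases exactly `U`.
#'
#' @return A `tc_tm_state` list with fields `u`, `R`, `t_last`.
#' @export
tm_state <- function() {
  structure(list(u = 0, R = 1, t_last = -Inf), class = "tc_tm_state")
}

#' Advance a Tsodyks-Markram synapse by one presynaptic spike
#'
#' Deterministic short-term plasticity: with `delta = t_spike - t_last`,
#' facilitation is applied before release
#' (`u <- U + u * (1 - U) * exp(-delta / F)`), depression recovery is applied
#' lazily (`R <- 1 + (R - 1) * exp(-delta / D)`), the release fraction is
#' `u * R`, and the post-release remainder `R * (1 - u)` is stored. The limits
#' `F -> 0` (u pinned at U, pure depression) and `D -> 0` (R pinned at 1, pure
#' facilitation) are handled exactly.
#'
#' @param state A [tm_state()].
#' @param params List or one-row tibble with `U`, `D`, `F` (D and F in ms).
#' @param t_spike Spike time in ms; must not precede the previous spike.
#' @return List with `state` (updated) and `release` (the release fraction
#'   `u * R`, in `[0, 1]`).
#' @export
tm_on_spike <- function(state, params, t_spike) {
  delta <- t_spike - state$t_last
  if (is.nan(delta) || delta < 0) abort("spike times must be non-decreasing")
  U <- params$U
  u <- if (params$F > 0) U + state$u * (1 - U) * exp(-delta / params$F) else U
  R <- if (params$D > 0) 1 + (state$R - 1) * exp(-delta / params$D) else 1
  release <- u * R
  state$u <- u
  state$R <- R * (1 - u)
  state$t_last <- t_spike
  list(state = state, release = release)
}

#' Run a Tsodyks-Markram synapse over a spike train
#'
#' @param params List with `U`, `D`, `F`.
#' @param spike_times Non-decreasing spike times in ms.
#' @return Tibble with per-spike `t`, `u`, `R` (pre-release, recovered) and
#'   `release`.
#' @export
tm_train <- function(params, spike_times) {
  st <- tm_state()
  out <- vector("list", length(spike_times))
  for (i in seq_along(spike_times)) {
    upd <- tm_on_spike(st, params, spike_times[i])
    out[[i]] <- tibble(t = spike_times[i], u = upd$state$u,
                       R = upd$state$R / (1 - upd$state$u),
                       release = upd$release)
    st <- upd$state
  }
  bind_rows(out)
}

#' Closed-form steady-state release at a fixed rate
#'
#' Fixed point of the iterated Tsodyks-Markram map for a periodic train with
#' inter-spike interval `isi`:
#' `u* = U / (1 - (1 - U) exp(-isi/F))` and
#' `R* = (1 - exp(-isi/D)) / (1 - (1 - u*) exp(-isi/D))`;
#' the steady-state release fraction is `u* R*`.
#'
#' @param U,D,F TM parameters (D, F in ms).
#' @param isi Inter-spike interval in ms.
#' @return List with `u_star`, `R_star`, `release`.
#' @export
tm_steady_state <- function(U, D, F, isi) {
  f <- if (F > 0) exp(-isi / F) else 0
  dd <- if (D > 0) exp(-isi / D) else 0
  u_star <- U / (1 - (1 - U) * f)
  R_star <- (1 - dd) / (1 - (1 - u_star) * dd)
  list(u_star = u_star, R_star = R_star, release = u_star * R_star)
}

#' Time of the dual-exponential conductance peak
#'
#' @param tau_rise,tau_decay Kernel time constants in ms.
#' @return Peak time after onset in ms.
#' @export
psp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# peak-normalization factor: kernel maximum of exp(-t/td) - exp(-t/tr) inverted
dualexp_norm <- function(tau_rise, tau_decay) {
  tp <- psp_peak_time(tau_rise, tau_decay)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Dual-exponential conductance waveform
#'
#' `g(t) = weight * N * (exp(-(t - onset)/tau_decay) - exp(-(t - onset)/tau_rise))`
#' for `t >= onset`, 0 before; `N` normalizes the peak to `weight`.
#'
#' @param event List with `onset` (ms), `weight` (nS), `tau_rise`, `tau_decay`
#'   (ms).
#' @param t Times in ms.
#' @return Conductance in nS.
#' @export
conductance_waveform <- function(event, t) {
  if (event$tau_decay <= event$tau_rise)
    abort("tau_decay must exceed tau_rise")
  s <- t - event$onset
  N <- dualexp_norm(event$tau_rise, event$tau_decay)
  ifelse(s >= 0,
         event$weight * N * (exp(-s / event$tau_decay) - exp(-s / event$tau_rise)),
         0)
}

#' Standalone PSP protocol on a passive point target
#'
#' Delivers a presynaptic spike train through a sampled synapse of the given
#' class onto a passive single-compartment membrane, repeats with fresh
#' parameter draws, and reports per-spike PSP peak amplitudes (absolute
#' deflection from the membrane value at each spike onset), averaged over
#' repeats. With point-neuron targets the relative amplitude sequence is the
#' meaningful readout; absolute millivolt values depend on morphology and are
#' not calibrated.
#'
#' @param registry Registry from [load_synapse_table()].
#' @param class_index Synapse class index (0-28).
#' @param spike_times Presynaptic spike times in ms (e.g.
#'   `seq(0, by = 50, length.out = 8)` for 20 Hz).
#' @param n_repeats Number of repeats with independent parameter draws.
#' @param seed Integer seed.
#' @param target Passive membrane: list with `C` (pF), `gL` (nS), `EL` (mV).
#' @param e_rev_exc,e_rev_inh Reversal potentials (mV).
#' @param dt Integration step (ms).
#' @return Tibble with `spike`, `onset`, `amplitude` (mV, mean over repeats).
#' @export
run_psp_protocol <- function(registry, class_index, spike_times,
                             n_repeats = 20, seed = 1,
                             target = list(C = 200, gL = 10, EL = -70),
                             e_rev_exc = 0, e_rev_inh = -80, dt = 0.025) {
  spike_times <- sort(spike_times)
  t_end <- max(spike_times) + 100
  times <- seq(0, t_end, by = dt)
  with_seed(seed, {
    amps <- matrix(0, nrow = n_repeats, ncol = length(spike_times))
    for (r in seq_len(n_repeats)) {
      par <- sample_synapse_params(registry, class_index, n = 1)
      erev <- if (par$receptor == "AMPA") e_rev_exc else e_rev_inh
      rel <- tm_train(par, spike_times)$release
      g <- rep(0, length(times))
      for (k in seq_along(spike_times)) {
        g <- g + conductance_waveform(
          list(onset = spike_times[k], weight = par$g_syn * rel[k],
               tau_rise = par$tau_rise, tau_decay = par$tau_decay), times)
      }
      v <- passive_membrane_response(g, erev, target, dt)
      onset_idx <- pmax(1L, floor(spike_times / dt) + 1L)
      for (k in seq_along(spike_times)) {
        upper <- if (k < length(spike_times)) onset_idx[k + 1] else length(times)
        win <- onset_idx[k]:upper
        amps[r, k] <- max(abs(v[win] - v[onset_idx[k]]))
      }
    }
    tibble(spike = seq_along(spike_times), onset = spike_times,
           amplitude = colMeans(amps))
  })
}

# exponential-Euler integration of a passive membrane driven by g(t)
passive_membrane_response <- function(g, erev, target, dt) {
  n <- length(g)
  v <- numeric(n)
  v[1] <- target$EL
  for (i in seq_len(n - 1)) {
    gtot <- target$gL + g[i]
    vinf <- (target$gL * target$EL + g[i] * erev) / gtot
    v[i + 1] <- vinf + (v[i] - vinf) * exp(-dt * gtot / target$C)
  }
  v
}
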