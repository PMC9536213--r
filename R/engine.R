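#' Simulation configuration
#'
#' @param duration Total simulated time (ms).
#' @param dt Integration step (ms).
#' @param transient Initial transient (ms) that analysis functions discard by
#'   default (the network needs about a second to reach a steady state).
#' @param seed Integer seed covering every source of randomness in the run.
#' @param record_v Cell ids whose membrane potential to record.
#' @param record_current Cell ids whose total synaptic current to record (the
#'   input of the LFP dipole mapping).
#' @param record_dt Recording interval (ms).
#' @param calcium A [calcium_state()]: the in-vitro state (`cao = 2.0`) leaves
#'   release probabilities unchanged; the in-vivo-like state (`cao = 1.2`)
#'   rescales U per connection dependence class.
#' @return A `tc_sim_config` object.
#' @export
simulation_config <- function(duration, dt = 0.1, transient = 1000, seed = 1,
                              record_v = integer(0),
                              record_current = integer(0), record_dt = 1,
                              calcium = calcium_state(2.0)) {
  if (dt <= 0) abort("dt must be positive")
  if (duration <= transient)
    abort("duration must exceed the transient")
  structure(list(duration = duration, dt = dt, transient = transient,
                 seed = seed, record_v = record_v,
                 record_current = record_current, record_dt = record_dt,
                 calcium = calcium),
            class = "tc_sim_config")
}

# background kernel constants (exc: AMPA-like, inh: GABA_A-like)
.bg_kernels <- list(exc = c(tau_rise = 0.2, tau_decay = 2, erev = 0),
                    inh = c(tau_rise = 0.2, tau_decay = 8, erev = -80))

#' Run a network simulation
#'
#' Clock-driven integration of the circuit: neuron states advance at fixed
#' `dt`, presynaptic spikes are delivered through per-edge delays into shared
#' dual-exponential conductance kernels, and deterministic Tsodyks-Markram
#' dynamics scale each synapse's release. Runs are bit-reproducible given the
#' config seed.
#'
#' @param circuit A `tc_circuit`.
#' @param config A [simulation_config()].
#' @return A `tc_sim` object: `spikes` (tibble `id`, `time`, sorted),
#'   `v` / `i_syn` trace tibbles, `cells`, `config`.
#' @export
run_simulation <- function(circuit, config) {
  cells <- circuit$cells
  ncell <- nrow(cells)
  if (ncell == 0) abort("circuit has no cells")
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))
  id2row <- setNames(seq_len(ncell), cells$id)

  syn <- circuit$synapses
  # calcium-dependent utilization rescaling
  if (nrow(syn) > 0 && !is.null(config$calcium)) {
    mult <- config$calcium$multipliers
    has_dep <- !is.na(syn$depclass)
    syn$U[has_dep] <- syn$U[has_dep] * unname(mult[syn$depclass[has_dep]])
  }

  # kernel classes shared by (erev, tau_rise, tau_kernel)
  bgk <- tibble(tau_rise = c(.bg_kernels$exc[["tau_rise"]],
                             .bg_kernels$inh[["tau_rise"]]),
                tau_decay = c(.bg_kernels$exc[["tau_decay"]],
                              .bg_kernels$inh[["tau_decay"]]),
                erev = c(.bg_kernels$exc[["erev"]], .bg_kernels$inh[["erev"]]))
  synk <- if (nrow(syn) > 0) {
    distinct(tibble(tau_rise = syn$tau_rise, tau_decay = syn$tau_kernel,
                    erev = syn$erev))
  } else NULL
  kernels <- distinct(bind_rows(bgk, synk))
  if (any(kernels$tau_decay <= kernels$tau_rise))
    abort("synaptic tau_decay must exceed tau_rise for every kernel")
  kernels$kernel <- seq_len(nrow(kernels)) - 1L
  kernels$norm <- dualexp_norm(kernels$tau_rise, kernels$tau_decay)

  if (nrow(syn) > 0) {
    syn$kernel <- kernels$kernel[match(
      paste(syn$tau_rise, syn$tau_kernel, syn$erev),
      paste(kernels$tau_rise, kernels$tau_decay, kernels$erev))]
    syn$pre_row <- unname(id2row[as.character(syn$pre)]) - 1L
    syn$post_row <- unname(id2row[as.character(syn$post)]) - 1L
  }

  # conductance slots: unique (post cell, kernel), cell-major
  bg <- circuit$background
  bg_rows <- if (!is.null(bg)) unname(id2row[as.character(bg$id)]) - 1L else integer(0)
  slot_src <- bind_rows(
    if (nrow(syn) > 0) tibble(cell = syn$post_row, kernel = syn$kernel) else NULL,
    if (length(bg_rows) > 0) tibble(cell = bg_rows, kernel = 0L) else NULL,
    if (length(bg_rows) > 0) tibble(cell = bg_rows, kernel = 1L) else NULL)
  if (nrow(slot_src) == 0) slot_src <- tibble(cell = integer(0), kernel = integer(0))
  slots <- distinct(slot_src)
  slots <- slots[order(slots$cell, slots$kernel), ]
  slots$slot <- seq_len(nrow(slots)) - 1L
  slot_key <- paste(slots$cell, slots$kernel)
  cell_start <- c(0L, cumsum(tabulate(slots$cell + 1L, nbins = ncell)))

  if (nrow(syn) > 0) {
    syn$slot <- slots$slot[match(paste(syn$post_row, syn$kernel), slot_key)]
    syn$wnorm <- syn$g * kernels$norm[syn$kernel + 1L]
    syn$delay_steps <- pmax(1L, as.integer(round(syn$delay / dt)))
    syn <- syn[order(syn$pre_row), ]
    out_start <- c(0L, cumsum(tabulate(syn$pre_row + 1L, nbins = ncell)))
  } else {
    out_start <- rep(0L, ncell + 1L)
  }

  # background per-cell totals (events per ms) and norm-multiplied weights
  rate_exc <- rate_inh <- w_exc <- w_inh <- numeric(ncell)
  slot_exc <- slot_inh <- rep(-1L, ncell)
  if (!is.null(bg)) {
    rows <- bg_rows + 1L
    rate_exc[rows] <- bg$n_sources * bg$exc_rate / 1000
    rate_inh[rows] <- bg$n_sources * bg$inh_rate / 1000
    w_exc[rows] <- bg$g_exc * kernels$norm[1]
    w_inh[rows] <- bg$g_inh * kernels$norm[2]
    slot_exc[rows] <- slots$slot[match(paste(bg_rows, 0L), slot_key)]
    slot_inh[rows] <- slots$slot[match(paste(bg_rows, 1L), slot_key)]
  }

  # replay sources
  is_replay <- integer(ncell)
  rep_step <- integer(0)
  rep_cell <- integer(0)
  if (!is.null(circuit$replay) && nrow(circuit$replay) > 0) {
    rp <- circuit$replay
    rp <- rp[order(rp$time), ]
    replay_ids <- attr(circuit$replay, "replay_ids") %||% unique(rp$id)
    is_replay[unname(id2row[as.character(replay_ids)])] <- 1L
    keep <- rp$time >= 0 & rp$time < config$duration
    rep_step <- as.integer(floor(rp$time[keep] / dt + 1e-6))
    rep_cell <- unname(id2row[as.character(rp$id[keep])]) - 1L
    ord <- order(rep_step)
    rep_step <- rep_step[ord]; rep_cell <- rep_cell[ord]
  }

  params_list <- circuit$params[cells$population]
  rec_v <- unname(id2row[as.character(config$record_v)]) - 1L
  rec_i <- unname(id2row[as.character(config$record_current)]) - 1L

  res <- with_seed(config$seed, run_network_cpp(
    neurons = neurons_for_engine(params_list),
    synapses = list(out_start = as.integer(out_start),
                    slot = if (nrow(syn) > 0) syn$slot else integer(0),
                    wnorm = if (nrow(syn) > 0) syn$wnorm else numeric(0),
                    U = if (nrow(syn) > 0) syn$U else numeric(0),
                    D = if (nrow(syn) > 0) syn$D else numeric(0),
                    F = if (nrow(syn) > 0) syn$F else numeric(0),
                    delay_steps = if (nrow(syn) > 0) syn$delay_steps else integer(0)),
    kernels = list(tau_rise = kernels$tau_rise, tau_decay = kernels$tau_decay,
                   erev = kernels$erev),
    slots = list(cell = as.integer(slots$cell), kernel = as.integer(slots$kernel),
                 cell_start = as.integer(cell_start)),
    background = list(rate_exc = rate_exc, rate_inh = rate_inh,
                      w_exc = w_exc, w_inh = w_inh,
                      slot_exc = slot_exc, slot_inh = slot_inh),
    replay = list(is_replay = is_replay, step = rep_step, cell = rep_cell),
    inject = list(I_const = numeric(ncell), pulse_amp = numeric(ncell),
                  pulse_on = rep(n_steps + 1L, ncell),
                  pulse_off = rep(n_steps + 1L, ncell)),
    record = list(v_idx = rec_v, i_idx = rec_i,
                  every = max(1L, as.integer(round(config$record_dt / dt)))),
    dt = dt, n_steps = n_steps))

  nrec <- res$n_rec
  times <- res$rec_times[seq_len(nrec)]
  spikes <- tibble(id = cells$id[res$spike_cell + 1L], time = res$spike_time)
  spikes <- arrange(spikes, .data$time, .data$id)
  v <- if (length(rec_v) > 0) {
    tibble(time = rep(times, length(rec_v)),
           id = rep(config$record_v, each = nrec),
           v = as.vector(res$v[seq_len(nrec), , drop = FALSE]))
  } else NULL
  i_syn <- if (length(rec_i) > 0) {
    tibble(time = rep(times, length(rec_i)),
           id = rep(config$record_current, each = nrec),
           i = as.vector(res$i_syn[seq_len(nrec), , drop = FALSE]))
  } else NULL
  structure(list(spikes = spikes, v = v, i_syn = i_syn,
                 cells = cells, config = config),
            class = "tc_sim")
}

#' @export
print.tc_sim <- function(x, ...) {
  cat(sprintf("<tc_sim> %d cells, %g ms, %d spikes\n", nrow(x$cells),
              x$config$duration, nrow(x$spikes)))
  invisible(x)
}

#' Hybrid replay simulation
#'
#' Simulates a selected subset of cells in full while every other cell is
#' replaced by a spike generator replaying a fixed train, so the detailed
#' subset receives exactly the presynaptic spike trains of the source run.
#'
#' @param circuit A `tc_circuit`.
#' @param detailed_ids Cell ids to integrate in full.
#' @param replay_spikes Spike tibble (`id`, `time`) for the remaining cells.
#' @param config A [simulation_config()].
#' @param replay_ids Ids covered by the replay (defaults to those present in
#'   `replay_spikes`; list silent cells here explicitly).
#' @return A `tc_sim` object.
#' @export
run_hybrid <- function(circuit, detailed_ids, replay_spikes, config,
                       replay_ids = unique(replay_spikes$id)) {
  non_detailed <- setdiff(circuit$cells$id, detailed_ids)
  uncovered <- setdiff(non_detailed, replay_ids)
  if (length(uncovered) > 0)
    abort(sprintf("replay trains missing for %d non-detailed cell(s), e.g. id %s",
                  length(uncovered), uncovered[1]))
  rp <- replay_spikes[replay_spikes$id %in% non_detailed, ]
  attr(rp, "replay_ids") <- non_detailed
  circuit$replay <- rp
  # background drive applies only to integrated cells
  if (!is.null(circuit$background))
    circuit$background <- circuit$background[
      circuit$background$id %in% detailed_ids, ]
  run_simulation(circuit, config)
}

#' Grid search over background rates
#'
#' Evaluates an objective on short simulations over a grid of excitatory and
#' inhibitory background rates and flags the argmin.
#'
#' @param circuit A `tc_circuit` (background settings other than the rates are
#'   taken from [attach_background()] defaults or `bg_args`).
#' @param exc_rates,inh_rates Rate grids (Hz per source).
#' @param objective Function of a `tc_sim` returning a scalar; the default
#'   targets a 1 Hz mean excitatory rate.
#' @param config A [simulation_config()] used for every grid point.
#' @param bg_args Extra arguments passed to [attach_background()].
#' @return List with `table` (tibble `exc_rate`, `inh_rate`, `objective`,
#'   `best`) and `best` (the winning row).
#' @export
grid_search_background <- function(circuit, exc_rates, inh_rates = 0,
                                   objective = NULL, config,
                                   bg_args = list()) {
  if (length(exc_rates) == 0 || length(inh_rates) == 0)
    abort("rate grids must be non-empty")
  if (is.null(objective)) {
    exc_ids <- circuit$cells$id[circuit$cells$excitatory]
    objective <- function(sim) {
      st <- population_rates(sim$spikes,
                             circuit$cells[circuit$cells$excitatory, ],
                             window = c(sim$config$transient,
                                        sim$config$duration))
      abs(sum(st$n_spikes) / max(length(exc_ids), 1) /
            ((sim$config$duration - sim$config$transient) / 1000) - 1)
    }
  }
  grid <- tidyr::expand_grid(exc_rate = exc_rates, inh_rate = inh_rates)
  vals <- purrr::pmap_dbl(grid, function(exc_rate, inh_rate) {
    cir <- do.call(attach_background,
                   c(list(circuit = circuit, exc_rate = exc_rate,
                          inh_rate = inh_rate), bg_args))
    objective(run_simulation(cir, config))
  })
  grid$objective <- vals
  grid$best <- seq_along(vals) == which.min(vals)
  list(table = grid, best = grid[grid$best, ])
}
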