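#' Circuit container
#'
#' A circuit bundles cell placements, per-population neuron parameter sets, a
#' synapse table, and optional background / replay specifications. Engine cell
#' indices follow the row order of `cells`.
#'
#' @param cells Cell tibble (see [place_cortical_cells()]).
#' @param params Named list mapping each population to a [neuron_params()] set.
#' @param synapses Synapse tibble (may be empty); see [empty_synapses()].
#' @return A `tc_circuit` object.
#' @export
new_circuit <- function(cells, params, synapses = empty_synapses()) {
  missing_pops <- setdiff(unique(cells$population), names(params))
  if (length(missing_pops) > 0)
    abort(paste0("no neuron parameters for population(s): ",
                 paste(missing_pops, collapse = ", ")))
  structure(list(cells = cells, params = params, synapses = synapses,
                 background = NULL, replay = NULL),
            class = "tc_circuit")
}

#' @export
print.tc_circuit <- function(x, ...) {
  cat(sprintf("<tc_circuit> %d cells, %d populations, %d synapses%s\n",
              nrow(x$cells), length(unique(x$cells$population)),
              nrow(x$synapses),
              if (!is.null(x$background)) ", background attached" else ""))
  invisible(x)
}

#' Empty synapse table
#'
#' One row per synapse: `pre`/`post` cell ids, sampled conductance `g` (nS),
#' kinetics (`tau_rise`, `tau_decay` per synapse; `tau_kernel` is the shared
#' class-mean decay used by the network engine's kernel grouping),
#' Tsodyks-Markram parameters `U`, `D`, `F` (static synapses use `U = 1`,
#' `D = F = 0`), `delay` (ms), `receptor`, `erev` (mV), `class_index` and
#' calcium `depclass`.
#'
#' @return A zero-row synapse tibble.
#' @export
empty_synapses <- function() {
  tibble(pre = integer(), post = integer(), class_index = integer(),
         g = numeric(), tau_rise = numeric(), tau_decay = numeric(),
         tau_kernel = numeric(), U = numeric(), D = numeric(), F = numeric(),
         delay = numeric(), receptor = character(), erev = numeric(),
         depclass = character())
}

#' Add synapses to a circuit
#'
#' @param circuit A `tc_circuit`.
#' @param synapses Synapse tibble to append.
#' @return The circuit with the rows appended.
#' @export
add_synapses <- function(circuit, synapses) {
  bad <- setdiff(unique(c(synapses$pre, synapses$post)), circuit$cells$id)
  if (length(bad) > 0)
    abort(paste0("synapse references unknown cell id(s), e.g. ", bad[1]))
  if (any(synapses$pre == synapses$post)) abort("self-edges are not allowed")
  circuit$synapses <- bind_rows(circuit$synapses, synapses)
  circuit
}

erev_for_receptor <- function(receptor) {
  unname(c(AMPA = 0, GABA_A = -80, GABA_B = -95)[receptor])
}

#' Default per-population neuron parameter map
#'
#' Cortical excitatory populations get the adapting AdEx set, cortical
#' inhibitory populations the fast-spiking set; thalamic relay nuclei (VPL,
#' VPM, POm) the relay set and RTN sectors the reticular set.
#'
#' @param cells Cell tibble.
#' @return Named list of [neuron_params()] keyed by population.
#' @export
default_params_map <- function(cells) {
  pops <- distinct(cells, .data$population, .data$layer, .data$excitatory)
  relay <- c("VPL", "VPM", "POm")
  rtn <- c("RTNo", "RTNm", "RTNi")
  out <- purrr::pmap(pops, function(population, layer, excitatory) {
    if (population %in% relay) relay_cell_params()
    else if (population %in% rtn) reticular_cell_params()
    else if (excitatory) cortical_exc_params(layer)
    else cortical_inh_params(layer)
  })
  setNames(out, pops$population)
}

#' Layer-level pathway grouping
#'
#' Adds a `pathway_group` column (`layer` + `E`/`I`, e.g. `L5E`) used to define
#' desk-scale pathways for rule fitting.
#'
#' @param cells Cell tibble.
#' @return `cells` with a `pathway_group` column.
#' @export
add_pathway_groups <- function(cells) {
  mutate(cells, pathway_group = paste0(.data$layer,
                                       ifelse(.data$excitatory, "E", "I")))
}

#' Default ground-truth cortical pathways
#'
#' The synthetic stand-in for the connectome-derived wiring statistics: one
#' distance-probability curve per ordered pair of layer-level groups. Peak
#' probability decreases with laminar separation; inhibitory axons are more
#' local than excitatory ones. All three fit families occur: within-layer
#' excitatory pathways saturate at short range (`exp_linsat`), other excitatory
#' pathways are Gaussian, and inhibitory pathways are exponential.
#'
#' @param groups Pathway group labels (defaults to the 9 groups of the packaged
#'   catalogue).
#' @return Pathway tibble (`pre`, `post`, `gt`) for
#'   [gen_connectome_instances()].
#' @export
default_cortical_pathways <- function(groups = c("L1I", "L23E", "L23I", "L4E",
                                                 "L4I", "L5E", "L5I", "L6E",
                                                 "L6I")) {
  layer_of <- function(g) sub("[EI]$", "", g)
  layer_rank <- c(L1 = 1, L23 = 2, L4 = 3, L5 = 4, L6 = 5)
  grid <- tidyr::expand_grid(pre = groups, post = groups)
  grid$gt <- purrr::pmap(grid, function(pre, post) {
    dlay <- abs(layer_rank[[layer_of(pre)]] - layer_rank[[layer_of(post)]])
    A <- c(0.15, 0.08, 0.04, 0.02, 0.02)[dlay + 1]
    pre_inh <- endsWith(pre, "I")
    if (pre_inh) {
      ground_truth_pathway("exponential", c(min(1, A * 1.3), 85), mean_nsyn = 3)
    } else if (dlay == 0) {
      ground_truth_pathway("exp_linsat", c(A * 1.6, 120, A), mean_nsyn = 4.5)
    } else {
      ground_truth_pathway("gaussian", c(A, 0, 110),
                           mean_nsyn = if (endsWith(post, "E")) 4.5 else 3.5)
    }
  })
  grid
}

# memoized synapse-class lookup over me-type pairs
class_lookup_factory <- function(registry) {
  memo <- new.env(parent = emptyenv())
  function(pre_me, post_me) {
    key <- paste0(pre_me, "|", post_me)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    row <- match_class(registry, pre_me, post_me)
    out <- list(index = row$index, s_type = row$s_type)
    assign(key, out, envir = memo)
    out
  }
}

#' Build the cortical connectome from fitted pathway rules
#'
#' For every ordered cell pair within each pathway, an edge is drawn Bernoulli
#' with the fitted probability at the pair's XZ distance; the number of
#' synapses per connection is `1 + Poisson(mean_nsyn - 1)`; the synapse class
#' comes from [match_class()] on the me-type pair and per-synapse parameters
#' are sampled from the class.
#'
#' @param cells Cell tibble carrying the rule grouping column.
#' @param rules Rules tibble from [fit_pathway_rules()] (or
#'   [read_pathway_rules()]).
#' @param registry Synapse registry.
#' @param seed Integer seed.
#' @param group_col Grouping column matching the rules' `pre`/`post`.
#' @param delay Synaptic delay (ms).
#' @param weight_scale Multiplier on sampled conductances (use to compensate
#'   reduced in-degree in scaled-down columns).
#' @return A synapse tibble.
#' @export
build_cortical_connectome <- function(cells, rules, registry, seed = 1,
                                      group_col = "pathway_group", delay = 1,
                                      weight_scale = 1) {
  if (!group_col %in% names(cells))
    abort(paste0("cells lack the grouping column ", group_col))
  groups_present <- unique(cells[[group_col]])
  uncovered <- setdiff(as.vector(outer(groups_present, groups_present, paste)),
                       paste(rules$pre, rules$post))
  if (length(uncovered) > 0)
    abort(paste0("no pathway rule for: ", uncovered[1]))
  lookup <- class_lookup_factory(registry)
  groups <- cells[[group_col]]
  with_seed(seed, {
    out <- purrr::pmap(rules, function(pre, post, fit, mean_nsyn, ...) {
      pre_c <- cells[groups == pre, ]
      post_c <- cells[groups == post, ]
      if (nrow(pre_c) == 0 || nrow(post_c) == 0) return(NULL)
      d <- xz_distance(pre_c, post_c)
      p <- matrix(predict(fit, as.vector(d)), nrow = nrow(d))
      p[outer(pre_c$id, post_c$id, "==")] <- 0
      hit <- which(runif(length(p)) < p)
      if (length(hit) == 0) return(NULL)
      ii <- (hit - 1) %% nrow(p) + 1
      jj <- (hit - 1) %/% nrow(p) + 1
      nsyn <- 1L + rpois(length(hit), max(mean_nsyn - 1, 0))
      edge_of_syn <- rep(seq_along(hit), nsyn)
      pre_me <- pre_c$me_type[ii][edge_of_syn]
      post_me <- post_c$me_type[jj][edge_of_syn]
      # class per synapse via memoized me-type pair lookup
      pair_key <- paste0(pre_me, "|", post_me)
      uk <- !duplicated(pair_key)
      cls_map <- purrr::map2(pre_me[uk], post_me[uk], lookup)
      names(cls_map) <- pair_key[uk]
      cls_idx <- vapply(cls_map[pair_key], function(x) x$index, numeric(1))
      syn <- vector("list", 0)
      params <- dplyr::bind_cols(
        tibble(pre = pre_c$id[ii][edge_of_syn],
               post = post_c$id[jj][edge_of_syn]),
        sample_params_by_class(registry, cls_idx))
      params$tau_kernel <- registry$tau_decay_mean[match(params$class_index,
                                                         registry$index)]
      params$g <- params$g_syn * weight_scale
      params$delay <- delay
      params$erev <- erev_for_receptor(params$receptor)
      params$depclass <- dependence_class(
        pre_c$excitatory[ii][edge_of_syn],
        post_c$m_type[jj][edge_of_syn],
        post_c$excitatory[jj][edge_of_syn])
      params[, names(empty_synapses())]
    })
    bind_rows(out)
  })
}

# vectorized sampling of per-synapse parameters grouped by class index
sample_params_by_class <- function(registry, cls_idx) {
  out <- vector("list", length(unique(cls_idx)))
  res <- tibble(class_index = cls_idx)
  res$row <- seq_len(nrow(res))
  drawn <- lapply(split(res$row, res$class_index), function(rows) {
    ci <- cls_idx[rows[1]]
    cbind(row = rows, sample_synapse_params(registry, ci, n = length(rows)))
  })
  drawn <- bind_rows(drawn)
  drawn <- drawn[order(drawn$row), ]
  drawn$row <- NULL
  drawn
}

#' Default thalamic footprint rules
#'
#' Footprint radii per projection. Printed footprint *diameters* (RTN->VPL and
#' RTN->VPM 64.33 um; VPL->RTN 97.67 um; VPM->RTN 103.57 um) are halved to
#' radii for the truncation rule; the intra-RTN value (264.63 um) is already a
#' radius. The probability decays exponentially with XZ distance (decay
#' constant equal to the footprint radius), is truncated to 0 outside the
#' radius, and the box-aligned depth offset is capped at `y_fraction` of the
#' radius.
#'
#' @param p0 Probability amplitude at zero distance.
#' @param y_fraction Maximum aligned depth offset as a fraction of the radius.
#' @return Footprint tibble: `projection`, `radius`, `p0`, `y_fraction`,
#'   `lambda`.
#' @export
default_footprints <- function(p0 = 1, y_fraction = 0.10) {
  tibble(projection = c("RTN->VPL", "RTN->VPM", "VPL->RTN", "VPM->RTN",
                        "RTN->RTN"),
         radius = c(64.33 / 2, 64.33 / 2, 97.67 / 2, 103.57 / 2, 264.63),
         p0 = p0, y_fraction = y_fraction,
         lambda = c(64.33 / 2, 64.33 / 2, 97.67 / 2, 103.57 / 2, 264.63))
}

# strategy 1/2 sampling: exponential decay in XZ, truncated at the footprint
# radius and at y_fraction * radius in box-aligned depth
footprint_connect <- function(pre_c, post_c, radius, p0, y_fraction, lambda,
                              pre_mid, post_mid) {
  d <- xz_distance(pre_c, post_c)
  dy <- abs(outer(pre_c$y - pre_mid, post_c$y - post_mid, "-"))
  p <- p0 * exp(-d / lambda)
  p[d > radius] <- 0
  p[dy > y_fraction * radius] <- 0
  p[outer(pre_c$id, post_c$id, "==")] <- 0
  hit <- which(runif(length(p)) < p)
  if (length(hit) == 0)
    return(tibble(pre = integer(), post = integer()))
  tibble(pre = pre_c$id[(hit - 1) %% nrow(p) + 1],
         post = post_c$id[(hit - 1) %/% nrow(p) + 1])
}

static_synapse_rows <- function(edges, g, receptor, delay, tau_rise, tau_decay) {
  if (nrow(edges) == 0) return(empty_synapses())
  tibble(pre = edges$pre, post = edges$post, class_index = NA_integer_,
         g = g, tau_rise = tau_rise, tau_decay = tau_decay,
         tau_kernel = tau_decay, U = 1, D = 0, F = 0, delay = delay,
         receptor = receptor, erev = erev_for_receptor(receptor),
         depclass = NA_character_)
}

#' Thalamic synaptic kinetics defaults
#'
#' Dual-exponential time constants (ms) and peak conductances (nS) for the
#' intrathalamic projections. GABA_B is approximated by a slow linear
#' dual-exponential kernel. These values are calibration parameters (the
#' connection weights were optimization targets in the source data), tuned so
#' the isolated thalamic network sustains rhythmic bursting near 6 Hz.
#'
#' @return Named list of kinetic and weight defaults.
#' @export
thalamic_synapse_defaults <- function() {
  list(ampa_tau_rise = 0.2, ampa_tau_decay = 2,
       gabaa_tau_rise = 0.2, gabaa_tau_decay = 10,
       gabab_tau_rise = 10, gabab_tau_decay = 35,
       g_relay_rtn = 12.0,   # relay -> RTN (AMPA)
       g_rtn_relay = 6.0,    # RTN -> relay (split GABA_A + GABA_B)
       g_rtn_rtn = 0.8)      # RTN -> RTN (GABA_A)
}

#' Build intrathalamic wiring
#'
#' Three strategies: (1) topological footprint wiring between first-order
#' nuclei and their preferred RTN sector (RTNo<->VPL, RTNm<->VPM by default);
#' (2) sector-specific distance-dependent wiring within each RTN sector; (3) a
#' divergence rule for all higher-order (POm) edges - each source projects to
#' a fixed number of targets with no spatial constraint. Receptors: RTN->RTN
#' GABA_A; RTN->relay a GABA_A + GABA_B combination with equal weight;
#' relay->RTN AMPA.
#'
#' @param cells Cell tibble containing the six thalamic populations.
#' @param footprints Footprint tibble (see [default_footprints()]).
#' @param divergence Fixed out-degree for higher-order edges (explored values
#'   5, 10, 20, 40).
#' @param sector_map Named map RTN sector -> preferred nucleus.
#' @param syn Kinetics/weights from [thalamic_synapse_defaults()].
#' @param delay Synaptic delay (ms).
#' @param seed Integer seed.
#' @return A synapse tibble.
#' @export
build_intrathalamic <- function(cells, footprints = default_footprints(),
                                divergence = 20,
                                sector_map = c(RTNo = "VPL", RTNm = "VPM",
                                               RTNi = "POm"),
                                syn = thalamic_synapse_defaults(),
                                delay = 1, seed = 1) {
  pops <- unique(cells$population)
  needed <- c(names(sector_map), unname(sector_map))
  if (length(setdiff(needed, pops)) > 0)
    abort(paste0("missing thalamic population(s): ",
                 paste(setdiff(needed, pops), collapse = ", ")))
  pop_cells <- function(p) cells[cells$population == p, ]
  mid_y <- population_depth_midpoints(cells)
  fp <- function(proj) footprints[footprints$projection == proj, ]
  gaba_split <- function(edges, g, delay) {
    bind_rows(
      static_synapse_rows(edges, g / 2, "GABA_A", delay,
                          syn$gabaa_tau_rise, syn$gabaa_tau_decay),
      static_synapse_rows(edges, g / 2, "GABA_B", delay,
                          syn$gabab_tau_rise, syn$gabab_tau_decay))
  }
  with_seed(seed, {
    out <- list()
    for (sector in names(sector_map)) {
      nucleus <- sector_map[[sector]]
      rtn <- pop_cells(sector)
      rel <- pop_cells(nucleus)
      if (nucleus == "POm") {
        # strategy 3: fixed divergence, no spatial constraint
        e1 <- divergence_connect(rtn, rel, divergence)
        e2 <- divergence_connect(rel, rtn, divergence)
        out <- c(out, list(
          gaba_split(e1, syn$g_rtn_relay, delay),
          static_synapse_rows(e2, syn$g_relay_rtn, "AMPA", delay,
                              syn$ampa_tau_rise, syn$ampa_tau_decay)))
      } else {
        # strategy 1: topological footprints
        f1 <- fp(paste0("RTN->", nucleus))
        e1 <- footprint_connect(rtn, rel, f1$radius, f1$p0, f1$y_fraction,
                                f1$lambda, mid_y[[sector]], mid_y[[nucleus]])
        f2 <- fp(paste0(nucleus, "->RTN"))
        e2 <- footprint_connect(rel, rtn, f2$radius, f2$p0, f2$y_fraction,
                                f2$lambda, mid_y[[nucleus]], mid_y[[sector]])
        out <- c(out, list(
          gaba_split(e1, syn$g_rtn_relay, delay),
          static_synapse_rows(e2, syn$g_relay_rtn, "AMPA", delay,
                              syn$ampa_tau_rise, syn$ampa_tau_decay)))
      }
      # strategy 2: within-sector RTN->RTN
      f3 <- fp("RTN->RTN")
      e3 <- footprint_connect(rtn, rtn, f3$radius, f3$p0, f3$y_fraction,
                              f3$lambda, mid_y[[sector]], mid_y[[sector]])
      out <- c(out, list(
        static_synapse_rows(e3, syn$g_rtn_rtn, "GABA_A", delay,
                            syn$gabaa_tau_rise, syn$gabaa_tau_decay)))
    }
    bind_rows(out)
  })
}

#' Depth midpoints per population
#'
#' The box-alignment convention used by the footprint wiring: each
#' population's depth offset is measured from the midpoint of its occupied
#' depth range.
#'
#' @param cells Cell tibble.
#' @return Named numeric vector of midpoints (um) keyed by population.
#' @export
population_depth_midpoints <- function(cells) {
  vapply(split(cells$y, cells$population), function(y) mean(range(y)),
         numeric(1))
}

# strategy 3: exact out-degree, uniform targets, no self-edges
divergence_connect <- function(pre_c, post_c, n_targets) {
  if (nrow(pre_c) == 0 || nrow(post_c) == 0)
    return(tibble(pre = integer(), post = integer()))
  out <- lapply(seq_len(nrow(pre_c)), function(i) {
    cand <- setdiff(post_c$id, pre_c$id[i])
    k <- min(n_targets, length(cand))
    tibble(pre = pre_c$id[i], post = sample(cand, k))
  })
  bind_rows(out)
}

#' Build corticothalamic feedback wiring
#'
#' Feedback originates from the L5_TTPC2 and L6_TPC_L4 m-types. Each thalamic
#' target receives a fixed convergence of sources sampled uniformly without
#' replacement among eligible cortical cells within the maximum XZ distance;
#' targets with fewer candidates take all of them (with a warning when a
#' target has none).
#'
#' @param cells Combined cell tibble (cortex + thalamus).
#' @param convergence Number of presynaptic sources per thalamic cell.
#' @param max_dist Maximum XZ distance (um).
#' @param source_m_types Eligible cortical m-types.
#' @param targets Thalamic populations receiving feedback.
#' @param g Peak conductance (nS).
#' @param delay Synaptic delay (ms).
#' @param seed Integer seed.
#' @return A synapse tibble (AMPA).
#' @export
build_corticothalamic <- function(cells, convergence = 30, max_dist = 50,
                                  source_m_types = c("TTPC2", "TPC_L4"),
                                  targets = c("VPL", "VPM", "POm"),
                                  g = 1.0, delay = 2, seed = 1) {
  src <- cells[cells$m_type %in% source_m_types, ]
  if (nrow(src) == 0) abort("no corticothalamic source cells present")
  tgt <- cells[cells$population %in% targets, ]
  with_seed(seed, {
    n_empty <- 0L
    out <- lapply(seq_len(nrow(tgt)), function(i) {
      d <- sqrt((src$x - tgt$x[i])^2 + (src$z - tgt$z[i])^2)
      cand <- src$id[d <= max_dist]
      if (length(cand) == 0) return(NULL)
      k <- min(convergence, length(cand))
      tibble(pre = if (k == length(cand)) cand else sample(cand, k),
             post = tgt$id[i])
    })
    n_empty <- sum(vapply(out, is.null, logical(1)))
    if (n_empty > 0)
      warn(sprintf("%d thalamic cell(s) had no corticothalamic candidates within %g um",
                   n_empty, max_dist))
    edges <- bind_rows(out)
    static_synapse_rows(edges, g, "AMPA", delay, 0.2, 2)
  })
}

#' Thalamic inhibitory convergence scaling factor
#'
#' The ratio of the thalamocortical inhibitory/excitatory innervation ratio to
#' the average population inhibitory/excitatory ratio:
#' `(vpm_inh / vpm_exc) / (pop_inh / pop_exc)`. With the tabulated counts
#' (83 / 775 and 4,779 / 26,567) this evaluates to approximately 0.595.
#'
#' @param vpm_inh,vpm_exc Thalamic synapse counts onto inhibitory / excitatory
#'   cortical cells.
#' @param pop_inh,pop_exc Inhibitory / excitatory population sizes.
#' @return The scaling factor (a real number).
#' @export
compute_ie_scaling_factor <- function(vpm_inh = 83, vpm_exc = 775,
                                      pop_inh = 4779, pop_exc = 26567) {
  if (any(c(vpm_inh, vpm_exc, pop_inh, pop_exc) <= 0))
    abort("all counts must be positive")
  (vpm_inh / vpm_exc) / (pop_inh / pop_exc)
}

#' Load the packaged (synthetic) thalamocortical convergence table
#'
#' Per-m-type convergence from VPL, VPM and POm. These values are a synthetic
#' fixture with the qualitative laminar structure of the source data
#' (strongest first-order input to L4, higher-order input biased to L1/L5/L23),
#' not measured values.
#'
#' @return Tibble: `m_type`, `layer`, `vpl`, `vpm`, `pom`.
#' @export
tc_convergence_table <- function() {
  read_tsv_strict(tcsim_extdata("tc_convergence_synthetic.tsv"))
}

#' Build thalamocortical projections
#'
#' Per cortical cell, the in-degree from each thalamic source population
#' equals the (scaled) convergence-table value; inhibitory targets'
#' convergence is multiplied by the inhibitory scaling factor (about 0.595),
#' rounded half-to-even. Every connection carries `nsyn` synapses (default 9)
#' with parameters sampled from the excitatory-depressing class used for
#' thalamocortical synapses (class 25).
#'
#' @param cells Combined cell tibble (cortex + thalamus).
#' @param registry Synapse registry.
#' @param convergence Convergence table (see [tc_convergence_table()]).
#' @param ie_factor Inhibitory-target scaling factor.
#' @param nsyn Synapses per connection.
#' @param convergence_scale Multiplier on table values (use the circuit scale
#'   for scaled-down columns).
#' @param tc_class Registry class index for TC synapses.
#' @param weight_scale Multiplier on sampled conductances.
#' @param delay Synaptic delay (ms).
#' @param seed Integer seed.
#' @return A synapse tibble.
#' @export
build_thalamocortical <- function(cells, registry,
                                  convergence = tc_convergence_table(),
                                  ie_factor = compute_ie_scaling_factor(),
                                  nsyn = 9, convergence_scale = 1,
                                  tc_class = 25, weight_scale = 1,
                                  delay = 2, seed = 1) {
  src_pops <- c(vpl = "VPL", vpm = "VPM", pom = "POm")
  ctx <- cells[!cells$population %in% c(src_pops, "RTNo", "RTNm", "RTNi"), ]
  # convergence rows are keyed by the layer-qualified m-type (e.g. L23_PC)
  ctx_key <- paste(ctx$layer, ctx$m_type, sep = "_")
  missing_mt <- setdiff(unique(ctx_key), convergence$m_type)
  if (length(missing_mt) > 0)
    abort(paste0("convergence table lacks m-type(s): ",
                 paste(missing_mt, collapse = ", ")))
  conv_row <- convergence[match(ctx_key, convergence$m_type), ]
  with_seed(seed, {
    out <- list()
    for (col in names(src_pops)) {
      src_ids <- cells$id[cells$population == src_pops[[col]]]
      if (length(src_ids) == 0) next
      k_target <- conv_row[[col]] * convergence_scale *
        ifelse(ctx$excitatory, 1, ie_factor)
      k_target <- pmin(round_half_even(k_target), length(src_ids))
      keep <- which(k_target > 0)
      edges <- lapply(keep, function(i) {
        tibble(pre = sample(src_ids, k_target[i]), post = ctx$id[i])
      })
      edges <- bind_rows(edges)
      if (nrow(edges) == 0) next
      edge_of_syn <- rep(seq_len(nrow(edges)), each = nsyn)
      params <- sample_synapse_params(registry, tc_class,
                                      n = length(edge_of_syn))
      params$pre <- edges$pre[edge_of_syn]
      params$post <- edges$post[edge_of_syn]
      params$tau_kernel <- registry$tau_decay_mean[registry$index == tc_class]
      params$g <- params$g_syn * weight_scale
      params$delay <- delay
      params$erev <- erev_for_receptor(params$receptor)
      post_rows <- match(params$post, cells$id)
      params$depclass <- dependence_class(rep(TRUE, nrow(params)),
                                          cells$m_type[post_rows],
                                          cells$excitatory[post_rows])
      out <- c(out, list(params[, names(empty_synapses())]))
    }
    bind_rows(out)
  })
}

#' Attach Poisson background drive
#'
#' Each targeted cell receives `n_sources` independent excitatory and
#' `n_sources` inhibitory Poisson spike sources with the given per-source
#' rates and quantal conductances (the quantal values are free calibration
#' parameters). Rates of zero disable the corresponding sources.
#'
#' @param circuit A `tc_circuit`.
#' @param exc_rate,inh_rate Per-source rates (Hz).
#' @param n_sources Sources per cell and polarity.
#' @param g_exc,g_inh Quantal peak conductances (nS).
#' @param populations Populations to target (default all).
#' @return The circuit with a background specification attached.
#' @export
attach_background <- function(circuit, exc_rate, inh_rate = 0, n_sources = 10,
                              g_exc = 1.0, g_inh = 1.0, populations = NULL) {
  if (exc_rate < 0 || inh_rate < 0) abort("background rates must be >= 0")
  ids <- if (is.null(populations)) circuit$cells$id
         else circuit$cells$id[circuit$cells$population %in% populations]
  spec <- tibble(id = ids, n_sources = n_sources, exc_rate = exc_rate,
                 inh_rate = inh_rate, g_exc = g_exc, g_inh = g_inh)
  old <- circuit$background
  if (!is.null(old)) {
    old <- old[!old$id %in% ids, ]
    spec <- bind_rows(old, spec)
  }
  circuit$background <- spec
  circuit
}

#' Realize background sources as explicit spike trains
#'
#' Draws the per-source Poisson trains implied by the attached background
#' specification (used for fixtures and bookkeeping checks; the engine itself
#' generates background events on the fly from the same rates).
#'
#' @param circuit Circuit with background attached.
#' @param duration Duration (ms).
#' @param seed Integer seed.
#' @return Tibble: `id`, `source`, `polarity`, `time`.
#' @export
background_spike_trains <- function(circuit, duration, seed = 1) {
  bg <- circuit$background
  if (is.null(bg)) abort("circuit has no background attached")
  with_seed(seed, {
    one <- function(id, n_sources, exc_rate, inh_rate, ...) {
      draws <- lapply(seq_len(n_sources), function(s) {
        n_e <- rpois(1, exc_rate * duration / 1000)
        n_i <- rpois(1, inh_rate * duration / 1000)
        bind_rows(
          tibble(id = id, source = s, polarity = "exc",
                 time = runif(n_e, 0, duration)),
          tibble(id = id, source = s, polarity = "inh",
                 time = runif(n_i, 0, duration)))
      })
      bind_rows(draws)
    }
    arrange(bind_rows(purrr::pmap(bg, one)), .data$time)
  })
}
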