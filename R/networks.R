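#' Build a scaled thalamic circuit
#'
#' Places the six thalamic populations (three RTN sectors and the VPL, VPM and
#' POm nuclei, POm at half density) in stacked boxes, wires them with the
#' three intrathalamic strategies, and attaches Poisson background drive.
#'
#' @param scale Population scale in (0, 1].
#' @param seed Integer seed (placements, wiring and background all derive from
#'   it).
#' @param divergence Fixed out-degree of higher-order (POm) edges.
#' @param syn Kinetics/weights from [thalamic_synapse_defaults()].
#' @param footprints Footprint rules (see [default_footprints()]).
#' @param bg_exc_rate Per-source background rate (Hz).
#' @param bg_g Background quantal conductance (nS).
#' @return A `tc_circuit` with background attached.
#' @export
build_thalamic_circuit <- function(scale = 0.1, seed = 1, divergence = 20,
                                   syn = thalamic_synapse_defaults(),
                                   footprints = default_footprints(),
                                   bg_exc_rate = 8, bg_g = 4) {
  counts <- thalamic_cell_counts(scale)
  cells <- place_thalamic_cells(counts, seed = seed)
  circuit <- new_circuit(cells, default_params_map(cells))
  circuit <- add_synapses(circuit,
    build_intrathalamic(cells, footprints = footprints,
                        divergence = divergence, syn = syn, seed = seed + 1))
  # background stands in for non-modeled afferents, which target the relay
  # nuclei; RTN sectors are driven by relay (and cortical) input
  attach_background(circuit, exc_rate = bg_exc_rate, inh_rate = 0,
                    g_exc = bg_g, g_inh = 0,
                    populations = c("VPL", "VPM", "POm"))
}

#' Build a scaled cortical column
#'
#' The full construction pipeline at configurable scale: place cells in the
#' layered cylinder, generate synthetic connectome instances from the default
#' ground-truth pathway curves, estimate distance-binned probabilities, fit and
#' select the probability rules, instantiate the connectome from the fitted
#' rules with registry synapse classes, and attach tuned background drive.
#' Synaptic conductances are compensated for the reduced in-degree of a scaled
#' column by `1 / scale` unless `weight_scale` is given.
#'
#' @param scale Column scale in (0, 1].
#' @param seed Integer seed.
#' @param registry Synapse registry.
#' @param pathways Ground-truth pathway table (see
#'   [default_cortical_pathways()]).
#' @param n_instances Connectome instances to generate and average.
#' @param rules Optional pre-fitted rules (skips instance generation).
#' @param weight_scale Conductance multiplier (default `1 / scale`).
#' @param bg_exc_rate,bg_inh_rate Per-source background rates (Hz).
#' @param bg_g_exc,bg_g_inh Background quantal conductances (nS).
#' @return A `tc_circuit` with background attached; the fitted rules are
#'   attached as attribute `"rules"`.
#' @export
build_cortical_column <- function(scale = 0.1, seed = 1,
                                  registry = load_synapse_table(),
                                  pathways = default_cortical_pathways(),
                                  n_instances = 7, rules = NULL,
                                  weight_scale = NULL,
                                  bg_exc_rate = 15, bg_inh_rate = 4,
                                  bg_g_exc = 4, bg_g_inh = 4) {
  cells <- place_cortical_cells(gen_cell_counts(scale), seed = seed)
  cells <- add_pathway_groups(cells)
  if (is.null(rules)) {
    inst <- gen_connectome_instances(cells, pathways,
                                     n_instances = n_instances,
                                     seed = seed + 1,
                                     group_col = "pathway_group")
    rules <- fit_pathway_rules(inst, cells)
  }
  if (is.null(weight_scale)) weight_scale <- 1 / scale
  synapses <- build_cortical_connectome(cells, rules, registry,
                                        seed = seed + 2,
                                        weight_scale = weight_scale)
  circuit <- new_circuit(cells, default_params_map(cells), synapses)
  circuit <- attach_background(circuit, exc_rate = bg_exc_rate,
                               inh_rate = bg_inh_rate, g_exc = bg_g_exc,
                               g_inh = bg_g_inh)
  attr(circuit, "rules") <- rules
  circuit
}

#' Combine cortical and thalamic circuits with bidirectional wiring
#'
#' Stacks the two cell tables (thalamic ids offset above the cortical ones),
#' keeps both synapse tables and backgrounds, and adds corticothalamic
#' feedback and thalamocortical projections.
#'
#' @param cortex,thalamus `tc_circuit` objects from [build_cortical_column()]
#'   and [build_thalamic_circuit()].
#' @param registry Synapse registry.
#' @param scale The common scale (drives thalamocortical convergence scaling).
#' @param seed Integer seed.
#' @param tc_weight_scale Conductance multiplier for TC synapses.
#' @return A combined `tc_circuit`.
#' @export
build_full_circuit <- function(cortex, thalamus, registry = load_synapse_table(),
                               scale = 0.1, seed = 1, tc_weight_scale = NULL) {
  offset <- max(cortex$cells$id)
  th_cells <- thalamus$cells
  old_ids <- th_cells$id
  th_cells$id <- th_cells$id + offset
  remap <- setNames(th_cells$id, old_ids)
  th_syn <- thalamus$synapses
  th_syn$pre <- unname(remap[as.character(th_syn$pre)])
  th_syn$post <- unname(remap[as.character(th_syn$post)])
  cells <- bind_rows(cortex$cells, th_cells)
  params <- c(cortex$params,
              thalamus$params[setdiff(names(thalamus$params),
                                      names(cortex$params))])
  circuit <- new_circuit(cells, params,
                         bind_rows(cortex$synapses, th_syn))
  bg_th <- thalamus$background
  if (!is.null(bg_th)) bg_th$id <- unname(remap[as.character(bg_th$id)])
  circuit$background <- bind_rows(cortex$background, bg_th)
  if (is.null(tc_weight_scale)) tc_weight_scale <- 1 / scale
  circuit <- add_synapses(circuit,
    build_corticothalamic(cells, seed = seed + 3))
  circuit <- add_synapses(circuit,
    build_thalamocortical(cells, registry, convergence_scale = scale,
                          weight_scale = tc_weight_scale, seed = seed + 4))
  circuit
}
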