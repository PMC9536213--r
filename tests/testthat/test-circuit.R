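small_column <- function(n = 60, seed = 1) {
  cells <- place_cortical_cells(gen_cell_counts(0.002), seed = seed)
  add_pathway_groups(cells)
}

test_that("a certain rule with one synapse yields the complete digraph", {
  cells <- disc_cells(12)
  cells$pathway_group <- "P"
  rules <- constant_rule("P", "P", p = 1, mean_nsyn = 1)
  syn <- build_cortical_connectome(cells, rules, tc_reg, seed = 1)
  expect_equal(nrow(syn), 12 * 11)
  expect_true(all(syn$pre != syn$post))
  expect_true(all(syn$class_index == 22))  # L5_TTPC:L5_TTPC exemplars
  syn2 <- build_cortical_connectome(cells, rules, tc_reg, seed = 1)
  expect_identical(syn$pre, syn2$pre)
  expect_identical(syn$g, syn2$g)
  syn3 <- build_cortical_connectome(cells, rules, tc_reg, seed = 2)
  expect_false(identical(syn$g, syn3$g))
})

test_that("realized connectome sizes match the expected-count oracle", {
  cells <- disc_cells(40, seed = 9)
  cells$pathway_group <- "P"
  gt <- ground_truth_pathway("exponential", c(0.4, 120))
  fit <- fit_probability_model(profile_from_curve(gt), "exponential")
  rules <- tibble::tibble(pre = "P", post = "P", form = "exponential",
                          params = list(fit$params), sse = fit$sse,
                          mean_nsyn = 1, fit = list(fit))
  mu <- expected_connection_count(fit, cells, cells)
  d <- xz_distance(cells, cells)
  p <- matrix(predict(fit, as.vector(d)), nrow = nrow(d)); diag(p) <- 0
  sigma <- sqrt(sum(p * (1 - p)))
  counts <- vapply(1:100, function(s) {
    nrow(build_cortical_connectome(cells, rules, tc_reg, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - mu), 3 * sigma / sqrt(100))
})

test_that("missing pathway rules are rejected by name", {
  cells <- small_column()
  rules <- constant_rule("L5E", "L5E")
  expect_error(build_cortical_connectome(cells, rules, tc_reg),
               "no pathway rule")
})

test_that("footprint wiring is truncated in radius and aligned depth", {
  cells <- place_thalamic_cells(thalamic_cell_counts(0.2), seed = 3)
  syn <- build_intrathalamic(cells, seed = 5)
  fp <- default_footprints()
  pos <- cells[, c("id", "population", "x", "y", "z")]
  mids <- population_depth_midpoints(cells)
  syn <- dplyr::distinct(syn, pre, post)
  syn <- dplyr::left_join(syn, pos, by = c(pre = "id"))
  syn <- dplyr::left_join(syn, pos, by = c(post = "id"),
                          suffix = c("_pre", "_post"))
  dxz <- sqrt((syn$x_pre - syn$x_post)^2 + (syn$z_pre - syn$z_post)^2)
  dy <- abs((syn$y_pre - mids[syn$population_pre]) -
              (syn$y_post - mids[syn$population_post]))
  proj <- dplyr::case_when(
    syn$population_pre == "RTNo" & syn$population_post == "VPL" ~ "RTN->VPL",
    syn$population_pre == "RTNm" & syn$population_post == "VPM" ~ "RTN->VPM",
    syn$population_pre == "VPL" ~ "VPL->RTN",
    syn$population_pre == "VPM" ~ "VPM->RTN",
    syn$population_pre == syn$population_post ~ "RTN->RTN",
    TRUE ~ NA_character_)
  for (pr in stats::na.omit(unique(proj))) {
    r <- fp$radius[fp$projection == pr]
    sel <- !is.na(proj) & proj == pr
    expect_true(all(dxz[sel] <= r))
    expect_true(all(dy[sel] <= 0.1 * r + 1e-9))
  }
})

test_that("within-sector wiring never crosses RTN sector boundaries", {
  cells <- place_thalamic_cells(thalamic_cell_counts(0.2), seed = 3)
  syn <- build_intrathalamic(cells, seed = 5)
  pop <- setNames(cells$population, cells$id)
  rtn <- c("RTNo", "RTNm", "RTNi")
  intra <- syn[pop[as.character(syn$pre)] %in% rtn &
                 pop[as.character(syn$post)] %in% rtn, ]
  expect_gt(nrow(intra), 0)
  expect_true(all(pop[as.character(intra$pre)] == pop[as.character(intra$post)]))
})

test_that("higher-order edges follow the exact divergence rule", {
  cells <- place_thalamic_cells(thalamic_cell_counts(0.2), seed = 3)
  syn <- build_intrathalamic(cells, divergence = 20, seed = 5)
  pop <- setNames(cells$population, cells$id)
  pom_out <- syn[pop[as.character(syn$pre)] == "POm", ]
  deg <- table(pom_out$pre)
  expect_true(all(deg == 20))
  # every POm cell is a source
  expect_equal(length(deg), sum(cells$population == "POm"))
  # receptors: POm->RTN is AMPA, RTN->POm is the GABA_A + GABA_B split
  expect_true(all(pom_out$receptor == "AMPA"))
  rtn_pom <- syn[pop[as.character(syn$pre)] == "RTNi" &
                   pop[as.character(syn$post)] == "POm", ]
  expect_setequal(unique(rtn_pom$receptor), c("GABA_A", "GABA_B"))
  ga <- rtn_pom[rtn_pom$receptor == "GABA_A", ]
  gb <- rtn_pom[rtn_pom$receptor == "GABA_B", ]
  expect_equal(nrow(ga), nrow(gb))
  expect_equal(sum(ga$g), sum(gb$g))  # equal weight split
})

test_that("corticothalamic feedback has exact convergence within 50 um", {
  ctx <- place_cortical_cells(gen_cell_counts(0.15), seed = 2)
  th <- place_thalamic_cells(thalamic_cell_counts(0.05), seed = 3,
                             id_offset = max(ctx$id))
  cells <- dplyr::bind_rows(ctx, th)
  suppressWarnings(syn <- build_corticothalamic(cells, convergence = 10,
                                                seed = 4))
  src <- cells[cells$id %in% syn$pre, ]
  expect_true(all(src$m_type %in% c("TTPC2", "TPC_L4")))
  deg <- dplyr::count(syn, post)
  expect_true(all(deg$n <= 10))
  # targets with enough candidates receive exactly 10
  tgt <- cells[match(deg$post, cells$id), ]
  cand <- vapply(seq_len(nrow(tgt)), function(i) {
    s <- cells[cells$m_type %in% c("TTPC2", "TPC_L4"), ]
    sum(sqrt((s$x - tgt$x[i])^2 + (s$z - tgt$z[i])^2) <= 50)
  }, numeric(1))
  expect_true(all(deg$n[cand >= 10] == 10))
  expect_true(all(deg$n[cand < 10] == cand[cand < 10]))
})

test_that("thalamocortical projections scale convergence and carry 9 synapses", {
  ctx <- place_cortical_cells(gen_cell_counts(0.01), seed = 2)
  th <- place_thalamic_cells(thalamic_cell_counts(0.3), seed = 3,
                             id_offset = max(ctx$id))
  cells <- dplyr::bind_rows(ctx, th)
  conv <- tc_convergence_table()
  conv$vpl <- 0; conv$pom <- 0; conv$vpm <- 100
  syn <- build_thalamocortical(cells, tc_reg, convergence = conv,
                               convergence_scale = 1, seed = 6)
  per_edge <- dplyr::count(syn, pre, post)
  expect_true(all(per_edge$n == 9))
  indeg <- dplyr::count(dplyr::distinct(syn, pre, post), post)
  tgt <- cells[match(indeg$post, cells$id), ]
  expect_true(all(indeg$n[tgt$excitatory] == 100))
  expect_true(all(indeg$n[!tgt$excitatory] == 60))  # round(100 * 0.595)
  expect_true(all(syn$class_index == 25))
  expect_true(all(syn$receptor == "AMPA"))
})

test_that("the inhibitory scaling factor reproduces the tabulated arithmetic", {
  expect_equal(round(83 / 775, 3), 0.107)
  expect_equal(round(4779 / 26567, 3), 0.180)
  expect_equal(compute_ie_scaling_factor(), 0.595, tolerance = 0.001)
  expect_error(compute_ie_scaling_factor(vpm_exc = 0), "positive")
})

test_that("background specifications generate calibrated Poisson sources", {
  cells <- disc_cells(30)
  cir <- new_circuit(cells, list(P = cortical_exc_params()))
  cir <- attach_background(cir, exc_rate = 5, inh_rate = 0, n_sources = 10)
  expect_true(all(cir$background$n_sources == 10))
  trains <- background_spike_trains(cir, duration = 2000, seed = 8)
  expect_equal(sort(unique(trains$source)), 1:10)
  lambda <- 30 * 10 * 5 * 2  # cells x sources x rate x seconds
  expect_lt(abs(nrow(trains) - lambda), 3 * sqrt(lambda))
  cir0 <- attach_background(cir, exc_rate = 0, inh_rate = 0)
  expect_equal(nrow(background_spike_trains(cir0, 1000, seed = 1)), 0)
})
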