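quiet_circuit <- function(n = 5) {
  cells <- disc_cells(n)
  new_circuit(cells, list(P = cortical_exc_params()))
}

test_that("an unconnected circuit with zero input stays silent", {
  sim <- run_simulation(quiet_circuit(),
                        simulation_config(duration = 500, transient = 100,
                                          seed = 1))
  expect_equal(nrow(sim$spikes), 0)
})

test_that("spike records are bit-identical under a fixed seed", {
  cir <- attach_background(quiet_circuit(20), exc_rate = 40, inh_rate = 5,
                           g_exc = 5, g_inh = 5)
  cfg <- simulation_config(duration = 2000, transient = 100, seed = 77)
  a <- run_simulation(cir, cfg)
  b <- run_simulation(cir, cfg)
  expect_identical(a$spikes, b$spikes)
  expect_gt(nrow(a$spikes), 0)
  cfg2 <- simulation_config(duration = 2000, transient = 100, seed = 78)
  expect_false(identical(run_simulation(cir, cfg2)$spikes, a$spikes))
})

test_that("no synaptic effect precedes emission time plus delay", {
  cells <- disc_cells(2)
  syn <- empty_synapses()
  syn[1, ] <- list(1L, 2L, NA_integer_, 3, 0.2, 2, 2, 1, 0, 0, 5,
                   "AMPA", 0, NA_character_)
  cir <- new_circuit(cells, list(P = cortical_exc_params()), syn)
  cir$replay <- tibble::tibble(id = 1L, time = 50)
  cfg <- simulation_config(duration = 100, transient = 1, seed = 1,
                           record_current = 2L, record_dt = 0.1)
  sim <- run_simulation(cir, cfg)
  before <- sim$i_syn$i[sim$i_syn$time < 55]
  after <- sim$i_syn$i[sim$i_syn$time >= 55.2 & sim$i_syn$time < 60]
  expect_true(all(before == 0))
  expect_gt(max(abs(after)), 0)
})

test_that("hybrid replay reduces to the full run and enforces coverage", {
  cir <- attach_background(quiet_circuit(15), exc_rate = 40, inh_rate = 0,
                           g_exc = 5)
  cfg <- simulation_config(duration = 1500, transient = 100, seed = 5)
  full <- run_simulation(cir, cfg)
  # detailed subset = all cells: identical output
  all_detailed <- run_hybrid(cir, detailed_ids = cir$cells$id,
                             replay_spikes = full$spikes[0, ], config = cfg,
                             replay_ids = integer(0))
  expect_identical(all_detailed$spikes, full$spikes)
  # detailed subset = none: pure passthrough of the replay
  none <- run_hybrid(cir, detailed_ids = integer(0),
                     replay_spikes = full$spikes, config = cfg,
                     replay_ids = cir$cells$id)
  expect_equal(nrow(none$spikes), nrow(full$spikes))
  expect_equal(sort(none$spikes$time), sort(full$spikes$time),
               tolerance = 1e-6)
  # missing trains are rejected
  expect_error(run_hybrid(cir, detailed_ids = cir$cells$id[1:2],
                          replay_spikes = full$spikes[0, ], config = cfg,
                          replay_ids = integer(0)),
               "replay trains missing")
})

test_that("hybrid detailed cells receive exactly the source-run inputs", {
  cells <- disc_cells(10)
  cells$pathway_group <- "P"
  rules <- constant_rule("P", "P", p = 1, mean_nsyn = 1)
  syn <- build_cortical_connectome(cells, rules, tc_reg, seed = 3)
  cir <- new_circuit(cells, list(P = cortical_exc_params()), syn)
  cir <- attach_background(cir, exc_rate = 50, inh_rate = 0, g_exc = 5)
  cfg <- simulation_config(duration = 1200, transient = 100, seed = 9)
  full <- run_simulation(cir, cfg)
  detailed <- cells$id[1:2]
  hyb <- run_hybrid(cir, detailed, full$spikes[!full$spikes$id %in% detailed, ],
                    cfg, replay_ids = cells$id[-(1:2)])
  # input spike count bookkeeping: replayed presynaptic spikes match the
  # source run exactly for every non-detailed cell
  src_counts <- table(full$spikes$id[!full$spikes$id %in% detailed])
  hyb_counts <- table(hyb$spikes$id[!hyb$spikes$id %in% detailed])
  expect_equal(as.vector(src_counts), as.vector(hyb_counts))
})

test_that("grid search returns the exhaustive argmin", {
  cir <- quiet_circuit(12)
  cfg <- simulation_config(duration = 1500, transient = 500, seed = 3)
  single <- grid_search_background(cir, exc_rates = 30, inh_rates = 0,
                                   config = cfg, bg_args = list(g_exc = 5))
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best$exc_rate, 30)

  res <- grid_search_background(cir, exc_rates = c(10, 30, 60),
                                inh_rates = c(0, 5), config = cfg,
                                bg_args = list(g_exc = 5, g_inh = 5))
  expect_equal(nrow(res$table), 6)
  expect_equal(res$best$objective, min(res$table$objective))
  # monotone toy: the mean rate grows with drive
  rate_of <- function(er) {
    sim <- run_simulation(attach_background(cir, er, 0, g_exc = 5), cfg)
    glance(sim)$mean_rate
  }
  rates <- vapply(c(10, 30, 60), rate_of, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("halving dt changes population rate by less than 5%", {
  cir <- attach_background(quiet_circuit(15), exc_rate = 40, inh_rate = 0,
                           g_exc = 5)
  r1 <- glance(run_simulation(cir, simulation_config(duration = 3000,
                                                     transient = 500,
                                                     dt = 0.1, seed = 4)))
  r2 <- glance(run_simulation(cir, simulation_config(duration = 3000,
                                                     transient = 500,
                                                     dt = 0.05, seed = 4)))
  expect_lt(abs(r1$mean_rate - r2$mean_rate) / r2$mean_rate, 0.05)
})
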