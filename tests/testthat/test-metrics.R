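fake_cells <- function(n, population = "P") {
  tibble::tibble(id = seq_len(n), population = population, me_type = "m",
                 m_type = "m", e_type = "e", layer = "L", x = 0, y = 0, z = 0,
                 excitatory = TRUE)
}

test_that("population rates are spikes per cell per second", {
  cells <- fake_cells(1)
  sp <- tibble::tibble(id = 1L, time = seq(100, 1050, by = 100))
  pr <- population_rates(sp, cells, window = c(50, 1050))
  expect_equal(pr$mean_rate, 10)
  pr0 <- population_rates(sp[0, ], cells, window = c(0, 1000))
  expect_equal(pr0$mean_rate, 0)
  expect_true(pr0$empty)
})

test_that("rate estimates match a Poisson oracle and add over windows", {
  cells <- fake_cells(100)
  sp <- gen_poisson_trains(cells$id, rate = 5, duration = 4000, seed = 6)
  pr <- population_rates(sp, cells, window = c(0, 4000))
  se <- sqrt(5 / (100 * 4))
  expect_lt(abs(pr$mean_rate - 5), 3 * se)
  # additivity: weighted mean of disjoint windows equals the full window
  a <- population_rates(sp, cells, c(0, 1000))$mean_rate
  b <- population_rates(sp, cells, c(1000, 4000))$mean_rate
  expect_equal((a * 1 + b * 3) / 4, pr$mean_rate, tolerance = 1e-9)
})

test_that("ISI CV separates periodic from Poisson firing", {
  periodic <- tibble::tibble(id = 1L, time = seq(0, 5000, by = 50))
  expect_equal(isi_cv(periodic)$cv, 0)
  pois <- gen_poisson_trains(1L, rate = 40, duration = 60000, seed = 3)
  cv <- isi_cv(pois)$cv
  n <- nrow(pois)
  expect_lt(abs(cv - 1), 3 / sqrt(n))
  # cells with too few spikes are excluded and counted
  two <- tibble::tibble(id = c(1L, 1L, 2L, 2L, 2L),
                        time = c(1, 2, 1, 2, 3))
  out <- isi_cv(two)
  expect_equal(out$id, 2L)
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("oscillation analysis finds constructed rhythms", {
  # all cells spiking at exactly 6 Hz in phase
  n <- 50
  times <- seq(0, 10000, by = 1000 / 6)
  sp <- tibble::tibble(id = rep(seq_len(n), each = length(times)),
                       time = rep(times, n))
  osc <- oscillation_peak(sp, n, band = c(1, 15), window = c(0, 10000))
  expect_equal(osc$peak_freq, 6, tolerance = 0.1)
  expect_gt(osc$synchrony, 0.9)

  # independent Poisson: synchrony near zero
  sp2 <- gen_poisson_trains(1:100, rate = 8, duration = 10000, seed = 2)
  osc2 <- oscillation_peak(sp2, 100, band = c(1, 15), window = c(0, 10000))
  expect_lt(osc2$synchrony, 0.1)

  # 1 Hz comodulated fixture: rate-modulated Poisson by thinning
  sp3 <- withr::with_seed(4, {
    cand <- gen_poisson_trains(1:100, rate = 20, duration = 12000, seed = 11)
    keep <- runif(nrow(cand)) < 0.5 * (1 + sin(2 * pi * cand$time / 1000))
    cand[keep, ]
  })
  osc3 <- oscillation_peak(sp3, 100, band = c(1, 15), window = c(0, 12000),
                           bin = 10)
  expect_equal(osc3$peak_freq, 1, tolerance = 0.15)
  expect_error(oscillation_peak(sp2, 100, band = c(1, 15), window = c(0, 5000)),
               "10 cycles")
})

test_that("synchrony is label-invariant and falls under shuffling", {
  times <- seq(0, 10000, by = 250)
  sp <- tibble::tibble(id = rep(1:20, each = length(times)),
                       time = rep(times, 20))
  osc_a <- oscillation_peak(sp, 20, band = c(1, 15), window = c(0, 10000))
  relabeled <- sp
  relabeled$id <- 21 - relabeled$id
  osc_b <- oscillation_peak(relabeled, 20, band = c(1, 15),
                            window = c(0, 10000))
  expect_equal(osc_a$synchrony, osc_b$synchrony, tolerance = 1e-12)
  shuffled <- sp
  shuffled$time <- withr::with_seed(9, runif(nrow(sp), 0, 10000))
  osc_c <- oscillation_peak(shuffled, 20, band = c(1, 15),
                            window = c(0, 10000))
  expect_lt(osc_c$synchrony, osc_a$synchrony)
})

test_that("burst detection recovers a constructed slow rhythm", {
  # 1 Hz population bursts: 50 cells each firing 5 spikes per burst
  burst_times <- seq(500, 9500, by = 1000)
  sp <- withr::with_seed(3, {
    tibble::tibble(
      id = rep(rep(1:50, each = 5), length(burst_times)),
      time = rep(burst_times, each = 250) + runif(250 * length(burst_times), 0, 30))
  })
  b <- detect_bursts(sp, 50, window = c(0, 10000))
  expect_equal(nrow(b), length(burst_times))
  expect_equal(burst_frequency(b), 1, tolerance = 0.05)
  expect_true(is.na(burst_frequency(b[1, ])))
})
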