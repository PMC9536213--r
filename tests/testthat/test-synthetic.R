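test_that("instance generation honors degenerate probability curves", {
  cells <- disc_cells(10)
  off <- tibble::tibble(pre = "P", post = "P",
                        gt = list(ground_truth_pathway("exponential", c(1e-12, 100),
                                                       mean_nsyn = 1)))
  inst <- gen_connectome_instances(cells, off, n_instances = 3, seed = 1)
  expect_true(all(vapply(inst$instances, nrow, integer(1)) == 0))

  # p identically 1: every ordered non-self pair connected
  on <- tibble::tibble(pre = "P", post = "P",
                       gt = list(ground_truth_pathway("exp_linsat",
                                                      c(5, 1e5, 1),
                                                      mean_nsyn = 1)))
  inst1 <- gen_connectome_instances(cells, on, n_instances = 2, seed = 1)
  for (edges in inst1$instances) {
    expect_equal(nrow(edges), 90)
    expect_true(all(edges$pre != edges$post))
  }
})

test_that("unknown pathway form is rejected by name", {
  expect_error(ground_truth_pathway("spline", c(1, 2)), "unknown pathway form")
})

test_that("empirical bin probabilities track the generating gaussian", {
  cells <- disc_cells(200, seed = 5)
  gt <- ground_truth_pathway("gaussian", c(0.2, 0, 100), mean_nsyn = 2)
  pw <- tibble::tibble(pre = "P", post = "P", gt = list(gt))
  inst <- gen_connectome_instances(cells, pw, n_instances = 7, seed = 9)
  profiles <- lapply(inst$instances, estimate_bin_probabilities,
                     placements = cells)
  pooled_conn <- Reduce(`+`, lapply(profiles, function(p) p$n_connected))
  pooled_pairs <- Reduce(`+`, lapply(profiles, function(p) p$n_pairs))
  # exact per-bin expectation: the generator probability averaged over the
  # actual pair distances falling in each bin
  d <- xz_distance(cells, cells)
  d <- d[outer(cells$id, cells$id, "!=")]
  bins <- distance_bins()
  idx <- findInterval(d, c(bins$centers - 25, max(bins$centers) + 25),
                      rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(bins$centers)
  p_bar <- vapply(seq_along(bins$centers), function(b) {
    mean(pathway_probability(gt, d[keep][idx[keep] == b]))
  }, numeric(1))
  ok <- pooled_pairs > 0
  se <- sqrt(p_bar * (1 - p_bar) / pooled_pairs)
  expect_true(all(abs(pooled_conn / pooled_pairs - p_bar)[ok] <= 3 * se[ok]))
})

test_that("fixtures are byte-identical under a fixed seed", {
  cells <- disc_cells(50)
  pw <- tibble::tibble(pre = "P", post = "P",
                       gt = list(ground_truth_pathway("exponential", c(0.5, 80))))
  a <- gen_connectome_instances(cells, pw, n_instances = 2, seed = 7)
  b <- gen_connectome_instances(cells, pw, n_instances = 2, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_edge_table(a$instances[[1]], f1)
  write_edge_table(b$instances[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$instances, b$instances)
  expect_equal(read_edge_table(f1)$pre, a$instances[[1]]$pre)
})

test_that("scaled cell counts keep the catalogue totals and floors", {
  expect_equal(sum(gen_cell_counts(1)$count), 31346)
  tiny <- gen_cell_counts(1e-6)
  expect_true(all(tiny$count == 1L))
  tenth <- gen_cell_counts(0.1)
  expect_lte(abs(sum(tenth$count) - 3135), nrow(tenth))
  expect_error(gen_cell_counts(0), "scale")
  expect_error(gen_cell_counts(-1), "scale")
})

test_that("toy cables produce the advertised current frames", {
  one <- gen_toy_cable(1, 100, waveform = function(t) 1, duration = 10,
                       balanced = FALSE)
  expect_true(all(one$currents == 1))

  bal <- gen_toy_cable(4, 200, waveform = function(t) sin(2 * pi * t / 20),
                       duration = 200, dt = 1)
  expect_true(all(abs(rowSums(bal$currents)) < 1e-14))

  # sine drive: discrete Fourier spectrum peaks at the drive frequency
  drive_hz <- 25
  sine <- gen_toy_cable(2, 100, waveform = function(t) sin(2 * pi * drive_hz * t / 1000),
                        duration = 2000, dt = 1)
  x <- sine$currents[, 1] - mean(sine$currents[, 1])
  P <- Mod(fft(x))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) * 1000 / n
  half <- 2:floor(n / 2)
  expect_equal(freqs[half][which.max(P[half])], drive_hz, tolerance = 0.03)
})

test_that("poisson train counts match the rate", {
  sp <- gen_poisson_trains(1:50, rate = 5, duration = 2000, seed = 4)
  lambda <- 50 * 5 * 2
  expect_lt(abs(nrow(sp) - lambda), 3 * sqrt(lambda))
  expect_true(!is.unsorted(sp$time))
  f <- tempfile()
  write_spike_trains(sp, f)
  expect_equal(read_spike_trains(f)$time, sp$time, tolerance = 1e-6)
})
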