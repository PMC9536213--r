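test_that("bin probabilities count ordered pairs per distance bin", {
  cells <- tibble::tibble(id = 1:2, population = "P", me_type = "m",
                          m_type = "m", e_type = "e", layer = "L5",
                          x = c(0, 30), y = 0, z = 0, excitatory = TRUE)
  edges <- tibble::tibble(pre = 1L, post = 2L)
  prof <- estimate_bin_probabilities(edges, cells, pre = 1, post = 2)
  expect_equal(prof$probability[prof$bin_center == 25], 1)
  expect_true(all(!prof$present[prof$bin_center != 25]))

  none <- estimate_bin_probabilities(edges[0, ], cells)
  expect_true(all(none$probability[none$present] == 0))

  expect_error(estimate_bin_probabilities(edges, cells[0, ]), "non-empty")
})

test_that("averaging across instances is the per-bin arithmetic mean", {
  cells <- disc_cells(30)
  prof <- estimate_bin_probabilities(tibble::tibble(pre = integer(),
                                                    post = integer()), cells)
  expect_identical(average_across_instances(list(prof, prof))$probability,
                   prof$probability)
  a <- prof; a$probability[a$present] <- 0
  b <- prof; b$probability[b$present] <- 1
  avg <- average_across_instances(list(a, b))
  expect_true(all(avg$probability[avg$present] == 0.5))
  c_bad <- prof; c_bad$bin_center <- c_bad$bin_center + 1
  expect_error(average_across_instances(list(prof, c_bad)), "mismatched")
})

test_that("noise-free fits recover generating parameters within 1%", {
  gt <- ground_truth_pathway("exponential", c(0.3, 100))
  fit <- fit_probability_model(profile_from_curve(gt), "exponential")
  expect_lt(abs(fit$params[["A"]] - 0.3) / 0.3, 0.01)
  expect_lt(abs(fit$params[["lambda"]] - 100) / 100, 0.01)
  expect_lt(fit$sse, 1e-10)

  zero <- profile_from_curve(ground_truth_pathway("exponential", c(1e-30, 100)))
  zero$probability <- 0
  fz <- fit_probability_model(zero, "exponential")
  expect_equal(fz$params[["A"]], 0)
  expect_equal(fz$sse, 0)
})

test_that("a gaussian profile is fitted worse by an exponential", {
  gt <- ground_truth_pathway("gaussian", c(0.25, 100, 80))
  prof <- profile_from_curve(gt)
  f_exp <- fit_probability_model(prof, "exponential")
  f_gau <- fit_probability_model(prof, "gaussian")
  expect_gt(f_exp$sse, f_gau$sse)
  expect_lt(f_gau$sse, 1e-8)
})

test_that("best-fit selection recovers the generating family and breaks ties", {
  gau <- profile_from_curve(ground_truth_pathway("gaussian", c(0.25, 100, 80)))
  expect_equal(select_best_fit(gau)$form, "gaussian")
  ex <- profile_from_curve(ground_truth_pathway("exponential", c(0.3, 100)))
  expect_equal(select_best_fit(ex)$form, "exponential")
  zero <- ex; zero$probability <- 0
  expect_equal(select_best_fit(zero)$form, "exponential")  # sse tie, fewest params
})

test_that("fitted curves behave like probabilities", {
  d <- seq(0, 400, by = 1)
  for (gt in list(ground_truth_pathway("exponential", c(0.9, 50)),
                  ground_truth_pathway("exp_linsat", c(2, 80, 0.6)),
                  ground_truth_pathway("gaussian", c(0.8, 120, 60)))) {
    fit <- fit_probability_model(profile_from_curve(gt), gt$form)
    p <- predict(fit, d)
    expect_true(all(p >= 0 & p <= 1))
    if (gt$form == "exponential") expect_true(all(diff(p) < 0))
  }
})

test_that("expected connection counts match construction and simulation", {
  pre <- disc_cells(10)
  post <- disc_cells(10, seed = 2)
  post$id <- post$id + 10L
  # p identically 1 on disjoint sets: 100 ordered pairs
  ones <- fit_probability_model(
    profile_from_curve(ground_truth_pathway("exp_linsat", c(5, 1e5, 1))),
    "exp_linsat")
  expect_equal(expected_connection_count(ones, pre, post), 100)
  zero_gt <- ground_truth_pathway("exponential", c(1e-30, 100))
  expect_lt(expected_connection_count(zero_gt, pre, post), 1e-20)

  # Poisson-binomial oracle: realized counts across seeds match expectation
  gt <- ground_truth_pathway("exponential", c(0.4, 120))
  cells <- disc_cells(40, seed = 3)
  expect_val <- expected_connection_count(gt, cells, cells)
  d <- xz_distance(cells, cells)
  p <- matrix(pathway_probability(gt, as.vector(d)), nrow = nrow(d))
  diag(p) <- 0
  sigma <- sqrt(sum(p * (1 - p)))
  pw <- tibble::tibble(pre = "P", post = "P", gt = list(gt))
  counts <- vapply(1:100, function(s) {
    nrow(gen_connectome_instances(cells, pw, n_instances = 1,
                                  seed = s)$instances[[1]])
  }, numeric(1))
  expect_lt(abs(mean(counts) - expect_val), 3 * sigma / sqrt(100))
})

test_that("generate-bin-average-fit-select round trip recovers all families", {
  cells <- disc_cells(800, seed = 21)
  gts <- list(exponential = ground_truth_pathway("exponential", c(0.3, 100)),
              exp_linsat = ground_truth_pathway("exp_linsat", c(0.9, 80, 0.3)),
              gaussian = ground_truth_pathway("gaussian", c(0.25, 100, 80)))
  for (form in names(gts)) {
    pw <- tibble::tibble(pre = "P", post = "P", gt = gts[form])
    inst <- gen_connectome_instances(cells, pw, n_instances = 7, seed = 33)
    rules <- fit_pathway_rules(inst, cells)
    expect_equal(rules$form, form)
    expect_lt(max(abs(rules$params[[1]] - gts[[form]]$params) /
                    abs(gts[[form]]$params)), 0.2)
    expect_gt(rules$mean_nsyn, 1)
  }
})

test_that("pathway rules survive a serialization round trip", {
  gt <- ground_truth_pathway("gaussian", c(0.25, 100, 80))
  fit <- fit_probability_model(profile_from_curve(gt), "gaussian")
  rules <- tibble::tibble(pre = "A", post = "B", form = fit$form,
                          params = list(fit$params), sse = fit$sse,
                          mean_nsyn = 3.5, fit = list(fit))
  f <- tempfile()
  write_pathway_rules(rules, f)
  back <- read_pathway_rules(f)
  expect_equal(back$form, "gaussian")
  expect_equal(back$params[[1]], fit$params, tolerance = 1e-6)
  expect_equal(predict(back$fit[[1]], 0:300), predict(fit, 0:300),
               tolerance = 1e-6)
})

test_that("tidy and glance summarize fits", {
  fit <- fit_probability_model(
    profile_from_curve(ground_truth_pathway("exponential", c(0.3, 100))),
    "exponential")
  td <- tidy(fit)
  expect_equal(td$term, c("A", "lambda"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$form, "exponential")
})
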