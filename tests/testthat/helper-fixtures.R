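# shared fixtures: the packaged registry and a couple of small placements

tc_reg <- load_synapse_table()

# n cells uniformly in a disc, single population, built in code
disc_cells <- function(n, radius = 210, population = "P", seed = 1,
                       excitatory = TRUE, layer = "L5",
                       me_type = "L5_TTPC2_cADpyr") {
  withr::with_seed(seed, {
    r <- radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    tibble::tibble(id = seq_len(n), population = population,
                   me_type = me_type,
                   m_type = sub("^L[0-9]+_(.*)_[^_]+$", "\\1", me_type),
                   e_type = sub(".*_", "", me_type), layer = layer,
                   x = r * cos(th), y = runif(n, 0, 100), z = r * sin(th),
                   excitatory = excitatory)
  })
}

# one-row rules tibble with an exactly-known probability curve
constant_rule <- function(pre, post, p = 1, mean_nsyn = 1) {
  prof <- tibble::tibble(bin_center = seq(25, 375, 50), n_pairs = 100L,
                         n_connected = as.integer(100 * p), probability = p,
                         present = TRUE)
  fit <- fit_probability_model(prof, "exp_linsat")
  tibble::tibble(pre = pre, post = post, form = fit$form,
                 params = list(fit$params), sse = fit$sse,
                 mean_nsyn = mean_nsyn, fit = list(fit))
}

# profile evaluated exactly on a ground-truth curve (noise-free bins)
profile_from_curve <- function(gt, centers = seq(25, 375, 50)) {
  p <- pathway_probability(gt, centers)
  tibble::tibble(bin_center = centers, n_pairs = 1000L,
                 n_connected = NA_integer_, probability = p, present = TRUE)
}
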