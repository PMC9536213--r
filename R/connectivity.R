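#' Distance bins for connection-probability profiles
#'
#' Default bins are evenly spaced intervals starting at 25 +/- 25 um, in 50 um
#' steps, up to 375 +/- 25 um (8 bins covering 0-400 um).
#'
#' @param centers Bin centers in um.
#' @param halfwidth Bin half-width in um.
#' @return A `tc_bins` object.
#' @export
distance_bins <- function(centers = seq(25, 375, by = 50), halfwidth = 25) {
  structure(list(centers = centers, halfwidth = halfwidth), class = "tc_bins")
}

bin_index <- function(d, bins) {
  breaks <- c(bins$centers - bins$halfwidth, bins$centers[length(bins$centers)] +
                bins$halfwidth)
  idx <- findInterval(d, breaks, left.open = FALSE, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(bins$centers)] <- NA_integer_
  idx
}

#' Estimate distance-binned connection probabilities
#'
#' For one connectome instance, computes per bin the fraction of connected
#' ordered cell pairs among all ordered pairs whose XZ distance falls in the
#' bin. Self-pairs are excluded. Bins containing no pairs are flagged absent.
#'
#' @param edges Edge tibble (`pre`, `post` ids); extra columns ignored.
#' @param placements Cell tibble with `id`, `x`, `z`.
#' @param bins A [distance_bins()] object.
#' @param pre,post Optional id vectors restricting the ordered pairs considered
#'   (defaults: all placements on both sides).
#' @return Profile tibble: `bin_center`, `n_pairs`, `n_connected`,
#'   `probability` (NA when absent), `present`.
#' @export
estimate_bin_probabilities <- function(edges, placements, bins = distance_bins(),
                                       pre = NULL, post = NULL) {
  if (nrow(placements) == 0) abort("placements must be non-empty")
  pre_cells <- if (is.null(pre)) placements else placements[placements$id %in% pre, ]
  post_cells <- if (is.null(post)) placements else placements[placements$id %in% post, ]
  d <- xz_distance(pre_cells, post_cells)
  self <- outer(pre_cells$id, post_cells$id, "==")
  d_free <- as.vector(d[!self])
  idx_all <- bin_index(d_free, bins)
  n_pairs <- tabulate(idx_all, nbins = length(bins$centers))
  d_sum <- vapply(seq_along(bins$centers), function(b)
    sum(d_free[!is.na(idx_all) & idx_all == b]), numeric(1))
  # connected pairs: distances recomputed from placements for consistency
  if (nrow(edges) > 0) {
    pos <- setNames(seq_len(nrow(placements)), placements$id)
    dpre <- placements[pos[as.character(edges$pre)], c("x", "z")]
    dpost <- placements[pos[as.character(edges$post)], c("x", "z")]
    d_edge <- sqrt((dpre$x - dpost$x)^2 + (dpre$z - dpost$z)^2)
    keep <- edges$pre %in% pre_cells$id & edges$post %in% post_cells$id &
      edges$pre != edges$post
    idx_conn <- bin_index(d_edge[keep], bins)
    n_conn <- tabulate(idx_conn, nbins = length(bins$centers))
  } else {
    n_conn <- rep(0L, length(bins$centers))
  }
  tibble(bin_center = bins$centers,
         d_mean = ifelse(n_pairs > 0, d_sum / n_pairs, bins$centers),
         n_pairs = n_pairs,
         n_connected = n_conn,
         probability = ifelse(n_pairs > 0, n_conn / n_pairs, NA_real_),
         present = n_pairs > 0)
}

#' Average bin profiles across connectome instances
#'
#' Arithmetic mean of the per-instance probabilities in each bin, over the
#' instances where the bin is present.
#'
#' @param profiles List of profile tibbles with identical binning.
#' @return A profile tibble of the same shape.
#' @export
average_across_instances <- function(profiles) {
  centers <- profiles[[1]]$bin_center
  for (p in profiles) {
    if (!identical(p$bin_center, centers)) abort("profiles have mismatched bins")
  }
  probs <- vapply(profiles, function(p) p$probability, numeric(length(centers)))
  probs <- matrix(probs, nrow = length(centers))
  n_present <- rowSums(!is.na(probs))
  pair_tot <- rowSums(vapply(profiles, function(p) p$n_pairs,
                             numeric(length(centers))))
  d_mean <- if (all(vapply(profiles, function(p) "d_mean" %in% names(p),
                           logical(1)))) {
    dsum <- rowSums(vapply(profiles, function(p) p$d_mean * p$n_pairs,
                           numeric(length(centers))))
    ifelse(pair_tot > 0, dsum / pair_tot, centers)
  } else centers
  tibble(bin_center = centers,
         d_mean = d_mean,
         n_pairs = rowSums(vapply(profiles, function(p) p$n_pairs,
                                  numeric(length(centers)))),
         n_connected = rowSums(vapply(profiles, function(p) p$n_connected,
                                      numeric(length(centers)))),
         probability = ifelse(n_present > 0, rowMeans(probs, na.rm = TRUE),
                              NA_real_),
         present = n_present > 0)
}

n_params_for_form <- function(form) {
  c(exponential = 2L, exp_linsat = 3L, gaussian = 3L)[[form]]
}

new_tc_fit <- function(form, params, sse, n_bins, converged = TRUE,
                       diagnostic = NA_character_) {
  structure(list(form = form, params = params, sse = sse, n_bins = n_bins,
                 converged = converged, diagnostic = diagnostic),
            class = "tc_fit")
}

#' Fit a probability-model family to a bin profile
#'
#' Unweighted least squares on the present bins; absent bins are excluded from
#' the objective, not imputed. Amplitudes are bounded so the fitted curve stays
#' a probability; predictions are additionally clipped to `[0, 1]`. A fit that
#' fails to converge is returned flagged (`converged = FALSE`) with a
#' diagnostic, never silently.
#'
#' @param profile Profile tibble (see [estimate_bin_probabilities()]).
#' @param form One of `"exponential"`, `"exp_linsat"`, `"gaussian"`.
#' @return A `tc_fit` object: `form`, named `params`, `sse`, `n_bins`,
#'   `converged`, `diagnostic`.
#' @export
fit_probability_model <- function(profile, form) {
  prof <- profile[profile$present & !is.na(profile$probability), ]
  # fit against the mean pair distance per bin when available: evaluating the
  # model at bin centers biases the short-distance bins, where pair density
  # grows with distance inside the bin
  d <- if ("d_mean" %in% names(prof)) prof$d_mean else prof$bin_center
  p <- prof$probability
  npar <- n_params_for_form(form)
  if (length(d) < npar)
    abort(sprintf("need at least %d populated bins to fit a %s model", npar, form))
  if (all(p == 0)) {
    params <- switch(form,
      exponential = c(A = 0, lambda = 100),
      exp_linsat = c(A = 0, lambda = 100, p_sat = 0),
      gaussian = c(A = 0, mu = 0, sigma = 100))
    return(new_tc_fit(form, params, sse = 0, n_bins = length(d)))
  }
  obj <- function(par) {
    pred <- eval_prob_form_raw(form, par, d)
    sum((pred - p)^2)
  }
  starts <- fit_starts(form, d, p)
  lower <- switch(form,
    exponential = c(1e-6, 1),
    exp_linsat = c(1e-6, 1, 1e-6),
    gaussian = c(1e-6, 0, 1))
  upper <- switch(form,
    exponential = c(1, 1e4),
    exp_linsat = c(3, 1e4, 1),
    gaussian = c(1, max(d) + 100, 1e4))
  best <- NULL
  for (start in starts) {
    start <- pmin(pmax(start, lower), upper)
    res <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    # Nelder-Mead polish (helps the non-smooth saturating form)
    if (!is.null(res)) {
      res2 <- tryCatch(
        optim(res$par, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(res2) && res2$value < res$value) res <- res2
      res$par <- pmin(pmax(res$par, lower), upper)
      res$value <- obj(res$par)
    }
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best) || any(!is.finite(best$par)))
    return(new_tc_fit(form, setNames(rep(NA_real_, npar), param_names(form)),
                      sse = Inf, n_bins = length(d), converged = FALSE,
                      diagnostic = "optimizer failed to produce finite parameters"))
  params <- setNames(best$par, param_names(form))
  new_tc_fit(form, params, sse = best$value, n_bins = length(d))
}

param_names <- function(form) {
  switch(form,
    exponential = c("A", "lambda"),
    exp_linsat = c("A", "lambda", "p_sat"),
    gaussian = c("A", "mu", "sigma"))
}

# unclipped model evaluation used inside the objective
eval_prob_form_raw <- function(form, par, d) {
  switch(form,
    exponential = par[1] * exp(-d / par[2]),
    exp_linsat = pmin(par[3], par[1] * exp(-d / par[2])),
    gaussian = par[1] * exp(-(d - par[2])^2 / (2 * par[3]^2)))
}

fit_starts <- function(form, d, p) {
  pos <- p > 1e-12
  loglin <- if (sum(pos) >= 2) {
    co <- stats::coef(stats::lm(log(p[pos]) ~ d[pos]))
    lam <- if (is.finite(co[2]) && co[2] < 0) -1 / co[2] else max(d)
    c(exp(co[1]), lam)
  } else c(max(p), mean(d))
  switch(form,
    exponential = list(loglin, c(max(p), mean(d))),
    exp_linsat = list(c(loglin, max(p)),
                      c(max(p) * 2, mean(d) / 2, max(p)),
                      c(max(p), mean(d), 0.9 * max(p))),
    gaussian = {
      mu0 <- d[which.max(p)]
      above <- d[p >= max(p) / 2]
      sig0 <- max((max(above) - min(above)) / 2.355, diff(range(d)) / 8, 10)
      list(c(max(p), mu0, sig0), c(max(p), 0, sig0 * 2))
    })
}

#' Predict connection probability from a fitted model
#'
#' @param object A `tc_fit`.
#' @param distance XZ distances in um.
#' @param ... Unused.
#' @return Probabilities clipped to `[0, 1]`.
#' @export
predict.tc_fit <- function(object, distance, ...) {
  pmin(pmax(eval_prob_form_raw(object$form, unname(object$params), distance), 0), 1)
}

#' @export
print.tc_fit <- function(x, ...) {
  cat(sprintf("<tc_fit> %s: %s | sse = %.4g over %d bins%s\n", x$form,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$sse, x$n_bins,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Select the best-fitting probability model
#'
#' Fits all three families and returns the best. Because the saturating
#' exponential nests the pure exponential, raw SSE comparison always favors the
#' richer family on noisy bins; the default criterion therefore scores fits by
#' small-sample-corrected AIC under Gaussian errors
#' (`n log(sse/n) + 2k + 2k(k+1)/(n-k-1)`), which reduces to minimal SSE
#' whenever the fits differ materially. Ties (within numerical tolerance)
#' are broken by fewer parameters, then by the order
#' exponential < exp_linsat < gaussian; noise-free data thus resolve exactly as
#' the tie-break rules state (an all-zero profile selects the exponential).
#'
#' @param profile Profile tibble.
#' @param forms Forms to try.
#' @param pathway Optional pathway label used in error messages.
#' @param criterion `"aic"` (default) or `"sse"`.
#' @return The winning `tc_fit`; the losing fits are attached as attribute
#'   `"all_fits"`.
#' @export
select_best_fit <- function(profile,
                            forms = c("exponential", "exp_linsat", "gaussian"),
                            pathway = NULL, criterion = c("aic", "sse")) {
  criterion <- match.arg(criterion)
  fits <- lapply(forms, function(f)
    tryCatch(fit_probability_model(profile, f), error = function(e) NULL))
  names(fits) <- forms
  ok <- !vapply(fits, is.null, logical(1)) &
    vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  if (!any(ok))
    abort(paste0("all fits failed", if (!is.null(pathway))
      paste0(" for pathway ", pathway) else ""))
  # identifiability guard: a saturating exponential whose ceiling binds on
  # fewer than two bins is indistinguishable from a pure exponential and is
  # not a candidate in its own right
  if (!is.null(fits$exp_linsat) && fits$exp_linsat$converged &&
      "exponential" %in% names(fits)[ok]) {
    par <- fits$exp_linsat$params
    prof <- profile[profile$present & !is.na(profile$probability), ]
    d <- if ("d_mean" %in% names(prof)) prof$d_mean else prof$bin_center
    n_sat <- sum(par[["A"]] * exp(-d / par[["lambda"]]) > par[["p_sat"]])
    if (n_sat < 2) ok[names(fits) == "exp_linsat"] <- FALSE
  }
  score <- vapply(names(fits)[ok], function(f) {
    fit <- fits[[f]]
    if (criterion == "sse") return(fit$sse)
    if (fit$sse < 1e-15) return(-Inf)
    k <- n_params_for_form(f)
    n <- fit$n_bins
    corr <- if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else 0
    n * log(fit$sse / n) + 2 * k + corr
  }, numeric(1))
  tied <- if (!any(is.finite(score))) {
    seq_along(score)
  } else {
    tol <- 1e-9 * max(abs(min(score[is.finite(score)])), 1)
    which(score <= min(score) + tol)
  }
  cand <- names(score)[tied]
  npars <- vapply(cand, n_params_for_form, integer(1))
  cand <- cand[npars == min(npars)]
  order_rank <- match(cand, c("exponential", "exp_linsat", "gaussian"))
  winner <- cand[which.min(order_rank)]
  out <- fits[[winner]]
  attr(out, "all_fits") <- fits
  out
}

#' Expected number of connections under a fitted rule
#'
#' Sums the fitted probability over all ordered eligible pairs (self-pairs
#' excluded).
#'
#' @param fit A `tc_fit` or [ground_truth_pathway()].
#' @param pre_cells,post_cells Cell tibbles with `id`, `x`, `z`.
#' @return The expected connection count (a real number).
#' @export
expected_connection_count <- function(fit, pre_cells, post_cells) {
  d <- xz_distance(pre_cells, post_cells)
  p <- if (inherits(fit, "tc_fit")) predict(fit, as.vector(d))
       else pathway_probability(fit, as.vector(d))
  p <- matrix(p, nrow = nrow(d))
  p[outer(pre_cells$id, post_cells$id, "==")] <- 0
  sum(p)
}

#' Fit pathway rules from a set of connectome instances
#'
#' The full estimation pipeline: per pathway, bin each instance, average the
#' per-instance profiles, fit all three model families, select the best, and
#' record the mean number of synapses per connection across instances.
#'
#' @param instance_set A [gen_connectome_instances()] result.
#' @param placements The cell placements the instances were drawn over.
#' @param bins A [distance_bins()] object.
#' @return A rules tibble: `pre`, `post`, `form`, `params` (list), `sse`,
#'   `mean_nsyn`, `fit` (list of `tc_fit`).
#' @export
fit_pathway_rules <- function(instance_set, placements, bins = distance_bins()) {
  group_col <- instance_set$group_col
  groups <- setNames(placements[[group_col]], placements$id)
  out <- purrr::pmap(instance_set$pathways, function(pre, post, gt, ...) {
    pre_ids <- placements$id[placements[[group_col]] == pre]
    post_ids <- placements$id[placements[[group_col]] == post]
    profiles <- lapply(instance_set$instances, function(edges) {
      estimate_bin_probabilities(edges, placements, bins,
                                 pre = pre_ids, post = post_ids)
    })
    avg <- average_across_instances(profiles)
    fit <- select_best_fit(avg, pathway = paste0(pre, "->", post))
    nsyn <- unlist(lapply(instance_set$instances, function(edges) {
      sel <- edges$pre %in% pre_ids & edges$post %in% post_ids
      edges$nsyn[sel]
    }))
    tibble(pre = pre, post = post, form = fit$form,
           params = list(fit$params), sse = fit$sse,
           mean_nsyn = if (length(nsyn) > 0) mean(nsyn) else 1,
           fit = list(fit))
  })
  bind_rows(out)
}

#' Serialize / load fitted pathway rules
#'
#' Versioned plain tabular format: one row per pathway with the form, up to
#' three parameters and the mean synapses per connection.
#'
#' @param rules Rules tibble from [fit_pathway_rules()].
#' @param path File path.
#' @return `path` (write) or a rules tibble (read).
#' @export
write_pathway_rules <- function(rules, path) {
  flat <- tibble(format_version = 1L, pre = rules$pre, post = rules$post,
                 form = rules$form,
                 p1 = vapply(rules$params, function(p) p[1], numeric(1)),
                 p2 = vapply(rules$params, function(p) p[2], numeric(1)),
                 p3 = vapply(rules$params, function(p)
                   if (length(p) >= 3) p[3] else NA_real_, numeric(1)),
                 mean_nsyn = rules$mean_nsyn)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathway_rules
#' @export
read_pathway_rules <- function(path) {
  flat <- read_tsv_strict(path)
  if (!"format_version" %in% names(flat) || any(flat$format_version != 1L))
    abort("unsupported pathway-rules file version")
  flat$params <- purrr::pmap(flat, function(form, p1, p2, p3, ...) {
    par <- c(p1, p2, if (!is.na(p3)) p3)
    setNames(par, param_names(form))
  })
  flat$fit <- purrr::pmap(flat, function(form, params, ...)
    new_tc_fit(form, params, sse = NA_real_, n_bins = NA_integer_))
  flat[, c("pre", "post", "form", "params", "mean_nsyn", "fit")]
}
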