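#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted probability model
#'
#' @param x A `tc_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`.
#' @method tidy tc_fit
#' @export
tidy.tc_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a fitted probability model
#'
#' @param x A `tc_fit`.
#' @param ... Unused.
#' @return Tibble with `form`, `sse`, `n_bins`, `converged`.
#' @method glance tc_fit
#' @export
glance.tc_fit <- function(x, ...) {
  tibble(form = x$form, sse = x$sse, n_bins = x$n_bins,
         converged = x$converged)
}

#' Tidy a simulation: its spike record
#'
#' @param x A `tc_sim`.
#' @param ... Unused.
#' @return Spike tibble with population labels.
#' @method tidy tc_sim
#' @export
tidy.tc_sim <- function(x, ...) {
  sp <- x$spikes
  sp$population <- x$cells$population[match(sp$id, x$cells$id)]
  sp
}

#' One-row summary of a simulation
#'
#' Overall mean rate excludes the configured transient.
#'
#' @param x A `tc_sim`.
#' @param ... Unused.
#' @return Tibble with `n_cells`, `duration`, `n_spikes`, `mean_rate` (Hz,
#'   post-transient).
#' @method glance tc_sim
#' @export
glance.tc_sim <- function(x, ...) {
  t0 <- x$config$transient
  t1 <- x$config$duration
  n_post <- sum(x$spikes$time >= t0)
  tibble(n_cells = nrow(x$cells), duration = t1, n_spikes = nrow(x$spikes),
         mean_rate = n_post / nrow(x$cells) / ((t1 - t0) / 1000))
}
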