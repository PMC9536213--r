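#' Ground-truth distance-probability pathway
#'
#' Defines the generating connection-probability curve for one directed
#' pathway, used to synthesize connectome instances with known structure.
#' Three families are supported:
#' \describe{
#'   \item{exponential}{`p(d) = A * exp(-d / lambda)`, params `c(A, lambda)`.}
#'   \item{exp_linsat}{`p(d) = min(p_sat, A * exp(-d / lambda))`, params
#'     `c(A, lambda, p_sat)`: a decaying exponential saturating at a ceiling at
#'     short distances.}
#'   \item{gaussian}{`p(d) = A * exp(-(d - mu)^2 / (2 sigma^2))`, params
#'     `c(A, mu, sigma)`.}
#' }
#' Evaluated probabilities are clipped to `[0, 1]`.
#'
#' @param form One of `"exponential"`, `"exp_linsat"`, `"gaussian"`.
#' @param params Numeric coefficient vector for the chosen form.
#' @param mean_nsyn Mean number of synapses per connection (>= 1).
#' @return A `tc_pathway` object.
#' @export
#' @examples
#' gt <- ground_truth_pathway("gaussian", c(0.2, 0, 100))
#' pathway_probability(gt, c(0, 100, 300))
ground_truth_pathway <- function(form, params, mean_nsyn = 3) {
  forms <- c(exponential = 2, exp_linsat = 3, gaussian = 3)
  if (!form %in% names(forms))
    abort(paste0("unknown pathway form: ", form))
  if (length(params) != forms[[form]])
    abort(sprintf("form %s takes %d parameters, got %d", form, forms[[form]],
                  length(params)))
  if (mean_nsyn < 1) abort("mean_nsyn must be >= 1")
  structure(list(form = form, params = as.numeric(params),
                 mean_nsyn = mean_nsyn),
            class = "tc_pathway")
}

#' Evaluate a pathway probability curve
#'
#' @param gt A [ground_truth_pathway()] (or a fitted `tc_fit`).
#' @param distance Numeric vector of XZ distances in um.
#' @return Connection probabilities in `[0, 1]`.
#' @export
pathway_probability <- function(gt, distance) {
  eval_prob_form(gt$form, gt$params, distance)
}

eval_prob_form <- function(form, params, d) {
  p <- switch(form,
    exponential = params[1] * exp(-d / params[2]),
    exp_linsat = pmin(params[3], params[1] * exp(-d / params[2])),
    gaussian = params[1] * exp(-(d - params[2])^2 / (2 * params[3]^2)),
    abort(paste0("unknown pathway form: ", form))
  )
  pmin(pmax(p, 0), 1)
}

#' Generate synthetic connectome instances
#'
#' Draws `n_instances` independent stochastic connectomes over fixed cell
#' placements: for every ordered pair of cells in a pathway's pre/post groups,
#' an edge is present with the pathway's probability at the pair's XZ distance,
#' independently per instance. The number of synapses on each edge is
#' `1 + Poisson(mean_nsyn - 1)` (mean matched, always >= 1). Placements are
#' shared across instances; only the edge draws differ.
#'
#' @param placements Cell tibble (see [place_cortical_cells()]).
#' @param pathways Tibble with columns `pre`, `post` (values of `group_col`)
#'   and a `gt` list column of [ground_truth_pathway()] objects.
#' @param n_instances Number of instances (default 7).
#' @param seed Integer seed; instance sets are reproducible given the seed.
#' @param group_col Column of `placements` that pathway `pre`/`post` refer to.
#' @return A `tc_instance_set`: list with `instances` (list of edge tibbles
#'   `pre`, `post`, `distance`, `nsyn`), `n_instances`, `seed`, `pathways`.
#' @export
gen_connectome_instances <- function(placements, pathways, n_instances = 7,
                                     seed = 1, group_col = "population") {
  if (nrow(placements) == 0) abort("placements must be non-empty")
  for (gt in pathways$gt) {
    if (!inherits(gt, "tc_pathway"))
      abort("pathways$gt must contain ground_truth_pathway objects")
  }
  groups <- placements[[group_col]]
  with_seed(seed, {
    instances <- lapply(seq_len(n_instances), function(k) {
      edges <- purrr::pmap(pathways, function(pre, post, gt, ...) {
        pre_cells <- placements[groups == pre, ]
        post_cells <- placements[groups == post, ]
        if (nrow(pre_cells) == 0 || nrow(post_cells) == 0) return(NULL)
        d <- xz_distance(pre_cells, post_cells)
        p <- matrix(pathway_probability(gt, as.vector(d)), nrow = nrow(d))
        # no self-connections
        self <- outer(pre_cells$id, post_cells$id, "==")
        p[self] <- 0
        hit <- which(runif(length(p)) < p)
        if (length(hit) == 0) return(NULL)
        ii <- (hit - 1) %% nrow(p) + 1
        jj <- (hit - 1) %/% nrow(p) + 1
        tibble(pre = pre_cells$id[ii], post = post_cells$id[jj],
               distance = d[hit],
               nsyn = 1L + rpois(length(hit), gt$mean_nsyn - 1))
      })
      edges <- bind_rows(edges)
      if (nrow(edges) == 0)
        edges <- tibble(pre = integer(), post = integer(),
                        distance = numeric(), nsyn = integer())
      edges
    })
    structure(list(instances = instances, n_instances = n_instances,
                   seed = seed, pathways = pathways, group_col = group_col),
              class = "tc_instance_set")
  })
}

#' Scaled cortical cell-count table
#'
#' Returns the default synthetic me-type count table scaled by `scale`. The
#' default table (scale 1) totals 31,346 cells with the excitatory/inhibitory
#' split 26,567 / 4,779 and layer proportions increasing from L1 (smallest) to
#' L6 (largest). Every population keeps at least one cell after scaling.
#'
#' @param scale Scaling factor in (0, 1].
#' @param table Base count table; defaults to the packaged synthetic catalogue.
#' @return Tibble with columns `me_type`, `layer`, `m_type`, `e_type`,
#'   `excitatory`, `count`.
#' @export
#' @examples
#' sum(gen_cell_counts(1)$count)  # 31346
gen_cell_counts <- function(scale = 1,
                            table = read_tsv_strict(tcsim_extdata("me_types_synthetic.tsv"))) {
  if (!is.numeric(scale) || scale <= 0) abort("scale must be > 0")
  if (scale > 1) abort("scale must be in (0, 1]")
  out <- as_tibble(table)
  out$excitatory <- as.logical(out$excitatory)
  out$count <- pmax(1L, as.integer(round(out$count * scale)))
  out[, c("me_type", "layer", "m_type", "e_type", "excitatory", "count")]
}

#' Scaled thalamic cell-count table
#'
#' Nominal per-population counts (before the POm density reduction applied at
#' placement time). At scale 1 the placed network totals 7,266 cells.
#'
#' @param scale Scaling factor in (0, 1].
#' @return Tibble with columns `population`, `excitatory`, `nominal_count`.
#' @export
thalamic_cell_counts <- function(scale = 1) {
  if (!is.numeric(scale) || scale <= 0) abort("scale must be > 0")
  tab <- read_tsv_strict(tcsim_extdata("thalamic_counts_synthetic.tsv"))
  tab$excitatory <- as.logical(tab$excitatory)
  tab$nominal_count <- pmax(1L, as.integer(round(tab$nominal_count * scale)))
  tab
}

#' Segment-current frames
#'
#' Container for per-timestep transmembrane currents of line segments, the
#' input of the LFP engine.
#'
#' @param segments Tibble with columns `x0, y0, z0, x1, y1, z1` (um), one row
#'   per segment.
#' @param currents Matrix of currents in nA, `length(times)` rows x
#'   `nrow(segments)` columns.
#' @param times Numeric vector of frame times in ms.
#' @return A `tc_frames` object.
#' @export
segment_frames <- function(segments, currents, times) {
  currents <- as.matrix(currents)
  if (nrow(currents) != length(times))
    abort("currents must have one row per time point")
  if (ncol(currents) != nrow(segments))
    abort("currents must have one column per segment")
  deg <- with(segments, (x0 - x1)^2 + (y0 - y1)^2 + (z0 - z1)^2 == 0)
  if (any(deg)) abort("segment endpoints must be distinct")
  structure(list(segments = as_tibble(segments), currents = currents,
                 times = times),
            class = "tc_frames")
}

#' Toy multi-segment cable fixture for LFP tests
#'
#' Builds a vertical cable of `n_segments` equal segments along the y axis at
#' `x = z = 0` and fills per-segment current frames from a drive waveform. In
#' the balanced-dipole variant the first half of the segments carries `+w(t)`
#' and the second half `-w(t)` (scaled so currents sum to zero exactly at every
#' timestep); otherwise all segments carry `w(t) / n_segments`.
#'
#' @param n_segments Number of segments (>= 1).
#' @param length Total cable length in um.
#' @param waveform Function of time (ms) returning the drive current in nA, or
#'   a numeric vector of per-frame drive values.
#' @param duration Duration in ms (ignored when `waveform` is a vector).
#' @param dt Frame interval in ms.
#' @param balanced Build the balanced-dipole variant?
#' @param y_top Depth of the cable's top end (um).
#' @return A [segment_frames()] object.
#' @export
gen_toy_cable <- function(n_segments = 2, length = 200, waveform = function(t) 1,
                          duration = 100, dt = 1, balanced = TRUE, y_top = 0) {
  if (n_segments < 1) abort("n_segments must be >= 1")
  if (balanced && n_segments < 2)
    abort("a balanced dipole needs at least 2 segments")
  ys <- seq(y_top, y_top + length, length.out = n_segments + 1)
  segments <- tibble(x0 = 0, y0 = ys[-(n_segments + 1)], z0 = 0,
                     x1 = 0, y1 = ys[-1], z1 = 0)
  if (is.function(waveform)) {
    times <- seq(0, duration, by = dt)
    w <- vapply(times, waveform, numeric(1))
  } else {
    w <- as.numeric(waveform)
    times <- seq(0, by = dt, length.out = length(w))
  }
  if (balanced) {
    n_top <- floor(n_segments / 2)
    n_bot <- n_segments - n_top
    sign_w <- c(rep(1 / n_top, n_top), rep(-1 / n_bot, n_bot))
  } else {
    sign_w <- rep(1 / n_segments, n_segments)
  }
  currents <- outer(w, sign_w)
  segment_frames(segments, currents, times)
}

#' Homogeneous Poisson spike trains
#'
#' @param ids Cell ids to generate trains for.
#' @param rate Rate in Hz.
#' @param duration Duration in ms.
#' @param seed Integer seed.
#' @return Spike tibble (`id`, `time` in ms), sorted by time.
#' @export
gen_poisson_trains <- function(ids, rate, duration, seed = 1) {
  if (rate < 0) abort("rate must be >= 0")
  with_seed(seed, {
    n <- rpois(length(ids), rate * duration / 1000)
    spikes <- tibble(id = rep(ids, n),
                     time = runif(sum(n), 0, duration))
    arrange(spikes, .data$time)
  })
}

#' Write / read an edge table fixture
#'
#' Plain tabular text with header, one edge per row (`pre`, `post`,
#' `distance` in um, `nsyn`), chosen for diffability.
#'
#' @param edges Edge tibble.
#' @param path File path.
#' @return `path` (write) or the edge tibble (read).
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) read_tsv_strict(path)

#' Write / read spike trains as two-column text
#'
#' @param spikes Spike tibble (`id`, `time` in ms).
#' @param path File path.
#' @return `path` (write) or the spike tibble (read).
#' @export
write_spike_trains <- function(spikes, path) {
  utils::write.table(spikes[, c("id", "time")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) read_tsv_strict(path)
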