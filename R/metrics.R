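#' Population firing statistics
#'
#' Mean firing rate (spikes/cell/second), spike counts and ISI CV summaries per
#' population over an analysis window (the transient should be excluded via
#' `window`).
#'
#' @param spikes Spike tibble (`id`, `time` in ms).
#' @param cells Cell tibble defining populations and population sizes.
#' @param window `c(t0, t1)` analysis window in ms.
#' @return Tibble per population: `population`, `n_cells`, `n_spikes`,
#'   `mean_rate` (Hz), `cv_mean`, `cv_sd`, `empty` flag.
#' @export
population_rates <- function(spikes, cells, window) {
  t_len <- (window[2] - window[1]) / 1000
  sp <- spikes[spikes$time >= window[1] & spikes$time < window[2], ]
  sp$population <- cells$population[match(sp$id, cells$id)]
  counts <- dplyr::count(sp, .data$population, name = "n_spikes")
  cv <- isi_cv(sp, window = window)
  cv$population <- cells$population[match(cv$id, cells$id)]
  cv_sum <- summarise(group_by(cv, .data$population),
                      cv_mean = mean(.data$cv), cv_sd = sd(.data$cv),
                      .groups = "drop")
  pops <- dplyr::count(cells, .data$population, name = "n_cells")
  out <- left_join(pops, counts, by = "population")
  out <- left_join(out, cv_sum, by = "population")
  out$n_spikes[is.na(out$n_spikes)] <- 0L
  out$mean_rate <- out$n_spikes / out$n_cells / t_len
  out$empty <- out$n_spikes == 0L
  out
}

#' Inter-spike-interval coefficient of variation per cell
#'
#' CV = sd(ISI) / mean(ISI) per cell. Cells with fewer than `min_spikes`
#' spikes are excluded; the number excluded is attached as attribute
#' `"n_excluded"`.
#'
#' @param spikes Spike tibble (`id`, `time`).
#' @param min_spikes Minimum spikes for inclusion (>= 3 so the CV is defined on
#'   at least two intervals).
#' @param window Optional `c(t0, t1)` restriction (ms).
#' @return Tibble: `id`, `n_spikes`, `cv`.
#' @export
isi_cv <- function(spikes, min_spikes = 3, window = NULL) {
  if (!is.null(window))
    spikes <- spikes[spikes$time >= window[1] & spikes$time < window[2], ]
  by_cell <- split(spikes$time, spikes$id)
  n_all <- length(by_cell)
  keep <- vapply(by_cell, length, integer(1)) >= min_spikes
  by_cell <- by_cell[keep]
  out <- tibble(id = as.integer(names(by_cell)),
                n_spikes = unname(vapply(by_cell, length, integer(1))),
                cv = unname(vapply(by_cell, function(tt) {
                  isi <- diff(sort(tt))
                  sd(isi) / mean(isi)
                }, numeric(1))))
  attr(out, "n_excluded") <- n_all - sum(keep)
  out
}

#' Binned population firing rate
#'
#' @param spikes Spike tibble.
#' @param n_cells Number of cells contributing.
#' @param bin Bin width (ms).
#' @param window `c(t0, t1)` in ms.
#' @return Tibble: `time` (bin centers, ms), `rate` (Hz per cell).
#' @export
bin_population_rate <- function(spikes, n_cells, bin = 5, window) {
  breaks <- seq(window[1], window[2], by = bin)
  sp <- spikes$time[spikes$time >= window[1] & spikes$time < breaks[length(breaks)]]
  counts <- tabulate(findInterval(sp, breaks), nbins = length(breaks) - 1)
  tibble(time = breaks[-length(breaks)] + bin / 2,
         rate = counts / n_cells / (bin / 1000))
}

#' Oscillation peak and synchrony of a spike record
#'
#' Bins the population rate (default 5 ms), locates the periodogram peak
#' within a frequency band, and computes a synchrony index: the variance of
#' the binned population rate compared against a spike-time-shuffled baseline
#' (each spike redrawn uniformly in the window, preserving counts), normalized
#' to `[0, 1]` - near 0 for independent Poisson activity, near 1 for lockstep
#' firing.
#'
#' @param spikes Spike tibble.
#' @param n_cells Number of cells.
#' @param band `c(f_lo, f_hi)` analysis band (Hz); the recording must span at
#'   least 10 cycles of `f_lo`.
#' @param window `c(t0, t1)` analysis window (ms).
#' @param bin Rate bin (ms).
#' @param n_shuffle Shuffle draws for the synchrony baseline.
#' @param seed Seed for the shuffles.
#' @return A `tc_osc` list: `peak_freq` (Hz), `peak_power`, `synchrony`,
#'   `spectrum` (tibble `freq`, `power`).
#' @export
oscillation_peak <- function(spikes, n_cells, band = c(1, 15), window,
                             bin = 5, n_shuffle = 20, seed = 1) {
  if (band[2] <= band[1] || band[1] <= 0) abort("band must be 0 < lo < hi")
  t_len <- window[2] - window[1]
  if (t_len < 10 * 1000 / band[1])
    abort("recording must span at least 10 cycles of the band's low edge")
  rate <- bin_population_rate(spikes, n_cells, bin, window)
  spec <- rate_periodogram(rate$rate, bin)
  in_band <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(in_band)) abort("analysis band contains no spectral estimates")
  pk <- which.max(spec$power[in_band])
  var_obs <- var(rate$rate)
  sp_win <- spikes[spikes$time >= window[1] & spikes$time < window[2], ]
  var_shuf <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(k) {
      sh <- tibble(time = runif(nrow(sp_win), window[1], window[2]))
      var(bin_population_rate(sh, n_cells, bin, window)$rate)
    }, numeric(1))
  })
  sync <- if (var_obs > 0) max(0, min(1, 1 - mean(var_shuf) / var_obs)) else 0
  structure(list(peak_freq = spec$freq[in_band][pk],
                 peak_power = spec$power[in_band][pk],
                 synchrony = sync,
                 spectrum = spec[in_band, ]),
            class = "tc_osc")
}

#' @export
print.tc_osc <- function(x, ...) {
  cat(sprintf("<tc_osc> peak %.2f Hz (power %.3g), synchrony %.3f\n",
              x$peak_freq, x$peak_power, x$synchrony))
  invisible(x)
}

# demeaned periodogram of a binned rate signal
rate_periodogram <- function(rate, bin_ms) {
  x <- rate - mean(rate)
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  fs <- 1000 / bin_ms
  k <- seq_len(floor(n / 2))
  tibble(freq = k * fs / n, power = P[k + 1])
}

#' Detect population bursts
#'
#' Thresholds the binned population rate at `mean + k * sd` (computed on the
#' window), merges crossings separated by less than `min_gap`, and reports
#' burst onsets.
#'
#' @param spikes Spike tibble.
#' @param n_cells Number of cells.
#' @param window `c(t0, t1)` in ms.
#' @param bin Rate bin (ms).
#' @param k Threshold in standard deviations above the mean.
#' @param min_gap Minimum gap between distinct bursts (ms).
#' @return Tibble of bursts: `onset`, `offset` (ms).
#' @export
detect_bursts <- function(spikes, n_cells, window, bin = 5, k = 2,
                          min_gap = 100) {
  rate <- bin_population_rate(spikes, n_cells, bin, window)
  thr <- mean(rate$rate) + k * sd(rate$rate)
  above <- rate$rate > thr
  if (!any(above)) return(tibble(onset = numeric(), offset = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- rate$time[starts[r$values]]
  off <- rate$time[ends[r$values]]
  # merge bursts separated by less than min_gap
  m_on <- on[1]; m_off <- off[1]
  out_on <- numeric(); out_off <- numeric()
  for (i in seq_along(on)[-1]) {
    if (on[i] - m_off <= min_gap) {
      m_off <- off[i]
    } else {
      out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
      m_on <- on[i]; m_off <- off[i]
    }
  }
  tibble(onset = c(out_on, m_on), offset = c(out_off, m_off))
}

#' Inter-burst frequency
#'
#' @param bursts Burst tibble from [detect_bursts()].
#' @return Frequency in Hz (`NA` with fewer than 2 bursts).
#' @export
burst_frequency <- function(bursts) {
  if (nrow(bursts) < 2) return(NA_real_)
  1000 / mean(diff(bursts$onset))
}
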