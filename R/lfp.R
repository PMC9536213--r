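#' Electrode array
#'
#' Default layout: four cortical depths (500, 1,000, 1,500 and 2,000 um) at
#' two radial XZ offsets (0 and 297 um) from the column axis.
#'
#' @param depths Electrode depths (um).
#' @param radial Radial XZ offsets (um; placed along the x axis).
#' @return Tibble: `electrode`, `x`, `y`, `z`.
#' @export
electrode_array <- function(depths = c(500, 1000, 1500, 2000),
                            radial = c(0, 297)) {
  grid <- tidyr::expand_grid(r = radial, y = depths)
  tibble(electrode = seq_len(nrow(grid)) - 1L,
         x = grid$r, y = grid$y, z = 0)
}

#' Line-source extracellular potential of one segment
#'
#' Closed-form potential of a segment carrying uniformly distributed current
#' in a homogeneous ohmic medium:
#' `phi = I / (4 pi sigma L) * [asinh((L - s0)/r) - asinh(-s0/r)]`,
#' where `L` is the segment length, `r` the perpendicular distance of the
#' electrode from the segment axis and `s0` its axial coordinate. Units:
#' current nA, distances um, conductivity mS/mm; the result is in uV. The
#' perpendicular distance is clamped at `min_dist` to guard electrodes on the
#' segment axis.
#'
#' @param segment List or one-row tibble with `x0, y0, z0, x1, y1, z1` (um).
#' @param current Transmembrane current (nA); vectorized.
#' @param electrode List or one-row tibble with `x, y, z` (um).
#' @param sigma Extracellular conductivity (mS/mm), homogeneous and
#'   frequency-independent.
#' @param min_dist Minimum electrode-segment distance (um).
#' @return Potential in uV (same length as `current`).
#' @export
line_source_potential <- function(segment, current, electrode, sigma = 0.3,
                                  min_dist = 1) {
  current * line_source_factor(segment, electrode, sigma, min_dist)
}

# geometry factor: potential in uV per nA of segment current
line_source_factor <- function(segment, electrode, sigma = 0.3, min_dist = 1) {
  a <- c(segment$x0, segment$y0, segment$z0)
  bb <- c(segment$x1, segment$y1, segment$z1)
  e <- c(electrode$x, electrode$y, electrode$z)
  L <- sqrt(sum((bb - a)^2))
  u <- (bb - a) / L
  rel <- e - a
  s0 <- sum(rel * u)
  r2 <- sum(rel * rel) - s0^2
  r <- sqrt(max(r2, 0))
  if (r < min_dist) r <- min_dist
  1000 / (4 * pi * sigma * L) * (asinh((L - s0) / r) - asinh(-s0 / r))
}

#' Compute LFP traces from segment-current frames
#'
#' Superposes the line-source potentials of all segments at each electrode and
#' timestep. The mapping is exactly linear in the currents: geometry factors
#' are computed once and applied as a matrix product.
#'
#' @param frames A [segment_frames()] object.
#' @param electrodes Electrode tibble (see [electrode_array()]).
#' @param sigma Conductivity (mS/mm).
#' @param min_dist Minimum electrode-segment distance (um).
#' @return A tibble with `time` and one `e<k>` column per electrode (uV).
#' @export
compute_lfp <- function(frames, electrodes, sigma = 0.3, min_dist = 1) {
  nseg <- nrow(frames$segments)
  nel <- nrow(electrodes)
  Fm <- matrix(0, nseg, nel)
  for (i in seq_len(nseg)) {
    for (j in seq_len(nel)) {
      Fm[i, j] <- line_source_factor(frames$segments[i, ], electrodes[j, ],
                                     sigma, min_dist)
    }
  }
  pot <- frames$currents %*% Fm
  out <- as_tibble(pot, .name_repair = ~ paste0("e", electrodes$electrode))
  dplyr::bind_cols(tibble(time = frames$times), out)
}

#' Welch power spectral density of an LFP trace
#'
#' Averaged windowed periodogram: the trace is split into segments of
#' `n_per_seg` samples with 50% overlap, Hann-windowed, and the per-segment
#' periodograms are averaged.
#'
#' @param trace Numeric signal (uV).
#' @param fs Sampling rate (Hz).
#' @param n_per_seg Samples per segment (defaults to 1/8 of the trace,
#'   rounded, at least 16).
#' @return Tibble: `freq` (Hz), `power`.
#' @export
lfp_psd <- function(trace, fs, n_per_seg = NULL) {
  n <- length(trace)
  if (is.null(n_per_seg)) n_per_seg <- max(16, floor(n / 8))
  if (n < n_per_seg) abort("trace shorter than the analysis window")
  step <- max(1, floor(n_per_seg / 2))
  starts <- seq(1, n - n_per_seg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_per_seg) / (n_per_seg + 1))
  scale <- fs * sum(win^2)
  acc <- numeric(floor(n_per_seg / 2))
  for (s in starts) {
    seg <- trace[s:(s + n_per_seg - 1)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(fft(seg))^2 / scale
    acc <- acc + P[2:(length(acc) + 1)]
  }
  acc <- acc / length(starts)
  tibble(freq = seq_along(acc) * fs / n_per_seg, power = acc)
}

#' Map recorded per-cell currents to balanced two-segment dipoles
#'
#' Point neurons carry no spatial current distribution; for LFP computation
#' each recorded cell is assigned a synthetic vertical two-segment cable: a
#' somatic segment at the cell position carrying the negative of its recorded
#' synaptic current (sink) and a dendritic return segment directly above
#' carrying the positive counterpart, so currents sum to zero at every
#' timestep. This is the minimal dipole consistent with synaptic currents
#' dominating the extracellular signal, and a deliberate simplification of
#' full-morphology currents.
#'
#' @param sim A `tc_sim` with recorded currents (`record_current` in the
#'   config).
#' @param dipole_length Somatic-to-dendritic segment offset (um).
#' @param segment_length Length of each segment (um).
#' @return A [segment_frames()] object.
#' @export
cell_current_frames <- function(sim, dipole_length = 200, segment_length = 50) {
  if (is.null(sim$i_syn)) abort("simulation has no recorded currents")
  ids <- unique(sim$i_syn$id)
  cells <- sim$cells[match(ids, sim$cells$id), ]
  times <- unique(sim$i_syn$time)
  imat <- matrix(sim$i_syn$i, nrow = length(times))
  # pA -> nA
  imat <- imat / 1000
  soma <- tibble(x0 = cells$x, y0 = cells$y, z0 = cells$z,
                 x1 = cells$x, y1 = cells$y + segment_length, z1 = cells$z)
  dend <- tibble(x0 = cells$x, y0 = cells$y - dipole_length, z0 = cells$z,
                 x1 = cells$x, y1 = cells$y - dipole_length + segment_length,
                 z1 = cells$z)
  segment_frames(bind_rows(soma, dend), cbind(-imat, imat), times)
}
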