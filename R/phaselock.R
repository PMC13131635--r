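#' Instantaneous phase via the Hilbert transform
#'
#' Zero-phase bandpass filters the signal to a narrow band (the gamma
#' phase-extraction band is 60-120 Hz), forms the analytic signal by FFT,
#' and returns its angle. Phase convention: 0 at the band-filtered signal
#' peak, +/- pi at the trough (cosine convention).
#'
#' @param x a [timeseries()] or numeric vector.
#' @param band a [band_spec()]; must span at most 2.5 octaves (the phase of
#'   a broadband signal is not meaningful). Pass NULL only if `x` is already
#'   narrowband filtered.
#' @param fs sample rate (from `x` when a `ts_sig`).
#' @return object of class `phase_series`: `phase` (radians in (-pi, pi]),
#'   `filtered` (the bandpassed signal), `fs`, `band`.
#' @export
hilbert_phase <- function(x, band = band_spec(60, 120), fs = NULL) {
  if (inherits(x, "ts_sig")) { fs <- x$fs; x <- x$data[, 1] }
  if (is.null(fs)) stopf("fs required for plain numeric input")
  if (is.null(band)) stopf("a narrowband filter specification is required prior to phase estimation")
  if (band$mode != "bandpass" || log2(band$high / band$low) > 2.5)
    stopf("phase extraction requires a bandpass spanning at most 2.5 octaves")
  xf <- band_filter(x, band, fs = fs)
  structure(list(phase = analytic_angle(xf), filtered = xf, fs = fs, band = band),
            class = "phase_series")
}

# angle of the FFT analytic signal
analytic_angle <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(X * h, inverse = TRUE) / n)
}

#' Downsample a phase series or filtered trace
#'
#' The phase path unwraps, linearly interpolates onto the coarse grid, and
#' rewraps to (-pi, pi]; the trace path uses cubic (spline) interpolation.
#'
#' @param phase a `phase_series` from [hilbert_phase()].
#' @param target_rate target sample rate, Hz (must be below the source
#'   rate).
#' @return a `phase_series` at the target rate (`filtered` resampled
#'   cubically alongside).
#' @export
downsample_phase <- function(phase, target_rate) {
  stopifnot(inherits(phase, "phase_series"))
  if (target_rate >= phase$fs) stopf("target rate must be below the source rate")
  n <- length(phase$phase)
  t_src <- (seq_len(n) - 1) / phase$fs
  t_tgt <- seq(0, t_src[n], by = 1 / target_rate)
  unw <- unwrap_phase(phase$phase)
  ph <- wrap_phase(approx(t_src, unw, xout = t_tgt)$y)
  filt <- spline(t_src, phase$filtered, xout = t_tgt)$y
  structure(list(phase = ph, filtered = filt, fs = target_rate, band = phase$band),
            class = "phase_series")
}

#' Downsample a trace with cubic interpolation
#' @param x a [timeseries()] or numeric vector.
#' @param target_rate target rate, Hz.
#' @param fs source rate (from `x` when a `ts_sig`).
#' @return numeric vector (or `ts_sig` if input was one) at `target_rate`.
#' @export
downsample_trace <- function(x, target_rate, fs = NULL) {
  is_ts <- inherits(x, "ts_sig")
  if (is_ts) { fs <- x$fs; dat <- x$data } else dat <- as.matrix(x)
  if (is.null(fs)) stopf("fs required for plain numeric input")
  if (target_rate >= fs) stopf("target rate must be below the source rate")
  n <- nrow(dat)
  t_src <- (seq_len(n) - 1) / fs
  t_tgt <- seq(0, t_src[n], by = 1 / target_rate)
  out <- apply(dat, 2, function(col) spline(t_src, col, xout = t_tgt)$y)
  if (is_ts) timeseries(out, target_rate, x$units, x$role, x$t0) else as.numeric(out)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  jump <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  p + jump
}

#' Register spike times to instantaneous phase
#'
#' Each spike is assigned the phase at the nearest sample of the phase
#' series. With `burst_collapse`, spikes whose preceding interspike interval
#' is below 6.67 ms belong to a burst and only the first spike of the burst
#' contributes a phase.
#'
#' @param spike_times_ms spike times in ms (relative to the phase series'
#'   first sample).
#' @param phase a `phase_series`.
#' @param burst_collapse apply the burst rule (default TRUE).
#' @param burst_isi_ms burst interspike-interval threshold, ms (default
#'   6.67).
#' @return list of class `spike_phase_set`: `phases`, `times_ms` (retained
#'   spikes), `n_dropped_outside`, `burst_collapsed`.
#' @export
register_spike_phases <- function(spike_times_ms, phase, burst_collapse = TRUE,
                                  burst_isi_ms = 6.67) {
  stopifnot(inherits(phase, "phase_series"))
  st <- sort(spike_times_ms)
  if (burst_collapse && length(st) > 1) {
    keep <- c(TRUE, diff(st) >= burst_isi_ms)
    st <- st[keep]
  }
  n <- length(phase$phase)
  idx <- round(st / 1000 * phase$fs) + 1L
  inside <- idx >= 1L & idx <= n
  dropped <- sum(!inside)
  structure(list(phases = phase$phase[idx[inside]], times_ms = st[inside],
                 n_dropped_outside = dropped, burst_collapsed = burst_collapse),
            class = "spike_phase_set")
}

#' Vector strength (phase-locking value) and mean angle
#'
#' R = |sum exp(i theta)| / N in [0, 1]; the mean angle is the argument of
#' the resultant.
#'
#' @param phases radians (a numeric vector or a `spike_phase_set`).
#' @return list with `R`, `mean_angle`, `n`.
#' @export
vector_strength <- function(phases) {
  if (inherits(phases, "spike_phase_set")) phases <- phases$phases
  n <- length(phases)
  if (n < 1) return(list(R = NA_real_, mean_angle = NA_real_, n = 0L))
  z <- sum(exp(1i * phases)) / n
  list(R = Mod(z), mean_angle = Arg(z), n = n)
}

#' Pairwise phase consistency (PPC)
#'
#' The bias-corrected phase-locking statistic: the average cosine of all
#' pairwise phase differences,
#' PPC = 2 / (N (N - 1)) * sum_{j<k} cos(theta_j - theta_k),
#' computed through the O(N) identity PPC = (N R^2 - 1) / (N - 1). Unlike
#' the vector strength, its expectation is 0 for uniform phases at any N,
#' making it robust to spike-count differences.
#'
#' @param phases radians (numeric vector or `spike_phase_set`).
#' @return PPC in [-1/(N-1), 1]; NA when N < 2.
#' @export
ppc <- function(phases) {
  if (inherits(phases, "spike_phase_set")) phases <- phases$phases
  n <- length(phases)
  if (n < 2) return(NA_real_)
  R <- vector_strength(phases)$R
  (n * R^2 - 1) / (n - 1)
}

#' Theta-phase and interspike-frequency histograms
#'
#' Spike-phase histogram over the stimulation period with 50 equally spaced
#' bins (width 2 pi / 50), and an interspike-frequency histogram with 10 Hz
#' bins (rate = 1000 / ISI_ms); both are normalized by the number of theta
#' cycles.
#'
#' @param spike_times_ms spike times, ms (same clock as the protocol).
#' @param protocol a [synth_protocol()] defining stimulation onset,
#'   frequency and cycle count.
#' @param n_phase_bins phase bins (default 50).
#' @param rate_bin_hz ISI-rate bin width (default 10 Hz).
#' @param max_rate_hz upper edge of the rate histogram (default 500).
#' @return list with data.frames `phase_hist` (bin centers in radians,
#'   spikes per cycle) and `isi_hist` (rate bin centers in Hz, counts per
#'   cycle), and `n_cycles`.
#' @export
theta_histograms <- function(spike_times_ms, protocol, n_phase_bins = 50,
                             rate_bin_hz = 10, max_rate_hz = 500) {
  ncyc <- protocol$n_cycles
  if (ncyc < 1) stopf("at least one stimulation cycle required")
  period <- 1000 / protocol$stim_freq
  st <- sort(spike_times_ms)
  st <- st[st >= protocol$pre_ms & st < protocol$pre_ms + protocol$stim_ms]
  ph <- wrap_phase(2 * pi * ((st - protocol$pre_ms) %% period) / period)
  edges <- seq(-pi, pi, length.out = n_phase_bins + 1)
  counts <- tabulate(findInterval(ph, edges, rightmost.closed = TRUE),
                     nbins = n_phase_bins)
  phase_hist <- data.frame(phase = (edges[-1] + edges[-length(edges)]) / 2,
                           per_cycle = counts / ncyc)
  isi <- diff(st)
  rates <- 1000 / isi[isi > 0]
  redges <- seq(0, max_rate_hz, by = rate_bin_hz)
  rates <- rates[rates < max_rate_hz]
  rcounts <- tabulate(findInterval(rates, redges, rightmost.closed = FALSE),
                      nbins = length(redges) - 1)
  isi_hist <- data.frame(rate = redges[-length(redges)] + rate_bin_hz / 2,
                         per_cycle = rcounts / ncyc)
  list(phase_hist = phase_hist, isi_hist = isi_hist, n_cycles = ncyc)
}

#' Pooled locking statistics per cell group
#'
#' Concatenates spike phases across cells of a type before computing the
#' vector strength and PPC (pooled, population-level locking), and also
#' reports per-cell statistics.
#'
#' @param phase_sets named list of `spike_phase_set` (or numeric phase
#'   vectors), one per cell.
#' @return list with `per_cell` (data.frame: cell, n, R, mean_angle, PPC)
#'   and `pooled` (n, R, mean_angle, PPC).
#' @export
locking_table <- function(phase_sets) {
  get_ph <- function(p) if (inherits(p, "spike_phase_set")) p$phases else p
  rows <- lapply(seq_along(phase_sets), function(i) {
    ph <- get_ph(phase_sets[[i]])
    vs <- vector_strength(ph)
    data.frame(cell = names(phase_sets)[i] %||% i, n = vs$n, R = vs$R,
               mean_angle = vs$mean_angle, PPC = ppc(ph))
  })
  all_ph <- unlist(lapply(phase_sets, get_ph))
  vs <- vector_strength(all_ph)
  list(per_cell = do.call(rbind, rows),
       pooled = list(n = vs$n, R = vs$R, mean_angle = vs$mean_angle,
                     PPC = ppc(all_ph)))
}
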