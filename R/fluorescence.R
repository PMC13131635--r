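#' Peak detection with prominence, width, height and distance constraints
#'
#' Local-maximum detection matching the constraint semantics of MATLAB's
#' findpeaks: a candidate peak must exceed `min_height`, have topographic
#' prominence of at least `min_prominence`, and a width measured at half the
#' peak height (width reference "halfheight") of at most `max_width`
#' samples; finally, of any peaks closer than `min_distance` samples, only
#' the highest is retained.
#'
#' @param x numeric vector.
#' @param min_height minimum peak value.
#' @param min_prominence minimum prominence (same units as `x`).
#' @param max_width maximum width at half height, samples (Inf = none).
#' @param min_distance minimum separation between retained peaks, samples.
#' @return data.frame with `index`, `height`, `prominence`, `width`.
#' @export
find_peaks <- function(x, min_height = -Inf, min_prominence = 0,
                       max_width = Inf, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(0), height = numeric(0),
                               prominence = numeric(0), width = numeric(0)))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(data.frame(index = integer(0), height = numeric(0),
                                       prominence = numeric(0), width = numeric(0)))
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  wid <- vapply(cand, function(i) peak_halfheight_width(x, i), numeric(1))
  keep <- wid <= max_width
  cand <- cand[keep]; prom <- prom[keep]; wid <- wid[keep]
  if (min_distance > 1 && length(cand) > 1) {
    ord <- order(x[cand], decreasing = TRUE)
    sel <- logical(length(cand))
    taken <- integer(0)
    for (j in ord) {
      if (!length(taken) || all(abs(cand[j] - taken) >= min_distance)) {
        sel[j] <- TRUE
        taken <- c(taken, cand[j])
      }
    }
    cand <- cand[sel]; prom <- prom[sel]; wid <- wid[sel]
  }
  ord <- order(cand)
  data.frame(index = cand[ord], height = x[cand][ord],
             prominence = prom[ord], width = wid[ord])
}

# topographic prominence of the peak at index i
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
  right <- if (i < length(x)) x[seq(i + 1, length(x))] else numeric(0)
  higher_l <- which(left >= h)
  base_l <- if (length(higher_l)) min(x[seq(max(higher_l) + 1L, i - 1L)]) else
    if (length(left)) min(left) else h
  higher_r <- which(right >= h)
  base_r <- if (length(higher_r)) {
    j <- min(higher_r)
    if (j > 1) min(right[seq_len(j - 1L)]) else h
  } else if (length(right)) min(right) else h
  h - max(base_l, base_r)
}

# width at half the peak height (interpolated crossings), in samples
peak_halfheight_width <- function(x, i) {
  ref <- x[i] / 2
  n <- length(x)
  li <- i
  while (li > 1 && x[li - 1] >= ref) li <- li - 1
  left <- if (li == 1) 1
          else (li - 1) + (ref - x[li - 1]) / (x[li] - x[li - 1])
  ri <- i
  while (ri < n && x[ri + 1] >= ref) ri <- ri + 1
  right <- if (ri == n) n
           else ri + (x[ri] - ref) / (x[ri] - x[ri + 1])
  right - left
}

#' Preprocess a raw fluorescence trace to depolarization-positive dF/F
#'
#' Slow fluorescence changes are removed with a zero-phase 4th-order
#' Butterworth bandstop (0.1-3 Hz) giving F_fast; dF/F is
#' (F_fast - mean(F_fast)) / mean(F_fast); because the indicator is
#' negative-going (depolarization darkens), the output is the inverted
#' trace -dF/F, in which spikes appear as positive peaks.
#'
#' @param trace a [timeseries()] (counts) or numeric vector.
#' @param frame_rate Hz (from `trace` when a `ts_sig`; default 800).
#' @return list of class `processed_trace` with `dff_fast` (the inverted,
#'   detrended dF/F), `frame_rate`.
#' @export
preprocess_dff <- function(trace, frame_rate = 800) {
  if (inherits(trace, "ts_sig")) { frame_rate <- trace$fs; trace <- trace$data[, 1] }
  if (frame_rate <= 6) stopf("frame rate must exceed 6 Hz for the 0.1-3 Hz bandstop")
  f_fast <- band_filter(as.numeric(trace), band_spec(0.1, 3, mode = "bandstop"),
                        fs = frame_rate)
  mu <- mean(f_fast)
  if (mu <= 0) stopf("non-positive mean fluorescence")
  dff <- (f_fast - mu) / mu
  structure(list(dff_fast = -dff, frame_rate = frame_rate),
            class = "processed_trace")
}

#' Noise estimate from the post-stimulation window
#'
#' Uses the first 100 ms after stimulation offset (when spiking is least
#' likely): the window is linearly detrended, restricted to negative values
#' (rectification against residual spike contamination), and the standard
#' deviation of the retained values is the noise estimate.
#'
#' @param x inverted dF/F trace (numeric or `processed_trace`).
#' @param stim_off_index frame index of stimulation offset.
#' @param frame_rate Hz.
#' @param window_ms noise window length, ms (default 100).
#' @return list with `sigma` and `degenerate` (TRUE when no negative values
#'   remain after detrending).
#' @export
estimate_noise <- function(x, stim_off_index, frame_rate = 800, window_ms = 100) {
  if (inherits(x, "processed_trace")) { frame_rate <- x$frame_rate; x <- x$dff_fast }
  nwin <- round(window_ms / 1000 * frame_rate)
  if (nwin < 10) stopf("noise window shorter than 10 frames")
  i0 <- stim_off_index + 1L
  i1 <- i0 + nwin - 1L
  if (i1 > length(x)) stopf("noise window extends beyond the trace")
  w <- x[i0:i1]
  w <- w - lsfit(seq_along(w), w)$coefficients %*% rbind(1, seq_along(w))
  w <- as.numeric(w)
  neg <- w[w < 0]
  if (!length(neg)) return(list(sigma = 0, degenerate = TRUE))
  list(sigma = sd(neg), degenerate = FALSE)
}

#' Detect spikes in an inverted dF/F trace
#'
#' The inverted trace is zero-phase highpass filtered at 50 Hz to remove
#' subthreshold activity, then peaks satisfying all four detector
#' constraints simultaneously (MinPeakDistance 2 samples, MaxPeakWidth 6
#' samples, MinPeakProminence 0.0075, MinPeakHeight 2 sigma_noise, width
#' reference half height) are located. Detected spikes are excised (peak
#' +/- one half-width, linear interpolation), the noise sd is recomputed on
#' the spike-removed trace (sigma_SRnoise), and peaks below 3.5
#' sigma_SRnoise are discarded. SNR_peak is the mean retained peak height
#' over sigma_SRnoise.
#'
#' @param proc a `processed_trace` from [preprocess_dff()], or numeric
#'   inverted dF/F.
#' @param sigma_noise noise estimate from [estimate_noise()].
#' @param frame_rate Hz.
#' @param min_prominence absolute -dF/F prominence threshold (default
#'   0.0075).
#' @param min_distance,max_width detector constants in samples (2 and 6).
#' @param final_sigma_mult final threshold in sigma_SRnoise multiples (3.5).
#' @return object of class `detected_spikes`: `frames`, `heights`,
#'   `widths`, `snr_peak`, `sigma_sr`, `dff_spikes` (the highpassed trace),
#'   `n_removed_final`.
#' @export
detect_spikes <- function(proc, sigma_noise, frame_rate = 800,
                          min_prominence = 0.0075, min_distance = 2,
                          max_width = 6, final_sigma_mult = 3.5) {
  if (inherits(proc, "processed_trace")) { frame_rate <- proc$frame_rate; x <- proc$dff_fast }
  else x <- as.numeric(proc)
  hp <- band_filter(x, band_spec(50, mode = "highpass"), fs = frame_rate)
  pk <- find_peaks(hp, min_height = 2 * sigma_noise,
                   min_prominence = min_prominence,
                   max_width = max_width, min_distance = min_distance)
  # excise detected spikes and re-estimate noise on the residual trace
  sr <- hp
  if (nrow(pk)) {
    for (r in seq_len(nrow(pk))) {
      hw <- max(1L, ceiling(pk$width[r] / 2))
      i0 <- max(1L, pk$index[r] - hw); i1 <- min(length(sr), pk$index[r] + hw)
      sr[i0:i1] <- NA
    }
    ok <- !is.na(sr)
    sr <- approx(which(ok), sr[ok], xout = seq_along(sr), rule = 2)$y
  }
  sigma_sr <- sd(sr)
  keep <- pk$height >= final_sigma_mult * sigma_sr
  n_removed <- sum(!keep)
  pk <- pk[keep, , drop = FALSE]
  snr_peak <- if (nrow(pk)) mean(pk$height) / sigma_sr else NA_real_
  structure(list(frames = pk$index, heights = pk$height, widths = pk$width,
                 snr_peak = snr_peak, sigma_sr = sigma_sr,
                 dff_spikes = hp, n_removed_final = n_removed,
                 frame_rate = frame_rate),
            class = "detected_spikes")
}

#' @export
print.detected_spikes <- function(x, ...) {
  cat(sprintf("<detected_spikes> %d spikes, SNR_peak %.2f (sigma_SR %.4g), %d below final threshold\n",
              length(x$frames), x$snr_peak, x$sigma_sr, x$n_removed_final))
  invisible(x)
}

#' Per-neuron quality control
#'
#' A neuron is excluded when SNR_peak < 3.75 or when it is "constantly
#' firing", operationalized as spiking in more than `tonic_frac` of the
#' recording's 50 ms bins.
#'
#' @param spikes a [detect_spikes()] result.
#' @param n_frames total frames of the recording.
#' @param min_snr SNR_peak cutoff (default 3.75).
#' @param bin_ms tonic-firing bin width, ms (default 50).
#' @param tonic_frac occupied-bin fraction above which the neuron counts as
#'   constantly firing (default 0.95).
#' @return list with `include` (logical) and `reason` ("ok", "low_snr",
#'   "constantly_firing", "no_spikes").
#' @export
qc_neuron <- function(spikes, n_frames, min_snr = 3.75, bin_ms = 50,
                      tonic_frac = 0.95) {
  if (!length(spikes$frames))
    return(list(include = FALSE, reason = "no_spikes"))
  if (is.na(spikes$snr_peak) || spikes$snr_peak < min_snr)
    return(list(include = FALSE, reason = "low_snr"))
  bin <- round(bin_ms / 1000 * spikes$frame_rate)
  nbins <- max(1L, floor(n_frames / bin))
  occupied <- length(unique(pmin(nbins, (spikes$frames - 1L) %/% bin + 1L)))
  if (occupied / nbins > tonic_frac)
    return(list(include = FALSE, reason = "constantly_firing"))
  list(include = TRUE, reason = "ok")
}

#' Full extraction pipeline for a fluorescence population
#'
#' Runs [preprocess_dff()], [estimate_noise()], [detect_spikes()] and
#' [qc_neuron()] per neuron.
#'
#' @param traces a `ts_sig` (columns = neurons) of raw fluorescence.
#' @param stim_off_index frame of stimulation offset.
#' @param ... passed to [detect_spikes()].
#' @return list with `spikes` (event table: neuron, frame, time_ms, height),
#'   `qc` (per-neuron table: neuron, n_spikes, snr_peak, include, reason),
#'   and `detections` (per-neuron `detected_spikes`).
#' @export
extract_spikes <- function(traces, stim_off_index, ...) {
  stopifnot(inherits(traces, "ts_sig"))
  fr <- traces$fs
  nn <- ncol(traces$data)
  dets <- vector("list", nn)
  qcs <- vector("list", nn)
  ev <- list()
  for (j in seq_len(nn)) {
    proc <- preprocess_dff(traces$data[, j], frame_rate = fr)
    nz <- estimate_noise(proc, stim_off_index)
    det <- detect_spikes(proc, nz$sigma, frame_rate = fr, ...)
    qc <- qc_neuron(det, n_frames = nrow(traces$data))
    dets[[j]] <- det
    qcs[[j]] <- data.frame(neuron = j, n_spikes = length(det$frames),
                           snr_peak = det$snr_peak, include = qc$include,
                           reason = qc$reason)
    if (qc$include && length(det$frames))
      ev[[length(ev) + 1L]] <- data.frame(neuron = j, frame = det$frames,
                                          time_ms = (det$frames - 1) * 1000 / fr,
                                          height = det$heights)
  }
  list(spikes = if (length(ev)) do.call(rbind, ev) else
         data.frame(neuron = integer(0), frame = integer(0),
                    time_ms = numeric(0), height = numeric(0)),
       qc = do.call(rbind, qcs), detections = dets)
}
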