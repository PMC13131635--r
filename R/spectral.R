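#' Band-filter specification
#'
#' 4th-order Butterworth filter applied forward and reverse (zero net phase
#' shift), the convention used for every filtering step in the pipeline.
#'
#' @param low,high band edges in Hz (`low` ignored for highpass, both used
#'   for bandpass/bandstop).
#' @param order filter order (default 4).
#' @param mode "bandpass", "bandstop" or "highpass".
#' @return list of class `band_spec`.
#' @export
band_spec <- function(low, high = NULL, order = 4, mode = "bandpass") {
  mode <- match.arg(mode, c("bandpass", "bandstop", "highpass"))
  if (mode != "highpass") {
    if (is.null(high) || low >= high) stopf("band requires low < high")
  }
  structure(list(low = low, high = high, order = order, mode = mode,
                 zero_phase = TRUE), class = "band_spec")
}

#' Zero-phase Butterworth filtering
#'
#' Designs the Butterworth filter for `spec` and applies it forward and
#' reverse so the net group delay is zero. Edges are handled by reflective
#' padding of three filter lengths to suppress start-up transients on short
#' windows.
#'
#' @param x a [timeseries()] or numeric vector.
#' @param spec a [band_spec()].
#' @param fs sample rate in Hz (taken from `x` when it is a `ts_sig`).
#' @return filtered series of the same class and length as `x`.
#' @export
band_filter <- function(x, spec, fs = NULL) {
  stopifnot(inherits(spec, "band_spec"))
  if (inherits(x, "ts_sig")) {
    fs <- x$fs
    out <- x
    out$data <- apply(x$data, 2, function(col) band_filter(col, spec, fs))
    if (!is.matrix(out$data)) out$data <- matrix(out$data, ncol = ncol(x$data))
    return(out)
  }
  if (is.null(fs)) stopf("fs required for plain numeric input")
  nyq <- fs / 2
  hi <- spec$high %||% Inf
  if (max(spec$low, if (is.finite(hi)) hi else spec$low) >= nyq)
    stopf("filter band [%g, %g] Hz reaches the Nyquist frequency (%g Hz)",
          spec$low, hi, nyq)
  sos <- butter_sos(spec$order, spec$low, spec$high, fs, spec$mode)
  filtfilt_refl(sos, as.numeric(x), fs = fs)
}

# Butterworth design in zero-pole-gain form, returned as second-order
# sections: transfer-function coefficients of narrow bands (e.g. 50-200 Hz
# at a 30+ kHz rate) are numerically singular, while biquad cascades stay
# well conditioned at any band.
butter_sos <- function(order, low, high, fs, mode) {
  proto <- exp(1i * pi * (2 * seq_len(order) + order - 1) / (2 * order))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (mode == "highpass") {
    wc <- warp(low)
    p <- wc / proto
    z <- rep(1 + 0i, order)            # digital zeros at z = +1
  } else {
    wl <- warp(low); wh <- warp(high)
    w0 <- sqrt(wl * wh); bw <- wh - wl
    if (mode == "bandpass") {
      pb <- proto * bw
      p <- c((pb + sqrt(pb^2 - 4 * w0^2)) / 2, (pb - sqrt(pb^2 - 4 * w0^2)) / 2)
      z <- rep(c(1 + 0i, -1 + 0i), order)   # one zero at z=1 and one at z=-1 per section
    } else {                           # bandstop
      pb <- bw / proto
      p <- c((pb + sqrt(pb^2 - 4 * w0^2)) / 2, (pb - sqrt(pb^2 - 4 * w0^2)) / 2)
      z0 <- (1 + 1i * w0 / (2 * fs)) / (1 - 1i * w0 / (2 * fs))
      z <- rep(c(z0, Conj(z0)), order)   # conjugate pair per section
    }
  }
  pd <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))    # bilinear transform
  pos <- pd[Im(pd) >= 0]
  pos <- pos[order(Mod(pos))]
  nsec <- length(pos)
  sos <- matrix(0, nsec, 6)
  zr <- z
  for (k in seq_len(nsec)) {
    pk <- pos[k]
    a <- if (abs(Im(pk)) > 1e-12) c(1, -2 * Re(pk), Mod(pk)^2) else {
      # pair real poles (arise only for odd orders; kept for generality)
      c(1, -Re(pk), 0)
    }
    take <- seq_len(min(2, length(zr)))
    zz <- zr[take]; zr <- zr[-take]
    b <- if (length(zz) == 2) c(1, -Re(zz[1] + zz[2]), Re(zz[1] * zz[2]))
         else if (length(zz) == 1) c(1, -Re(zz), 0) else c(1, 0, 0)
    sos[k, ] <- c(b, a)
  }
  # normalize overall gain at a band-specific reference frequency
  fref <- switch(mode, bandpass = sqrt(low * high), bandstop = 0, highpass = fs / 2)
  zref <- exp(2i * pi * fref / fs)
  H <- prod(vapply(seq_len(nsec), function(k) {
    b <- sos[k, 1:3]; a <- sos[k, 4:6]
    Mod(sum(b * zref^(0:-2)) / sum(a * zref^(0:-2)))
  }, numeric(1)))
  sos[1, 1:3] <- sos[1, 1:3] / H
  sos
}

# single biquad with steady-state initialization: the filter state starts
# at its fixed point for a constant input equal to the first sample, so
# slow poles (e.g. the 0.1 Hz bandstop edge) produce no start-up transient
biquad_filter <- function(b, a, x) {
  x0 <- x[1]
  K <- sum(b) / sum(a)
  xw <- stats::filter(c(x0, x0, x), b, method = "convolution", sides = 1)
  xw <- xw[-(1:2)]
  as.numeric(stats::filter(xw, -a[2:3], method = "recursive",
                           init = c(K * x0, K * x0)))
}

sos_apply <- function(sos, x) {
  for (k in seq_len(nrow(sos)))
    x <- biquad_filter(sos[k, 1:3], sos[k, 4:6], x)
  x
}

# forward-reverse (zero-phase) cascade with odd reflective padding sized to
# the slowest pole's time constant (so even near-unit-circle notch states
# have room to settle before the data proper)
filtfilt_refl <- function(sos, x, fs = 180) {
  n <- length(x)
  pmax_mod <- sqrt(max(sos[, 6]))           # |pole| of each conjugate pair
  tau <- if (pmax_mod < 1) 1 / (1 - pmax_mod) else n
  npad <- min(n - 1L, max(300L, as.integer(ceiling(3 * tau))))
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- c(pre, x, post)
  y <- sos_apply(sos, y)
  y <- rev(sos_apply(sos, rev(y)))
  y[npad + seq_len(n)]
}

#' Theta filtering band for a stimulation frequency
#'
#' The theta bandpass is adapted to the stimulation frequency: 4 Hz -> 2-6,
#' 8 Hz -> 4-12, 12 Hz -> 8-16, 16 Hz -> 12-20 Hz. Other frequencies have no
#' defined band and are rejected.
#'
#' @param stim_freq stimulation frequency, Hz (4, 8, 12 or 16).
#' @return a [band_spec()] for the matching theta band.
#' @export
theta_band_for_stim <- function(stim_freq) {
  tab <- list(`4` = c(2, 6), `8` = c(4, 12), `12` = c(8, 16), `16` = c(12, 20))
  key <- as.character(stim_freq)
  if (!key %in% names(tab)) stopf("no theta band defined for %s Hz stimulation", stim_freq)
  band_spec(tab[[key]][1], tab[[key]][2])
}

#' Analytic Morlet wavelet scalogram
#'
#' Continuous wavelet transform with the analytic Morlet wavelet
#' (omega0 = 6) on a log-spaced frequency grid with 32 voices per octave.
#' Power is the squared magnitude of the complex transform, normalized so a
#' unit-amplitude sinusoid yields peak power 1 independent of frequency
#' (i.e. peak power of A*sin(2 pi f t) is A^2); the 20 pA^2 quality-control
#' threshold is interpreted on this scale.
#'
#' @param x a [timeseries()] (single channel used) or numeric vector.
#' @param f_lo,f_hi analysis band in Hz.
#' @param fs sample rate (from `x` when a `ts_sig`).
#' @param voices voices per octave (default 32).
#' @return object of class `scalogram`: `power` (time x frequency),
#'   `freqs`, `fs`, `signal`, `omega0`, `voices`.
#' @export
morlet_scalogram <- function(x, f_lo = 30, f_hi = 200, fs = NULL, voices = 32) {
  if (inherits(x, "ts_sig")) { fs <- x$fs; x <- x$data[, 1] }
  if (is.null(fs)) stopf("fs required for plain numeric input")
  if (f_lo <= 0) stopf("f_lo must be positive")
  if (f_hi >= fs / 2) stopf("f_hi must lie below the Nyquist frequency")
  omega0 <- 6
  n_oct <- log2(f_hi / f_lo)
  freqs <- f_lo * 2^(seq(0, n_oct, by = 1 / voices))
  n <- length(x)
  nfft <- nextn(2 * n, 2)
  X <- fft(c(x - mean(x), rep(0, nfft - n)))
  w <- 2 * pi * fs * c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1)) / nfft
  pow <- matrix(0, n, length(freqs))
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])               # scale for center frequency
    psi <- numeric(nfft)
    pos <- w > 0
    psi[pos] <- 2 * exp(-0.5 * (s * w[pos] - omega0)^2)
    W <- fft(X * psi, inverse = TRUE) / nfft
    pow[, k] <- Mod(W[seq_len(n)])^2
  }
  structure(list(power = pow, freqs = freqs, fs = fs, signal = x,
                 omega0 = omega0, voices = voices),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d samples x %d frequencies (%.1f-%.1f Hz, %d voices/octave)\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs), x$voices))
  invisible(x)
}

#' @export
plot.scalogram <- function(x, ...) {
  t <- (seq_len(nrow(x$power)) - 1) / x$fs
  graphics::image(t, log2(x$freqs), x$power, xlab = "time (s)",
                  ylab = "log2 frequency (Hz)", yaxt = "n", ...)
  at <- pretty(log2(x$freqs))
  graphics::axis(2, at = at, labels = round(2^at))
  invisible(x)
}

#' Theta-cycle-averaged gamma peak with quality control
#'
#' Splits the scalogram into theta cycles, drops the first stimulation cycle
#' (transient network behaviour) and any cycle whose raw signal exceeds the
#' artifact threshold (3000 pA for currents, 1000 uV for LFP), averages
#' power over the remaining cycles (up to `max_cycles`), and extracts the
#' gamma peak. Quality control: peak power >= 20 units^2, half-power
#' bandwidth <= 100 Hz, and SNR (peak / band-mean power) >= 5.
#'
#' @param scalo a [morlet_scalogram()] result.
#' @param cycle_times cycle start times in ms (first entry = stimulation
#'   onset), including the end of the last cycle.
#' @param artifact_threshold per-cycle absolute signal threshold in the
#'   signal's units (3000 for pA, 1000 for uV).
#' @param max_cycles cycles averaged after dropping the first (default 40).
#' @param min_power,max_bw_hz,min_snr QC thresholds.
#' @param drop_first drop the first stimulation cycle (default TRUE).
#' @return object of class `gamma_peak`: `peak_freq`, `peak_power`,
#'   `bandwidth`, `snr`, `qc_pass`, `spectrum` (frequency profile),
#'   `cycles_used`, `cycles_rejected`.
#' @export
cycle_average_gamma_peak <- function(scalo, cycle_times, artifact_threshold = 3000,
                                     max_cycles = 40, min_power = 20,
                                     max_bw_hz = 100, min_snr = 5,
                                     drop_first = TRUE) {
  stopifnot(inherits(scalo, "scalogram"))
  if (length(cycle_times) < 3) stopf("need at least 2 cycles")
  idx <- round(cycle_times / 1000 * scalo$fs) + 1L
  ncyc <- length(cycle_times) - 1L
  first <- if (drop_first) 2L else 1L
  used <- 0L; rejected <- 0L
  acc <- matrix(0, 1, length(scalo$freqs))
  for (c in seq(first, ncyc)) {
    if (used >= max_cycles) break
    i0 <- max(1L, idx[c]); i1 <- min(nrow(scalo$power), idx[c + 1L] - 1L)
    if (i1 <= i0) next
    if (max(abs(scalo$signal[i0:i1])) > artifact_threshold) {
      rejected <- rejected + 1L
      next
    }
    acc <- acc + colMeans(scalo$power[i0:i1, , drop = FALSE])
    used <- used + 1L
  }
  if (used == 0L) {
    return(structure(list(peak_freq = NA_real_, peak_power = NA_real_,
                          bandwidth = NA_real_, snr = NA_real_, qc_pass = FALSE,
                          spectrum = NULL, cycles_used = 0L,
                          cycles_rejected = rejected, empty = TRUE),
                     class = "gamma_peak"))
  }
  spec <- as.numeric(acc / used)
  k <- which.max(spec)
  peak_freq <- scalo$freqs[k]
  peak_power <- spec[k]
  bw <- half_power_bandwidth(scalo$freqs, spec, k)
  snr <- peak_power / mean(spec)
  qc <- (peak_power >= min_power) && (bw <= max_bw_hz) && (snr >= min_snr)
  structure(list(peak_freq = peak_freq, peak_power = peak_power,
                 bandwidth = bw, snr = snr, qc_pass = qc,
                 spectrum = data.frame(freq = scalo$freqs, power = spec),
                 cycles_used = used, cycles_rejected = rejected, empty = FALSE),
            class = "gamma_peak")
}

# width at half maximum of the averaged power profile, linear interpolation
half_power_bandwidth <- function(freqs, spec, k) {
  half <- spec[k] / 2
  lo <- freqs[1]; hi <- freqs[length(freqs)]
  if (k > 1) {
    below <- which(spec[1:(k - 1)] < half)
    if (length(below)) {
      i <- max(below)
      lo <- freqs[i] + (freqs[i + 1] - freqs[i]) * (half - spec[i]) / (spec[i + 1] - spec[i])
    }
  }
  if (k < length(spec)) {
    below <- which(spec[(k + 1):length(spec)] < half) + k
    if (length(below)) {
      i <- min(below)
      hi <- freqs[i - 1] + (freqs[i] - freqs[i - 1]) * (spec[i - 1] - half) / (spec[i - 1] - spec[i])
    }
  }
  hi - lo
}

#' @export
print.gamma_peak <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<gamma_peak> empty (all cycles rejected)\n")
    return(invisible(x))
  }
  cat(sprintf("<gamma_peak> %.1f Hz, power %.2f, bandwidth %.1f Hz, SNR %.2f, QC %s\n",
              x$peak_freq, x$peak_power, x$bandwidth, x$snr,
              if (x$qc_pass) "pass" else "FAIL"))
  cat(sprintf("  cycles used %d, rejected %d\n", x$cycles_used, x$cycles_rejected))
  invisible(x)
}

#' Cross-correlation peak lag between two signals
#'
#' Pearson-normalized cross-correlation computed per analysis window (e.g.
#' stimulation theta cycles 2-6), averaged across windows; the peak is then
#' located according to `polarity` and reported as an absolute coefficient.
#' Lag sign convention: negative lag means the first signal precedes the
#' second.
#'
#' @param a,b equal-rate [timeseries()] or numeric vectors.
#' @param windows list of c(start_ms, end_ms) analysis windows; NULL = whole
#'   overlap as one window.
#' @param max_lag_ms maximum |lag| searched, ms.
#' @param polarity "positive", "negative" or "either": sign of the
#'   correlogram extremum to locate (currents that are sign-inverted
#'   relative to the LFP peak at a negative coefficient).
#' @param first if TRUE, report the local extremum of the requested polarity
#'   nearest zero lag (the "first peak" of a periodic correlogram) instead
#'   of the global extremum within the window.
#' @param fs sample rate (from inputs when `ts_sig`).
#' @return object of class `xcorr_result`: `peak_coefficient` (absolute
#'   value), `lag_ms`, `correlogram` (data.frame lag_ms, r), `n_windows`.
#' @export
xcorr_peak_lag <- function(a, b, windows = NULL, max_lag_ms = 10,
                           polarity = c("either", "positive", "negative"),
                           first = FALSE, fs = NULL) {
  polarity <- match.arg(polarity)
  if (inherits(a, "ts_sig")) { fs_a <- a$fs; t0 <- a$t0; a <- a$data[, 1] } else { fs_a <- fs; t0 <- 0 }
  if (inherits(b, "ts_sig")) { fs_b <- b$fs; b <- b$data[, 1] } else fs_b <- fs
  if (is.null(fs_a) || is.null(fs_b)) stopf("fs required for plain numeric input")
  if (fs_a != fs_b) stopf("sample rates differ (%g vs %g Hz)", fs_a, fs_b)
  fs <- fs_a
  maxlag <- round(max_lag_ms / 1000 * fs)
  if (maxlag < 1) stopf("max_lag_ms smaller than one sample")
  n <- min(length(a), length(b))
  if (is.null(windows)) {
    win_idx <- list(seq_len(n))
  } else {
    win_idx <- lapply(windows, function(w) {
      i0 <- max(1L, round((w[1] - t0) / 1000 * fs) + 1L)
      i1 <- min(n, round((w[2] - t0) / 1000 * fs))
      if (i1 - i0 < 2 * maxlag) stopf("window [%g, %g] ms too short for max lag", w[1], w[2])
      seq(i0, i1)
    })
  }
  lags <- seq(-maxlag, maxlag)
  acc <- numeric(length(lags))
  for (idx in win_idx) {
    aw <- a[idx]; bw <- b[idx]
    aw <- aw - mean(aw); bw <- bw - mean(bw)
    m <- length(aw)
    r <- vapply(lags, function(l) {
      if (l >= 0) {
        ia <- seq_len(m - l); ib <- ia + l
      } else {
        ib <- seq_len(m + l); ia <- ib - l
      }
      sum(aw[ia] * bw[ib]) / (sqrt(sum(aw^2) * sum(bw^2)))
    }, numeric(1))
    acc <- acc + r
  }
  avg <- acc / length(win_idx)
  sgn <- switch(polarity, positive = avg, negative = -avg, either = abs(avg))
  if (first) {
    nl <- length(sgn)
    locmax <- which(sgn[2:(nl - 1)] > sgn[1:(nl - 2)] &
                      sgn[2:(nl - 1)] >= sgn[3:nl]) + 1L
    locmax <- locmax[sgn[locmax] > 0]
    k <- if (length(locmax)) locmax[which.min(abs(lags[locmax]))] else which.max(sgn)
  } else {
    k <- which.max(sgn)
  }
  # internal lag l is the shift of b relative to a (b[i+l] ~ a[i]); the
  # reported convention is negative when a precedes b, i.e. reported = -l
  rep_lags <- -lags / fs * 1000
  ord <- order(rep_lags)
  structure(list(peak_coefficient = abs(avg[k]),
                 lag_ms = rep_lags[k],
                 correlogram = data.frame(lag_ms = rep_lags[ord], r = avg[ord]),
                 n_windows = length(win_idx)),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> |r| = %.3f at lag %.3f ms (%d window(s))\n",
              x$peak_coefficient, x$lag_ms, x$n_windows))
  invisible(x)
}
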