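#' Stimulation protocol for synthetic recordings
#'
#' Mirrors the acquisition protocol of the study conditions: sinusoidal
#' theta-frequency stimulation at 4, 8, 12 or 16 Hz with a per-frequency
#' number of cycles (16, 23, 17 and 16 respectively by default) and 500 ms
#' of unstimulated baseline before and after.
#'
#' @param stim_freq stimulation frequency, Hz: 4, 8, 12 or 16.
#' @param n_cycles number of stimulation cycles; default is the per-frequency
#'   protocol value.
#' @param pre_ms,post_ms unstimulated padding, ms.
#' @param sample_rate sample (or frame) rate, Hz.
#' @param seed RNG seed.
#' @return list of class `synth_protocol` with derived fields `stim_ms`
#'   (stimulation duration) and `total_ms`.
#' @export
synth_protocol <- function(stim_freq = 8, n_cycles = NULL, pre_ms = 500,
                           post_ms = 500, sample_rate = 30000, seed = 1) {
  if (!stim_freq %in% c(4, 8, 12, 16)) stopf("stim_freq must be 4, 8, 12 or 16 Hz")
  if (is.null(n_cycles))
    n_cycles <- c(`4` = 16, `8` = 23, `12` = 17, `16` = 16)[[as.character(stim_freq)]]
  if (n_cycles < 1) stopf("n_cycles must be >= 1")
  if (pre_ms < 0 || post_ms < 0) stopf("padding must be non-negative")
  stim_ms <- n_cycles * 1000 / stim_freq
  structure(list(stim_freq = stim_freq, n_cycles = n_cycles, pre_ms = pre_ms,
                 post_ms = post_ms, sample_rate = sample_rate, seed = seed,
                 stim_ms = stim_ms, total_ms = pre_ms + stim_ms + post_ms),
            class = "synth_protocol")
}

#' Theta-cycle start times of a protocol
#' @param protocol a [synth_protocol()].
#' @return cycle boundary times in ms (length n_cycles + 1), measured from
#'   the start of the recording.
#' @export
protocol_cycle_times <- function(protocol) {
  protocol$pre_ms + seq(0, protocol$n_cycles) * 1000 / protocol$stim_freq
}

# time grid (ms) and stimulation mask for a protocol
protocol_grid <- function(p) {
  n <- round(p$total_ms / 1000 * p$sample_rate)
  t <- (seq_len(n) - 1) * 1000 / p$sample_rate
  list(t = t, stim = t >= p$pre_ms & t < p$pre_ms + p$stim_ms, n = n)
}

# half-wave-rectified theta envelope (unit peak) on the stimulated window
theta_envelope <- function(t_ms, p) {
  env <- pmax(0, sin(2 * pi * p$stim_freq * (t_ms - p$pre_ms) / 1000))
  env[t_ms < p$pre_ms | t_ms >= p$pre_ms + p$stim_ms] <- 0
  env
}

#' Synthetic theta-nested gamma LFP
#'
#' Theta sinusoid plus a gamma sinusoid whose amplitude is gated by the
#' half-wave-rectified theta waveform (so gamma power peaks near the theta
#' peak), plus white Gaussian noise. Padding intervals carry noise only.
#'
#' @param protocol a [synth_protocol()].
#' @param gamma_freq gamma frequency, Hz (30-200, below Nyquist).
#' @param gamma_amp,theta_amp component amplitudes (signal units).
#' @param noise_sd white-noise standard deviation.
#' @return list with `lfp` (a `ts_sig`) and `truth` (planted parameters).
#' @export
gen_theta_gamma_lfp <- function(protocol, gamma_freq = 90, gamma_amp = 1,
                                theta_amp = 1, noise_sd = 0.1) {
  if (gamma_freq < 30 || gamma_freq > 200) stopf("gamma_freq must lie in [30, 200] Hz")
  if (protocol$sample_rate <= 2 * gamma_freq)
    stopf("gamma_freq %g Hz is at or above the Nyquist frequency", gamma_freq)
  with_seed(protocol$seed, {
    g <- protocol_grid(protocol)
    th_phase <- 2 * pi * protocol$stim_freq * (g$t - protocol$pre_ms) / 1000
    theta <- theta_amp * sin(th_phase)
    theta[!g$stim] <- 0
    env <- theta_envelope(g$t, protocol)
    gamma <- gamma_amp * env * sin(2 * pi * gamma_freq * (g$t - protocol$pre_ms) / 1000)
    x <- theta + gamma + rnorm(g$n, 0, noise_sd)
    list(lfp = timeseries(x, protocol$sample_rate, units = "uV", role = "lfp"),
         truth = list(gamma_freq = gamma_freq, gamma_amp = gamma_amp,
                      theta_amp = theta_amp, noise_sd = noise_sd,
                      stim_freq = protocol$stim_freq,
                      cycle_times = protocol_cycle_times(protocol)))
  })
}

#' Synthetic EPSC/IPSC pair with planted lag
#'
#' Two gamma-rhythmic, theta-enveloped currents: the IPSC is the EPSC
#' waveform shifted by `lag_ms` with independent noise and the opposite sign
#' convention (EPSC negative-going at -70 mV, IPSC positive-going at 0 mV).
#'
#' @param protocol a [synth_protocol()].
#' @param gamma_freq gamma frequency, Hz.
#' @param lag_ms IPSC lag behind the EPSC, ms; |lag| must be below half a
#'   gamma period (lag ambiguity otherwise).
#' @param amp_e,amp_i peak amplitudes, pA.
#' @param noise_sd additive noise sd, pA.
#' @return list with `epsc`, `ipsc` (ts_sig, pA) and `truth`.
#' @export
gen_psc_pair <- function(protocol, gamma_freq = 90, lag_ms = 3,
                         amp_e = 100, amp_i = 150, noise_sd = 5) {
  half_period <- 1000 / gamma_freq / 2
  if (abs(lag_ms) >= half_period)
    stopf("|lag_ms| = %g exceeds half a gamma period (%g ms)", abs(lag_ms), half_period)
  with_seed(protocol$seed, {
    g <- protocol_grid(protocol)
    wave <- function(t) {
      env <- theta_envelope(t, protocol)
      env * 0.5 * (1 + sin(2 * pi * gamma_freq * (t - protocol$pre_ms) / 1000))
    }
    epsc <- -amp_e * wave(g$t) + rnorm(g$n, 0, noise_sd)
    ipsc <- amp_i * wave(g$t - lag_ms) + rnorm(g$n, 0, noise_sd)
    list(epsc = timeseries(epsc, protocol$sample_rate, units = "pA", role = "current"),
         ipsc = timeseries(ipsc, protocol$sample_rate, units = "pA", role = "current"),
         truth = list(lag_ms = lag_ms, gamma_freq = gamma_freq,
                      amp_e = amp_e, amp_i = amp_i, noise_sd = noise_sd,
                      cycle_times = protocol_cycle_times(protocol)))
  })
}

# biexponential spike kernel sampled at frame resolution, peak height 1,
# width at half height ~2 frames (satisfies the 6-sample MaxPeakWidth bound)
spike_kernel <- function(tau_r = 0.5, tau_d = 1.2, len = 10) {
  t <- seq(0, len - 1)
  k <- exp(-t / tau_d) - exp(-t / tau_r)
  k / max(k)
}

#' Synthetic Voltron2-like fluorescence population
#'
#' Negative-going voltage-indicator traces: positive baseline with slow
#' drift, a small subthreshold theta component, negative biexponential spike
#' transients at planted times, and i.i.d. Gaussian noise per frame. The
#' planted spike amplitude is `snr_peak` times the noise sd.
#'
#' @param protocol a [synth_protocol()] (frame rate default 800 Hz).
#' @param n_neurons number of neurons.
#' @param firing_model "theta" (rate modulated by theta phase), "poisson"
#'   (homogeneous during stimulation), "tonic" (every ~3rd frame; emulates a
#'   constantly firing neuron) or "silent".
#' @param snr_peak planted spike amplitude / noise sd.
#' @param drift_amp slow drift amplitude as a fraction of baseline.
#' @param noise_sd noise sd in dF/F units (default 0.004).
#' @param rate_hz mean firing rate during stimulation, Hz.
#' @param theta_sub_amp subthreshold theta amplitude in dF/F units.
#' @param positions optional n x 2 matrix of pixel centroids; defaults to
#'   uniform positions on a 1160 x 325 px field (1 um/px).
#' @param baseline mean fluorescence counts.
#' @return list with `traces` (ts_sig matrix, counts; one column per
#'   neuron), `positions`, and `truth` (per-neuron planted spike frames and
#'   parameters).
#' @export
gen_fluorescence_population <- function(protocol = synth_protocol(sample_rate = 800),
                                        n_neurons = 40,
                                        firing_model = c("theta", "poisson", "tonic", "silent"),
                                        snr_peak = 8, drift_amp = 0.05,
                                        noise_sd = 0.004, rate_hz = 20,
                                        theta_sub_amp = 0.003,
                                        positions = NULL, baseline = 1000) {
  firing_model <- match.arg(firing_model)
  if (n_neurons < 1) stopf("n_neurons must be >= 1")
  if (snr_peak <= 0) stopf("snr_peak must be positive")
  with_seed(protocol$seed, {
    g <- protocol_grid(protocol)
    fr <- protocol$sample_rate
    kern <- spike_kernel()
    amp <- snr_peak * noise_sd
    if (is.null(positions))
      positions <- cbind(x = runif(n_neurons, 0, 1160), y = runif(n_neurons, 0, 325))
    traces <- matrix(0, g$n, n_neurons)
    spike_frames <- vector("list", n_neurons)
    env <- theta_envelope(g$t, protocol)
    for (j in seq_len(n_neurons)) {
      frames <- switch(firing_model,
        silent = integer(0),
        tonic = seq(3L, g$n - length(kern), by = 3L),
        poisson = which(g$stim & runif(g$n) < rate_hz / fr),
        theta = which(runif(g$n) < 3 * rate_hz / fr * env))
      # enforce the detector's minimum peak separation on planted truth
      if (length(frames) > 1) frames <- frames[c(TRUE, diff(frames) >= 3)]
      frames <- frames[frames + length(kern) <= g$n]
      spk <- numeric(g$n)
      for (f in frames) {
        rng <- f:(f + length(kern) - 1L)
        spk[rng] <- spk[rng] + amp * kern
      }
      drift <- drift_amp * sin(2 * pi * 0.2 * g$t / 1000 + runif(1, 0, 2 * pi))
      sub <- theta_sub_amp * env * sin(2 * pi * protocol$stim_freq *
                                         (g$t - protocol$pre_ms) / 1000)
      dff <- drift + sub - spk + rnorm(g$n, 0, noise_sd)
      traces[, j] <- baseline * (1 + dff)
      spike_frames[[j]] <- frames + 1L   # kernel peak is at offset +1 frame
    }
    stim_off_ms <- protocol$pre_ms + protocol$stim_ms
    list(traces = timeseries(traces, fr, units = "counts", role = "fluorescence"),
         positions = positions,
         truth = list(spike_frames = spike_frames, snr_peak = snr_peak,
                      amp_dff = amp, noise_sd = noise_sd,
                      stim_off_index = round(stim_off_ms / 1000 * fr),
                      firing_model = firing_model))
  })
}

#' Synthetic clustered population with shared latent signals
#'
#' Each neuron in cluster k mixes a common latent standard-normal signal
#' z_k with private noise: x = w z_k + sqrt(1 - w^2) e, with w =
#' sqrt(within_r), so the expected within-cluster Pearson correlation is
#' `within_r` and across-cluster correlation is 0.
#'
#' The per-neuron mixing weight carries mild jitter (`w_sd`): real neurons
#' do not share identical coupling to a population signal, and exactly
#' identical weights produce degenerate dendrograms whose within-cluster
#' merge heights tie, which the inconsistency criterion over-cuts.
#'
#' @param n_clusters number of clusters K.
#' @param sizes integer vector of cluster sizes (length K).
#' @param within_r target within-cluster correlation in [0, 1).
#' @param w_sd sd of the per-neuron mixing-weight jitter (0 = exactly
#'   exchangeable neurons, used by the closed-form checks).
#' @param n_samples samples per trace.
#' @param spatially_localized if TRUE, cluster members' centroids are drawn
#'   from compact 2-D blobs; otherwise positions are uniform on the field.
#' @param blob_sd blob sd in px.
#' @param seed RNG seed.
#' @return list with `traces` (matrix, columns = neurons), `positions`,
#'   `truth` (labels 1..K, mixing weight).
#' @export
gen_clustered_population <- function(n_clusters = 3, sizes = rep(12, n_clusters),
                                     within_r = 0.9, w_sd = 0.03,
                                     n_samples = 2800,
                                     spatially_localized = TRUE, blob_sd = 30,
                                     seed = 1) {
  if (within_r < 0 || within_r >= 1) stopf("within_r must lie in [0, 1)")
  if (length(sizes) != n_clusters) stopf("sizes must have length n_clusters")
  with_seed(seed, {
    n <- sum(sizes)
    labels <- rep(seq_len(n_clusters), sizes)
    w <- pmin(0.995, pmax(0.1, sqrt(within_r) + rnorm(n, 0, w_sd)))
    z <- matrix(rnorm(n_samples * n_clusters), n_samples, n_clusters)
    x <- sweep(z[, labels, drop = FALSE], 2, w, `*`) +
      sweep(matrix(rnorm(n_samples * n), n_samples, n), 2, sqrt(1 - w^2), `*`)
    if (spatially_localized) {
      centers <- cbind(runif(n_clusters, 150, 1010), runif(n_clusters, 80, 245))
      positions <- cbind(x = rnorm(n, centers[labels, 1], blob_sd),
                         y = rnorm(n, centers[labels, 2], blob_sd))
    } else {
      positions <- cbind(x = runif(n, 0, 1160), y = runif(n, 0, 325))
    }
    list(traces = x, positions = positions,
         truth = list(labels = labels, within_r = within_r, mixing_w = w,
                      w_sd = w_sd))
  })
}

#' Draw von Mises spike phases
#'
#' Best-Fisher rejection sampler. kappa = 0 gives uniform phases on
#' (-pi, pi].
#'
#' @param n number of phases.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @param seed RNG seed (NULL = current stream).
#' @return numeric vector of phases in (-pi, pi].
#' @export
gen_vonmises_phases <- function(n, mu = 0, kappa = 2, seed = NULL) {
  if (kappa < 0) stopf("kappa must be >= 0")
  with_seed(seed, {
    if (kappa == 0) {
      wrap_phase(runif(n, -pi, pi))
    } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(n)
    i <- 1L
    while (i <= n) {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        i <- i + 1L
      }
    }
    wrap_phase(out + mu)
    }
  })
}
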