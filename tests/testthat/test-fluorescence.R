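test_that("peak detector honors height, prominence, width and distance", {
  # two peaks 1 sample apart: only the larger survives the distance rule
  x <- numeric(50)
  x[20] <- 1; x[21] <- 0.8
  pk <- find_peaks(x, min_distance = 2)
  expect_identical(pk$index, 20L)
  # 2 samples apart: both retained
  y <- numeric(50); y[20] <- 1; y[22] <- 0.8
  pk2 <- find_peaks(y, min_distance = 2)
  expect_identical(pk2$index, c(20L, 22L))
  # min height
  expect_identical(nrow(find_peaks(y, min_height = 0.9, min_distance = 2)), 1L)
  # prominence: a ripple on a tall shoulder has low prominence
  z <- c(seq(0, 1, length.out = 20), 0.95, 0.97, 0.95, seq(0.9, 0, length.out = 20))
  ripple <- find_peaks(z, min_prominence = 0.1)
  expect_false(22L %in% ripple$index)
  # width at half height: a broad plateau-like peak is rejected by max_width
  w <- exp(-((1:100) - 50)^2 / (2 * 9^2))
  expect_identical(nrow(find_peaks(w, max_width = 6)), 0L)
  expect_identical(nrow(find_peaks(w, max_width = 30)), 1L)
})

test_that("dF/F preprocessing: constant trace, drift removal, inversion", {
  fr <- 800
  n <- 4000
  cst <- preprocess_dff(rep(1000, n), frame_rate = fr)
  expect_lt(max(abs(cst$dff_fast)), 1e-9)
  # pure 1 Hz drift attenuated below 5% of its amplitude
  t <- (seq_len(n) - 1) / fr
  dr <- preprocess_dff(1000 * (1 + 0.1 * sin(2 * pi * 1 * t)), frame_rate = fr)
  expect_lt(max(abs(dr$dff_fast[400:3600])), 0.05 * 0.1)
  # negative transient appears as a positive peak after inversion
  f <- rep(1000, n)
  f[2000:2002] <- f[2000:2002] * (1 - 0.02)
  inv <- preprocess_dff(f, frame_rate = fr)
  expect_gt(max(inv$dff_fast[2000:2002]), 0.015)
  expect_true(which.max(inv$dff_fast) %in% 2000:2002)
  expect_error(preprocess_dff(rep(-5, n), frame_rate = fr), "mean")
  expect_error(preprocess_dff(rep(1, 100), frame_rate = 5), "frame rate")
})

test_that("noise estimator matches the rectified-Gaussian Monte-Carlo oracle", {
  fr <- 800
  s <- 0.01
  # independent oracle: sd of the negative half of a detrended Gaussian window
  set.seed(31)
  mc <- replicate(4000, {
    w <- rnorm(80, 0, 1)
    w <- w - lsfit(seq_along(w), w)$coefficients %*% rbind(1, seq_along(w))
    sd(w[w < 0])
  })
  oracle <- mean(mc) * s
  set.seed(32)
  x <- rnorm(2000, 0, s)
  est <- estimate_noise(x, stim_off_index = 1000, frame_rate = fr)
  expect_equal(est$sigma, oracle, tolerance = 0.15)
  # scale equivariance
  est2 <- estimate_noise(2 * x, stim_off_index = 1000, frame_rate = fr)
  expect_equal(est2$sigma, 2 * est$sigma, tolerance = 1e-12)
  # all-positive window after detrend -> degenerate flag
  pos <- estimate_noise(c(numeric(100), rep(1, 80), numeric(100)) + seq(0, 1, length.out = 280) * 0,
                        stim_off_index = 100, frame_rate = fr)
  expect_true(pos$degenerate || pos$sigma == 0)
  expect_error(estimate_noise(x, stim_off_index = 1990, frame_rate = fr), "beyond")
})

test_that("final 3.5 sigma threshold prunes marginal peaks", {
  fr <- 800
  set.seed(33)
  x <- rnorm(4000, 0, 0.004)
  det0 <- detect_spikes(x, sigma_noise = 0.0024, frame_rate = fr)
  # plant one large and one marginal peak well separated
  xx <- x
  xx[1000] <- xx[1000] + 12 * det0$sigma_sr
  xx[2000] <- xx[2000] + 3.0 * det0$sigma_sr
  det <- detect_spikes(xx, sigma_noise = 0.0024, frame_rate = fr,
                       min_prominence = 0)
  expect_true(any(abs(det$frames - 1000) <= 1))
  expect_false(any(abs(det$frames - 2000) <= 1))
  expect_gt(det$n_removed_final, 0)
})

test_that("extraction hits the >90% sensitivity / <10% FDR bar at snr 8", {
  proto <- synth_protocol(8, sample_rate = 800, seed = 41)
  pop <- gen_fluorescence_population(proto, n_neurons = 12, snr_peak = 8)
  ex <- extract_spikes(pop$traces, pop$truth$stim_off_index)
  fid <- score_detection(ex, pop$truth, tol_frames = 2)
  expect_gte(fid$sensitivity, 0.9)
  expect_lte(fid$fdr, 0.1)
})

test_that("detection fidelity is monotone in snr_peak", {
  proto <- synth_protocol(8, n_cycles = 12, sample_rate = 800, seed = 42)
  sens <- vapply(c(3, 5, 8), function(s) {
    pop <- gen_fluorescence_population(proto, n_neurons = 6, snr_peak = s)
    ex <- extract_spikes(pop$traces, pop$truth$stim_off_index)
    score_detection(ex, pop$truth, tol_frames = 2)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= -0.02))   # non-decreasing up to noise
  expect_gt(sens[3], sens[1])
})

test_that("detection is translation-equivariant and amplitude-scale invariant", {
  proto <- synth_protocol(8, n_cycles = 6, sample_rate = 800, seed = 43)
  pop <- gen_fluorescence_population(proto, n_neurons = 1, snr_peak = 10)
  f <- pop$traces$data[, 1]
  run <- function(f) {
    pr <- preprocess_dff(f, frame_rate = 800)
    nz <- estimate_noise(pr, pop$truth$stim_off_index)
    detect_spikes(pr, nz$sigma, frame_rate = 800)$frames
  }
  base <- run(f)
  k <- 160
  shifted <- run(c(f[(k + 1):length(f)], f[1:k]))
  common <- base[base > k + 10 & base < length(f) - 10]
  expect_true(all((common - k) %in% shifted))
  # multiplying raw fluorescence leaves dF/F and detections unchanged
  expect_identical(run(3.7 * f), base)
})

test_that("neuron QC applies the 3.75 SNR cutoff and the tonic-firing rule", {
  set.seed(124)
  det <- list(frames = sort(sample(4000, 60)), snr_peak = 3.7, frame_rate = 800)
  expect_identical(qc_neuron(det, 4000)$reason, "low_snr")
  det$snr_peak <- 5
  expect_true(qc_neuron(det, 4000)$include)
  # firing in ~every 50 ms bin across the recording
  tonic <- list(frames = seq(2, 4000, by = 10), snr_peak = 8, frame_rate = 800)
  expect_identical(qc_neuron(tonic, 4000)$reason, "constantly_firing")
  none <- list(frames = integer(0), snr_peak = NA_real_, frame_rate = 800)
  expect_identical(qc_neuron(none, 4000)$reason, "no_spikes")
})

test_that("generator rejects spikes closer than the detector minimum distance", {
  proto <- synth_protocol(8, n_cycles = 4, sample_rate = 800, seed = 44)
  pop <- gen_fluorescence_population(proto, n_neurons = 5, firing_model = "poisson",
                                     rate_hz = 120)
  for (fr in pop$truth$spike_frames)
    if (length(fr) > 1) expect_true(all(diff(fr) >= 3))
})
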