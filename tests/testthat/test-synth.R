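test_that("generators are bit-reproducible under a fixed seed", {
  p <- short_protocol()
  a <- gen_theta_gamma_lfp(p)
  b <- gen_theta_gamma_lfp(p)
  expect_identical(a$lfp$data, b$lfp$data)
  pa <- gen_psc_pair(p)
  pb <- gen_psc_pair(p)
  expect_identical(pa$epsc$data, pb$epsc$data)
  fa <- gen_fluorescence_population(synth_protocol(8, n_cycles = 4, sample_rate = 800),
                                    n_neurons = 3)
  fb <- gen_fluorescence_population(synth_protocol(8, n_cycles = 4, sample_rate = 800),
                                    n_neurons = 3)
  expect_identical(fa$traces$data, fb$traces$data)
  expect_identical(gen_vonmises_phases(50, 0.3, 2, seed = 7),
                   gen_vonmises_phases(50, 0.3, 2, seed = 7))
})

test_that("degenerate LFP settings give a pure theta sinusoid", {
  p <- short_protocol()
  g <- gen_theta_gamma_lfp(p, gamma_amp = 0, theta_amp = 1, noise_sd = 0)
  x <- g$lfp$data[, 1]
  t <- ts_time(g$lfp)
  stim <- t >= p$pre_ms & t < p$pre_ms + p$stim_ms
  expect_equal(x[stim], sin(2 * pi * 8 * (t[stim] - p$pre_ms) / 1000),
               tolerance = 1e-12)
  expect_true(all(x[!stim] == 0))
})

test_that("generated gamma peaks at the planted frequency (FFT oracle)", {
  p <- synth_protocol(8, n_cycles = 8, sample_rate = 4000, seed = 2)
  g <- gen_theta_gamma_lfp(p, gamma_freq = 90, noise_sd = 0.02)
  # independent oracle: periodogram argmax of the gamma-band component
  x <- g$lfp$data[, 1]
  n <- length(x)
  spec <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) * p$sample_rate / n
  gb <- freqs > 50 & freqs < 200
  f_fft <- freqs[gb][which.max(spec[gb])]
  sc <- morlet_scalogram(g$lfp, 50, 200)
  f_wav <- sc$freqs[which.max(colSums(sc$power))]
  voice <- 2^(1 / 32)
  expect_lt(abs(log(f_wav / f_fft)), log(voice) * 1.5)
  expect_lt(abs(log(f_wav / 90)), log(voice) * 1.5)
})

test_that("gamma power concentrates in the stimulated epoch", {
  p <- short_protocol(sample_rate = 4000)
  g <- gen_theta_gamma_lfp(p, gamma_freq = 90, noise_sd = 0.02)
  sc <- morlet_scalogram(g$lfp, 60, 120)
  t <- ts_time(g$lfp)
  stim <- t >= p$pre_ms & t < p$pre_ms + p$stim_ms
  expect_gt(mean(sc$power[stim, ]), 10 * mean(sc$power[!stim, ]))
})

test_that("PSC pair carries the planted lag and sign conventions", {
  p <- synth_protocol(8, n_cycles = 6, sample_rate = 30000, seed = 3)
  ps <- gen_psc_pair(p, gamma_freq = 90, lag_ms = 3, noise_sd = 1)
  expect_lt(mean(ps$epsc$data), 0)   # EPSC negative-going
  expect_gt(mean(ps$ipsc$data), 0)   # IPSC positive-going
  wins <- lapply(2:6, function(c) c(ps$truth$cycle_times[c], ps$truth$cycle_times[c + 1]))
  x <- xcorr_peak_lag(band_filter(ps$epsc, band_spec(50, 200)),
                      band_filter(ps$ipsc, band_spec(50, 200)),
                      windows = wins, max_lag_ms = 5, polarity = "negative",
                      first = TRUE)
  expect_equal(x$lag_ms, -3, tolerance = 1 / 30)   # one sample at 30 kHz
  # zero lag, zero noise: peak exactly at 0
  p0 <- gen_psc_pair(p, lag_ms = 0, noise_sd = 0)
  x0 <- xcorr_peak_lag(-p0$epsc$data[, 1], p0$ipsc$data[, 1], max_lag_ms = 4,
                       polarity = "positive", fs = 30000)
  expect_equal(x0$lag_ms, 0)
  expect_gt(x0$peak_coefficient, 0.99)
})

test_that("PSC lag beyond half a gamma period is rejected", {
  p <- short_protocol()
  expect_error(gen_psc_pair(p, gamma_freq = 90, lag_ms = 6), "half a gamma period")
  expect_error(gen_theta_gamma_lfp(synth_protocol(8, sample_rate = 300), gamma_freq = 190),
               "Nyquist")
})

test_that("noise-only PSC fails scalogram QC with SNR below 5", {
  p <- synth_protocol(8, n_cycles = 8, sample_rate = 2000, seed = 4)
  ps <- gen_psc_pair(p, amp_e = 0, amp_i = 150, noise_sd = 5)
  sc <- morlet_scalogram(ps$epsc, 50, 200)
  gp <- cycle_average_gamma_peak(sc, ps$truth$cycle_times)
  expect_false(gp$qc_pass)
  expect_lt(gp$snr, 5)
})

test_that("latent-model pairwise correlation matches the closed form", {
  # r = w^2 / (w^2 + (1 - w^2)) = w^2 for the shared-latent mixture
  cl <- gen_clustered_population(2, c(6, 6), within_r = 0.64, w_sd = 0,
                                 n_samples = 10000, seed = 5)
  r <- cor(cl$traces)
  same <- outer(cl$truth$labels, cl$truth$labels, `==`) & upper.tri(r)
  diff <- !outer(cl$truth$labels, cl$truth$labels, `==`) & upper.tri(r)
  expect_equal(mean(r[same]), 0.64, tolerance = 0.05)
  expect_lt(abs(mean(r[diff])), 0.05)
})

test_that("clustered generator validates inputs and labels cover 1..K", {
  expect_error(gen_clustered_population(2, c(5, 5), within_r = 1), "within_r")
  cl <- gen_clustered_population(4, c(3, 4, 5, 6), seed = 6)
  expect_identical(sort(unique(cl$truth$labels)), 1:4)
  expect_identical(length(cl$truth$labels), ncol(cl$traces))
})

test_that("von Mises phases: uniform limit, degenerate limit, Bessel PPC", {
  u <- gen_vonmises_phases(100000, 0, 0, seed = 8)
  expect_lt(vector_strength(u)$R, 0.02)
  expect_true(all(u > -pi & u <= pi))
  expect_equal(ppc(rep(1.2, 50)), 1)
  v <- gen_vonmises_phases(5000, 1, 2, seed = 9)
  bessel <- (besselI(2, 1) / besselI(2, 0))^2
  expect_equal(ppc(v), bessel, tolerance = 0.05)
  expect_equal(vector_strength(v)$mean_angle, 1, tolerance = 0.1)
})
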