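test_that("Hilbert phase follows the cosine convention on a pure tone", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  x <- cos(2 * pi * 90 * t)
  ph <- hilbert_phase(x, band_spec(60, 120), fs = fs)
  mid <- 500:3500
  peaks <- mid[x[mid] > 0.9999]
  expect_lt(max(abs(ph$phase[peaks])), 0.05)           # phase 0 at peak
  troughs <- mid[x[mid] < -0.9999]
  expect_gt(min(abs(ph$phase[troughs])), pi - 0.05)    # +/- pi at trough
  # phase advances 2 pi f / fs per sample
  dp <- diff(thetagamma:::unwrap_phase(ph$phase[mid]))
  expect_equal(median(dp), 2 * pi * 90 / fs, tolerance = 1e-3)
  expect_error(hilbert_phase(x, NULL, fs = fs), "narrowband")
  expect_error(hilbert_phase(x, band_spec(10, 120), fs = fs), "octaves")
})

test_that("instantaneous frequency tracks a planted frequency modulation", {
  fs <- 4000
  t <- seq(0, 3, by = 1 / fs)
  f_inst <- 90 + 8 * sin(2 * pi * 0.5 * t)
  x <- cos(2 * pi * cumsum(f_inst) / fs)
  ph <- hilbert_phase(x, band_spec(60, 120), fs = fs)
  est <- diff(thetagamma:::unwrap_phase(ph$phase)) * fs / (2 * pi)
  sm <- stats::filter(est, rep(1 / 201, 201))
  mid <- 2000:10000
  expect_lt(max(abs(sm[mid] - f_inst[mid]), na.rm = TRUE), 2)
})

test_that("phase downsampling interpolates the unwrapped path", {
  fs <- 33000
  t <- seq(0, 1, by = 1 / fs)
  x <- cos(2 * pi * 90 * t)
  ph <- hilbert_phase(x, band_spec(60, 120), fs = fs)
  dn <- downsample_phase(ph, 800)
  expect_identical(dn$fs, 800)
  # no interpolation across wrap discontinuities: steps stay below pi
  dd <- abs(diff(dn$phase))
  expect_true(all(pmin(dd, 2 * pi - dd) < pi))
  # slope preserved: 90 Hz at 800 Hz is ~0.7069 rad/sample
  dun <- diff(thetagamma:::unwrap_phase(dn$phase[100:600]))
  expect_equal(median(dun), 2 * pi * 90 / 800, tolerance = 1e-3)
  expect_error(downsample_phase(ph, 50000), "below the source")
  # cubic trace downsampling evaluates through the knots
  dt <- downsample_trace(x, 800, fs = fs)
  keep <- seq(1, length(dt))
  tt <- (keep - 1) / 800
  expect_equal(dt[100:500], cos(2 * pi * 90 * tt[100:500]), tolerance = 1e-3)
})

test_that("spike registration applies the 6.67 ms burst rule", {
  fs <- 1000
  ph <- structure(list(phase = rep(0, 1000), filtered = numeric(1000),
                       fs = fs, band = band_spec(60, 120)),
                  class = "phase_series")
  # ISIs 4 and 5 ms: one burst, first spike only
  s1 <- register_spike_phases(c(100, 104, 109), ph)
  expect_identical(length(s1$phases), 1L)
  # ISI 10 ms: both retained
  s2 <- register_spike_phases(c(100, 110), ph)
  expect_identical(length(s2$phases), 2L)
  # collapsing never increases the count
  set.seed(51)
  st <- sort(runif(40, 0, 900))
  expect_lte(length(register_spike_phases(st, ph)$phases),
             length(register_spike_phases(st, ph, burst_collapse = FALSE)$phases))
  # spikes outside support are dropped and counted
  s3 <- register_spike_phases(c(-5, 100, 2000), ph, burst_collapse = FALSE)
  expect_identical(s3$n_dropped_outside, 2L)
})

test_that("spikes planted at gamma troughs register phases near +/- pi", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  x <- cos(2 * pi * 80 * t)
  ph <- hilbert_phase(x, band_spec(60, 120), fs = fs)
  trough_times <- (seq(20, 130) + 0.5) * 1000 / 80   # cos trough at (k+1/2)/f
  sp <- register_spike_phases(trough_times, ph, burst_collapse = FALSE)
  expect_gt(min(abs(sp$phases)), pi - 0.3)
})

test_that("vector strength and PPC: exact cases and the O(n) identity", {
  expect_equal(vector_strength(rep(0.7, 9))$R, 1)
  expect_equal(ppc(rep(0.7, 9)), 1)
  anti <- c(0.3, 0.3 - pi)
  expect_equal(vector_strength(anti)$R, 0, tolerance = 1e-12)
  expect_equal(ppc(anti), -1, tolerance = 1e-12)
  expect_identical(vector_strength(numeric(0))$n, 0L)
  expect_true(is.na(ppc(1.0)))
  # brute-force pairwise sum equals (N R^2 - 1)/(N - 1) to machine precision
  set.seed(52)
  for (n in c(2, 5, 40)) {
    th <- runif(n, -pi, pi)
    brute <- mean(cos(outer(th, th, `-`)[upper.tri(diag(n))]))
    expect_equal(ppc(th), brute, tolerance = 1e-12)
  }
})

test_that("PPC is unbiased at N = 5 while R is positively biased", {
  set.seed(53)
  draws <- replicate(1000, {
    th <- runif(5, -pi, pi)
    c(R = vector_strength(th)$R, ppc = ppc(th))
  })
  se <- sd(draws["ppc", ]) / sqrt(1000)
  expect_lt(abs(mean(draws["ppc", ])), 3 * se)
  expect_gt(mean(draws["R", ]), 0.2)
})

test_that("rotating phases shifts the mean angle and leaves R and PPC fixed", {
  set.seed(54)
  th <- gen_vonmises_phases(300, 0.4, 3)
  rot <- wrap_phase(th + 1.1)
  expect_equal(vector_strength(rot)$R, vector_strength(th)$R, tolerance = 1e-12)
  expect_equal(ppc(rot), ppc(th), tolerance = 1e-12)
  expect_equal(wrap_phase(vector_strength(rot)$mean_angle -
                            vector_strength(th)$mean_angle), 1.1,
               tolerance = 1e-9)
})

test_that("theta histograms: bin placement and per-cycle normalization", {
  p <- synth_protocol(8, n_cycles = 40, pre_ms = 500, post_ms = 500,
                      sample_rate = 1000, seed = 55)
  # one spike per cycle at cycle phase 0
  st <- p$pre_ms + (0:39) * 125
  h <- theta_histograms(st, p)
  expect_equal(sum(h$phase_hist$per_cycle), 1)
  expect_identical(sum(h$phase_hist$per_cycle > 0), 1L)
  expect_equal(max(h$phase_hist$per_cycle), 1)
  expect_identical(nrow(h$phase_hist), 50L)
  expect_equal(diff(h$phase_hist$phase)[1], 2 * pi / 50)
  # 12.5 ms within-pair ISIs (rate 1000/12.5 = 80 Hz) land in the 80-90 Hz
  # bin with one event per cycle; the slow between-pair ISIs fall below 10 Hz
  st2 <- sort(c(st, st + 12.5))
  h2 <- theta_histograms(st2, p)
  expect_equal(h2$isi_hist$per_cycle[h2$isi_hist$rate == 85], 1)
  expect_true(all(h2$isi_hist$per_cycle[h2$isi_hist$rate > 10 &
                                          h2$isi_hist$rate != 85] == 0))
  # uniform-phase Poisson spikes: flat histogram by chi-squared
  set.seed(56)
  st3 <- sort(runif(4000, p$pre_ms, p$pre_ms + p$stim_ms))
  h3 <- theta_histograms(st3, p)
  counts <- h3$phase_hist$per_cycle * 40
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = 49))
})

test_that("pooled locking concatenates phases across cells", {
  a <- gen_vonmises_phases(200, 0, 2, seed = 57)
  b <- gen_vonmises_phases(300, 0, 2, seed = 58)
  tab <- locking_table(list(a = a, b = b))
  expect_identical(tab$pooled$n, 500L)
  expect_equal(tab$pooled$R, vector_strength(c(a, b))$R)
  expect_identical(nrow(tab$per_cell), 2L)
})
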