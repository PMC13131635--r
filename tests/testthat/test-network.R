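test_that("theta drive follows the half-wave-rectified conductance waveform", {
  spec <- drive_spec(freq_hz = 8, g_peak_nS = 15)
  # theta peak: g = 15 nS, v = -60 mV -> 15 * 60 = 900 pA inward
  t_peak <- 1000 / 8 / 4
  expect_equal(theta_drive(t_peak, spec, v = -60), 900)
  # trough (sin < 0): rectified to zero
  t_trough <- 3 * 1000 / 8 / 4
  expect_equal(theta_drive(t_trough, spec, v = -60), 0)
  # at the reversal potential the driving force vanishes
  expect_equal(theta_drive(t_peak, spec, v = 0), 0)
  # settling window carries no drive
  expect_equal(theta_drive(2500, spec, v = -60, absolute = TRUE), 0)
  expect_error(drive_spec(g_peak_nS = -1), "non-negative")
})

test_that("connectivity sampling matches configured Bernoulli probabilities", {
  fr <- sapply(1:20, function(s) connection_fractions(
    build_network(n_e = 80, n_i = 40, seed = s)))
  m <- rowMeans(fr)
  # 3 binomial SEs of the mean over 20 seeds
  se <- function(p, n) 3 * sqrt(p * (1 - p) / (n * 20))
  expect_lt(abs(m["ii"] - 0.35), se(0.35, 40 * 39))
  expect_lt(abs(m["ie"] - 0.20), se(0.20, 40 * 80))
  expect_lt(abs(m["ei"] - 0.25), se(0.25, 80 * 40))
  expect_lt(abs(m["gap"] - 0.20), se(0.20, 40 * 39 / 2))
})

test_that("network construction enforces structural rules", {
  net <- build_network(n_e = 30, n_i = 10, seed = 3)
  expect_true(all(net$ii$pre != net$ii$post))           # no self-connections
  expect_true(all(net$gap$a < net$gap$b))               # unordered pairs
  expect_true(all(net$ii$delay >= 0.6 & net$ii$delay <= 1.0))
  expect_error(build_network(p_ee = 0.1), "E->E")
  expect_error(build_network(p_ii = 1.2), "probabilities")
  p0 <- build_network(n_e = 10, n_i = 5, p_ii = 0, p_ie = 0, p_ei = 0,
                      p_gap = 0, seed = 1)
  expect_identical(nrow(p0$ii) + nrow(p0$ie) + nrow(p0$ei) + nrow(p0$gap), 0L)
  expect_identical(build_network(n_e = 20, n_i = 10, seed = 9)$ie,
                   build_network(n_e = 20, n_i = 10, seed = 9)$ie)
})

test_that("gap-junction pair currents are antisymmetric", {
  net <- tiny_net(seed = 2)
  v <- c(-70, -55, -62)
  gc <- gap_pair_currents(v, net$gap)
  expect_equal(gc$i_a, -gc$i_b)
  expect_equal(gc$i_a, net$gap$g * (v[net$gap$b] - v[net$gap$a]))
})

test_that("sampled populations are quiescent at rest and silent without drive", {
  net <- build_network(n_e = 20, n_i = 10, p_ii = 0.35, p_ie = 0.2, p_ei = 0.25,
                       p_gap = 0.2, seed = 4)
  sim <- simulate_ping(net, drive = drive_spec(g_peak_nS = 0, settle_s = 1),
                       duration_s = 1, n_readout = 0, record_v = c(1, 21),
                       seed = 4)
  expect_identical(sum(sim$spikes$time_ms >= 0), 0L)
})

test_that("drive evokes E spikes and E->I removal silences the I population", {
  net <- build_network(n_e = 20, n_i = 10, seed = 5,
                       syn = synapse_spec(ie_mean_nS = 0.15 / 0.05,
                                          w_ii = 1 / 0.05, g_gap = 0.8 / 0.05,
                                          w_ei = 0.8 / 0.05))
  sim <- simulate_ping(net, drive = drive_spec(settle_s = 1), duration_s = 1,
                       n_readout = 2, seed = 5)
  spk <- sim$spikes[sim$spikes$time_ms >= 0, ]
  expect_gt(sum(spk$pop == "E"), 0)
  expect_gt(sum(spk$pop == "I"), 0)
  # same network without E->I edges: I cells never fire (driven-I PING)
  net0 <- net
  net0$ei <- net0$ei[0, ]
  sim0 <- simulate_ping(net0, e_pop = NULL, i_pop = NULL,
                        drive = drive_spec(settle_s = 1), duration_s = 1,
                        n_readout = 2, seed = 5)
  expect_identical(sum(sim0$spikes$pop == "I" & sim0$spikes$time_ms >= 0), 0L)
  # every I spike is preceded by an E spike within one gamma period
  ispk <- spk$time_ms[spk$pop == "I"]
  espk <- spk$time_ms[spk$pop == "E"]
  if (length(ispk))
    expect_true(all(vapply(ispk, function(ti) any(espk < ti & espk > ti - 15),
                           logical(1))))
})

test_that("simulation output is identical across repeated seeded runs", {
  net <- build_network(n_e = 8, n_i = 4, seed = 6)
  a <- simulate_ping(net, drive = drive_spec(settle_s = 0.5), duration_s = 0.5,
                     n_readout = 1, seed = 11)
  b <- simulate_ping(net, drive = drive_spec(settle_s = 0.5), duration_s = 0.5,
                     n_readout = 1, seed = 11)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$ipsc$data, b$ipsc$data)
})

test_that("clamped readouts: holding rules, sign conventions and synaptic charge", {
  # readouts with n_readout = 1 are E1 (clamped 0 mV) and I1 (clamped -70);
  # E2 is driven and makes the unclamped I2 fire; I2 -> E1 delivers the
  # GABA events whose charge is checked at the clamp
  net <- build_network(n_e = 2, n_i = 2, p_ii = 0, p_ie = 0, p_ei = 0,
                       p_gap = 0, seed = 7)
  net$ei <- data.frame(pre = 2L, post = 2L, w = 40, delay = 0.8)   # E2 -> I2
  net$ie <- data.frame(pre = 2L, post = 1L, w = 2.0, delay = 0.8)  # I2 -> E1
  pops <- tiny_pops(net)
  sim <- simulate_ping(net, pops$e, pops$i, drive = drive_spec(settle_s = 0.5),
                       duration_s = 1, n_readout = 1, seed = 7)
  expect_error(simulate_ping(net, pops$e, pops$i, e_hold_mV = 50), "holding")

  spk <- sim$spikes[sim$spikes$time_ms >= 0, ]
  expect_gt(sum(spk$pop == "E" & spk$id == 2), 0)   # driver E2 spikes
  # stellate readout at 0 mV (= AMPA reversal): only GABA current, positive-going
  ipsc <- sim$ipsc$data[, 1]
  expect_gte(min(ipsc), 0)
  n_ev <- sum(spk$pop == "I")
  if (n_ev > 0) {
    # total charge = n_events * (w / nrm) * (tau_d - tau_r) * driving force
    tr <- 0.4; td <- 6
    tp <- tr * td / (td - tr) * log(td / tr)
    nrm <- exp(-tp / td) - exp(-tp / tr)
    q_expect <- n_ev * 2.0 / nrm * (td - tr) * (0 - (-65))
    dt <- sim$meta$dt
    sel <- ts_time(sim$ipsc) >= 0
    q_sim <- sum(ipsc[sel]) * dt
    expect_equal(q_sim, q_expect, tolerance = 0.05)
  }
})

test_that("PV readout clamped at -70 mV sees purely inward EPSCs", {
  net <- build_network(n_e = 2, n_i = 1, p_ii = 0, p_ie = 0, p_ei = 0,
                       p_gap = 0, seed = 8)
  net$ei <- data.frame(pre = 2L, post = 1L, w = 0.8, delay = 0.8)
  pops <- list(e = NULL, i = NULL)
  sim <- simulate_ping(net, drive = drive_spec(settle_s = 0.5), duration_s = 1,
                       n_readout = 1, seed = 8)
  epsc <- sim$epsc$data[, 1]
  expect_lte(max(epsc), 1e-9)     # outward-positive convention: inward only
  n_ev <- sum(sim$spikes$pop == "E" & sim$spikes$id == 2 & sim$spikes$time_ms >= 0)
  if (n_ev > 0) {
    q_expect <- n_ev * 0.8 * 1 * (-70 - 0)    # single-exp: w * tau_d * (Vh - E)
    sel <- ts_time(sim$epsc) >= 0
    expect_equal(sum(epsc[sel]) * sim$meta$dt, q_expect, tolerance = 0.05)
  }
})
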