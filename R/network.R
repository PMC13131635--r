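#' Stellate-cell population specification
#'
#' Single-compartment conductance-based stellate templates carrying transient
#' Na, delayed-rectifier K, persistent Na, a two-component (fast/slow)
#' hyperpolarization-activated H current and leak, with per-cell lognormal
#' jitter on the maximal conductances to emulate the intrinsic heterogeneity
#' of layer II stellate cells. Cells are quiescent at rest and fire only under
#' synaptic or conductance drive.
#'
#' Conductance densities follow the classic stellate formulation for the
#' fast spike currents (Na 52, K 11 mS/cm^2) on a 5e-5 cm^2 membrane patch
#' (C = 75 pF), with the persistent-Na and H conductances set so the cell
#' rests near -62 mV, shows the H-current sag phenotype, and is quiescent
#' without input; units below are nS and pF.
#'
#' @param n number of cells.
#' @param cv coefficient of variation of the per-cell conductance jitter.
#' @param el_sd standard deviation (mV) of the leak-reversal jitter.
#' @return list with `kind` and a data.frame `params` (one row per cell).
#' @export
stellate_population <- function(n = 400, cv = 0.20, el_sd = 1.0) {
  stopifnot(n > 0)
  draw <- function(n, cv, el_sd) {
    jit <- function(m) m * exp(rnorm(n, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2))))
    data.frame(
      C = rep(75, n),                 # pF
      gNa = jit(2600), gK = jit(550), # nS
      gNaP = jit(15), gH = jit(30),
      # EL capped so the template stays below its spontaneous-firing threshold
      gL = jit(25), EL = pmin(rnorm(n, -72.8, el_sd), -70)
    )
  }
  params <- enforce_quiescence(draw, n, cv, el_sd, kind = "stellate")
  list(kind = "stellate", n = n, params = params)
}

#' PV+ fast-spiking interneuron population specification
#'
#' Wang-Buzsaki-type fast-spiking templates (transient Na with instantaneous
#' activation, delayed-rectifier K, leak) on a 1e-4 cm^2 patch (C = 85 pF),
#' with lognormal conductance jitter. Quiescent without input; capable of
#' high-frequency burst firing when driven.
#'
#' @inheritParams stellate_population
#' @return list with `kind` and a data.frame `params`.
#' @export
pv_population <- function(n = 100, cv = 0.20, el_sd = 2.0) {
  stopifnot(n > 0)
  draw <- function(n, cv, el_sd) {
    jit <- function(m) m * exp(rnorm(n, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2))))
    data.frame(
      C = rep(85, n),
      gNa = jit(3500), gK = jit(900),
      # cap keeps the template below its spontaneous-firing threshold
      gL = jit(10), EL = pmin(rnorm(n, -64.5, el_sd), -64)
    )
  }
  params <- enforce_quiescence(draw, n, cv, el_sd, kind = "pv_interneuron")
  list(kind = "pv_interneuron", n = n, params = params)
}

# Every sampled cell must be quiescent at rest (fires only under drive or
# synaptic input). Jitter tails can produce tonically active parameter
# combinations, so each candidate set is screened by simulating the isolated
# cells (no synapses, no drive) and offenders are redrawn with progressively
# shrunken jitter; as a last resort a cell falls back to the template.
enforce_quiescence <- function(draw, n, cv, el_sd, kind,
                               settle_ms = 2000, test_ms = 2000) {
  params <- draw(n, cv, el_sd)
  shrink <- 1
  for (round in 1:5) {
    bad <- which(spontaneous_cells(params, kind, settle_ms, test_ms))
    if (!length(bad)) return(params)
    shrink <- shrink * 0.6
    params[bad, ] <- draw(length(bad), cv * shrink, el_sd * shrink)
  }
  bad <- which(spontaneous_cells(params, kind, settle_ms, test_ms))
  if (length(bad)) params[bad, ] <- draw(length(bad), 0, 0)
  params
}

# simulate isolated cells at rest and flag any that fire after settling
spontaneous_cells <- function(params, kind, settle_ms, test_ms) {
  n <- nrow(params)
  empty <- list(pre = integer(0), post = integer(0), w = numeric(0),
                dsteps = integer(0))
  stub <- data.frame(C = 100, gNa = 3500, gK = 900, gL = 10, EL = -70)
  if (kind == "stellate") {
    epar <- as.list(params); ipar <- as.list(stub)
  } else {
    epar <- as.list(data.frame(C = 75, gNa = 2600, gK = 550, gNaP = 15,
                               gH = 30, gL = 25, EL = -72.8))
    ipar <- as.list(params)
  }
  res <- .ping_simulate_cpp(epar, ipar,
                            list(ii = empty, ie = empty, ei = empty),
                            list(a = integer(0), b = integer(0), g = numeric(0)),
                            integer(0), numeric(0),
                            8, 0, 0, settle_ms, test_ms, 0.025,
                            0L, settle_ms + test_ms, 1L,
                            list(tau_r_ii = 0.3, tau_d_ii = 2, e_gaba_ii = -75,
                                 tau_r_ie = 0.4, tau_d_ie = 6, e_gaba_ie = -65,
                                 tau_d_ei = 1, e_ampa = 0))
  keep <- res$spike_t > settle_ms
  ids <- res$spike_id[keep] + 1L
  n_e <- if (kind == "stellate") n else 1L
  out <- logical(n)
  if (kind == "stellate") out[ids[ids <= n_e]] <- TRUE
  else out[ids[ids > n_e] - n_e] <- TRUE
  out
}

#' Synapse kinetics and weight defaults
#'
#' The three chemical projections of the circuit: I->I GABA (biexponential,
#' rise 0.3 ms / decay 2 ms, reversal -75 mV), I->E GABA (0.4 / 6 ms,
#' reversal -65 mV, lognormal weights with the configured mean scaled by
#' `ie_mean_scale`), and E->I AMPA (single-exponential, decay 1 ms, reversal
#' 0 mV, fixed 0.8 nS peak). Delays for every chemical synapse are uniform
#' on [0.6, 1] ms.
#'
#' @param w_ii I->I peak conductance, nS.
#' @param ie_mean_nS base mean of the lognormal I->E peak conductance, nS.
#' @param ie_mean_scale scaling applied to the I->E mean (default 5).
#' @param ie_sigma_log log-sd of the I->E lognormal.
#' @param w_ei E->I peak conductance, nS.
#' @param g_gap gap-junction coupling conductance, nS.
#' @param delay_range chemical synaptic delay range, ms.
#' @return list of synapse settings consumed by [build_network()].
#' @export
synapse_spec <- function(w_ii = 1.0, ie_mean_nS = 0.15, ie_mean_scale = 5,
                         ie_sigma_log = 0.5, w_ei = 0.8, g_gap = 0.8,
                         delay_range = c(0.6, 1.0)) {
  stopifnot(delay_range[1] < delay_range[2], delay_range[1] >= 0)
  list(
    ii = list(tau_r = 0.3, tau_d = 2.0, e_rev = -75, w = w_ii),
    ie = list(tau_r = 0.4, tau_d = 6.0, e_rev = -65,
              mean_nS = ie_mean_nS * ie_mean_scale, sigma_log = ie_sigma_log),
    ei = list(tau_d = 1.0, e_rev = 0, w = w_ei),
    gap = list(g = g_gap),
    delay_range = delay_range
  )
}

#' Theta-frequency conductance drive specification
#'
#' Optogenetic-like drive: a half-wave-rectified sinusoidal conductance
#' g(t) = g_peak * max(0, sin(2 pi f t)) applied to the excitatory
#' (stellate) cells only, converted to a current through the driving force
#' with a 0 mV reversal potential. The network runs without stimulation for
#' `settle_s` seconds first to eliminate transients of the slow H-current
#' dynamics.
#'
#' @param freq_hz drive frequency, Hz (default 8).
#' @param g_peak_nS peak conductance, nS (default 15).
#' @param e_rev_mV reversal potential, mV (default 0).
#' @param settle_s unstimulated settling time, s (default 5).
#' @return list of class `drive_spec`.
#' @export
drive_spec <- function(freq_hz = 8, g_peak_nS = 15, e_rev_mV = 0, settle_s = 5) {
  if (g_peak_nS < 0) stopf("drive peak conductance must be non-negative")
  structure(list(freq_hz = freq_hz, g_peak_nS = g_peak_nS,
                 e_rev_mV = e_rev_mV, settle_s = settle_s),
            class = "drive_spec")
}

#' Theta drive current at given membrane voltages
#'
#' Evaluates I(t) = g(t) * (E_rev - v) with the half-wave-rectified
#' conductance g(t) = g_peak * max(0, sin(2 pi f t)). Times inside the
#' settling window give zero drive. Positive values are inward
#' (depolarizing) current in pA.
#'
#' @param t_ms time points, ms (stimulus time; settling precedes t = 0 when
#'   `settle_s > 0` and `absolute = TRUE`).
#' @param spec a [drive_spec()].
#' @param v membrane voltage(s), mV (scalar or vector matching `t_ms`).
#' @param absolute if TRUE, `t_ms` is absolute simulation time and the first
#'   `settle_s` seconds are unstimulated.
#' @return drive current in pA (g in nS x mV = pA).
#' @export
theta_drive <- function(t_ms, spec, v, absolute = FALSE) {
  stopifnot(inherits(spec, "drive_spec"))
  tt <- if (absolute) t_ms - spec$settle_s * 1000 else t_ms
  g <- spec$g_peak_nS * pmax(0, sin(2 * pi * spec$freq_hz * tt / 1000))
  g[tt < 0] <- 0
  g * (spec$e_rev_mV - v)
}

#' Build the E-I connectivity graph
#'
#' Independent Bernoulli sampling per ordered pair for the chemical
#' projections (I->I 35%, I->E 20%, E->I 25% by default) and per unordered
#' I-cell pair for gap junctions (20%). Stellate cells are never connected
#' to each other; requesting E->E connectivity is an error. I->E weights are
#' lognormal; other chemical weights fixed; delays uniform on the configured
#' range.
#'
#' @param n_e,n_i population sizes.
#' @param p_ii,p_ie,p_ei,p_gap connection probabilities.
#' @param p_ee must be 0; present only to reject attempts at recurrent
#'   excitation explicitly.
#' @param syn a [synapse_spec()].
#' @param seed RNG seed (NULL = use current stream).
#' @return list of class `ping_network`: edge tables `ii`, `ie`, `ei`
#'   (pre, post, w, delay), gap-junction pair table `gap` (a, b, g), and the
#'   resolved sizes/probabilities.
#' @export
build_network <- function(n_e = 400, n_i = 100,
                          p_ii = 0.35, p_ie = 0.20, p_ei = 0.25, p_gap = 0.20,
                          p_ee = 0, syn = synapse_spec(), seed = NULL) {
  probs <- c(p_ii, p_ie, p_ei, p_gap)
  if (any(probs < 0 | probs > 1)) stopf("connection probabilities must lie in [0, 1]")
  if (p_ee != 0) stopf("E->E connections are not part of this circuit (stellate cells are unconnected)")
  with_seed(seed, {
    bern_pairs <- function(npre, npost, p, self_ok) {
      hit <- which(runif(npre * npost) < p)
      pre <- (hit - 1L) %% npre + 1L
      post <- (hit - 1L) %/% npre + 1L
      if (!self_ok) {
        keep <- pre != post
        pre <- pre[keep]; post <- post[keep]
      }
      list(pre = pre, post = post)
    }
    mk_delay <- function(k) runif(k, syn$delay_range[1], syn$delay_range[2])

    ii <- bern_pairs(n_i, n_i, p_ii, self_ok = FALSE)
    ii <- data.frame(pre = ii$pre, post = ii$post,
                     w = rep(syn$ii$w, length(ii$pre)), delay = mk_delay(length(ii$pre)))
    ie <- bern_pairs(n_i, n_e, p_ie, self_ok = TRUE)
    mu <- log(syn$ie$mean_nS) - 0.5 * syn$ie$sigma_log^2
    ie <- data.frame(pre = ie$pre, post = ie$post,
                     w = exp(rnorm(length(ie$pre), mu, syn$ie$sigma_log)),
                     delay = mk_delay(length(ie$pre)))
    ei <- bern_pairs(n_e, n_i, p_ei, self_ok = TRUE)
    ei <- data.frame(pre = ei$pre, post = ei$post,
                     w = rep(syn$ei$w, length(ei$pre)), delay = mk_delay(length(ei$pre)))
    # unordered I pairs for gap junctions
    idx <- which(upper.tri(matrix(0, n_i, n_i)), arr.ind = TRUE)
    hit <- runif(nrow(idx)) < p_gap
    gap <- data.frame(a = idx[hit, 1], b = idx[hit, 2],
                      g = rep(syn$gap$g, sum(hit)))
    structure(list(n_e = n_e, n_i = n_i, ii = ii, ie = ie, ei = ei, gap = gap,
                   syn = syn,
                   probs = list(ii = p_ii, ie = p_ie, ei = p_ei, gap = p_gap)),
              class = "ping_network")
  })
}

#' @export
print.ping_network <- function(x, ...) {
  cat(sprintf("<ping_network> %d E (stellate) + %d I (PV) cells\n", x$n_e, x$n_i))
  cat(sprintf("  edges: I->I %d, I->E %d, E->I %d, gap %d\n",
              nrow(x$ii), nrow(x$ie), nrow(x$ei), nrow(x$gap)))
  invisible(x)
}

#' Realized connection fractions of a network
#'
#' @param net a [build_network()] result.
#' @return named numeric vector of realized fractions for the I->I, I->E and
#'   E->I ordered-pair projections and the unordered gap-junction pairs.
#' @export
connection_fractions <- function(net) {
  c(ii = nrow(net$ii) / (net$n_i * (net$n_i - 1)),
    ie = nrow(net$ie) / (net$n_i * net$n_e),
    ei = nrow(net$ei) / (net$n_e * net$n_i),
    gap = nrow(net$gap) / (net$n_i * (net$n_i - 1) / 2))
}

#' Pairwise gap-junction currents
#'
#' For coupled pair (i, j) with conductance g, the current into i is
#' g * (V_j - V_i); the current into j is its negative (antisymmetry).
#'
#' @param v membrane voltages of the I cells, mV.
#' @param gap gap table from [build_network()] (columns a, b, g).
#' @return data.frame with currents `i_a` (into cell a) and `i_b` (into b), pA.
#' @export
gap_pair_currents <- function(v, gap) {
  i_a <- gap$g * (v[gap$b] - v[gap$a])
  data.frame(a = gap$a, b = gap$b, i_a = i_a, i_b = -i_a)
}

#' Simulate the PING network
#'
#' Integrates the conductance-based dynamics of all cells with fixed-step
#' exponential Euler (default dt = 0.025 ms): chemical synapses as
#' event-triggered conductance waveforms with per-edge delay, gap-junction
#' currents g*(V_j - V_i), and the theta conductance drive on E cells only.
#' Designated readout neurons are voltage-clamped (E readouts at 0 mV
#' recording inhibitory currents, I readouts at -70 mV recording excitatory
#' currents); clamped cells do not spike and so do not feed back into the
#' network.
#'
#' @param net a [build_network()] result.
#' @param e_pop,i_pop population specs ([stellate_population()],
#'   [pv_population()]); sizes must match the network.
#' @param drive a [drive_spec()].
#' @param duration_s stimulated duration, s.
#' @param dt integration step, ms (warning above 0.1 ms).
#' @param n_readout number of clamped readouts per population (default 5).
#' @param e_hold_mV,i_hold_mV holding potentials (defaults 0 and -70 mV).
#' @param record_v indices (global: E cells first, then I) whose membrane
#'   voltage to record; defaults to the first unclamped cell of each type.
#' @param record_from_ms absolute time to start recording traces; defaults
#'   to 100 ms before stimulation onset.
#' @param seed RNG seed for parameter/connectivity-independent sampling
#'   reproducibility of this call (population specs are sampled by their own
#'   constructors; pass pre-built specs for full control).
#' @return object of class `ping_sim`: `spikes` (data.frame: time_ms from
#'   stimulation onset, id, pop), `v` (ts_sig, mV), `ipsc`/`epsc` (ts_sig,
#'   pA; clamp currents of the E and I readouts), `readouts`, `meta`.
#' @export
simulate_ping <- function(net, e_pop = NULL, i_pop = NULL, drive = drive_spec(),
                          duration_s = 2, dt = 0.025, n_readout = 5,
                          e_hold_mV = 0, i_hold_mV = -70,
                          record_v = NULL, record_from_ms = NULL, seed = NULL) {
  stopifnot(inherits(net, "ping_network"))
  if (dt > 0.1) warning("dt > 0.1 ms is coarse for spike dynamics")
  if (e_hold_mV < -100 || e_hold_mV > 20 || i_hold_mV < -100 || i_hold_mV > 20)
    stopf("holding potentials must lie in [-100, 20] mV")
  with_seed(seed, {
    if (is.null(e_pop)) e_pop <- stellate_population(net$n_e)
    if (is.null(i_pop)) i_pop <- pv_population(net$n_i)
  })
  stopifnot(e_pop$n == net$n_e, i_pop$n == net$n_i)

  n_e <- net$n_e; n_i <- net$n_i
  ro_e <- seq_len(min(n_readout, n_e))                 # global ids (1-based)
  ro_i <- n_e + seq_len(min(n_readout, n_i))
  clamp_idx <- c(ro_e, ro_i)
  clamp_v <- c(rep(e_hold_mV, length(ro_e)), rep(i_hold_mV, length(ro_i)))

  if (is.null(record_v))
    record_v <- c(min(n_readout, n_e) + 1L, n_e + min(n_readout, n_i) + 1L)
  settle_ms <- drive$settle_s * 1000
  stim_ms <- duration_s * 1000
  if (is.null(record_from_ms)) record_from_ms <- max(0, settle_ms - 100)

  to_steps <- function(d) pmax(1L, as.integer(round(d / dt)))
  conn <- list(
    ii = list(pre = net$ii$pre - 1L, post = net$ii$post - 1L,
              w = net$ii$w, dsteps = to_steps(net$ii$delay)),
    ie = list(pre = net$ie$pre - 1L, post = net$ie$post - 1L,
              w = net$ie$w, dsteps = to_steps(net$ie$delay)),
    ei = list(pre = net$ei$pre - 1L, post = net$ei$post - 1L,
              w = net$ei$w, dsteps = to_steps(net$ei$delay)))
  gap <- list(a = net$gap$a - 1L, b = net$gap$b - 1L, g = net$gap$g)
  syn_kin <- list(tau_r_ii = net$syn$ii$tau_r, tau_d_ii = net$syn$ii$tau_d,
                  e_gaba_ii = net$syn$ii$e_rev,
                  tau_r_ie = net$syn$ie$tau_r, tau_d_ie = net$syn$ie$tau_d,
                  e_gaba_ie = net$syn$ie$e_rev,
                  tau_d_ei = net$syn$ei$tau_d, e_ampa = net$syn$ei$e_rev)

  res <- .ping_simulate_cpp(as.list(e_pop$params), as.list(i_pop$params),
                            conn, gap,
                            as.integer(clamp_idx - 1L), clamp_v,
                            drive$freq_hz, drive$g_peak_nS, drive$e_rev_mV,
                            settle_ms, stim_ms, dt,
                            as.integer(record_v - 1L), record_from_ms, 1L, syn_kin)

  fs <- 1000 / dt
  t0 <- res$t[1] - settle_ms                    # times relative to stim onset
  spikes <- data.frame(time_ms = res$spike_t - settle_ms,
                       id = res$spike_id + 1L,
                       pop = ifelse(res$spike_id + 1L <= n_e, "E", "I"))
  spikes <- spikes[order(spikes$time_ms, spikes$id), , drop = FALSE]
  rownames(spikes) <- NULL

  ipsc <- timeseries(res$clamp_i[, seq_along(ro_e), drop = FALSE], fs,
                     units = "pA", role = "current", t0 = t0)
  epsc <- timeseries(res$clamp_i[, length(ro_e) + seq_along(ro_i), drop = FALSE],
                     fs, units = "pA", role = "current", t0 = t0)
  v <- timeseries(res$v, fs, units = "mV", role = "voltage", t0 = t0)

  structure(list(spikes = spikes, v = v, ipsc = ipsc, epsc = epsc,
                 readouts = list(e = ro_e, i = ro_i - n_e,
                                 e_hold = e_hold_mV, i_hold = i_hold_mV),
                 meta = list(dt = dt, drive = drive, n_e = n_e, n_i = n_i,
                             duration_s = duration_s)),
            class = "ping_sim")
}

#' @export
print.ping_sim <- function(x, ...) {
  ne_spk <- sum(x$spikes$pop == "E" & x$spikes$time_ms >= 0)
  ni_spk <- sum(x$spikes$pop == "I" & x$spikes$time_ms >= 0)
  cat(sprintf("<ping_sim> %d E + %d I cells, %g s at %g Hz drive\n",
              x$meta$n_e, x$meta$n_i, x$meta$duration_s, x$meta$drive$freq_hz))
  cat(sprintf("  spikes during stimulation: E %d, I %d\n", ne_spk, ni_spk))
  invisible(x)
}

#' @export
plot.ping_sim <- function(x, ...) {
  s <- x$spikes[x$spikes$time_ms >= 0, ]
  graphics::plot(s$time_ms, s$id, pch = ".", col = ifelse(s$pop == "E", "red", "blue"),
                 xlab = "time from stimulation onset (ms)", ylab = "neuron", ...)
  invisible(x)
}

#' Scaled default network configuration
#'
#' Convenience constructor for desk-scale runs: population counts are scaled
#' by `scale` and synaptic weights (I->I, I->E mean, E->I, gap) divided by
#' `scale` so each cell's expected aggregate synaptic conductance is
#' preserved.
#'
#' @param scale fraction of the full 400 E / 100 I network (e.g. 0.5 gives
#'   200 E / 50 I).
#' @param seed RNG seed passed to [build_network()].
#' @param ... further arguments to [synapse_spec()].
#' @return a `ping_network`.
#' @export
default_network <- function(scale = 1, seed = NULL, ...) {
  syn <- synapse_spec(...)
  syn$ii$w <- syn$ii$w / scale
  syn$ie$mean_nS <- syn$ie$mean_nS / scale
  syn$ei$w <- syn$ei$w / scale
  syn$gap$g <- syn$gap$g / scale
  build_network(n_e = round(400 * scale), n_i = round(100 * scale),
                syn = syn, seed = seed)
}
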