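#' Write / read a time series as CSV
#'
#' Columnar text format: a `time_ms` column plus one column per channel.
#' Reading checks that sampling is uniform and infers the rate; irregular
#' timestamps are rejected (resample first).
#'
#' @param x a [timeseries()].
#' @param path file path.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a `ts_sig`.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "ts_sig"))
  df <- data.frame(time_ms = ts_time(x))
  dat <- as.data.frame(x$data)
  names(dat) <- paste0("ch", seq_len(ncol(dat)))
  df <- cbind(df, dat)
  attr_line <- sprintf("# fs_hz=%.10g units=%s role=%s", x$fs, x$units, x$role)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param tol relative tolerance on sampling regularity.
#' @export
read_timeseries <- function(path, tol = 1e-6) {
  first <- readLines(path, n = 1)
  has_hdr <- startsWith(first, "#")
  meta <- list(fs = NULL, units = "a.u.", role = "signal")
  if (has_hdr) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (p in kv) {
      k <- sub("=.*", "", p); v <- sub(".*=", "", p)
      if (k == "fs_hz") meta$fs <- as.numeric(v)
      if (k == "units") meta$units <- v
      if (k == "role") meta$role <- v
    }
  }
  df <- read.csv(path, skip = if (has_hdr) 1 else 0)
  if (!"time_ms" %in% names(df)) stopf("missing time_ms column")
  t <- df$time_ms
  dts <- diff(t)
  if (length(dts) && (max(dts) - min(dts)) > tol * max(abs(dts)))
    stopf("irregular sampling detected; resample to a uniform grid first")
  fs <- meta$fs %||% (1000 / stats::median(dts))
  if (!is.null(meta$fs) && length(dts)) {
    if (abs(1000 / stats::median(dts) - fs) > tol * fs)
      stopf("declared rate (%g Hz) disagrees with timestamps", fs)
  }
  timeseries(as.matrix(df[, setdiff(names(df), "time_ms"), drop = FALSE]),
             fs = fs, units = meta$units, role = meta$role, t0 = t[1])
}

#' Write / read spike event tables
#'
#' CSV with columns `neuron_id`, `time_ms` (and any extra columns, e.g.
#' amplitude or provenance).
#'
#' @param spikes data.frame with at least neuron_id and time_ms.
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(all(c("neuron_id", "time_ms") %in% names(spikes)))
  write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- read.csv(path)
  if (!all(c("neuron_id", "time_ms") %in% names(df)))
    stopf("spike table needs neuron_id and time_ms columns")
  df[order(df$neuron_id, df$time_ms), , drop = FALSE]
}

#' Default run configuration
#'
#' Aggregates every analysis constant at its published default: filter
#' bands, scalogram settings, QC thresholds (20 pA^2 peak power, 100 Hz
#' bandwidth, SNR 5), artifact thresholds (3000 pA / 1000 uV), the spike
#' detector constants, the 6.67 ms burst rule, the 3.75 SNR_peak neuron
#' cutoff, the 1.1 inconsistency threshold, network connection
#' probabilities (35/20/25/20 %), and the 15 nS / 8 Hz drive.
#'
#' @param seed master seed.
#' @param scale network scale fraction (1 = 400 E / 100 I).
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1, scale = 1) {
  structure(list(
    seed = seed,
    network = list(scale = scale, p_ii = 0.35, p_ie = 0.20, p_ei = 0.25,
                   p_gap = 0.20, drive_freq_hz = 8, drive_g_peak_nS = 15,
                   drive_e_rev_mV = 0, settle_s = 5, duration_s = 2,
                   dt_ms = 0.025, n_readout = 5, e_hold_mV = 0, i_hold_mV = -70),
    spectral = list(gamma_band = c(50, 200), phase_band = c(60, 120),
                    voices = 32, omega0 = 6, max_cycles = 40,
                    artifact_pA = 3000, artifact_uV = 1000,
                    qc_min_power = 20, qc_max_bw_hz = 100, qc_min_snr = 5),
    detector = list(min_distance = 2, max_width = 6, min_prominence = 0.0075,
                    height_sigma = 2, final_sigma = 3.5, snr_cutoff = 3.75,
                    tonic_bin_ms = 50, tonic_frac = 0.95),
    phaselock = list(burst_isi_ms = 6.67, phase_bins = 50, rate_bin_hz = 10,
                     polar_bins = 36),
    clustering = list(inconsistency = 1.1, depth = 2, linkage = "average")
  ), class = "run_config")
}

#' Save / load a run configuration (lossless JSON round-trip)
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order on fully synthetic inputs and
#' returns a manifest sufficient to reproduce every number: the resolved
#' configuration, seeds, and per-stage summary outputs.
#'
#' Stages: `simulate` (PING network at the configured drive; scalogram
#' gamma peak of the stellate-readout IPSC; EPSC-IPSC cross-correlation
#' lag) and `imaging` (synthetic fluorescence population; spike extraction
#' + QC; spike-correlation clustering and distance regression).
#'
#' @param config a [default_config()].
#' @param stages character subset of c("simulate", "imaging").
#' @return list of class `run_manifest`.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "imaging")) {
  stopifnot(inherits(config, "run_config"))
  out <- list(config = config, package_version = as.character(utils::packageVersion("thetagamma")))
  if ("simulate" %in% stages) {
    nc <- config$network
    net <- default_network(scale = nc$scale, seed = config$seed)
    sim <- simulate_ping(net,
                         drive = drive_spec(nc$drive_freq_hz, nc$drive_g_peak_nS,
                                            nc$drive_e_rev_mV, nc$settle_s),
                         duration_s = nc$duration_s, dt = nc$dt_ms,
                         n_readout = nc$n_readout, e_hold_mV = nc$e_hold_mV,
                         i_hold_mV = nc$i_hold_mV, seed = config$seed + 1)
    gp <- sim_gamma_peak(sim, config)
    lag <- sim_ei_lag(sim, config)
    out$simulate <- list(n_spikes_e = sum(sim$spikes$pop == "E" & sim$spikes$time_ms >= 0),
                         n_spikes_i = sum(sim$spikes$pop == "I" & sim$spikes$time_ms >= 0),
                         gamma_peak_hz = gp$peak_freq, gamma_qc = gp$qc_pass,
                         ei_lag_ms = lag$lag_ms, ei_peak_r = lag$peak_coefficient)
  }
  if ("imaging" %in% stages) {
    proto <- synth_protocol(sample_rate = 800, seed = config$seed)
    pop <- gen_fluorescence_population(proto, n_neurons = 30)
    ex <- extract_spikes(pop$traces, pop$truth$stim_off_index)
    fid <- score_detection(ex, pop$truth, tol_frames = 2)
    stim_win <- round(c(proto$pre_ms, proto$pre_ms + proto$stim_ms) / 1000 * 800)
    sm <- vapply(seq_len(ncol(pop$traces$data)), function(j) {
      fr <- ex$detections[[j]]$frames
      smoothed_spike_signal(fr, nrow(pop$traces$data))
    }, numeric(nrow(pop$traces$data)))
    cm <- correlation_matrix(sm, source = "smoothed_spikes", window = stim_win)
    dd <- distance_dependence(cm, pop$positions)
    out$imaging <- list(n_neurons = ncol(pop$traces$data),
                        n_included = sum(ex$qc$include),
                        sensitivity = fid$sensitivity, fdr = fid$fdr,
                        dist_r_squared = dd$r_squared)
  }
  structure(out, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  if (!is.null(x$simulate))
    cat(sprintf("  simulate: gamma peak %.1f Hz (QC %s), E->I lag %.2f ms, E/I spikes %d/%d\n",
                x$simulate$gamma_peak_hz, x$simulate$gamma_qc, x$simulate$ei_lag_ms,
                x$simulate$n_spikes_e, x$simulate$n_spikes_i))
  if (!is.null(x$imaging))
    cat(sprintf("  imaging: %d/%d neurons included, sensitivity %.3f, FDR %.3f, distance R^2 %.4f\n",
                x$imaging$n_included, x$imaging$n_neurons,
                x$imaging$sensitivity, x$imaging$fdr, x$imaging$dist_r_squared))
  invisible(x)
}

#' Score detected spikes against planted ground truth
#'
#' Matches detected to planted spikes greedily within `tol_frames`;
#' sensitivity = matched / planted, FDR = unmatched detections /
#' detections.
#'
#' @param ex an [extract_spikes()] result (or list of `detected_spikes`).
#' @param truth generator truth with `spike_frames` per neuron.
#' @param tol_frames match tolerance in frames.
#' @param included_only score only QC-included neurons (default FALSE:
#'   score all detections).
#' @return list with `sensitivity`, `fdr`, `n_planted`, `n_detected`,
#'   `n_matched`.
#' @export
score_detection <- function(ex, truth, tol_frames = 2, included_only = FALSE) {
  dets <- if (!is.null(ex$detections)) ex$detections else ex
  n_planted <- 0L; n_detected <- 0L; n_matched <- 0L
  for (j in seq_along(dets)) {
    if (included_only && !is.null(ex$qc) && !ex$qc$include[j]) next
    planted <- truth$spike_frames[[j]]
    got <- dets[[j]]$frames
    n_planted <- n_planted + length(planted)
    n_detected <- n_detected + length(got)
    if (length(planted) && length(got)) {
      used <- logical(length(got))
      for (p in planted) {
        cand <- which(!used & abs(got - p) <= tol_frames)
        if (length(cand)) {
          used[cand[which.min(abs(got[cand] - p))]] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  list(sensitivity = if (n_planted) n_matched / n_planted else NA_real_,
       fdr = if (n_detected) (n_detected - n_matched) / n_detected else NA_real_,
       n_planted = n_planted, n_detected = n_detected, n_matched = n_matched)
}

# gamma peak of the first stellate readout's IPSC, cycle-averaged
sim_gamma_peak <- function(sim, config = default_config()) {
  sc <- config$spectral
  ipsc <- sim$ipsc$data[, 1]
  fs <- sim$ipsc$fs
  i_on <- which(ts_time(sim$ipsc) >= 0)[1]
  x <- ipsc[i_on:length(ipsc)]
  scalo <- morlet_scalogram(x, f_lo = sc$gamma_band[1], f_hi = sc$gamma_band[2],
                            fs = fs, voices = sc$voices)
  period <- 1000 / sim$meta$drive$freq_hz
  ncyc <- floor(sim$meta$duration_s * 1000 / period)
  cycles <- seq(0, ncyc) * period
  cycle_average_gamma_peak(scalo, cycles, artifact_threshold = sc$artifact_pA,
                           max_cycles = sc$max_cycles,
                           min_power = sc$qc_min_power,
                           max_bw_hz = sc$qc_max_bw_hz, min_snr = sc$qc_min_snr)
}

# average EPSC->IPSC cross-correlogram lag over stimulation cycles 2-6;
# readout currents averaged across the clamped readouts of each population
sim_ei_lag <- function(sim, config = default_config(), cycles = 2:6,
                       max_lag_ms = 6) {
  band <- band_spec(config$spectral$gamma_band[1], config$spectral$gamma_band[2])
  fs <- sim$epsc$fs
  epsc <- band_filter(rowMeans(sim$epsc$data), band, fs = fs)
  ipsc <- band_filter(rowMeans(sim$ipsc$data), band, fs = fs)
  t <- ts_time(sim$epsc)
  period <- 1000 / sim$meta$drive$freq_hz
  wins <- lapply(cycles, function(c) c((c - 1) * period, c * period))
  a <- timeseries(epsc, fs, t0 = t[1])
  b <- timeseries(ipsc, fs, t0 = t[1])
  # EPSCs are negative-going, IPSCs positive-going: the aligned correlation
  # is negative, so locate the negative extremum
  xcorr_peak_lag(a, b, windows = wins, max_lag_ms = max_lag_ms,
                 polarity = "negative", first = TRUE)
}
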