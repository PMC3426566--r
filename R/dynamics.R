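#' Parameter sets for the culture simulator
#'
#' The simulator models the culture as purely excitatory leaky
#' integrate-and-fire neurons coupled by current-based exponential
#' synapses with Tsodyks-Markram short-term depression, driven by
#' independent Poisson spike trains ("minis").  Units: time constants in
#' ms, voltages in mV above a resting level of 0, weights in pA
#' (current-based arbitrary scale fixed by `g_leak`), rates in Hz.
#'
#' `neuron_params()` holds the membrane constants: time constant `tau_m`,
#' leak conductance `g_leak`, firing threshold `v_th`, refractory period
#' `t_ref`, conduction delay and the integration step `dt` (which must
#' not exceed the delay).
#'
#' @param tau_m membrane time constant (ms).
#' @param g_leak leak conductance (arbitrary conductance units).
#' @param v_th firing threshold (mV above rest).
#' @param t_ref absolute refractory period (ms).
#' @param delay conduction delay of recurrent synapses (ms).
#' @param dt integration step (ms).
#' @return a named list of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, g_leak = 0.05, v_th = 20,
                          t_ref = 2, delay = 2, dt = 0.1) {
  p <- list(tau_m = tau_m, g_leak = g_leak, v_th = v_th,
            t_ref = t_ref, delay = delay, dt = dt)
  if (any(unlist(p) <= 0)) stop_structural("neuron parameters must be positive")
  if (dt > delay) stop_structural("dt must not exceed the conduction delay")
  structure(p, class = "neuron_params")
}

#' @rdname neuron_params
#' @param g_int homogeneous recurrent synaptic weight (pA).
#' @param u_frac release fraction: portion of recovered resources moved to
#'   the effective state by a presynaptic spike.
#' @param tau_inact decay time of the effective state (ms).
#' @param tau_rec recovery time of the inactive state (ms);
#'   `tau_rec > tau_inact` is required for depression.
#' @param tau_syn synaptic current time constant (ms); together with
#'   `tau_m` it gives EPSPs a difference-of-exponentials time course.
#' @export
synapse_params <- function(g_int = 6, u_frac = 0.3, tau_inact = 3,
                           tau_rec = 500, tau_syn = 2) {
  if (g_int <= 0 || tau_inact <= 0 || tau_syn <= 0)
    stop_structural("synapse parameters must be positive")
  if (u_frac <= 0 || u_frac > 1)
    stop_structural("u_frac must lie in (0, 1]")
  if (tau_rec <= tau_inact)
    stop_structural("tau_rec must exceed tau_inact")
  structure(list(g_int = g_int, u_frac = u_frac, tau_inact = tau_inact,
                 tau_rec = tau_rec, tau_syn = tau_syn),
            class = "synapse_params")
}

#' @rdname neuron_params
#' @param nu rate of the independent Poisson drive per neuron (Hz).
#' @param g_noise weight of a single drive spike (pA); the default is
#'   calibrated so the uncoupled network fires sparsely at roughly
#'   0.1-0.5 Hz per neuron.
#' @export
drive_params <- function(nu = 1.6, g_noise = 12) {
  if (nu < 0) stop_structural("drive rate must be non-negative")
  structure(list(nu = nu, g_noise = g_noise), class = "drive_params")
}

#' Spike record container
#'
#' @param spikes list with one sorted numeric vector of spike times (s)
#'   per neuron.
#' @param duration recording duration (s).
#' @param params snapshot of the parameter sets used.
#' @param seed RNG seed of the run.
#' @return object of class `spike_record`.
#' @export
spike_record <- function(spikes, duration, params = list(), seed = NA_integer_) {
  structure(list(spikes = spikes, duration = duration,
                 params = params, seed = seed),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat(sprintf("<spike_record> %d neurons, %d spikes over %.1f s (%.3f Hz/neuron)\n",
              length(x$spikes), n_sp, x$duration,
              n_sp / length(x$spikes) / x$duration))
  invisible(x)
}

#' Simulate the spiking dynamics of a culture
#'
#' Integrates the network on a fixed grid with exact exponential updates
#' of the membrane, synaptic-current and synaptic-resource subsystems;
#' threshold crossings are resolved at grid resolution.  A presynaptic
#' spike moves a fraction `u_frac` of that neuron's recovered resources
#' into the effective state and, after the conduction delay, injects a
#' current proportional to the released fraction into every postsynaptic
#' target.  The run is deterministic given `seed`.
#'
#' @param net a `directed_network` (row = presynaptic source).
#' @param neuron,syn,drive parameter sets, see [neuron_params()].
#' @param duration simulated time in seconds.
#' @param seed integer RNG seed.
#' @param forced_spikes optional list (one numeric vector of times in s
#'   per neuron) of spikes imposed on top of the dynamics; used to probe
#'   single-synapse responses.
#' @param record_neuron index of one neuron whose synaptic-resource state
#'   (E, R, I) and membrane potential are recorded every step (0 = none).
#' @return a `spike_record`; with `record_neuron > 0` it carries a
#'   `state` element with per-step E/R/I/V vectors.
#' @export
simulate_network <- function(net, neuron = neuron_params(),
                             syn = synapse_params(), drive = drive_params(),
                             duration = 3600, seed = 1,
                             forced_spikes = NULL, record_neuron = 0L) {
  stopifnot(inherits(net, "directed_network"), duration > 0)
  n <- n_nodes(net)
  targets <- lapply(seq_len(n), function(i) which(net$adjacency[i, ]) - 1L)
  forced <- if (is.null(forced_spikes)) list() else
    lapply(forced_spikes, function(t) as.numeric(t) * 1e3)
  res <- simulate_lif_tm_cpp(targets, n,
                             neuron$tau_m, neuron$g_leak, neuron$v_th,
                             neuron$t_ref, neuron$delay, neuron$dt,
                             syn$g_int, syn$u_frac, syn$tau_inact,
                             syn$tau_rec, syn$tau_syn,
                             drive$nu, drive$g_noise,
                             duration * 1e3, as.integer(seed),
                             forced, as.integer(record_neuron))
  spikes <- split(res$times, factor(res$ids, levels = seq_len(n)))
  spikes <- lapply(spikes, sort)
  out <- spike_record(spikes, duration,
                      params = list(neuron = neuron, syn = syn, drive = drive),
                      seed = seed)
  if (!is.null(res$state)) out$state <- as.data.frame(res$state)
  out
}

#' Detect network bursts in a spike raster
#'
#' A network burst is declared when more than `fraction` of the neurons
#' are active (fire at least one spike) within a sliding window of
#' `window_ms`, scanned at `stride_ms` resolution.  A burst closes when
#' the active fraction drops back below the threshold; events are
#' non-overlapping by construction.
#'
#' @param spikes a `spike_record`.
#' @param window_ms window length (ms).
#' @param fraction active-neuron fraction that must be exceeded.
#' @param stride_ms scan stride (ms).
#' @return object of class `burst_list`: data frame with burst `onset`
#'   times (s) and the `participating` neuron fraction of each burst.
#' @export
detect_bursts <- function(spikes, window_ms = 50, fraction = 0.4,
                          stride_ms = 5) {
  stopifnot(window_ms > 0, stride_ms > 0)
  n <- length(spikes$spikes)
  stride <- stride_ms / 1e3
  window <- window_ms / 1e3
  n_win <- max(0L, floor((spikes$duration - window) / stride) + 1L)
  empty <- structure(data.frame(onset = numeric(0), participating = numeric(0)),
                     class = c("burst_list", "data.frame"))
  if (n_win == 0L || all(lengths(spikes$spikes) == 0L)) return(empty)

  # active-neuron count per window via union of per-spike window ranges
  acc <- numeric(n_win + 1L)
  for (i in seq_len(n)) {
    t <- spikes$spikes[[i]]
    if (!length(t)) next
    # windows [w*stride, w*stride + window) containing each spike
    lo <- pmax(0L, as.integer(ceiling((t - window) / stride + 1e-9)))
    hi <- pmin(n_win - 1L, as.integer(floor(t / stride + 1e-9)))
    ok <- lo <= hi
    if (!any(ok)) next
    lo <- lo[ok]; hi <- hi[ok]
    # merge overlapping ranges (spikes are sorted, so lo is non-decreasing)
    run_max <- cummax(hi)
    new_run <- c(TRUE, lo[-1] > run_max[-length(run_max)] + 1L)
    grp <- cumsum(new_run)
    m_lo <- lo[new_run]
    m_hi <- tapply(hi, grp, max)
    acc[m_lo + 1L] <- acc[m_lo + 1L] + 1
    acc[m_hi + 2L] <- acc[m_hi + 2L] - 1
  }
  frac <- cumsum(acc[seq_len(n_win)]) / n

  above <- frac > fraction
  if (!any(above)) return(empty)
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L

  all_t <- sort(unlist(spikes$spikes, use.names = FALSE))
  all_id <- rep.int(seq_len(n), lengths(spikes$spikes))[order(unlist(spikes$spikes, use.names = FALSE))]
  onset <- (starts - 1L) * stride
  close <- (ends - 1L) * stride + window
  participating <- vapply(seq_along(starts), function(b) {
    sel <- all_t >= onset[b] & all_t < close[b]
    length(unique(all_id[sel])) / n
  }, numeric(1))
  structure(data.frame(onset = onset, participating = participating),
            class = c("burst_list", "data.frame"))
}

#' Burst rate of a spike record
#'
#' @inheritParams detect_bursts
#' @return bursts per second (Hz).
#' @export
burst_rate <- function(spikes, window_ms = 50, fraction = 0.4) {
  nrow(detect_bursts(spikes, window_ms, fraction)) / spikes$duration
}

# Secant-with-fallback root search on a monotone rate(g) response:
# first step changes g by 10% in the corrective direction, later steps
# linearly extrapolate the last two probes toward the target.
tune_root <- function(rate_fn, g0, target, tol, max_probes) {
  trace <- data.frame(g = numeric(0), rate = numeric(0))
  g1 <- g0
  r1 <- rate_fn(g1)
  trace[1, ] <- c(g1, r1)
  if (abs(r1 - target) < tol) return(list(g = g1, trace = trace))
  g2 <- g1 * if (r1 > target) 0.9 else 1.1
  for (probe in seq_len(max_probes - 1L)) {
    r2 <- rate_fn(g2)
    trace[nrow(trace) + 1L, ] <- c(g2, r2)
    if (abs(r2 - target) < tol) return(list(g = g2, trace = trace))
    if (r2 == r1) {
      g3 <- g2 * if (r2 > target) 0.9 else 1.1
    } else {
      g3 <- g2 + (target - r2) * (g2 - g1) / (r2 - r1)
      # keep the extrapolation step bounded and positive
      g3 <- min(max(g3, 0.5 * g2), 2 * g2)
    }
    g1 <- g2; r1 <- r2; g2 <- g3
  }
  stop(errorCondition(
    sprintf("weight tuning did not converge within %d probes", max_probes),
    class = c("gtenet_tuning_error", "error", "condition"), trace = trace))
}

#' Tune the recurrent weight to a target burst rate
#'
#' Simulates `probe_duration` seconds of dynamics, measures the network
#' burst rate, and adjusts the homogeneous recurrent weight: the first
#' correction is -10\% (+10\%) when the rate is too high (too low), and
#' subsequent probes linearly extrapolate the last two (weight, rate)
#' pairs toward the target until the probe rate is within `tol`.
#'
#' @inheritParams simulate_network
#' @param target_rate desired network burst rate (Hz).
#' @param tol convergence tolerance on the probe burst rate (Hz).
#' @param probe_duration length of each probe simulation (s).
#' @param max_probes probe budget; exceeding it raises a tuning error
#'   carrying the (weight, rate) trace.
#' @return tuned `g_int` (pA) with the probe trace attached as attribute
#'   `"trace"`.
#' @export
tune_weight <- function(net, neuron = neuron_params(), syn = synapse_params(),
                        drive = drive_params(), target_rate = 0.1, tol = 0.01,
                        probe_duration = 200, seed = 1, max_probes = 30L) {
  stopifnot(target_rate > 0)
  probe_i <- 0L
  rate_fn <- function(g) {
    probe_i <<- probe_i + 1L
    s <- syn
    s$g_int <- g
    sp <- simulate_network(net, neuron, s, drive, duration = probe_duration,
                           seed = (seed + 7919L * probe_i) %% 2147483647L)
    burst_rate(sp)
  }
  res <- tune_root(rate_fn, syn$g_int, target_rate, tol, max_probes)
  structure(res$g, trace = res$trace)
}

#' Write / read a spike raster as plain text
#'
#' Two tab-delimited columns `time_s` / `neuron_id` sorted by time, with
#' duration, neuron count and seed in `#`-prefixed header lines.
#'
#' @param spikes a `spike_record`.
#' @param file output path.
#' @return `read_spikes()` returns a `spike_record`.
#' @export
write_spikes <- function(spikes, file) {
  n <- length(spikes$spikes)
  t <- unlist(spikes$spikes, use.names = FALSE)
  id <- rep.int(seq_len(n), lengths(spikes$spikes))
  o <- order(t)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration_s\t%.10g", spikes$duration),
               sprintf("# n_neurons\t%d", n),
               sprintf("# seed\t%s", spikes$seed),
               "time_s\tneuron_id"), con)
  utils::write.table(data.frame(time_s = t[o], neuron_id = id[o]), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(file) {
  hdr <- readLines(file, n = 3L)
  duration <- as.numeric(sub("# duration_s\t", "", hdr[1]))
  n <- as.integer(sub("# n_neurons\t", "", hdr[2]))
  seed <- suppressWarnings(as.integer(sub("# seed\t", "", hdr[3])))
  tab <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#")
  spikes <- split(tab$time_s, factor(tab$neuron_id, levels = seq_len(n)))
  spike_record(lapply(spikes, sort), duration, seed = seed)
}
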