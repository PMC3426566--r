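#' Calcium and scattering parameter sets
#'
#' `calcium_params()` controls the forward model from spikes to
#' fluorescence: each action potential raises the bound-calcium
#' concentration by `a_ca` (arbitrary concentration units), which decays
#' back with time constant `tau_ca`; fluorescence is a saturating
#' function of the concentration, `F = Ca / (Ca + k_sat)`, plus i.i.d.
#' Gaussian noise of standard deviation `noise_sd` per frame and neuron.
#' Frames are sampled every `frame_dt` seconds.
#'
#' @param a_ca per-spike calcium increment (concentration a.u.).
#' @param tau_ca calcium decay time constant (s).
#' @param k_sat half-saturation concentration of the indicator (a.u.).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (fluorescence units).
#' @param frame_dt frame interval (s); must be much larger than the
#'   simulator integration step.
#' @return a named list of class `calcium_params`.
#' @export
calcium_params <- function(a_ca = 50, tau_ca = 1, k_sat = 300,
                           noise_sd = 0.03, frame_dt = 0.02) {
  p <- list(a_ca = a_ca, tau_ca = tau_ca, k_sat = k_sat,
            noise_sd = noise_sd, frame_dt = frame_dt)
  if (any(unlist(p) <= 0)) stop_structural("calcium parameters must be positive")
  structure(p, class = "calcium_params")
}

#' @rdname calcium_params
#' @param a_sc overall strength of the scattering artifact
#'   (dimensionless).
#' @param r_sc scattering length scale (mm).
#' @export
scatter_params <- function(a_sc = 0.15, r_sc = 0.05) {
  if (a_sc < 0 || r_sc <= 0)
    stop_structural("scattering parameters must be non-negative (r_sc > 0)")
  structure(list(a_sc = a_sc, r_sc = r_sc), class = "scatter_params")
}

#' Fluorescence recording container
#'
#' @param fluor frames x neurons numeric matrix of fluorescence values.
#' @param frame_dt frame interval (s).
#' @param positions optional N x 2 matrix of ROI positions (mm).
#' @param provenance `"simulated"` or `"experimental"`.
#' @param meta free-form metadata (seeds, parameter snapshots).
#' @return object of class `fluorescence_recording`.
#' @export
fluorescence_recording <- function(fluor, frame_dt, positions = NULL,
                                   provenance = "simulated", meta = list()) {
  fluor <- as.matrix(fluor)
  if (!all(is.finite(fluor)))
    stop_structural("fluorescence matrix contains non-finite values")
  if (!is.null(positions) && nrow(positions) != ncol(fluor))
    stop_structural("positions do not match the number of traces")
  structure(list(fluor = fluor, frame_dt = frame_dt, positions = positions,
                 provenance = provenance, meta = meta),
            class = "fluorescence_recording")
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf("<fluorescence_recording> %d frames x %d neurons, dt = %g s (%s)\n",
              nrow(x$fluor), ncol(x$fluor), x$frame_dt, x$provenance))
  invisible(x)
}

#' Convert a spike raster to bound-calcium concentration
#'
#' Frame-sampled recursion
#' `Ca[n] = Ca[n-1] * (1 - frame_dt / tau_ca) + a_ca * spikes_in_frame_n`,
#' starting from zero.
#'
#' @param spikes a `spike_record`.
#' @param params a `calcium_params`.
#' @return frames x neurons matrix of calcium concentrations.
#' @export
spikes_to_calcium <- function(spikes, params = calcium_params()) {
  n_frames <- floor(spikes$duration / params$frame_dt)
  decay <- 1 - params$frame_dt / params$tau_ca
  counts <- vapply(spikes$spikes, function(t) {
    frame <- pmin(n_frames, floor(t / params$frame_dt) + 1L)
    tabulate(frame, nbins = n_frames)
  }, numeric(n_frames))
  ca <- apply(params$a_ca * counts, 2, function(x)
    stats::filter(x, decay, method = "recursive"))
  matrix(as.numeric(ca), n_frames, length(spikes$spikes))
}

#' Saturating fluorescence with additive noise
#'
#' `F = Ca / (Ca + k_sat) + eta`, with `eta` zero-mean Gaussian noise of
#' standard deviation `noise_sd`, drawn independently per frame and
#' neuron.
#'
#' @param ca frames x neurons calcium matrix from [spikes_to_calcium()].
#' @param params a `calcium_params`.
#' @param seed integer RNG seed for the noise.
#' @param positions optional ROI positions, carried into the recording.
#' @return a `fluorescence_recording`.
#' @export
calcium_to_fluorescence <- function(ca, params = calcium_params(), seed = 1,
                                    positions = NULL) {
  set.seed(seed)
  f <- ca / (ca + params$k_sat) +
    matrix(stats::rnorm(length(ca), 0, params$noise_sd), nrow(ca), ncol(ca))
  fluorescence_recording(f, params$frame_dt, positions,
                         provenance = "simulated",
                         meta = list(calcium = unclass(params), noise_seed = seed))
}

#' Add light-scattering crosstalk between ROIs
#'
#' Each trace receives a distance-weighted sum of all other traces,
#' `F'_i = F_i + a_sc * sum_j exp(-d_ij^2 / r_sc^2) * F_j`, emulating
#' light scattered into a region of interest from surrounding cells.
#' With `a_sc = 0` the recording is returned unchanged.  No deconvolution
#' is applied anywhere in the package: the artifact is treated as an
#' irreducible property of the imaging data.
#'
#' @param rec a `fluorescence_recording`.
#' @param params a `scatter_params`.
#' @param positions ROI positions (mm); defaults to those stored in `rec`.
#' @return a `fluorescence_recording` with crosstalk applied.
#' @export
apply_scattering <- function(rec, params = scatter_params(),
                             positions = rec$positions) {
  if (params$a_sc == 0) return(rec)
  if (is.null(positions))
    stop_structural("positions are required to model light scattering")
  kernel <- exp(-pairwise_distances(positions)^2 / params$r_sc^2)
  diag(kernel) <- 0
  dimnames(kernel) <- NULL
  out <- rec
  out$fluor <- rec$fluor + params$a_sc * (rec$fluor %*% kernel)
  out$meta$scatter <- unclass(params)
  out
}

#' Write / read fluorescence recordings
#'
#' Text format: tab-delimited with a leading `time_s` column and one
#' column per neuron, full precision; positions (if any) are stored next
#' to it as `paste0(file, ".pos")`.  With `format = "rds"` the whole
#' recording object is stored in R's native serialization as an array
#' container.
#'
#' @param rec a `fluorescence_recording`.
#' @param file output path.
#' @param format `"tsv"` or `"rds"`.
#' @return `read_fluorescence()` returns a `fluorescence_recording`.
#' @export
write_fluorescence <- function(rec, file, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(rec, file)
    return(invisible(file))
  }
  tab <- data.frame(time_s = (seq_len(nrow(rec$fluor)) - 1L) * rec$frame_dt,
                    rec$fluor)
  names(tab) <- c("time_s", sprintf("n%03d", seq_len(ncol(rec$fluor))))
  utils::write.table(format(tab, digits = 17, scientific = TRUE, trim = TRUE),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(rec$positions)) {
    pos <- data.frame(id = seq_len(nrow(rec$positions)) - 1L,
                      x_mm = rec$positions[, 1], y_mm = rec$positions[, 2])
    utils::write.table(pos, paste0(file, ".pos"), sep = "\t",
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(file)
}

#' @rdname write_fluorescence
#' @export
read_fluorescence <- function(file, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(file))
  tab <- utils::read.table(file, sep = "\t", header = TRUE)
  if (any(!is.finite(as.matrix(tab))))
    stop_structural("fluorescence file contains non-finite entries")
  f <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(f) <- NULL
  dt <- stats::median(diff(tab$time_s))
  pos_file <- paste0(file, ".pos")
  positions <- NULL
  if (file.exists(pos_file)) {
    pos <- utils::read.table(pos_file, sep = "\t", header = TRUE)
    positions <- as.matrix(pos[order(pos$id), c("x_mm", "y_mm")])
    dimnames(positions) <- NULL
  }
  fluorescence_recording(f, dt, positions, provenance = "experimental",
                         meta = list(source_file = file))
}

#' Shorten a recording to its first `1/divisor` fraction
#'
#' @param rec a `fluorescence_recording`.
#' @param divisor integer >= 1; the output keeps the first
#'   `floor(frames / divisor)` frames.
#' @return the trimmed `fluorescence_recording`.
#' @export
trim_recording <- function(rec, divisor) {
  stopifnot(divisor >= 1)
  keep <- floor(nrow(rec$fluor) / divisor)
  out <- rec
  out$fluor <- rec$fluor[seq_len(keep), , drop = FALSE]
  out$meta$trim_divisor <- divisor
  out
}
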