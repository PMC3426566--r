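#' Pipeline configuration
#'
#' Collects every tunable of the benchmark pipeline in named sections
#' mirroring the package modules, with defaults equal to the documented
#' study conditions.  The configuration round-trips through JSON and is
#' written alongside every pipeline output.
#'
#' @param topology list: `ensemble` ("nonlocal" or "local"), `n`, `p`,
#'   `target_cc`, `lambda_mm`, `area_side`.
#' @param neuron,synapse,drive,calcium,scatter parameter overrides
#'   merged over [neuron_params()], [synapse_params()], [drive_params()],
#'   [calcium_params()], [scatter_params()].
#' @param estimator overrides merged over [estimator_spec()];
#'   `cond_level = "auto"` selects the conditioning level from the data.
#' @param evaluation list: `top_fraction`, `tune` (logical: tune the
#'   recurrent weight before the main run), `target_burst_rate`.
#' @param duration recording length in seconds.
#' @param seed master seed; all stage seeds are derived from it.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(topology = list(), neuron = list(),
                            synapse = list(), drive = list(),
                            calcium = list(), scatter = list(),
                            estimator = list(), evaluation = list(),
                            duration = 3600, seed = 1) {
  merge <- function(defaults, over) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop_structural("unknown configuration field(s): %s",
                      paste(bad, collapse = ", "))
    defaults[names(over)] <- over
    defaults
  }
  cfg <- list(
    topology = merge(list(ensemble = "nonlocal", n = 100, p = 0.12,
                          target_cc = 0.5, lambda_mm = 0.5, area_side = 0.5),
                     topology),
    neuron = merge(unclass(neuron_params()), neuron),
    synapse = merge(unclass(synapse_params()), synapse),
    drive = merge(unclass(drive_params()), drive),
    calcium = merge(unclass(calcium_params()), calcium),
    scatter = merge(unclass(scatter_params()), scatter),
    estimator = merge(c(unclass(estimator_spec()), list(cond_level = "auto")),
                      estimator),
    evaluation = merge(list(top_fraction = 0.10, tune = TRUE,
                            target_burst_rate = 0.1), evaluation),
    duration = duration, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param file JSON path.
#' @return `read_config()` returns the `pipeline_config`.
#' @export
write_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  # JSON stores infinite bounds as strings
  for (f in c("cond_low", "cond_high"))
    raw$estimator[[f]] <- as.numeric(raw$estimator[[f]])
  do.call(pipeline_config,
          c(raw[c("topology", "neuron", "synapse", "drive", "calcium",
                  "scatter", "estimator", "evaluation")],
            list(duration = raw$duration, seed = raw$seed)))
}

#' Derive a stage seed from the master seed
#'
#' Deterministic 31-bit hash of the master seed and a stage name, so
#' that re-running any stage in isolation reproduces the pipeline's
#' stream for that stage.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

cfg_params <- function(config) {
  list(neuron = do.call(neuron_params, config$neuron),
       syn = do.call(synapse_params, config$synapse),
       drive = do.call(drive_params, config$drive),
       calcium = do.call(calcium_params, config$calcium),
       scatter = do.call(scatter_params, config$scatter))
}

stage_log <- function(stage, t0, ...) {
  extra <- paste(vapply(list(...), as.character, character(1)), collapse = " ")
  message(sprintf("[gtenet] %-12s %6.1fs %s", stage,
                  as.numeric(Sys.time()) - t0, extra))
}

#' Generate the ground-truth network of a configuration
#'
#' @param config a `pipeline_config`.
#' @param seed overrides the derived generation seed.
#' @return a `directed_network`.
#' @export
generate_network <- function(config, seed = derive_seed(config$seed, "topology")) {
  top <- config$topology
  if (top$ensemble == "nonlocal")
    generate_nonlocal(top$n, top$p, top$target_cc, seed = seed,
                      area_side = top$area_side)
  else
    generate_local(top$n, top$p, top$lambda_mm, seed = seed,
                   area_side = top$area_side)
}

#' Run the full synthetic benchmark pipeline
#'
#' generate -> (tune) -> simulate -> fluorescence (+ scattering) ->
#' reconstruct -> evaluate, with every stage seeded from the master seed
#' and one structured log line per stage.  Artifacts are written to
#' `out_dir` when given (network, spikes, fluorescence, score matrix,
#' ROC table, config sidecar).
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @return list with the ground-truth `network`, tuned weight `g_int`,
#'   `spikes`, `bursts`, `recording`, conditioning level `cond_level`,
#'   `scores`, reconstructed network `recon`, `roc` and `motifs`.
#' @export
pipeline_benchmark <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- as.numeric(Sys.time())
  prm <- cfg_params(config)

  net <- generate_network(config)
  stage_log("generate", t0, sprintf("links=%d", net$meta$n_links))

  syn <- prm$syn
  if (isTRUE(config$evaluation$tune)) {
    syn$g_int <- as.numeric(tune_weight(
      net, prm$neuron, syn, prm$drive,
      target_rate = config$evaluation$target_burst_rate,
      seed = derive_seed(config$seed, "tune")))
    stage_log("tune", t0, sprintf("g_int=%.3f", syn$g_int))
  }

  spikes <- simulate_network(net, prm$neuron, syn, prm$drive,
                             duration = config$duration,
                             seed = derive_seed(config$seed, "dynamics"))
  bursts <- detect_bursts(spikes)
  stage_log("simulate", t0, sprintf("spikes=%d bursts=%d",
                                    sum(lengths(spikes$spikes)), nrow(bursts)))

  ca <- spikes_to_calcium(spikes, prm$calcium)
  rec <- calcium_to_fluorescence(ca, prm$calcium,
                                 seed = derive_seed(config$seed, "noise"),
                                 positions = net$positions)
  rec <- apply_scattering(rec, prm$scatter)
  stage_log("fluorify", t0, sprintf("frames=%d", nrow(rec$fluor)))

  est <- config$estimator
  cond <- est$cond_level
  if (identical(cond, "auto"))
    cond <- select_conditioning_level(rec, method = "range")
  spec <- estimator_spec(est$method, est$order, est$same_bin, est$bins,
                         cond_low = est$cond_low, cond_high = cond,
                         xc_lag = est$xc_lag)
  scores <- score_matrix(rec, spec)
  stage_log("reconstruct", t0, sprintf("method=%s cond=%.4f n=%d",
                                       spec$method, cond, scores$n_samples))

  recon <- rank_and_threshold(scores, config$evaluation$top_fraction,
                              positions = net$positions)
  roc_res <- roc(scores, net)
  motifs <- motif_audit(recon, net)
  stage_log("evaluate", t0, sprintf("TP@10%%FP=%.3f", roc_res$performance))

  res <- list(network = net, g_int = syn$g_int, spikes = spikes,
              bursts = bursts, recording = rec, cond_level = cond,
              scores = scores, recon = recon, roc = roc_res,
              motifs = motifs, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    write_network(net, file.path(out_dir, "network.tsv"))
    write_spikes(spikes, file.path(out_dir, "spikes.tsv"))
    write_fluorescence(rec, file.path(out_dir, "fluorescence.tsv"))
    write_scores(scores, file.path(out_dir, "scores.tsv"))
    write_network(recon, file.path(out_dir, "reconstruction.tsv"))
    utils::write.table(data.frame(fpr = roc_res$fpr, tpr = roc_res$tpr),
                       file.path(out_dir, "roc.tsv"), sep = "\t",
                       row.names = FALSE)
  }
  res
}

#' Reconstruct a network from an experimental recording
#'
#' Applies the identical processing used for simulated data to a real
#' fluorescence matrix: discrete differentiation, automatic conditioning
#' two standard deviations above the left (noise) peak of the
#' population-average histogram, generalized TE scoring, and thresholding
#' at the top 5\% of links.  The reconstruction is compared against full
#' and partial (out-degree preserving) randomization ensembles.
#'
#' @param rec a `fluorescence_recording`, or a path readable by
#'   [read_fluorescence()].
#' @param config a `pipeline_config` (estimator and evaluation sections
#'   are honoured; `evaluation$top_fraction` defaults to 0.05 here).
#' @param n_draws randomization draws per ensemble.
#' @return list with `cond_level`, `scores`, `recon` and the
#'   `topology_report`s against both ensembles.
#' @export
pipeline_real <- function(rec, config = pipeline_config(
                            evaluation = list(top_fraction = 0.05)),
                          n_draws = 100) {
  if (is.character(rec)) rec <- read_fluorescence(rec)
  if (!all(is.finite(rec$fluor)))
    stop_structural("recording contains non-finite values")
  est <- config$estimator
  cond <- est$cond_level
  if (identical(cond, "auto"))
    cond <- select_conditioning_level(rec, method = "peak")
  spec <- estimator_spec(est$method, est$order, est$same_bin, est$bins,
                         cond_low = est$cond_low, cond_high = cond,
                         xc_lag = est$xc_lag)
  scores <- score_matrix(rec, spec)
  recon <- rank_and_threshold(scores, config$evaluation$top_fraction,
                              positions = rec$positions)
  seeds <- derive_seed(config$seed, "randomize") + seq_len(n_draws)
  full_rand <- lapply(seeds, function(s) randomize_full(recon, s))
  part_rand <- lapply(seeds, function(s) randomize_partial(recon, s))
  list(cond_level = cond, scores = scores, recon = recon,
       vs_full = topology_report(recon, full_rand),
       vs_partial = topology_report(recon, part_rand))
}

#' Write / read a score matrix
#'
#' Dense tab-delimited matrix plus a JSON sidecar
#' (`paste0(file, ".json")`) holding the estimator specification and the
#' retained-sample count.
#'
#' @param scores a `score_matrix`.
#' @param file output path.
#' @return `read_scores()` returns a `score_matrix`.
#' @export
write_scores <- function(scores, file) {
  txt <- matrix(sprintf("%.17g", scores$scores), nrow(scores$scores))
  txt[is.na(scores$scores)] <- "NA"
  utils::write.table(txt, file, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(spec = unclass(scores$spec),
                            n_samples = scores$n_samples,
                            warnings = scores$warnings),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_scores
#' @export
read_scores <- function(file) {
  s <- as.matrix(utils::read.table(file, sep = "\t"))
  dimnames(s) <- NULL
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  for (f in c("cond_low", "cond_high"))
    side$spec[[f]] <- as.numeric(side$spec[[f]])
  spec <- do.call(estimator_spec, side$spec[c("method", "order", "same_bin",
                                              "bins", "cond_low", "cond_high",
                                              "xc_lag")])
  structure(list(scores = s, spec = spec, n_samples = side$n_samples,
                 warnings = side$warnings),
            class = "score_matrix")
}
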