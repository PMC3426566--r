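#' ROC analysis of a score matrix against ground truth
#'
#' Sweeps a threshold over all distinct off-diagonal score values and
#' records, at each, the fraction of true positives (retained links
#' present in the ground truth) against the fraction of false positives.
#' The diagonal is excluded from both counts.
#'
#' @param scores a `score_matrix` or bare numeric matrix.
#' @param truth a `directed_network` (the ground-truth topology).
#' @return object of class `roc_result`: list with monotone `fpr` and
#'   `tpr` vectors (starting at (0,0), ending at (1,1)) and the scalar
#'   `performance`, the true-positive fraction at 10\% false positives.
#' @export
roc <- function(scores, truth) {
  s <- if (inherits(scores, "score_matrix")) scores$scores else scores
  A <- if (inherits(truth, "directed_network")) truth$adjacency else truth
  if (!all(dim(s) == dim(A)))
    stop_structural("score matrix and ground truth have different sizes")
  off <- which(row(s) != col(s))
  sv <- s[off]
  lab <- A[off]
  o <- order(sv, decreasing = TRUE)
  lab <- lab[o]
  sv <- sv[o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  # one ROC point per distinct threshold (last index of each tie block)
  last <- c(sv[-1] != sv[-length(sv)], TRUE)
  tpr <- c(0, tp[last] / max(tp[length(tp)], 1L))
  fpr <- c(0, fp[last] / max(fp[length(fp)], 1L))
  out <- structure(list(fpr = fpr, tpr = tpr), class = "roc_result")
  out$performance <- performance(out, 0.10)
  out
}

#' True-positive fraction at a fixed false-positive fraction
#'
#' Reads the reconstruction performance off a ROC curve by linear
#' interpolation between the bracketing curve points.
#'
#' @param roc a `roc_result`.
#' @param fp false-positive fraction at which to evaluate (default 0.10).
#' @return interpolated true-positive fraction.
#' @export
performance <- function(roc, fp = 0.10) {
  stats::approx(roc$fpr, roc$tpr, xout = fp, ties = max, rule = 2)$y
}

#' Positive precision curve
#'
#' For every number of retained links `TFS` (links included in rank
#' order), plots the true-false ratio
#' `TFR = (#TP - #FP) / (#TP + #FP)`; `TFR = 0` marks the point where a
#' reconstructed link is equally likely to be true as false.
#'
#' @inheritParams roc
#' @return object of class `ppc_result`: data frame with columns `tfs`
#'   (increasing retained-link count), `tfr`, `tp` and `fp`.
#' @export
ppc <- function(scores, truth) {
  s <- if (inherits(scores, "score_matrix")) scores$scores else scores
  A <- if (inherits(truth, "directed_network")) truth$adjacency else truth
  off <- which(row(s) != col(s))
  src <- row(s)[off]
  tgt <- col(s)[off]
  o <- order(-s[off], src, tgt)
  lab <- A[off][o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  structure(data.frame(tfs = seq_along(lab), tfr = (tp - fp) / (tp + fp),
                       tp = tp, fp = fp),
            class = c("ppc_result", "data.frame"))
}

#' Topology comparison tables
#'
#' Compares the per-node clustering, in-degree and per-link connection
#' distance distributions of a reconstructed network against one or more
#' reference networks (the ground truth, or an ensemble of randomized
#' controls).  For ensembles, the empirical two-sided percentile of each
#' observed mean within the reference means is reported.
#'
#' @param recon a `directed_network` (the reconstruction).
#' @param refs a single `directed_network` or a list of them.
#' @return list with `observed` (per-node/per-link distributions and
#'   means of `recon`), `reference` (per-network means), and
#'   `percentile` (empirical percentile of each observed mean within the
#'   reference ensemble; `NA` with a single reference).
#' @export
topology_report <- function(recon, refs) {
  if (inherits(refs, "directed_network")) refs <- list(refs)
  obs <- graph_stats(recon)
  ref_means <- t(vapply(refs, function(r) graph_stats(r)$means, numeric(3)))
  percentile <- if (length(refs) >= 10) {
    vapply(colnames(ref_means), function(k) {
      mean(ref_means[, k] <= obs$means[[k]]) * 100
    }, numeric(1))
  } else rep(NA_real_, 3)
  list(observed = obs, reference = ref_means, percentile = percentile)
}

#' Motif audit of a reconstruction
#'
#' Quantifies how specific ground-truth connectivity motifs fare in the
#' retained link set:
#' \describe{
#'   \item{bidir_recovered}{fraction of ground-truth reciprocal pairs
#'     with *both* directions retained,}
#'   \item{unidir_recovered}{fraction of ground-truth unidirectional
#'     links present in the retained set,}
#'   \item{unidir_spurious_reverse}{among retained unidirectional-true
#'     links, fraction whose (false) reverse is also retained,}
#'   \item{shared_source_spurious}{fraction of shared-source motifs
#'     (`k -> i`, `k -> j`, no true lateral link either way) in which a
#'     spurious lateral link was retained,}
#'   \item{chain_spurious}{fraction of embedded chains (`i -> j -> k`,
#'     no true shortcut `i -> k`) in which the spurious shortcut was
#'     retained.}
#' }
#'
#' @param recon reconstructed `directed_network` (the retained links).
#' @param truth ground-truth `directed_network`.
#' @return named list of the five fractions plus the underlying counts.
#' @export
motif_audit <- function(recon, truth) {
  R <- recon$adjacency
  A <- truth$adjacency
  if (!all(dim(R) == dim(A)))
    stop_structural("reconstruction and truth have different sizes")

  bidir <- A & t(A)
  bidir_pairs <- which(bidir & upper.tri(bidir))
  bidir_recovered <- mean((R & t(R))[bidir_pairs])

  unidir <- A & !t(A)
  unidir_links <- which(unidir)
  unidir_recovered <- mean(R[unidir_links])
  kept <- unidir_links[R[unidir_links]]
  unidir_spurious_reverse <- mean(t(R)[kept])

  # shared-source motifs: common input, no true lateral link
  Ad <- A * 1
  common_src <- crossprod(Ad)           # [i, j] = number of shared sources
  lateral_free <- common_src > 0 & !A & !t(A)
  ss_pairs <- which(lateral_free & upper.tri(lateral_free))
  shared_source_spurious <- mean((R | t(R))[ss_pairs])

  # embedded chains i -> j -> k without a true shortcut i -> k
  two_step <- (Ad %*% Ad) > 0
  chains <- two_step & !A & row(A) != col(A)
  chain_idx <- which(chains)
  chain_spurious <- mean(R[chain_idx])

  list(bidir_recovered = bidir_recovered,
       unidir_recovered = unidir_recovered,
       unidir_spurious_reverse = unidir_spurious_reverse,
       shared_source_spurious = shared_source_spurious,
       chain_spurious = chain_spurious,
       counts = c(bidir_pairs = length(bidir_pairs),
                  unidir_links = length(unidir_links),
                  retained_unidir = length(kept),
                  shared_source_pairs = length(ss_pairs),
                  chain_triples = length(chain_idx)))
}

#' Cross-correlogram of a neuron group against the population
#'
#' Correlates the discretely differentiated average fluorescence of a
#' group of neurons with that of the whole population, over integer
#' frame lags, and fits a Gaussian
#' `a * exp(-(lag - mu)^2 / (2 * sigma^2))` to the correlogram.  A
#' negative fitted peak lag means the group leads the population.
#'
#' @param rec a `fluorescence_recording`.
#' @param members integer indices of the group.
#' @param max_lag correlogram half-width in frames.
#' @return list with the correlogram (`lag`, `xc`) and the fitted
#'   `amplitude`, `peak_lag` and `sigma` (`NA` plus `fit_ok = FALSE` on
#'   fit failure).
#' @export
group_correlogram <- function(rec, members, max_lag = 50) {
  g_grp <- diff(rowMeans(rec$fluor[, members, drop = FALSE]))
  g_all <- diff(rowMeans(rec$fluor))
  lags <- -max_lag:max_lag
  # C(tau) = cor(group(t), population(t - tau)): a group that fires
  # earlier than the population peaks at negative tau
  xc <- vapply(lags, function(l) {
    if (l >= 0) {
      stats::cor(g_grp[(1 + l):length(g_grp)], g_all[seq_len(length(g_all) - l)])
    } else {
      stats::cor(g_grp[seq_len(length(g_grp) + l)], g_all[(1 - l):length(g_all)])
    }
  }, numeric(1))
  resid_fn <- function(p) xc - p[1] * exp(-(lags - p[2])^2 / (2 * p[3]^2))
  best <- NULL
  for (s0 in c(5, 2, 0.8)) {  # multi-start: correlograms vary in sharpness
    out <- tryCatch(
      minpack.lm::nls.lm(par = c(max(xc), lags[which.max(xc)], s0),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:3)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best))
    return(list(lag = lags, xc = xc, amplitude = NA_real_,
                peak_lag = NA_real_, sigma = NA_real_, fit_ok = FALSE))
  cf <- best$par
  list(lag = lags, xc = xc, amplitude = cf[1],
       peak_lag = cf[2], sigma = abs(cf[3]),
       fit_ok = TRUE)
}

#' State-dependent functional-connectivity hubs
#'
#' For each conditioning range, ranks nodes by their summed incoming
#' transfer entropy ("causal sinks"), selects the top `n_hubs`, and
#' characterizes each hub's neighborhood (the hub plus its first
#' in-neighbors in the retained functional graph of that range): the
#' mean pairwise cross-correlation within the neighborhood versus across
#' (neighborhood against the rest), with a Mann-Whitney test, and the
#' Gaussian-fitted group-versus-population correlogram.
#'
#' @param rec the `fluorescence_recording` the scores were computed from.
#' @param scores_per_range list of TE `score_matrix` objects, one per
#'   conditioning range.
#' @param ranges list (or 2-column matrix) of `(low, high)` conditioning
#'   bounds matching `scores_per_range`.
#' @param n_hubs number of hub nodes per range (20 unless fewer nodes).
#' @param top_fraction link fraction used to build the retained
#'   functional graph of each range.
#' @param xc_spec estimator specification for the pairwise synchrony
#'   cross-correlations.
#' @return object of class `hub_report`: per-range list with `hubs`
#'   (node ids), `within`/`across` synchrony means, `p_value`
#'   (Mann-Whitney), and per-hub correlogram fits.
#' @export
hub_analysis <- function(rec, scores_per_range, ranges, n_hubs = 20,
                         top_fraction = 0.10,
                         xc_spec = estimator_spec(method = "xc")) {
  if (is.matrix(ranges))
    ranges <- lapply(seq_len(nrow(ranges)), function(i) ranges[i, ])
  stopifnot(length(ranges) == length(scores_per_range))
  x <- differentiate(rec)
  g <- population_average(rec)[-1L]
  out <- vector("list", length(ranges))
  for (r in seq_along(ranges)) {
    sm <- scores_per_range[[r]]
    s <- if (inherits(sm, "score_matrix")) sm$scores else sm
    N <- ncol(s)
    k <- min(n_hubs, N)
    incoming <- colSums(s, na.rm = TRUE)
    hubs <- order(incoming, decreasing = TRUE)[seq_len(k)]
    retained <- rank_and_threshold(s, top_fraction)$adjacency
    mask <- conditioning_mask(g, ranges[[r]][1], ranges[[r]][2])
    xc <- xc_matrix(x, xc_spec, mask)

    within <- numeric(0)
    across <- numeric(0)
    fits <- vector("list", k)
    for (h in seq_len(k)) {
      grp <- unique(c(hubs[h], which(retained[, hubs[h]])))
      fits[[h]] <- c(list(hub = hubs[h], size = length(grp)),
                     group_correlogram(rec, grp)[c("amplitude", "peak_lag",
                                                   "sigma", "fit_ok")])
      if (length(grp) < 2) next
      inside <- xc[grp, grp]
      within <- c(within, inside[upper.tri(inside)])
      outside <- setdiff(seq_len(N), grp)
      if (length(outside)) across <- c(across, as.numeric(xc[grp, outside]))
    }
    p_value <- if (length(within) && length(across))
      stats::wilcox.test(within, across)$p.value else NA_real_
    out[[r]] <- list(range = ranges[[r]], hubs = hubs,
                     within = mean(within), across = mean(across),
                     p_value = p_value, fits = fits)
  }
  structure(out, class = "hub_report")
}

#' Reconstruction quality across dynamical states
#'
#' Divides the population-average fluorescence distribution into
#' `n_ranges` non-overlapping ranges of equal width, reconstructs the
#' network with generalized TE restricted to each range, and evaluates a
#' ROC curve per range.  With `equal_samples = TRUE`, every range is
#' randomly subsampled to the sample count of the highest range, so that
#' performance differences reflect the dynamical state rather than
#' sample size.
#'
#' @param rec a `fluorescence_recording`.
#' @param truth the ground-truth `directed_network`.
#' @param spec TE estimator specification (conditioning bounds are
#'   overridden per range).
#' @param n_ranges number of equal-width fluorescence ranges.
#' @param equal_samples subsample all ranges to the top range's count.
#' @param seed RNG seed for the subsampling.
#' @return list with `ranges` (bounds), `counts` (samples per range),
#'   `rocs` (per-range `roc_result`) and `performance` (per-range
#'   TP fraction at 10\% FP).
#' @export
state_range_analysis <- function(rec, truth, spec = estimator_spec(),
                                 n_ranges = 7, equal_samples = FALSE,
                                 seed = 1) {
  g <- population_average(rec)[-1L]
  edges <- seq(min(g), max(g), length.out = n_ranges + 1L)
  masks <- lapply(seq_len(n_ranges), function(r) {
    if (r < n_ranges) g >= edges[r] & g < edges[r + 1L]
    else g >= edges[r] & g <= edges[r + 1L]  # top range closed above
  })
  counts <- vapply(masks, sum, integer(1))
  if (equal_samples) {
    set.seed(seed)
    n_min <- counts[n_ranges]
    masks <- lapply(masks, function(m) {
      idx <- which(m)
      if (length(idx) > n_min) {
        m[] <- FALSE
        m[sample(idx, n_min)] <- TRUE
      }
      m
    })
  }
  rocs <- lapply(masks, function(m) roc(score_matrix(rec, spec, mask = m), truth))
  list(ranges = cbind(low = edges[-length(edges)], high = edges[-1]),
       counts = counts,
       rocs = rocs,
       performance = vapply(rocs, function(r) r$performance, numeric(1)))
}
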