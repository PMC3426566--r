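#' Estimator specification
#'
#' Bundles every choice that defines one directed functional-connectivity
#' scoring run: the method (generalized transfer entropy `"te"`, mutual
#' information `"mi"`, cross-correlation `"xc"`, Granger causality
#' `"gc"`), the Markov / model order, whether same-bin (zero-lag) source
#' terms are included, the number of discretization levels, the
#' conditioning bounds on the population-average fluorescence and the
#' cross-correlogram lag range.
#'
#' The conditioning contract used throughout: a sample tuple is retained
#' iff the population-average fluorescence at its *latest* time index
#' falls in `[cond_low, cond_high)`.  A differentiated sample
#' `x[t] = F[t+1] - F[t]` is timestamped at frame `t + 1` for this
#' purpose.
#'
#' @param method one of `"te"`, `"mi"`, `"xc"`, `"gc"`.
#' @param order Markov order (TE) / autoregressive order (GC); history
#'   length in frames.
#' @param same_bin include same-bin source interactions (TE, GC).
#' @param bins number of equal-width discretization levels (TE, MI).
#' @param cond_low,cond_high conditioning bounds on the population
#'   average; defaults keep every sample.
#' @param xc_lag maximum cross-correlogram lag in frames (XC).
#' @return object of class `estimator_spec`.
#' @export
estimator_spec <- function(method = c("te", "mi", "xc", "gc"), order = 2L,
                           same_bin = TRUE, bins = 3L,
                           cond_low = -Inf, cond_high = Inf, xc_lag = 2L) {
  method <- match.arg(method)
  if (method %in% c("te", "mi") && bins < 2)
    stop_structural("at least 2 discretization levels are required")
  if (order < 1) stop_structural("order must be >= 1")
  if (cond_low >= cond_high)
    stop_structural("cond_low must be below cond_high")
  structure(list(method = method, order = as.integer(order),
                 same_bin = isTRUE(same_bin), bins = as.integer(bins),
                 cond_low = cond_low, cond_high = cond_high,
                 xc_lag = as.integer(xc_lag)),
            class = "estimator_spec")
}

#' Discrete differentiation of fluorescence traces
#'
#' `x[t] = F[t+1] - F[t]`, the basic pre-processing step that isolates
#' baseline modulations associated with firing; applied before every
#' scoring method.
#'
#' @param rec a `fluorescence_recording` or a frames x neurons matrix.
#' @return (frames - 1) x neurons matrix of differenced values.
#' @export
differentiate <- function(rec) {
  f <- if (inherits(rec, "fluorescence_recording")) rec$fluor else as.matrix(rec)
  diff(f)
}

#' Population-average fluorescence
#'
#' @param rec a `fluorescence_recording` or matrix.
#' @return numeric vector `g`, the mean over neurons at every frame.
#' @export
population_average <- function(rec) {
  f <- if (inherits(rec, "fluorescence_recording")) rec$fluor else as.matrix(rec)
  rowMeans(f)
}

#' Conditioning mask from the population average
#'
#' @param g population-average vector.
#' @param cond_low,cond_high bounds; a time point is kept when
#'   `cond_low <= g < cond_high`.
#' @return logical vector of the same length as `g`.
#' @export
conditioning_mask <- function(g, cond_low = -Inf, cond_high = Inf) {
  g >= cond_low & g < cond_high
}

#' Automatic conditioning level
#'
#' Two selection rules for the conditioning level on the
#' population-average fluorescence, both aimed at excluding fully
#' developed bursts while keeping most samples:
#' \describe{
#'   \item{`"peak"`}{fits a Gaussian to the left (noise / inter-burst)
#'     peak of the fluorescence histogram and returns `mean + 2 * sd`
#'     of the fitted component -- the heuristic used for experimental
#'     recordings, where the noise peak is broad;}
#'   \item{`"range"`}{returns the upper bound of the second of seven
#'     equal-width fluorescence ranges, i.e. the interface between the
#'     silent and bursting regimes -- the convention used for the
#'     simulated benchmark, where reconstruction quality peaks when
#'     exactly the two lowest ranges are retained.}
#' }
#'
#' @param rec a `fluorescence_recording`, or the population-average
#'   vector itself.
#' @param method `"peak"` or `"range"`.
#' @param n_bins histogram resolution for the Gaussian fit.
#' @return the conditioning level (fluorescence units).
#' @export
select_conditioning_level <- function(rec, method = c("peak", "range"),
                                      n_bins = 100) {
  g <- if (inherits(rec, "fluorescence_recording")) population_average(rec) else rec
  method <- match.arg(method)
  if (method == "range")
    return(min(g) + (2 / 7) * (max(g) - min(g)))
  h <- graphics::hist(g, breaks = n_bins, plot = FALSE)
  dens <- h$density
  mids <- h$mids
  peak <- which.max(dens)
  if (peak >= length(dens) - 1L ||
      dens[peak] < 1.5 * stats::median(dens[dens > 0]))
    stop_structural(paste("no left peak found in the fluorescence histogram;",
                          "supply a manual conditioning level"))
  # fit the Gaussian on the peak, its left flank and the decreasing part
  # of its right flank, stopping where a high-fluorescence tail takes over
  right <- peak
  while (right < length(dens) && dens[right + 1L] <= dens[right] &&
         dens[right + 1L] > 0.02 * dens[peak]) right <- right + 1L
  use <- seq_len(right)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                      data = data.frame(x = mids[use], d = dens[use]),
                      start = list(a = dens[peak], mu = mids[peak],
                                   s = diff(range(mids[use])) / 4 + 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop_structural(paste("Gaussian fit to the left fluorescence peak failed;",
                          "supply a manual conditioning level"))
  cf <- stats::coef(fit)
  unname(cf["mu"] + 2 * abs(cf["s"]))
}

#' Equal-width discretization
#'
#' Bins a signal into `b` equal-width levels spanning the range of the
#' supplied reference samples (by default the signal itself).  A
#' zero-range signal maps entirely to level 0.
#'
#' @param x numeric vector.
#' @param b number of levels.
#' @param ref samples defining the bin range (e.g. the conditioned subset).
#' @return integer vector of symbols in `0 .. b-1`.
#' @export
discretize <- function(x, b, ref = x) {
  b <- as.integer(b)
  if (length(ref) == 0) return(integer(length(x)))
  lo <- min(ref)
  hi <- max(ref)
  if (!is.finite(lo) || hi <= lo) return(integer(length(x)))
  sym <- as.integer(floor((x - lo) / (hi - lo) * b))
  pmin(pmax(sym, 0L), b - 1L)
}

# Encode per-neuron symbol streams into the combined codes consumed by
# the C++ kernel.  D is the (samples x neurons) integer symbol matrix.
encode_codes <- function(D, b, k, same_bin) {
  T_n <- nrow(D)
  tp <- D  # fut symbol
  for (m in seq_len(k)) {
    shifted <- rbind(matrix(0L, m, ncol(D)), D[seq_len(T_n - m), , drop = FALSE])
    tp <- tp + b^m * shifted
  }
  if (same_bin) {
    sp <- D
    for (m in seq_len(k)) {
      shifted <- rbind(matrix(0L, m, ncol(D)), D[seq_len(T_n - m), , drop = FALSE])
      sp <- sp + b^m * shifted
    }
    n_sp <- b^(k + 1)
  } else {
    sp <- matrix(0L, T_n, ncol(D))
    for (m in seq_len(k)) {
      shifted <- rbind(matrix(0L, m, ncol(D)), D[seq_len(T_n - m), , drop = FALSE])
      sp <- sp + b^(m - 1) * shifted
    }
    n_sp <- b^k
  }
  list(tp = tp, sp = sp, n_tp = as.integer(b^(k + 1)), n_sp = as.integer(n_sp))
}

# Samples (rows of the differentiated matrix) usable as tuple endpoints:
# past depth k available and conditioning mask satisfied.
valid_tuples <- function(mask, k) {
  idx <- which(mask)
  idx[idx > k]
}

#' Directed functional-connectivity score matrix
#'
#' Scores every ordered pair of neurons under one estimator
#' specification.  The recording is differentiated, the conditioning
#' mask is derived from the population average (or taken from `mask`),
#' and -- for the discrete estimators -- each neuron's conditioned
#' samples are binned with per-neuron equal-width edges so that scores
#' are comparable across pairs.
#'
#' @param rec a `fluorescence_recording`.
#' @param spec an `estimator_spec`.
#' @param mask optional logical vector over differentiated samples
#'   overriding the conditioning bounds (e.g. for equal-sample-size
#'   range analyses).
#' @return object of class `score_matrix`: list with the `scores`
#'   matrix (`scores[j, i]` = score of link `j -> i`, diagonal `NA`),
#'   the `spec`, the retained tuple count `n_samples` and any
#'   `warnings`.
#' @export
score_matrix <- function(rec, spec = estimator_spec(), mask = NULL) {
  x <- differentiate(rec)
  g <- population_average(rec)[-1L]  # align g to sample timestamps
  if (is.null(mask)) mask <- conditioning_mask(g, spec$cond_low, spec$cond_high)
  if (length(mask) != nrow(x))
    stop_structural("mask length does not match the differentiated samples")
  warn <- character(0)

  scores <- switch(spec$method,
    te = {
      D <- discretize_by_neuron(x, spec$bins, mask)
      codes <- encode_codes(D, spec$bins, spec$order, spec$same_bin)
      valid <- valid_tuples(mask, spec$order)
      n_states <- codes$n_tp * codes$n_sp
      if (length(valid) < 10 * n_states)
        warn <- c(warn, sprintf("only %d retained tuples for %d joint states",
                                length(valid), n_states))
      gte_matrix_cpp(codes$tp, codes$sp, valid - 1L, spec$bins,
                     codes$n_tp, codes$n_sp)
    },
    mi = mi_matrix(x, spec, mask),
    xc = xc_matrix(x, spec, mask),
    gc = gc_matrix(x, spec, mask))

  n_used <- if (spec$method %in% c("te", "gc"))
    length(valid_tuples(mask, spec$order)) else sum(mask)
  structure(list(scores = scores, spec = spec, n_samples = n_used,
                 warnings = warn),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s, %d neurons, %d retained samples\n",
              toupper(x$spec$method), ncol(x$scores), x$n_samples))
  invisible(x)
}

discretize_by_neuron <- function(x, b, mask) {
  D <- matrix(0L, nrow(x), ncol(x))
  for (i in seq_len(ncol(x)))
    D[, i] <- discretize(x[, i], b, ref = x[mask, i])
  D
}

#' Pairwise scores
#'
#' Single-pair counterparts of [score_matrix()], mainly useful for
#' testing and for scoring hand-picked links: `gte_score()` is the
#' plug-in generalized transfer entropy from a source onto a target
#' series (bits), `mi_score()` the zero-lag mutual information (bits),
#' `xc_score()` the largest cross-correlogram peak over lags within
#' `spec$xc_lag` frames, and `gc_score()` the log-ratio of residual
#' variances of the univariate versus bivariate autoregressions.
#'
#' @param x_target,x_source numeric vectors: differentiated traces of
#'   the (putative) postsynaptic and presynaptic neuron.
#' @param spec an `estimator_spec`.
#' @param mask logical vector marking retained samples (default: all).
#' @return a single numeric score.
#' @export
gte_score <- function(x_target, x_source, spec = estimator_spec(),
                      mask = NULL) {
  pair_score(x_target, x_source, spec, mask, method = "te")
}

#' @rdname gte_score
#' @export
mi_score <- function(x_target, x_source, spec = estimator_spec(method = "mi"),
                     mask = NULL) {
  pair_score(x_target, x_source, spec, mask, method = "mi")
}

#' @rdname gte_score
#' @export
xc_score <- function(x_target, x_source, spec = estimator_spec(method = "xc"),
                     mask = NULL) {
  pair_score(x_target, x_source, spec, mask, method = "xc")
}

#' @rdname gte_score
#' @export
gc_score <- function(x_target, x_source, spec = estimator_spec(method = "gc"),
                     mask = NULL) {
  pair_score(x_target, x_source, spec, mask, method = "gc")
}

pair_score <- function(x_target, x_source, spec, mask, method) {
  x <- cbind(as.numeric(x_target), as.numeric(x_source))
  if (is.null(mask)) mask <- rep(TRUE, nrow(x))
  spec$method <- method
  sm <- score_matrix(fake_recording(x), spec, mask = mask)
  sm$scores[2L, 1L]
}

# wrap an already-differentiated matrix so score_matrix() can consume it:
# prepend a zero row that differencing removes again
fake_recording <- function(x) {
  fluorescence_recording(apply(rbind(0, x), 2, cumsum), frame_dt = 1,
                         provenance = "simulated")
}

mi_matrix <- function(x, spec, mask) {
  D <- discretize_by_neuron(x, spec$bins, mask)[mask, , drop = FALSE]
  n <- nrow(D)
  N <- ncol(D)
  b <- spec$bins
  ind <- lapply(0:(b - 1L), function(a) (D == a) * 1)
  joint <- vector("list", b * b)
  marg <- vapply(ind, colSums, numeric(N))  # N x b counts
  mi <- matrix(0, N, N)
  for (a in 0:(b - 1L)) for (v in 0:(b - 1L)) {
    cnt <- crossprod(ind[[a + 1L]], ind[[v + 1L]])  # joint counts, all pairs
    pa <- matrix(marg[, a + 1L], N, N)              # margins of neuron i (rows)
    pv <- matrix(marg[, v + 1L], N, N, byrow = TRUE)
    term <- cnt / n * log2((cnt * n) / (pa * pv))
    term[cnt == 0] <- 0
    mi <- mi + term
  }
  diag(mi) <- NA_real_
  mi
}

xc_matrix <- function(x, spec, mask) {
  N <- ncol(x)
  idx <- which(mask)
  best <- matrix(-Inf, N, N)
  for (lag in -spec$xc_lag:spec$xc_lag) {
    src_idx <- idx - lag
    ok <- src_idx >= 1L & src_idx <= nrow(x)
    ct <- suppressWarnings(
      stats::cor(x[idx[ok], , drop = FALSE], x[src_idx[ok], , drop = FALSE]))
    ct[is.na(ct)] <- -Inf
    best <- pmax(best, t(ct))  # best[j, i]: source j at lag, target i
  }
  diag(best) <- NA_real_
  best
}

gc_matrix <- function(x, spec, mask) {
  N <- ncol(x)
  gc <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    gc[j, i] <- gc_pair(x[, i], x[, j], spec$order, spec$same_bin, mask)
  }
  gc
}

# univariate vs bivariate least-squares AR fit; GC = log(rss_uni/rss_biv)
gc_pair <- function(xt, xs, p, same_bin, mask) {
  T_n <- length(xt)
  rows <- valid_tuples(mask, p)
  y <- xt[rows]
  lag_cols <- function(v, lags) vapply(lags, function(l) v[rows - l], numeric(length(rows)))
  Xu <- cbind(1, lag_cols(xt, seq_len(p)))
  src_lags <- if (same_bin) 0:p else seq_len(p)
  Xb <- cbind(Xu, lag_cols(xs, src_lags))
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  log(rss(Xu) / rss(Xb))
}

#' Threshold ranked scores into a reconstructed network
#'
#' Ranks all off-diagonal scores, rescales ranks to the unit interval and
#' retains exactly `round(fraction * N * (N - 1))` top links.  Ties are
#' broken deterministically by (source, target) lexical order.
#'
#' @param scores a `score_matrix` (or bare numeric matrix).
#' @param fraction fraction of all possible directed links to keep, in
#'   (0, 1\]; 0.10 is the convention for simulated networks, 0.05 for
#'   biological recordings.
#' @param positions optional positions forwarded to the result.
#' @return a `directed_network` of the retained links; `meta$rescaled`
#'   holds the rank-rescaled score matrix in \[0, 1\].
#' @export
rank_and_threshold <- function(scores, fraction = 0.10, positions = NULL) {
  s <- if (inherits(scores, "score_matrix")) scores$scores else scores
  if (fraction <= 0 || fraction > 1)
    stop_structural("fraction must lie in (0, 1]")
  N <- nrow(s)
  off <- which(row(s) != col(s))
  src <- row(s)[off]
  tgt <- col(s)[off]
  o <- order(-s[off], src, tgt)
  keep_n <- round(fraction * N * (N - 1))
  A <- matrix(FALSE, N, N)
  A[off[o[seq_len(keep_n)]]] <- TRUE
  rescaled <- matrix(NA_real_, N, N)
  rescaled[off] <- (rank(s[off], ties.method = "average") - 1) / (length(off) - 1)
  directed_network(A, positions,
                   meta = list(ensemble = "reconstructed", fraction = fraction,
                               rescaled = rescaled))
}
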