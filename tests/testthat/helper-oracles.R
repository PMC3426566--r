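# Independent reference implementations used as oracles.  These are
# deliberately written in the most transparent (brute-force) style and
# share no code with the package internals.

# Fagiolo full clustering by exhaustive directed-triangle enumeration
bf_clustering <- function(A) {
  A <- (A * 1) + 0
  n <- nrow(A)
  W <- A + t(A)
  sapply(seq_len(n), function(i) {
    tri <- 0
    for (j in seq_len(n)) for (k in seq_len(n))
      tri <- tri + W[i, j] * W[j, k] * W[k, i]
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbid <- sum(A[i, ] * A[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbid)
    if (den > 0) tri / den else 0
  })
}

# plain transfer entropy (no same-bin, no conditioning) from symbol
# streams, looping over observed history tuples
bf_transfer_entropy <- function(x, y, k, b) {
  n <- length(x)
  rows <- (k + 1):n
  key <- function(v) paste(v, collapse = ",")
  joint <- new.env(); ctp <- new.env(); cft <- new.env(); cts <- new.env()
  bump <- function(env, kk) assign(kk, (if (is.null(env[[kk]])) 0 else env[[kk]]) + 1, env)
  for (t in rows) {
    xp <- x[(t - 1):(t - k)]
    yp <- y[(t - 1):(t - k)]
    bump(joint, key(c(x[t], xp, yp)))
    bump(ctp, key(xp))
    bump(cft, key(c(x[t], xp)))
    bump(cts, key(c(xp, yp)))
  }
  nn <- length(rows)
  te <- 0
  for (kk in ls(joint)) {
    parts <- as.integer(strsplit(kk, ",")[[1]])
    xp <- parts[2:(k + 1)]
    yp <- parts[(k + 2):(2 * k + 1)]
    c1 <- joint[[kk]]
    te <- te + c1 / nn * log2((c1 * ctp[[key(xp)]]) /
                              (cts[[key(c(xp, yp))]] * cft[[key(parts[1:(k + 1)])]]))
  }
  te
}

# analytic TE over an explicitly enumerated joint distribution
# p(future, target_past, source_past); inputs are named vectors keyed by
# "fut|tgt|src" strings
te_from_joint <- function(p) {
  keys <- do.call(rbind, strsplit(names(p), "|", fixed = TRUE))
  marg <- function(cols) tapply(p, apply(keys[, cols, drop = FALSE], 1,
                                         paste, collapse = "|"), sum)
  ctp <- marg(2); cft <- marg(1:2); cts <- marg(2:3)
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] == 0) next
    s <- s + p[i] * log2(p[i] * ctp[[keys[i, 2]]] /
                         (cts[[paste(keys[i, 2:3], collapse = "|")]] *
                          cft[[paste(keys[i, 1:2], collapse = "|")]]))
  }
  unname(s)
}

# mutual information of a 2x2 joint count table, direct formula
bf_mi_2x2 <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in 1:2) for (j in 1:2)
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  s
}

# brute-force best cross-correlogram peak over lags
bf_xc_peak <- function(a, b, max_lag) {
  best <- -Inf
  for (l in -max_lag:max_lag) {
    if (l >= 0) {
      v <- suppressWarnings(cor(a[seq_len(length(a) - l)], b[(1 + l):length(b)]))
    } else {
      v <- suppressWarnings(cor(a[(1 - l):length(a)], b[seq_len(length(b) + l)]))
    }
    if (!is.na(v) && v > best) best <- v
  }
  best
}

# small deterministic spike record builder
make_spikes <- function(times_list, duration) {
  spike_record(lapply(times_list, as.numeric), duration)
}

# random directed network helper
rand_net <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n) < p, n, n)
  diag(A) <- FALSE
  directed_network(A, positions = cbind(runif(n, 0, 0.5), runif(n, 0, 0.5)))
}

pair_fun <- function(method) {
  switch(method, te = gte_score, mi = mi_score, xc = xc_score, gc = gc_score)
}
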