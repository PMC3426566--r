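test_that("differentiation and population average are exact", {
  f <- matrix(c(1, 2, 4, 7, 0, 0, 0, 0), 4, 2)
  rec <- fluorescence_recording(f, 0.02)
  expect_equal(differentiate(rec), diff(f))
  expect_equal(differentiate(fluorescence_recording(matrix(5, 10, 2), 1)),
               matrix(0, 9, 2))
  # linear ramp gives a constant difference
  ramp <- fluorescence_recording(matrix(seq(0, 1, length.out = 11), 11, 1), 1)
  expect_equal(unique(round(differentiate(ramp), 12)), matrix(0.1, 1, 1))
  expect_equal(population_average(rec), rowMeans(f))
  # identical columns: average equals any column
  same <- fluorescence_recording(cbind(1:5, 1:5), 1)
  expect_equal(population_average(same), as.numeric(1:5))
})

test_that("conditioning masks select half-open intervals that partition", {
  g <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(conditioning_mask(g, -Inf, 0.35), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(conditioning_mask(g, -Inf, Inf)))
  # seven equal-width ranges partition every sample exactly once
  set.seed(2)
  g2 <- runif(5000)
  edges <- seq(min(g2), max(g2), length.out = 8)
  counts <- vapply(1:7, function(r) {
    hi <- if (r < 7) edges[r + 1] else Inf
    sum(conditioning_mask(g2, edges[r], hi))
  }, numeric(1))
  expect_identical(sum(counts), 5000)
})

test_that("automatic conditioning level finds the left-peak Gaussian", {
  set.seed(5)
  g <- rnorm(20000, 0.1, 0.02)
  lvl <- select_conditioning_level(g)
  expect_equal(lvl, 0.1 + 2 * 0.02, tolerance = 0.04)
  # two-component mixture: Gaussian body plus uniform high tail
  g2 <- c(rnorm(18000, 0.1, 0.02), runif(2000, 0.2, 1))
  expect_equal(select_conditioning_level(g2), 0.14, tolerance = 0.02)
  # a peakless monotone distribution has no fittable left peak
  expect_error(select_conditioning_level(seq(1, 2, length.out = 1000)),
               class = "gtenet_structural_error")
  # range method: upper edge of the second of seven equal-width ranges
  g3 <- c(0, rep(0.1, 10), 7)
  expect_equal(select_conditioning_level(g3, method = "range"), 2)
})

test_that("equal-width discretization covers the documented cases", {
  expect_identical(discretize(rep(1.5, 10), 3), integer(10))
  expect_identical(discretize(c(0, 0.5, 1), 2), c(0L, 1L, 1L))
  expect_identical(discretize(c(0, 0.32, 0.34, 0.65, 0.67, 1), 3),
                   c(0L, 0L, 1L, 1L, 2L, 2L))
  # reference range from a subset; out-of-range values clamp to end bins
  expect_identical(discretize(c(-5, 0.5, 5), 3, ref = c(0, 1)),
                   c(0L, 1L, 2L))
})

test_that("plug-in TE recovers the analytic value of a driven binary chain", {
  # y[n+1] = x[n], x iid fair coin; enumerate the stationary joint
  # distribution of (y_future, y_past, x_past) for k = 1
  p <- c()
  for (xp in 0:1) for (yp in 0:1) for (fut in 0:1) {
    pr <- 0.25 * (fut == xp)  # y_future determined by x_past
    p[sprintf("%d|%d|%d", fut, yp, xp)] <- pr
  }
  expect_equal(te_from_joint(p), 1)  # exactly one bit
  set.seed(11)
  n <- 1e5
  x <- rbinom(n, 1, 0.5)
  y <- c(0, x[-n])
  spec <- estimator_spec(order = 1, same_bin = FALSE, bins = 2)
  te <- gte_score(y, x, spec)
  expect_equal(te, 1, tolerance = 0.02)
  # reverse direction carries no information
  expect_lt(gte_score(x, y, spec), 0.01)
})

test_that("same-bin coupling is invisible to conventional TE but not to GTE", {
  set.seed(12)
  x <- rbinom(5e4, 1, 0.5)
  y <- x  # zero-lag coupling
  conventional <- gte_score(y, x, estimator_spec(order = 1, same_bin = FALSE,
                                                 bins = 2))
  generalized <- gte_score(y, x, estimator_spec(order = 1, same_bin = TRUE,
                                                bins = 2))
  expect_lt(conventional, 0.01)
  expect_gt(generalized, 0.5)
})

test_that("TE of independent streams stays below shuffled surrogates", {
  set.seed(13)
  n <- 2e4
  x <- sample(0:2, n, replace = TRUE)
  y <- sample(0:2, n, replace = TRUE)
  spec <- estimator_spec(order = 1, same_bin = FALSE, bins = 3)
  te <- gte_score(y, x, spec)
  surro <- vapply(1:100, function(i) {
    gte_score(y, sample(x), spec)
  }, numeric(1))
  expect_lt(te, quantile(surro, 0.95) * 1.5 + 1e-4)
  expect_lt(te, 0.005)
})

test_that("generalized TE without extensions reduces to standard TE", {
  set.seed(14)
  x <- sample(0:2, 3000, replace = TRUE)
  y <- head(c(0, x), 3000) + sample(0:1, 3000, replace = TRUE)
  y <- pmin(y, 2L)
  for (k in 1:2) {
    spec <- estimator_spec(order = k, same_bin = FALSE, bins = 3)
    expect_equal(gte_score(y, x, spec), bf_transfer_entropy(y, x, k, 3),
                 tolerance = 1e-12)
  }
})

test_that("TE and MI are invariant under monotone relabeling of symbols", {
  set.seed(15)
  x <- rnorm(5000)
  y <- c(0, head(x, -1)) + rnorm(5000, 0, 0.5)
  s_te <- estimator_spec(order = 1, bins = 3)
  s_mi <- estimator_spec(method = "mi", bins = 3)
  # positive affine maps leave the equal-width symbol partition intact
  expect_equal(gte_score(y, x, s_te), gte_score(3 * y + 1, 3 * x + 1, s_te),
               tolerance = 1e-12)
  expect_equal(mi_score(y, x, s_mi), mi_score(3 * y + 1, 3 * x + 1, s_mi),
               tolerance = 1e-12)
  # monotone relabeling of the discrete symbols themselves
  xs <- sample(0:2, 5000, replace = TRUE)
  ys <- pmin(2L, xs + sample(0:1, 5000, replace = TRUE))
  relab <- function(v) c(0, 10, 25)[v + 1L]  # lands in the same 3 bins
  expect_equal(gte_score(ys, xs, s_te), gte_score(relab(ys), relab(xs), s_te),
               tolerance = 1e-12)
  expect_equal(mi_score(ys, xs, s_mi), mi_score(relab(ys), relab(xs), s_mi),
               tolerance = 1e-12)
})

test_that("plug-in TE converges to the enumerated truth at root-n rate", {
  # noisy binary chain: y[n+1] = x[n] xor noise(q); analytic TE by
  # enumeration of the joint distribution
  q <- 0.2
  p <- c()
  for (xp in 0:1) for (yp in 0:1) for (fut in 0:1) {
    pr <- 0.25 * (if (fut == xp) 1 - q else q)
    p[sprintf("%d|%d|%d", fut, yp, xp)] <- pr
  }
  truth <- te_from_joint(p)
  spec <- estimator_spec(order = 1, same_bin = FALSE, bins = 2)
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    e <- vapply(1:5, function(s) {
      set.seed(100 + s + n)
      x <- rbinom(n, 1, 0.5)
      noise <- rbinom(n, 1, q)
      y <- c(0, xor(x[-n], noise[-n]) * 1L)
      abs(gte_score(y, x, spec) - truth)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  # error shrinks, and at a rate consistent with 1/sqrt(n): one decade of
  # n buys about sqrt(10) of accuracy
  expect_true(all(diff(err) < 0))
  rate <- log10(err[1] / err[3]) / 2
  expect_gt(rate, 0.3)
})

test_that("MI matches closed-form values on known joints", {
  # identical streams: MI equals the entropy of the stream
  set.seed(16)
  x <- sample(0:2, 4000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  spec <- estimator_spec(method = "mi", bins = 3)
  tab <- tabulate(x + 1L, 3) / 4000
  expect_equal(mi_score(x, x, spec), -sum(tab * log2(tab)), tolerance = 1e-12)
  # independent streams
  y <- sample(0:2, 4000, replace = TRUE)
  expect_lt(mi_score(x, y, spec), 0.01)
  # crafted 2x2 joint against hand computation
  xy <- rbind(c(30, 10), c(5, 55))
  xs <- rep(c(0, 0, 1, 1), as.numeric(t(xy)))
  ys <- rep(c(0, 1, 0, 1), as.numeric(t(xy)))
  expect_equal(mi_score(xs, ys, estimator_spec(method = "mi", bins = 2)),
               bf_mi_2x2(xy), tolerance = 1e-12)
  # symmetry
  expect_equal(mi_score(xs, ys), mi_score(ys, xs), tolerance = 1e-12)
})

test_that("cross-correlation scores find the best lag", {
  set.seed(17)
  x <- rnorm(2000)
  spec <- estimator_spec(method = "xc", xc_lag = 2)
  expect_equal(xc_score(x, x, spec), 1, tolerance = 1e-12)
  # a one-frame shift is recovered within the lag range
  y <- c(0, head(x, -1))
  expect_equal(xc_score(y, x, spec), 1, tolerance = 1e-6)
  # AR(1) pair against the brute-force correlogram oracle
  z <- as.numeric(arima.sim(list(ar = 0.6), 2000))
  w <- 0.5 * c(0, head(z, -1)) + rnorm(2000, 0, 0.4)
  expect_equal(xc_score(w, z, spec), bf_xc_peak(w, z, 2), tolerance = 1e-10)
})

test_that("Granger scores match an independent regression oracle", {
  set.seed(18)
  n <- 5000
  x <- rnorm(n)
  y <- 0.8 * c(0, head(x, -1)) + rnorm(n)
  spec <- estimator_spec(method = "gc", order = 1, same_bin = FALSE)
  got <- gc_score(y, x, spec)
  # oracle: two lm fits and the log residual-variance ratio
  yt <- y[2:n]; yl <- y[1:(n - 1)]; xl <- x[1:(n - 1)]
  rss_u <- sum(resid(lm(yt ~ yl))^2)
  rss_b <- sum(resid(lm(yt ~ yl + xl))^2)
  expect_equal(got, log(rss_u / rss_b), tolerance = 1e-10)
  expect_gt(got, 0.3)
  # independent white noise: no causality
  expect_lt(gc_score(x, rnorm(n), spec), 0.005)
  # fitting order 2 on an order-1 process changes nothing material
  got2 <- gc_score(y, x, estimator_spec(method = "gc", order = 2,
                                        same_bin = FALSE))
  expect_equal(got2, got, tolerance = 0.01)
})

test_that("score matrices agree with per-pair calls and are deterministic", {
  set.seed(19)
  f <- matrix(cumsum(rnorm(300)), 100, 3)
  f <- f + matrix(rnorm(300, 0, 0.1), 100, 3)
  rec <- fluorescence_recording(f, 0.02)
  x <- differentiate(rec)
  for (m in c("te", "mi", "xc", "gc")) {
    spec <- estimator_spec(method = m, order = 1, bins = 2)
    sm <- score_matrix(rec, spec)
    expect_true(all(is.na(diag(sm$scores))))
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      got <- sm$scores[j, i]
      single <- pair_fun(m)(x[, i], x[, j], spec)
      expect_equal(got, single, tolerance = 1e-10)
    }
  }
  # determinism: identical runs give identical matrices
  s1 <- score_matrix(rec, estimator_spec(order = 2))
  s2 <- score_matrix(rec, estimator_spec(order = 2))
  expect_identical(s1$scores, s2$scores)
})

test_that("permuting neurons permutes scores consistently", {
  set.seed(20)
  f <- matrix(rnorm(400), 100, 4)
  rec <- fluorescence_recording(f, 0.02)
  perm <- c(3, 1, 4, 2)
  rec_p <- fluorescence_recording(f[, perm], 0.02)
  s <- score_matrix(rec, estimator_spec(order = 1))$scores
  s_p <- score_matrix(rec_p, estimator_spec(order = 1))$scores
  expect_equal(s_p, s[perm, perm], tolerance = 1e-12)
})

test_that("conditioning above the signal maximum is a no-op", {
  set.seed(21)
  f <- matrix(rnorm(600, 10), 200, 3)
  rec <- fluorescence_recording(f, 0.02)
  for (m in c("te", "mi", "xc", "gc")) {
    a <- score_matrix(rec, estimator_spec(method = m, order = 1, bins = 2))
    b <- score_matrix(rec, estimator_spec(method = m, order = 1, bins = 2,
                                          cond_high = 1e9))
    expect_equal(a$scores, b$scores, tolerance = 1e-12)
  }
})

test_that("thresholding retains the exact link budget with stable ties", {
  set.seed(22)
  s <- matrix(runif(100), 10, 10)
  diag(s) <- NA
  net <- rank_and_threshold(s, 0.1)
  expect_identical(sum(net$adjacency), as.integer(round(0.1 * 90)))
  expect_false(any(diag(net$adjacency)))
  # fraction 1 keeps the complete off-diagonal graph
  expect_identical(sum(rank_and_threshold(s, 1)$adjacency), 90L)
  # all-tied scores resolve by (source, target) lexical order
  tie <- matrix(1, 5, 5)
  diag(tie) <- NA
  nt <- rank_and_threshold(tie, 0.1)  # keeps round(0.1 * 20) = 2 links
  expect_identical(which(nt$adjacency), c(6L, 11L))  # links 1->2 and 1->3
  expect_error(rank_and_threshold(s, 0), class = "gtenet_structural_error")
  # 10% of a 100-node matrix is 990 links
  big <- matrix(runif(1e4), 100, 100)
  expect_identical(sum(rank_and_threshold(big, 0.1)$adjacency), 990L)
})
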