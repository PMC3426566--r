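#' Directed network with spatial positions
#'
#' Container for a ground-truth (or reconstructed) directed graph over
#' neurons placed in a square culture area.  The adjacency matrix is
#' boolean with `adjacency[i, j] = TRUE` meaning a directed link from
#' neuron `i` (source) to neuron `j` (target); the diagonal is always
#' empty (autaptic links are excluded).
#'
#' @param adjacency square logical (or 0/1) matrix, rows = sources.
#' @param positions N x 2 numeric matrix of coordinates in mm, or `NULL`.
#' @param meta named list of generation metadata (ensemble tag, target
#'   clustering or length scale, connection probability, seed, ...).
#' @return An object of class `directed_network` with elements
#'   `adjacency`, `positions`, `meta`; `meta$n_links` always records the
#'   realized link count.
#' @export
directed_network <- function(adjacency, positions = NULL, meta = list()) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop_structural("adjacency matrix must be square, got %d x %d",
                    nrow(adjacency), ncol(adjacency))
  mode(adjacency) <- "logical"
  if (any(is.na(adjacency)))
    stop_structural("adjacency matrix contains missing values")
  if (any(diag(adjacency)))
    stop_structural("adjacency matrix must not contain diagonal entries")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(adjacency) || ncol(positions) != 2L)
      stop_structural("positions must be an N x 2 matrix matching the adjacency")
  }
  meta$n_links <- sum(adjacency)
  structure(list(adjacency = adjacency, positions = positions, meta = meta),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("<directed_network> %d nodes, %d links (p = %.3f)%s\n",
              n, x$meta$n_links, x$meta$n_links / (n * (n - 1)),
              if (!is.null(x$meta$ensemble)) paste0(", ensemble: ", x$meta$ensemble) else ""))
  invisible(x)
}

n_nodes <- function(net) nrow(net$adjacency)

stop_structural <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("gtenet_structural_error", "error", "condition")))
}

#' Full (directed) clustering coefficient
#'
#' Per-node clustering for directed graphs counting all directed triangle
#' types through a node:
#' \deqn{C_i = \frac{[(A + A^T)^3]_{ii}}{2\,[d^{tot}_i (d^{tot}_i - 1) - 2 d^{bid}_i]}}
#' where \eqn{d^{tot}} is the total (in + out) degree and \eqn{d^{bid}}
#' the number of reciprocated links of the node.  Nodes with a zero
#' denominator (degree 0 or 1, or all links reciprocated in a 2-clique)
#' return 0 by convention.
#'
#' @param net a `directed_network` or a square adjacency matrix.
#' @return numeric vector of per-node clustering values in \[0, 1\].
#' @export
full_clustering <- function(net) {
  A <- if (inherits(net, "directed_network")) net$adjacency else as.matrix(net)
  if (nrow(A) != ncol(A))
    stop_structural("adjacency matrix must be square, got %d x %d",
                    nrow(A), ncol(A))
  storage.mode(A) <- "double"
  W <- A + t(A)
  tri <- rowSums((W %*% W) * W)     # diag(W^3), W symmetric
  dtot <- rowSums(A) + colSums(A)
  dbid <- rowSums(A * t(A))
  den <- 2 * (dtot * (dtot - 1) - 2 * dbid)
  ifelse(den > 0, tri / den, 0)
}

#' Per-node and per-link graph statistics
#'
#' @param net a `directed_network`.
#' @return list with a per-node data frame (`clustering`, `in_degree`,
#'   `out_degree`, `tot_degree`, `bidir`), the per-link Euclidean
#'   distances (mm, `NULL` without positions) and the ensemble means.
#' @export
graph_stats <- function(net) {
  A <- net$adjacency
  nodes <- data.frame(
    clustering = full_clustering(net),
    in_degree = colSums(A),
    out_degree = rowSums(A),
    bidir = rowSums(A & t(A)))
  nodes$tot_degree <- nodes$in_degree + nodes$out_degree
  dists <- if (is.null(net$positions)) NULL else connection_distances(net)
  list(nodes = nodes,
       distances = dists,
       means = c(clustering = mean(nodes$clustering),
                 in_degree = mean(nodes$in_degree),
                 distance = if (is.null(dists)) NA_real_ else mean(dists)))
}

#' Euclidean length of every link
#'
#' @param net a `directed_network` with positions.
#' @return numeric vector, one distance (mm) per `TRUE` adjacency entry,
#'   in column-major link order.
#' @export
connection_distances <- function(net) {
  if (is.null(net$positions))
    stop_structural("network has no positions; distances are undefined")
  idx <- which(net$adjacency, arr.ind = TRUE)
  p <- net$positions
  sqrt(rowSums((p[idx[, 1], , drop = FALSE] - p[idx[, 2], , drop = FALSE])^2))
}

pairwise_distances <- function(positions) {
  as.matrix(stats::dist(positions))
}

er_adjacency <- function(n, p) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  diag(A) <- FALSE
  A
}

#' Generate a non-locally clustered network
#'
#' Draws an Erdos-Renyi directed graph and then applies degree-preserving
#' "crossing" moves (two links `a->b`, `c->d` become `a->d`, `c->b`),
#' accepting only moves that bring the mean full clustering coefficient
#' closer to `target_cc`.  Every node's in- and out-degree is left exactly
#' as in the initial draw.  Node positions are uniform in the culture
#' square; the ensemble is spatially random by construction.
#'
#' @param n number of neurons.
#' @param p connection probability of the initial random draw.
#' @param target_cc desired mean full clustering coefficient; the result
#'   is within 0.1\% (relative) of this value or an error is raised.
#' @param seed integer RNG seed.
#' @param area_side culture side length in mm.
#' @param tol relative convergence tolerance on the mean clustering.
#' @param max_iter hard cap on candidate crossing moves.
#' @param max_stall stop after this many candidates without improvement.
#' @return a `directed_network`; `meta` records the achieved clustering
#'   and the number of accepted moves.
#' @export
generate_nonlocal <- function(n = 100, p = 0.12, target_cc = 0.5, seed = 1,
                              area_side = 0.5, tol = 1e-3,
                              max_iter = 1e7, max_stall = 2e5) {
  stopifnot(p > 0, p < 1, n > 2)
  set.seed(seed)
  A <- er_adjacency(n, p)
  res <- rewire_cc_cpp(A * 1L, target_cc, tol * target_cc,
                       max_iter, max_stall, seed)
  if (!res$converged)
    stop(errorCondition(
      sprintf("clustering target %.3f not reached (best %.4f after %.0f moves)",
              target_cc, res$cc, res$iterations),
      class = c("gtenet_convergence_error", "error", "condition"),
      cc = res$cc))
  positions <- cbind(stats::runif(n, 0, area_side), stats::runif(n, 0, area_side))
  directed_network(res$adjacency, positions,
                   meta = list(ensemble = "nonlocal", target_cc = target_cc,
                               achieved_cc = res$cc, p = p, seed = seed,
                               area_side = area_side,
                               accepted_moves = res$accepted))
}

#' Generate a locally clustered network
#'
#' Connects neurons with a Gaussian distance-dependent probability
#' `exp(-d^2 / lambda^2)` (non-periodic boundaries).  The kernel is
#' rescaled in a second pass so that the expected link count matches
#' `p * n * (n - 1)`: a first network is drawn from the unscaled kernel,
#' its realized link count fixes the rescaling prefactor, and the final
#' network is drawn from the rescaled kernel.  Probabilities pushed above
#' 1 by the rescaling are clamped with a warning.
#'
#' @inheritParams generate_nonlocal
#' @param lambda_mm characteristic length scale of the kernel in mm.
#' @return a `directed_network` from the local ensemble.
#' @export
generate_local <- function(n = 100, p = 0.12, lambda_mm = 0.5, seed = 1,
                           area_side = 0.5) {
  stopifnot(lambda_mm > 0, p > 0, p < 1)
  set.seed(seed)
  positions <- cbind(stats::runif(n, 0, area_side), stats::runif(n, 0, area_side))
  kernel <- exp(-pairwise_distances(positions)^2 / lambda_mm^2)
  diag(kernel) <- 0
  first <- matrix(stats::runif(n * n), n, n) < kernel
  diag(first) <- FALSE
  scale <- (p * n * (n - 1)) / sum(first)
  prob <- scale * kernel
  if (any(prob > 1)) {
    warning(sprintf("rescaled connection kernel clamped at 1 for %d pairs",
                    sum(prob > 1)))
    prob <- pmin(prob, 1)
  }
  A <- matrix(stats::runif(n * n), n, n) < prob
  diag(A) <- FALSE
  directed_network(A, positions,
                   meta = list(ensemble = "local", lambda_mm = lambda_mm,
                               p = p, seed = seed, area_side = area_side,
                               rescale_factor = scale))
}

#' Full randomization of a network
#'
#' Redraws all links uniformly over the off-diagonal slots, preserving
#' only the total link count.  Serves as the Erdos-Renyi null for
#' reconstructed topologies.
#'
#' @param net a `directed_network`.
#' @param seed integer RNG seed.
#' @return a randomized `directed_network` (positions carried over).
#' @export
randomize_full <- function(net, seed = 1) {
  set.seed(seed)
  n <- n_nodes(net)
  m <- sum(net$adjacency)
  slots <- which(row(net$adjacency) != col(net$adjacency))
  A <- matrix(FALSE, n, n)
  A[sample(slots, m)] <- TRUE
  directed_network(A, net$positions,
                   meta = list(ensemble = "randomized_full", seed = seed))
}

#' Partial (out-degree preserving) randomization
#'
#' Shuffles the target entries of each row of the adjacency matrix
#' internally, so every node keeps its exact out-degree while all other
#' structure (clustering, in/out degree correlations) is destroyed.
#' Diagonal entries remain disallowed.
#'
#' @inheritParams randomize_full
#' @return a randomized `directed_network`.
#' @export
randomize_partial <- function(net, seed = 1) {
  set.seed(seed)
  n <- n_nodes(net)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cols <- setdiff(seq_len(n), i)
    k <- sum(net$adjacency[i, ])
    if (k > 0) A[i, sample(cols, k)] <- TRUE
  }
  directed_network(A, net$positions,
                   meta = list(ensemble = "randomized_partial", seed = seed))
}

#' Write / read a network as plain text
#'
#' `write_network()` stores the dense 0/1 adjacency matrix (tab-delimited)
#' and, when positions are present, a 3-column `id / x_mm / y_mm` table at
#' `paste0(file, ".pos")`.  `write_edge_list()` stores a 2-column
#' `source / target` table with 0-based identifiers.  The readers invert
#' the formats losslessly.
#'
#' @param net a `directed_network`.
#' @param file output path for the adjacency matrix.
#' @return `read_network()` returns a `directed_network`; the writers
#'   return `file` invisibly.
#' @export
write_network <- function(net, file) {
  utils::write.table(net$adjacency * 1L, file, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(net$positions)) {
    pos <- data.frame(id = seq_len(n_nodes(net)) - 1L,
                      x_mm = net$positions[, 1], y_mm = net$positions[, 2])
    utils::write.table(pos, paste0(file, ".pos"), sep = "\t",
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  A <- as.matrix(utils::read.table(file, sep = "\t"))
  dimnames(A) <- NULL
  pos_file <- paste0(file, ".pos")
  positions <- NULL
  if (file.exists(pos_file)) {
    pos <- utils::read.table(pos_file, sep = "\t", header = TRUE)
    positions <- as.matrix(pos[order(pos$id), c("x_mm", "y_mm")])
    dimnames(positions) <- NULL
  }
  directed_network(A, positions, meta = list(source_file = file))
}

#' @rdname write_network
#' @export
write_edge_list <- function(net, file) {
  idx <- which(net$adjacency, arr.ind = TRUE)
  utils::write.table(data.frame(source = idx[, 1] - 1L, target = idx[, 2] - 1L),
                     file, sep = "\t", row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' @rdname write_network
#' @param n_nodes node count for `read_edge_list()` (edge lists do not
#'   record isolated trailing nodes).
#' @export
read_edge_list <- function(file, n_nodes) {
  edges <- utils::read.table(file, sep = "\t", header = TRUE)
  A <- matrix(FALSE, n_nodes, n_nodes)
  A[cbind(edges$source + 1L, edges$target + 1L)] <- TRUE
  directed_network(A, meta = list(source_file = file))
}
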