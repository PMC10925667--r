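#' Construct and validate a weighted connectome
#'
#' A weighted connectome is a symmetric, non-negative matrix `W` whose entry
#' `W[i, j]` measures the strength of the structural connection between brain
#' regions (ROIs) `i` and `j` -- typically a streamline count scaled by ROI
#' volume. The diagonal must be zero: a region is not connected to itself.
#'
#' @param W numeric square matrix of non-negative weights with zero diagonal.
#' @param labels optional character vector of unique node identifiers, one per
#'   row of `W`; defaults to `"node_1" ... "node_N"`.
#' @param fix_diagonal if `TRUE`, a nonzero diagonal is zeroed with a warning
#'   instead of raising an error. Off by default so malformed inputs are
#'   noticed.
#' @return an object of class `weighted_connectome`: a list with elements
#'   `W` (the validated matrix) and `labels`.
#' @details Symmetry is accepted up to a relative tolerance of
#'   `1e-12 * max(W)`; the matrix is then symmetrised exactly as
#'   `(W + t(W)) / 2` so downstream code can rely on `W == t(W)`.
#' @examples
#' W <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
#' wc <- weighted_connectome(W)
#' @export
weighted_connectome <- function(W, labels = NULL, fix_diagonal = FALSE) {
  if (!is.matrix(W) || !is.numeric(W))
    stop("W must be a numeric matrix", call. = FALSE)
  n <- nrow(W)
  if (ncol(W) != n)
    stop("W must be square; got ", n, " x ", ncol(W), call. = FALSE)
  if (anyNA(W) || any(!is.finite(W)))
    stop("W contains non-finite entries", call. = FALSE)
  neg <- which(W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("W has a negative entry at (%d, %d): %g",
                 neg[1, 1], neg[1, 2], W[neg[1, 1], neg[1, 2]]),
         call. = FALSE)
  asym <- abs(W - t(W))
  tol <- 1e-12 * max(W, 1e-300)
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "W is not symmetric: |W[%d,%d] - W[%d,%d]| = %g exceeds tolerance %g",
      idx[1], idx[2], idx[2], idx[1], max(asym), tol), call. = FALSE)
  }
  W <- (W + t(W)) / 2
  dg <- which(diag(W) != 0)
  if (length(dg) > 0) {
    if (fix_diagonal) {
      warning("zeroing ", length(dg), " nonzero diagonal entries of W",
              call. = FALSE)
      diag(W) <- 0
    } else {
      stop(sprintf(
        "W has a nonzero diagonal entry at (%d, %d): %g (use fix_diagonal = TRUE to zero it)",
        dg[1], dg[1], W[dg[1], dg[1]]), call. = FALSE)
    }
  }
  if (is.null(labels)) labels <- paste0("node_", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must have one entry per node (", n, ")", call. = FALSE)
  if (anyDuplicated(labels))
    stop("labels must be unique", call. = FALSE)
  dimnames(W) <- NULL
  structure(list(W = W, labels = labels), class = "weighted_connectome")
}

#' @exportS3Method base::print
print.weighted_connectome <- function(x, ...) {
  nz <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("<weighted_connectome> %d nodes, %d nonzero weights, max weight %g\n",
              nrow(x$W), nz, max(x$W)))
  invisible(x)
}

#' Construct a binary graph from an adjacency matrix
#'
#' @param A square 0/1 matrix, symmetric with zero diagonal.
#' @param labels optional unique node labels.
#' @param threshold_used the weight threshold that produced `A`, or `NA` when
#'   the adjacency was given directly.
#' @return object of class `binary_graph`: list with adjacency `A` (numeric
#'   0/1 matrix), degree vector `k`, `threshold_used` and `labels`.
#' @export
binary_graph <- function(A, labels = NULL, threshold_used = NA_real_) {
  if (!is.matrix(A)) stop("A must be a matrix", call. = FALSE)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square", call. = FALSE)
  storage.mode(A) <- "double"
  if (!all(A %in% c(0, 1)))
    stop("A entries must be exactly 0 or 1", call. = FALSE)
  if (any(A != t(A))) stop("A must be symmetric", call. = FALSE)
  if (any(diag(A) != 0)) stop("A must have a zero diagonal", call. = FALSE)
  if (is.null(labels)) labels <- paste0("node_", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("labels must be unique with one entry per node", call. = FALSE)
  dimnames(A) <- NULL
  structure(list(A = A, k = rowSums(A), threshold_used = threshold_used,
                 labels = labels),
            class = "binary_graph")
}

#' @exportS3Method base::print
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d links, degree range [%d, %d]%s\n",
              length(x$k), sum(x$k) / 2, min(x$k), max(x$k),
              if (is.na(x$threshold_used)) ""
              else sprintf(", thresholded at S_w = %g", x$threshold_used)))
  invisible(x)
}

#' Threshold a weighted connectome into a binary graph
#'
#' Applies the edge rule `A[i, j] = 1` iff `W[i, j] >= S_w` (the boundary is
#' inclusive), with the diagonal forced to zero, and recomputes node degrees
#' `k[i] = sum_j A[i, j]`.
#'
#' @param wc a [weighted_connectome()].
#' @param s_w positive weight threshold.
#' @return a [binary_graph()] with `threshold_used = s_w`.
#' @examples
#' wc <- weighted_connectome(matrix(c(0, 0.05, 0.05, 0), 2, 2))
#' g <- threshold_adjacency(wc, 0.034)
#' g$k  # both nodes have degree 1
#' @export
threshold_adjacency <- function(wc, s_w) {
  stopifnot(inherits(wc, "weighted_connectome"))
  if (!is.numeric(s_w) || length(s_w) != 1 || !is.finite(s_w) || s_w <= 0)
    stop("s_w must be a single positive number", call. = FALSE)
  A <- (wc$W >= s_w) * 1
  diag(A) <- 0
  binary_graph(A, labels = wc$labels, threshold_used = s_w)
}

#' Graph Laplacian L = A - K
#'
#' The discrete Laplacian of the graph: the adjacency matrix minus the diagonal
#' degree matrix. With this sign convention every row sums to zero, `L` is
#' symmetric and negative semidefinite, and `theta' = w L theta` is the network
#' diffusion (heat) equation.
#'
#' @param g a [binary_graph()].
#' @return numeric N x N matrix.
#' @export
graph_laplacian <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  L <- g$A
  diag(L) <- diag(L) - g$k
  L
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$A, mode = "undirected", diag = FALSE)
}

#' Is the graph connected?
#'
#' @param g a [binary_graph()].
#' @return `TRUE` iff every node can be reached from every other node.
#' @export
graph_is_connected <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (length(g$k) <= 1) return(TRUE)
  igraph::is_connected(as_igraph(g), mode = "weak")
}

#' Summarize a binary graph
#'
#' Counts nodes and undirected links, tests connectivity, identifies the
#' most- and least-connected nodes (ties broken by lowest index, so the result
#' is deterministic), and -- on connected graphs -- computes each node's mean
#' shortest-path distance to the other `N - 1` nodes in unweighted hops.
#'
#' @param g a [binary_graph()].
#' @param paths compute per-node mean shortest paths (requires connectivity
#'   unless `paths = FALSE`).
#' @return object of class `graph_summary`: list with `n_nodes`, `n_links`,
#'   `is_connected`, `max_degree_node` / `min_degree_node` (each a list with
#'   `index`, `label`, `degree`), and `mean_shortest_path_from` (numeric vector
#'   or `NULL`).
#' @export
summarize_graph <- function(g, paths = TRUE) {
  stopifnot(inherits(g, "binary_graph"))
  n <- length(g$k)
  conn <- graph_is_connected(g)
  imax <- which.max(g$k)   # which.max/min take the first (lowest-index) tie
  imin <- which.min(g$k)
  msp <- NULL
  if (paths) {
    if (!conn)
      stop("mean shortest paths are undefined on a disconnected graph",
           call. = FALSE)
    if (n == 1) {
      msp <- NaN
    } else {
      D <- igraph::distances(as_igraph(g), algorithm = "unweighted")
      msp <- (rowSums(D)) / (n - 1)  # diagonal is 0; denominator excludes self
    }
    names(msp) <- g$labels
  }
  structure(list(
    n_nodes = n,
    n_links = sum(g$k) / 2,
    is_connected = conn,
    max_degree_node = list(index = imax, label = g$labels[imax],
                           degree = g$k[[imax]]),
    min_degree_node = list(index = imin, label = g$labels[imin],
                           degree = g$k[[imin]]),
    mean_shortest_path_from = msp
  ), class = "graph_summary")
}

#' @exportS3Method base::print
print.graph_summary <- function(x, ...) {
  cat(sprintf("<graph_summary> %d nodes, %d links, %sconnected\n",
              x$n_nodes, x$n_links, if (x$is_connected) "" else "NOT "))
  cat(sprintf("  max degree: node %d (%s), k = %d%s\n",
              x$max_degree_node$index, x$max_degree_node$label,
              x$max_degree_node$degree,
              if (!is.null(x$mean_shortest_path_from))
                sprintf(", mean path %.3f",
                        x$mean_shortest_path_from[[x$max_degree_node$index]])
              else ""))
  cat(sprintf("  min degree: node %d (%s), k = %d%s\n",
              x$min_degree_node$index, x$min_degree_node$label,
              x$min_degree_node$degree,
              if (!is.null(x$mean_shortest_path_from))
                sprintf(", mean path %.3f",
                        x$mean_shortest_path_from[[x$min_degree_node$index]])
              else ""))
  invisible(x)
}

#' Largest threshold that keeps the graph connected
#'
#' Scans a sorted set of candidate thresholds and returns the largest one for
#' which [threshold_adjacency()] still yields a connected graph. This
#' reproduces the usual rationale for picking a connectome threshold: as high
#' as possible (discarding weak, likely spurious connections) while keeping
#' every region reachable.
#'
#' @param wc a [weighted_connectome()].
#' @param candidates ascending vector of positive thresholds to try.
#' @return the largest connecting candidate (scalar).
#' @export
largest_connecting_threshold <- function(wc, candidates) {
  stopifnot(inherits(wc, "weighted_connectome"))
  if (length(candidates) == 0 || any(candidates <= 0) || is.unsorted(candidates))
    stop("candidates must be a non-empty ascending vector of positive values",
         call. = FALSE)
  for (s in rev(candidates)) {
    if (graph_is_connected(threshold_adjacency(wc, s))) return(s)
  }
  stop("no candidate threshold yields a connected graph", call. = FALSE)
}
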