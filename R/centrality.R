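#' Node score vectors
#'
#' All comparator centralities return a `node_scores` object: a named
#' numeric vector (one finite score per node) carrying a `method`
#' attribute, accepted everywhere a ranking is consumed.
#'
#' @param x named numeric vector of scores.
#' @param method character method name.
#' @return A `node_scores` object.
#' @export
node_scores <- function(x, method) {
  stopifnot(is.numeric(x), !is.null(names(x)), is.character(method))
  structure(x, method = method, class = "node_scores")
}

#' @export
print.node_scores <- function(x, ...) {
  cat(sprintf("<node_scores: %s, %d nodes>\n", attr(x, "method"), length(x)))
  print(unclass(x)[order(-x, names(x))], ...)
  invisible(x)
}

#' Read externally computed node scores
#'
#' Loads a two-column (node, score) TSV so centralities computed by other
#' tools can enter the evaluation framework as a named method.
#'
#' @param path file path; `%`/`#` comment lines are skipped.
#' @param method method name to attach.
#' @return A [node_scores()] object.
#' @export
read_node_scores <- function(path, method = basename(path)) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("node", "score"),
                         colClasses = c("character", "numeric"))
  node_scores(stats::setNames(d$score, d$node), method)
}

#' Degree centrality
#'
#' The number of distinct nodes adjacent to each node. For directed
#' networks `mode = "in"`/`"out"` give the in-/out-degree counts instead
#' of the union neighborhood size.
#'
#' @param net an [emi_network()].
#' @param mode `"all"` (default), `"in"` or `"out"`.
#' @return A [node_scores()] vector.
#' @export
degree_centrality <- function(net, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  if (mode == "all") {
    adj <- .adjacency(net)
    sc <- vapply(adj, length, integer(1L))
  } else {
    deg <- .degree_table(net)
    sc <- stats::setNames(deg[[if (mode == "in") "d_in" else "d_out"]], deg$node)
  }
  node_scores(stats::setNames(as.numeric(sc), net$nodes),
              paste0("degree", if (mode != "all") paste0("_", mode) else ""))
}

# shortest-path edge lengths: weights are affinities by default elsewhere in
# the package, but path-based centralities need lengths
.path_weights <- function(net, weight_as) {
  if (!net$weighted || nrow(net$edges) == 0) return(NULL)
  if (weight_as == "distance") net$edges$weight else 1 / net$edges$weight
}

#' Closeness centrality
#'
#' The reciprocal of a node's farness, `1 / sum(d(x, y))`, summing
#' shortest-path distances from `x` over the nodes it can reach. Nodes
#' reaching nothing score 0. On weighted networks edge weights are used as
#' path lengths by default; set `weight_as = "affinity"` to use `1/w`
#' (appropriate when large weights mean strong ties).
#'
#' @param net an [emi_network()].
#' @param weight_as `"distance"` (default) or `"affinity"`.
#' @return A [node_scores()] vector.
#' @export
closeness_centrality <- function(net, weight_as = c("distance", "affinity")) {
  weight_as <- match.arg(weight_as)
  n <- length(net$nodes)
  if (n == 0) return(node_scores(stats::setNames(numeric(0), character(0)), "closeness"))
  d <- igraph::distances(as_igraph(net), mode = "out",
                         weights = .path_weights(net, weight_as))
  sc <- apply(d, 1L, function(row) {
    row <- row[is.finite(row)]
    s <- sum(row)            # self-distance 0 included, contributes nothing
    if (s > 0) 1 / s else 0
  })
  node_scores(stats::setNames(as.numeric(sc), rownames(d))[net$nodes], "closeness")
}

#' k-shell (coreness) index
#'
#' Iteratively prunes minimum-degree nodes: a node's shell index is the
#' largest `k` such that it survives in the subgraph where every node has
#' degree at least `k`. Directed networks use the total (in + out) degree.
#'
#' @param net an [emi_network()].
#' @return A [node_scores()] vector of integer shell indices.
#' @export
k_shell <- function(net) {
  if (length(net$nodes) == 0)
    return(node_scores(stats::setNames(numeric(0), character(0)), "k_shell"))
  ks <- igraph::coreness(as_igraph(net), mode = "all")
  node_scores(stats::setNames(as.numeric(ks[net$nodes]), net$nodes), "k_shell")
}

#' Betweenness centrality
#'
#' The fraction of shortest paths between every other pair of nodes that
#' pass through each node, `sum over s != v != t of sigma_st(v) / sigma_st`.
#' Normalisation divides by the number of ordered pairs excluding `v`:
#' `(n-1)(n-2)` for directed and `(n-1)(n-2)/2` for undirected networks.
#' Weighted networks use edge weights as path lengths (see
#' [closeness_centrality()] for the affinity option).
#'
#' @inheritParams closeness_centrality
#' @param normalized logical; default `TRUE`.
#' @return A [node_scores()] vector.
#' @export
betweenness_centrality <- function(net, normalized = TRUE,
                                   weight_as = c("distance", "affinity")) {
  weight_as <- match.arg(weight_as)
  n <- length(net$nodes)
  if (n == 0) return(node_scores(stats::setNames(numeric(0), character(0)), "betweenness"))
  b <- igraph::betweenness(as_igraph(net), directed = net$directed,
                           weights = .path_weights(net, weight_as))
  b <- as.numeric(b[net$nodes])
  if (normalized) {
    denom <- if (net$directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
    b <- if (n >= 3) b / denom else rep(0, n)
  }
  node_scores(stats::setNames(b, net$nodes), "betweenness")
}

#' Eigenvector centrality by power iteration
#'
#' Scores satisfying `x_v = (1/lambda) * sum over neighbors t of x_t`, the
#' dominant eigenvector of the (symmetrised, unweighted) adjacency matrix,
#' normalised to unit sum. Computed by power iteration on `A + I`; the
#' spectral shift leaves the eigenvectors unchanged while making the
#' Perron vector strictly dominant, so the iteration also converges on
#' bipartite graphs where the extreme eigenvalues come in a `+/-lambda`
#' pair.
#'
#' @param net an [emi_network()] with at least one edge.
#' @param max_iter maximum iterations.
#' @param tol max-norm convergence tolerance between successive iterates.
#' @return A [node_scores()] vector summing to 1.
#' @export
eigenvector_centrality <- function(net, max_iter = 1000L, tol = 1e-10) {
  n <- length(net$nodes)
  if (nrow(net$edges) == 0) stop("eigenvector centrality requires at least one edge")
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  A[cbind(e$from, e$to)] <- 1
  A[cbind(e$to, e$from)] <- 1
  diag(A) <- diag(A) + 1        # spectral shift
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(A %*% x)
    x_new <- x_new / sum(x_new)
    if (max(abs(x_new - x)) < tol)
      return(node_scores(stats::setNames(x_new, net$nodes), "eigenvector"))
    x <- x_new
  }
  stop(sprintf("eigenvector power iteration did not converge in %d iterations (residual %.3g)",
               max_iter, max(abs(as.numeric(A %*% x) / sum(A %*% x) - x))))
}

#' Simplified PageRank iteration
#'
#' The textbook update `PR <- t(A) %*% PR` with a column-normalised
#' transition matrix: every node starts with `1/n`, then repeatedly passes
#' its current score in equal parts along its out-edges (undirected edges
#' count both ways). Mass on dangling nodes (no out-edges) is
#' redistributed uniformly, so the scores sum to 1 at every iteration.
#' Damping is off by default; pass e.g. `damping = 0.85` for the damped
#' variant.
#'
#' @param net an [emi_network()].
#' @param iterations number of update sweeps (default 100).
#' @param damping `NULL` (none, the default) or a damping factor in (0, 1).
#' @return A [node_scores()] vector summing to 1.
#' @export
pagerank_paper <- function(net, iterations = 100L, damping = NULL) {
  n <- length(net$nodes)
  if (n == 0) return(node_scores(stats::setNames(numeric(0), character(0)), "pagerank"))
  e <- net$edges
  from <- e$from; to <- e$to
  if (!net$directed) { from <- c(from, e$to); to <- c(to, e$from) }
  outdeg <- stats::setNames(numeric(n), net$nodes)
  tf <- table(from); outdeg[names(tf)] <- as.numeric(tf)
  M <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes)) # M[i, j] = P(j -> i)
  if (length(from)) M[cbind(to, from)] <- 1 / outdeg[from]
  dangling <- outdeg == 0
  pr <- rep(1 / n, n)
  for (it in seq_len(iterations)) {
    flow <- as.numeric(M %*% pr) + sum(pr[dangling]) / n
    pr <- if (is.null(damping)) flow else (1 - damping) / n + damping * flow
  }
  node_scores(stats::setNames(pr, net$nodes), "pagerank")
}
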