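#' Construct a network from an edge table
#'
#' The single graph container used throughout the package. Edges are stored
#' as a `from`/`to`/`weight` table of opaque character node identifiers.
#' Self-loops are dropped (with a warning), parallel edges are merged by
#' summing weights so each (un)ordered pair appears at most once, and for
#' unweighted networks every stored weight is 1.
#'
#' Edge weights must be positive: the entropy definitions turn weight sums
#' into probability distributions. When a weighted input contains
#' non-positive weights (rating scales often include negative values) and
#' `shift_nonpositive` is `TRUE`, all weights are shifted by
#' `w' = w - min(w) + 1` so the smallest becomes 1.
#'
#' @param edges data frame (or matrix) with columns source, target and
#'   optionally weight. Zero rows give an edgeless network.
#' @param nodes optional character vector of node identifiers; endpoints of
#'   `edges` are always included. Use this to add isolated nodes.
#' @param directed logical; are edges ordered pairs?
#' @param weighted logical; do edges carry weights? A weight column on an
#'   unweighted network is an error unless all weights equal 1 (silent
#'   truncation is refused).
#' @param shift_nonpositive logical; shift weights when any is `<= 0`.
#' @return An object of class `emi_network`: a list with elements `nodes`
#'   (sorted character), `edges` (data frame `from`, `to`, `weight`),
#'   `directed`, `weighted`.
#' @examples
#' net <- emi_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' net
#' @seealso [load_edge_list()], [toy_network()], [neighbors_of()]
#' @export
emi_network <- function(edges, nodes = NULL, directed = FALSE,
                        weighted = FALSE, shift_nonpositive = TRUE) {
  stopifnot(is.logical(directed), length(directed) == 1L,
            is.logical(weighted), length(weighted) == 1L)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && ncol(edges) < 2)
    stop("`edges` needs at least source and target columns")
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    from <- as.character(edges[[1L]])
    to <- as.character(edges[[2L]])
    weight <- if (ncol(edges) >= 3) as.numeric(edges[[3L]]) else rep(1, length(from))
    if (anyNA(from) || anyNA(to) || anyNA(weight))
      stop("edge table contains missing values")
    if (!weighted && ncol(edges) >= 3 && any(weight != 1))
      stop("weight column with non-unit weights supplied for an unweighted network; ",
           "set weighted = TRUE (silent truncation refused)")
    if (!weighted) weight <- rep(1, length(from))
    loops <- from == to
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop(s)", sum(loops)))
      from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
    }
    if (weighted && length(weight) && any(weight <= 0)) {
      if (shift_nonpositive) {
        shift <- 1 - min(weight)
        message(sprintf("shifted all weights by %+g so the minimum weight is 1", shift))
        weight <- weight + shift
      } else {
        stop("non-positive edge weights; entropy requires positive weights ",
             "(set shift_nonpositive = TRUE to shift)")
      }
    }
    key <- if (directed) paste(from, to, sep = "\r") else
      paste(pmin(from, to), pmax(from, to), sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(weight, key, sum)
      first <- !duplicated(key)
      from <- from[first]; to <- to[first]
      weight <- as.numeric(w[key[first]])
      if (!weighted) weight <- rep(1, length(from))
    }
    edges <- data.frame(from = from, to = to, weight = weight,
                        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges, directed = directed,
                 weighted = weighted),
            class = "emi_network")
}

#' @export
print.emi_network <- function(x, ...) {
  cat(sprintf("<emi_network: %d nodes, %d edges, %s, %s>\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Read a network from an edge-list file
#'
#' Parses whitespace/tab-separated edge lists with 2 (source, target) or
#' 3 (source, target, weight) columns. Lines starting with `%` or `#`
#' (KONECT-style headers) and blank lines are skipped. A missing weight
#' column yields unit weights; a 3-column file read with `weighted = FALSE`
#' is an error so weights are never silently discarded.
#'
#' @inheritParams emi_network
#' @param path path to the edge-list file.
#' @return An [emi_network()].
#' @export
load_edge_list <- function(path, directed = FALSE, weighted = FALSE,
                           shift_nonpositive = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([%#]|$)", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (!length(lines))
    return(emi_network(data.frame(from = character(), to = character()),
                       directed = directed, weighted = weighted))
  tok <- strsplit(lines, "[ \t]+")
  nf <- lengths(tok)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("malformed edge list line %d: %s", lineno[bad[1L]], lines[bad[1L]]))
  if (any(nf == 3L) && !weighted)
    stop(sprintf(
      "file has a weight column (first at line %d) but weighted = FALSE; refusing silent truncation",
      lineno[which(nf == 3L)[1L]]))
  from <- vapply(tok, `[[`, "", 1L)
  to <- vapply(tok, `[[`, "", 2L)
  weight <- rep(1, length(tok))
  has_w <- nf == 3L
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(tok[has_w], `[[`, "", 3L)))
    if (anyNA(w)) {
      bad <- lineno[has_w][which(is.na(w))[1L]]
      stop(sprintf("non-numeric weight at line %d", bad))
    }
    weight[has_w] <- w
  }
  emi_network(data.frame(from = from, to = to, weight = weight,
                         stringsAsFactors = FALSE),
              directed = directed, weighted = weighted,
              shift_nonpositive = shift_nonpositive)
}

#' Write a network as an edge-list file
#'
#' Emits the same 2/3-column format [load_edge_list()] reads, preceded by
#' `%` comment lines recording the directedness and weightedness flags, so
#' load/write/load round-trips to an identical network.
#'
#' @param net an [emi_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "emi_network"))
  hdr <- sprintf("%% eminet edge list: directed=%s weighted=%s",
                 net$directed, net$weighted)
  body <- if (net$weighted) {
    sprintf("%s\t%s\t%.15g", net$edges$from, net$edges$to, net$edges$weight)
  } else {
    sprintf("%s\t%s", net$edges$from, net$edges$to)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

.check_node <- function(net, v) {
  if (length(v) != 1L || !(v %in% net$nodes))
    stop("unknown node: ", paste(v, collapse = ", "))
  as.character(v)
}

#' Neighbors of a node
#'
#' Two nodes are neighbors if an edge connects them in either direction:
#' for directed networks the neighborhood is the union of in- and
#' out-neighbors. The node itself is never a member.
#'
#' @param net an [emi_network()].
#' @param v a node identifier.
#' @return Sorted character vector of neighbor identifiers.
#' @export
neighbors_of <- function(net, v) {
  v <- .check_node(net, v)
  e <- net$edges
  sort(unique(c(e$to[e$from == v], e$from[e$to == v])))
}

#' Adjacency list for all nodes (internal)
#' @noRd
.adjacency <- function(net) {
  adj <- lapply(stats::setNames(vector("list", length(net$nodes)), net$nodes),
                function(x) character())
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' In/out degrees and strengths of a node
#'
#' For directed networks `d_in`/`d_out` count inbound/outbound edges and
#' `w_in`/`w_out` sum their weights. For undirected networks all incident
#' edges count toward both directions, so `d_in = d_out` (the degree) and
#' `w_in = w_out` (the strength). Unweighted networks have unit weights,
#' hence `w_in = d_in` and `w_out = d_out`.
#'
#' @inheritParams neighbors_of
#' @return A one-row data frame with columns `node`, `d_in`, `d_out`,
#'   `w_in`, `w_out`.
#' @export
degree_record <- function(net, v) {
  v <- .check_node(net, v)
  .degree_table(net)[v, , drop = FALSE]
}

#' Degree/strength table for all nodes (internal)
#' @noRd
.degree_table <- function(net) {
  e <- net$edges
  zero <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  acc <- function(keys, vals) {
    out <- zero
    if (length(keys)) {
      s <- tapply(vals, keys, sum)
      out[names(s)] <- as.numeric(s)
    }
    out
  }
  if (net$directed) {
    d_in <- acc(e$to, rep(1, nrow(e)));  d_out <- acc(e$from, rep(1, nrow(e)))
    w_in <- acc(e$to, e$weight);         w_out <- acc(e$from, e$weight)
  } else {
    keys <- c(e$from, e$to); w <- c(e$weight, e$weight)
    d_in <- d_out <- acc(keys, rep(1, length(keys)))
    w_in <- w_out <- acc(keys, w)
  }
  data.frame(node = net$nodes, d_in = as.integer(d_in), d_out = as.integer(d_out),
             w_in = w_in, w_out = w_out,
             row.names = net$nodes, stringsAsFactors = FALSE)
}

#' Secondary neighbors of a node
#'
#' Nodes adjacent to a neighbor of `v` that are neither `v` itself nor a
#' neighbor of `v` -- the second ring the structural entropy reaches through
#' the neighbors' degrees.
#'
#' @inheritParams neighbors_of
#' @return Sorted character vector of node identifiers.
#' @export
secondary_neighbors <- function(net, v) {
  v <- .check_node(net, v)
  nb <- neighbors_of(net, v)
  second <- unique(unlist(lapply(nb, neighbors_of, net = net), use.names = FALSE))
  sort(setdiff(second, c(v, nb)))
}

#' The four-node worked-example network
#'
#' A directed, weighted network of four nodes with edges a->b (weight 1),
#' a->d (4), b->c (2), c->a (3). Small enough to evaluate every formula in
#' this package by hand, it is used as a fixture throughout the tests: the
#' neighbor degree/strength sums, entropies, mutual powers and the final
#' ranking a > b > c > d all have known closed-form values.
#'
#' @return An [emi_network()].
#' @examples
#' emi(toy_network())
#' @export
toy_network <- function() {
  emi_network(data.frame(from = c("a", "a", "b", "c"),
                         to = c("b", "d", "c", "a"),
                         weight = c(1, 4, 2, 3),
                         stringsAsFactors = FALSE),
              directed = TRUE, weighted = TRUE)
}

#' Convert to an igraph object
#'
#' @param net an [emi_network()].
#' @return An [igraph::graph][igraph] with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "emi_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")], directed = net$directed,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' Summary statistics of a network
#'
#' Node/edge counts, mean and maximum total degree, the global clustering
#' coefficient (transitivity) and the degree assortativity coefficient.
#' Clustering and assortativity are `NA` where undefined (fewer than 2
#' edges or constant degrees).
#'
#' @param net an [emi_network()].
#' @return A list with elements `n`, `e`, `avg_degree`, `max_degree`,
#'   `clustering`, `assortativity`.
#' @export
describe <- function(net) {
  stopifnot(inherits(net, "emi_network"))
  n <- length(net$nodes); e <- nrow(net$edges)
  if (n == 0)
    return(list(n = 0L, e = 0L, avg_degree = 0, max_degree = 0L,
                clustering = NA_real_, assortativity = NA_real_))
  deg <- .degree_table(net)
  total <- if (net$directed) deg$d_in + deg$d_out else deg$d_in
  g <- as_igraph(net)
  cc <- if (e >= 2) igraph::transitivity(g, type = "global") else NA_real_
  rho <- if (e >= 2) suppressWarnings(igraph::assortativity_degree(g)) else NA_real_
  list(n = n, e = e, avg_degree = 2 * e / n, max_degree = max(total, 0L),
       clustering = cc, assortativity = rho)
}
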