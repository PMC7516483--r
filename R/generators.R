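#' Analytic network families
#'
#' Unweighted, undirected graphs with closed-form centrality values, used
#' as test anchors: the star center has structural entropy `log10(n - 1)`
#' while its leaves score 0, complete graphs are fully symmetric so every
#' ranking collapses to one tie group, and so on.
#'
#' @param kind `"star"` (node `v1` is the hub), `"path"`, `"cycle"` or
#'   `"complete"`.
#' @param n number of nodes; at least 2 (3 for a cycle).
#' @return An [emi_network()].
#' @examples
#' analytic_family("star", 6)
#' @export
analytic_family <- function(kind = c("star", "path", "cycle", "complete"), n) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2, kind != "cycle" || n >= 3)
  n <- as.integer(n)
  ids <- sprintf("v%d", seq_len(n))
  edges <- switch(kind,
    star = data.frame(from = ids[1L], to = ids[-1L]),
    path = data.frame(from = ids[-n], to = ids[-1L]),
    cycle = data.frame(from = ids, to = ids[c(2:n, 1L)]),
    complete = {
      pairs <- utils::combn(ids, 2L)
      data.frame(from = pairs[1L, ], to = pairs[2L, ])
    })
  emi_network(edges, nodes = ids, directed = FALSE, weighted = FALSE)
}

#' Erdos-Renyi style random networks
#'
#' Samples each (ordered, if directed) node pair independently with
#' probability `p`; weighted networks draw integer weights uniformly from
#' `weight_range` (flight-count-style weights; pass a non-integer range
#' via `integer_weights = FALSE` for continuous uniform draws). Fully
#' reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param n number of nodes.
#' @param p edge probability in `[0, 1]`.
#' @param directed,weighted network-type flags.
#' @param weight_range length-2 numeric range for weights (default 1..5).
#' @param integer_weights logical; draw integer weights (default `TRUE`).
#' @param seed integer RNG seed.
#' @return An [emi_network()].
#' @export
random_network <- function(n, p, directed = FALSE, weighted = FALSE,
                           weight_range = c(1, 5), integer_weights = TRUE,
                           seed = 1L) {
  stopifnot(n >= 1, p >= 0, p <= 1, length(weight_range) == 2L,
            weight_range[1L] > 0, weight_range[1L] <= weight_range[2L])
  n <- as.integer(n)
  ids <- sprintf("v%d", seq_len(n))
  pairs <- if (n >= 2) utils::combn(seq_len(n), 2L) else
    matrix(integer(0), nrow = 2L)
  .with_seed(seed, {
    if (directed) {
      cand_from <- c(pairs[1L, ], pairs[2L, ])
      cand_to <- c(pairs[2L, ], pairs[1L, ])
    } else {
      cand_from <- pairs[1L, ]
      cand_to <- pairs[2L, ]
    }
    keep <- stats::runif(length(cand_from)) < p
    from <- ids[cand_from[keep]]
    to <- ids[cand_to[keep]]
    w <- if (weighted && any(keep)) {
      if (integer_weights)
        sample(seq(weight_range[1L], weight_range[2L]), sum(keep), replace = TRUE)
      else stats::runif(sum(keep), weight_range[1L], weight_range[2L])
    } else rep(1, sum(keep))
    emi_network(data.frame(from = from, to = to, weight = w,
                           stringsAsFactors = FALSE),
                nodes = ids, directed = directed, weighted = weighted)
  })
}

#' Two hubs with a tunable shared neighborhood
#'
#' The canonical over-valuation scenario the mutual-information penalty
#' targets: two connected hub nodes (`hubA`, `hubB`) with `shared` common
#' leaf neighbors plus `private_a`/`private_b` private leaves each.
#' Holding the hub degrees fixed, increasing `shared` strictly decreases
#' each hub's mutual power, and hence its final score.
#'
#' @param shared number of common leaf neighbors (`>= 0`).
#' @param private_a,private_b private leaf counts for each hub.
#' @return An undirected, unweighted [emi_network()].
#' @export
overlap_pair_network <- function(shared, private_a = 0L, private_b = 0L) {
  stopifnot(shared >= 0, private_a >= 0, private_b >= 0)
  shared_ids <- if (shared > 0) sprintf("s%02d", seq_len(shared)) else character()
  pa <- if (private_a > 0) sprintf("pa%02d", seq_len(private_a)) else character()
  pb <- if (private_b > 0) sprintf("pb%02d", seq_len(private_b)) else character()
  edges <- data.frame(
    from = c("hubA", rep("hubA", length(shared_ids)), rep("hubB", length(shared_ids)),
             rep("hubA", length(pa)), rep("hubB", length(pb))),
    to = c("hubB", shared_ids, shared_ids, pa, pb),
    stringsAsFactors = FALSE)
  emi_network(edges, directed = FALSE, weighted = FALSE)
}
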