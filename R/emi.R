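#' Configuration for the EMI score
#'
#' @param log_base logarithm base for all entropies; must exceed 1.
#'   Default 10.
#' @param compat_single_neighbor logical. The strict entropy definitions
#'   give a node with exactly one neighbor a score of 0 (a singleton
#'   multiset carries no information). Under the compatibility rule such a
#'   node additionally includes its own degree and strength in the
#'   multisets, so leaf nodes retain a small positive score. Default
#'   `FALSE` (strict).
#' @param weight_shift logical; default for the non-positive-weight shift
#'   applied when networks are loaded (see [emi_network()]).
#' @param mi_terms `"pair"` (default) sums one mutual-information term per
#'   neighbor pair; `"common-squared"` repeats each term `F(Nvj)^2` times.
#'   See [mutual_power()].
#' @return An object of class `emi_config`.
#' @export
emi_config <- function(log_base = 10, compat_single_neighbor = FALSE,
                       weight_shift = TRUE,
                       mi_terms = c("pair", "common-squared")) {
  stopifnot(is.numeric(log_base), length(log_base) == 1L, log_base > 1,
            is.logical(compat_single_neighbor), is.logical(weight_shift))
  structure(list(log_base = log_base,
                 compat_single_neighbor = isTRUE(compat_single_neighbor),
                 weight_shift = isTRUE(weight_shift),
                 mi_terms = match.arg(mi_terms)),
            class = "emi_config")
}

#' Entropy and mutual-information (EMI) node importance
#'
#' Scores every node of a network by combining the entropy of its
#' neighborhood's degree distribution (structural entropy `S`), for
#' weighted networks the entropy of the neighborhood's strength
#' distribution (interactive entropy `I`), and a non-positive
#' mutual-information correction (`MI`) that penalises redundant influence
#' between adjacent nodes sharing neighbors:
#'
#' * weighted networks: `K = S + I + MI`
#' * unweighted networks: `K = S + MI`
#'   (directed-unweighted uses `S = S_in + S_out`)
#'
#' Isolated nodes score `K = 0` (with a warning) so whole-network ranking
#' never aborts. Nodes are returned sorted by decreasing `K`, ties broken
#' by node identifier, so output files are deterministic.
#'
#' @param net an [emi_network()].
#' @param config an [emi_config()].
#' @return An object of class `emi`: a list with elements `scores` (data
#'   frame with columns `node`, `S_in`, `S_out`, `S`, `I_in`, `I_out`,
#'   `I`, `MI`, `K`, `rank`), `config`, `directed`, `weighted`, `call`.
#'   Components that do not apply (in/out splits on undirected networks,
#'   `I` on unweighted ones) are `NA`.
#' @examples
#' fit <- emi(toy_network())
#' fit
#' coef(fit)
#' summary(fit)
#' @seealso [structural_entropy()], [interactive_entropy()],
#'   [mutual_power()], [make_ranking()]
#' @export
emi <- function(net, config = emi_config()) {
  stopifnot(inherits(net, "emi_network"), inherits(config, "emi_config"))
  nodes <- net$nodes
  n <- length(nodes)
  deg <- .degree_table(net)
  adj <- .adjacency(net)
  cols <- c("S_in", "S_out", "S", "I_in", "I_out", "I", "MI", "K")
  m <- matrix(NA_real_, nrow = n, ncol = length(cols),
              dimnames = list(nodes, cols))
  isolated <- character()
  for (v in nodes) {
    nb <- adj[[v]]
    if (!length(nb)) isolated <- c(isolated, v)
    s <- .structural_entropy(v, nb, deg, net$directed, config)
    m[v, c("S_in", "S_out", "S")] <- s
    if (net$weighted)
      m[v, c("I_in", "I_out", "I")] <-
        .interactive_entropy(v, nb, deg, net$directed, config)
    m[v, "MI"] <- .mutual_power(v, adj, config)
    m[v, "K"] <- if (net$weighted) s[["S"]] + m[v, "I"] + m[v, "MI"]
                 else s[["S"]] + m[v, "MI"]
  }
  if (length(isolated))
    warning(sprintf("%d isolated node(s) scored K = 0: %s",
                    length(isolated),
                    paste(utils::head(isolated, 5L), collapse = ", ")))
  ord <- order(-m[, "K"], nodes)
  scores <- data.frame(node = nodes[ord], m[ord, , drop = FALSE],
                       rank = seq_len(n), row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, config = config, directed = net$directed,
                 weighted = net$weighted, n = n, e = nrow(net$edges),
                 call = match.call()),
            class = "emi")
}

#' @export
print.emi <- function(x, digits = 5, max_rows = 10L, ...) {
  cat(sprintf("EMI node importance (%s, %s; log base %g%s)\n",
              if (x$directed) "directed" else "undirected",
              if (x$weighted) "weighted" else "unweighted",
              x$config$log_base,
              if (x$config$compat_single_neighbor) ", compat" else ""))
  cat(sprintf("%d nodes, %d edges\n", x$n, x$e))
  s <- utils::head(x$scores, max_rows)
  num <- vapply(s, is.numeric, logical(1L))
  s[num] <- lapply(s[num], round, digits = digits)
  print(s, row.names = FALSE)
  if (nrow(x$scores) > max_rows)
    cat(sprintf("... %d more nodes\n", nrow(x$scores) - max_rows))
  invisible(x)
}

#' @export
coef.emi <- function(object, ...) {
  stats::setNames(object$scores$K, object$scores$node)
}

#' @export
as.data.frame.emi <- function(x, ...) x$scores

#' @export
summary.emi <- function(object, tol = 1e-10, ...) {
  r <- make_ranking(object, tol = tol)
  structure(list(fit = object, ranking = r,
                 monotonicity = if (object$n >= 2) monotonicity(r) else NA_real_,
                 tie_sizes = table(r$sizes)),
            class = "summary.emi")
}

#' @export
print.summary.emi <- function(x, ...) {
  print(x$fit)
  cat(sprintf("tie groups: %d; monotonicity M(R) = %s\n",
              length(x$ranking$groups),
              format(x$monotonicity, digits = 6)))
  invisible(x)
}

#' Plot the rank-occupancy CCDF of an EMI fit
#'
#' Step plot of the complementary cumulative distribution of nodes over
#' ranks (see [ccdf()]); a slowly decaying curve indicates a ranking that
#' separates nodes into many small tie groups.
#'
#' @param x an [emi()] fit.
#' @param tol tie tolerance passed to [make_ranking()].
#' @param ... passed on to [graphics::plot()].
#' @export
plot.emi <- function(x, tol = 1e-10, ...) {
  cc <- ccdf(make_ranking(x, tol = tol))
  graphics::plot(cc$rank, cc$ccdf, type = "s", xlab = "rank r",
                 ylab = "CCDF(r)", ylim = c(0, 1),
                 main = "Rank occupancy CCDF", ...)
  invisible(cc)
}
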