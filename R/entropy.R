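#' Shannon entropy of a non-negative multiset
#'
#' Normalises the values to a probability distribution
#' `p_i = v_i / sum(v)` and returns `H = -sum(p_i * log(p_i, base))`,
#' with the usual convention that zero values contribute nothing
#' (`0 * log 0 := 0`). This is the primitive behind both the structural
#' and the interactive entropy.
#'
#' @param values numeric vector of non-negative magnitudes (degrees or
#'   weight sums); at least one must be positive.
#' @param base logarithm base; must exceed 1. Default 10, the base used
#'   throughout this package.
#' @return The entropy in `log base` units, a non-negative scalar bounded
#'   by `log(length(values), base)`.
#' @examples
#' multiset_entropy(c(1, 1, 1))        # log10(3)
#' multiset_entropy(c(1, 1, 0))        # log10(2): zeros contribute nothing
#' @export
multiset_entropy <- function(values, base = 10) {
  stopifnot(is.numeric(values), length(values) >= 1L, base > 1)
  if (any(!is.finite(values)) || any(values < 0))
    stop("`values` must be finite and non-negative")
  if (sum(values) <= 0)
    stop("entropy undefined for an all-zero multiset")
  .h0(values, base)
}

# entropy with the all-zero multiset mapped to 0; internal workhorse so the
# per-node scores never abort on e.g. neighbours that all have out-degree 0
.h0 <- function(values, base) {
  s <- sum(values)
  if (s <= 0) return(0)
  p <- values[values > 0] / s
  -sum(p * log(p, base))
}

# entropy multiset for node v: its neighbours' column `col` values, with the
# single-neighbor compatibility rule optionally appending v's own value
.entropy_values <- function(v, nb, deg, col, config) {
  ids <- nb
  if (isTRUE(config$compat_single_neighbor) && length(nb) == 1L)
    ids <- c(nb, v)
  deg[ids, col]
}

#' Structural entropy of a node
#'
#' The entropy of the degree distribution of a node's neighborhood. For a
#' directed network the score splits into `S_in` (entropy of the neighbors'
#' in-degrees) and `S_out` (their out-degrees) with `S = S_in + S_out`; for
#' undirected networks a single entropy over the neighbors' degrees is
#' returned in `S` with `S_in`/`S_out` set to `NA`.
#'
#' A node whose neighborhood degree multiset is all-zero (or an isolated
#' node, which scores 0 with a warning) contributes no information and the
#' corresponding component is 0.
#'
#' @param net an [emi_network()].
#' @param v a node identifier.
#' @param config an [emi_config()].
#' @return Named numeric vector `c(S_in, S_out, S)`.
#' @seealso [interactive_entropy()], [mutual_power()], [emi()]
#' @export
structural_entropy <- function(net, v, config = emi_config()) {
  v <- .check_node(net, v)
  .structural_entropy(v, neighbors_of(net, v), .degree_table(net),
                      net$directed, config, warn = TRUE)
}

.structural_entropy <- function(v, nb, deg, directed, config, warn = FALSE) {
  if (length(nb) == 0L) {
    if (warn) warning("isolated node '", v, "': structural entropy set to 0")
    return(c(S_in = if (directed) 0 else NA_real_,
             S_out = if (directed) 0 else NA_real_, S = 0))
  }
  b <- config$log_base
  if (directed) {
    s_in <- .h0(.entropy_values(v, nb, deg, "d_in", config), b)
    s_out <- .h0(.entropy_values(v, nb, deg, "d_out", config), b)
    c(S_in = s_in, S_out = s_out, S = s_in + s_out)
  } else {
    c(S_in = NA_real_, S_out = NA_real_,
      S = .h0(.entropy_values(v, nb, deg, "d_in", config), b))
  }
}

#' Interactive entropy of a node
#'
#' The weighted counterpart of [structural_entropy()]: the entropy of the
#' neighbors' strength (edge-weight sum) distribution. Directed networks
#' split into `I_in` (inbound strengths) and `I_out` (outbound strengths)
#' with `I = I_in + I_out`; undirected networks use one entropy over the
#' neighbor strengths. Only defined for weighted networks -- on an
#' unweighted network every strength equals the degree and the score would
#' duplicate `S`, so an error is raised instead.
#'
#' @inheritParams structural_entropy
#' @return Named numeric vector `c(I_in, I_out, I)`.
#' @export
interactive_entropy <- function(net, v, config = emi_config()) {
  if (!net$weighted)
    stop("interactive entropy is not applicable to an unweighted network")
  v <- .check_node(net, v)
  .interactive_entropy(v, neighbors_of(net, v), .degree_table(net),
                       net$directed, config, warn = TRUE)
}

.interactive_entropy <- function(v, nb, deg, directed, config, warn = FALSE) {
  if (length(nb) == 0L) {
    if (warn) warning("isolated node '", v, "': interactive entropy set to 0")
    return(c(I_in = if (directed) 0 else NA_real_,
             I_out = if (directed) 0 else NA_real_, I = 0))
  }
  b <- config$log_base
  if (directed) {
    i_in <- .h0(.entropy_values(v, nb, deg, "w_in", config), b)
    i_out <- .h0(.entropy_values(v, nb, deg, "w_out", config), b)
    c(I_in = i_in, I_out = i_out, I = i_in + i_out)
  } else {
    c(I_in = NA_real_, I_out = NA_real_,
      I = .h0(.entropy_values(v, nb, deg, "w_in", config), b))
  }
}

#' Mutual power of a node
#'
#' The redundancy penalty: for each neighbor `j` of `v`, the shared
#' neighborhood contributes
#' `F(Nvj)/(F(Nv)+F(Nj)) * log((F(Nv)+F(Nj)-F(Nvj)) / (F(Nv)+F(Nj)), base)`,
#' where `Nv`, `Nj` are the (direction-ignoring) neighbor sets, `Nvj` their
#' intersection and `F` the set size. Each term is non-positive -- the log
#' ratio is below 1 whenever neighbors are shared -- so `MI <= 0`, with
#' equality exactly when `v` shares no neighbor with any of its neighbors.
#' Adjacent nodes with heavily overlapping neighborhoods are thereby pulled
#' down the ranking instead of being double-counted.
#'
#' With `mi_terms = "common-squared"` each pair term is repeated
#' `F(Nvj)^2` times (once per ordered pair of common neighbors), an
#' alternative reading of the double sum that coincides with the default
#' whenever `F(Nvj) <= 1`.
#'
#' @inheritParams structural_entropy
#' @return A non-positive scalar; 0 for isolated nodes.
#' @export
mutual_power <- function(net, v, config = emi_config()) {
  v <- .check_node(net, v)
  .mutual_power(v, .adjacency(net), config)
}

.mutual_power <- function(v, adj, config) {
  nb <- adj[[v]]
  if (!length(nb)) return(0)
  b <- config$log_base
  fv <- length(nb)
  total <- 0
  for (j in nb) {
    nj <- adj[[j]]
    fc <- length(intersect(nb, nj))
    if (fc == 0L) next
    denom <- fv + length(nj)
    term <- (fc / denom) * log((denom - fc) / denom, b)
    if (identical(config$mi_terms, "common-squared")) term <- term * fc^2
    total <- total + term
  }
  total
}
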