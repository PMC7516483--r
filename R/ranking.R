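#' Group scores into a ranking list with tie groups
#'
#' Sorts scores in decreasing order and merges scores that agree after
#' rounding to `-log10(tol)` decimals into one tie group. Rounding-based
#' grouping is deterministic and order-independent, unlike pairwise
#' tolerance chaining. Members within a group are sorted by node
#' identifier, which also fixes the deterministic top-k flattening order.
#'
#' @param scores a named numeric vector, a [node_scores()] vector, or an
#'   [emi()] fit (whose `K` values are used).
#' @param tol non-negative absolute tolerance for treating two scores as
#'   tied (default `1e-10`).
#' @return An object of class `ranking_list`: list with `groups` (list of
#'   character vectors in decreasing score order), `sizes`, `n` (total
#'   node count) and `method`.
#' @examples
#' make_ranking(c(a = 3, b = 2, c = 2, d = 1))
#' @export
make_ranking <- function(scores, tol = 1e-10) {
  UseMethod("make_ranking")
}

#' @export
make_ranking.emi <- function(scores, tol = 1e-10) {
  r <- make_ranking.default(coef(scores), tol = tol)
  r$method <- "emi"
  r
}

#' @export
make_ranking.ranking_list <- function(scores, tol = 1e-10) scores

#' @export
make_ranking.default <- function(scores, tol = 1e-10) {
  stopifnot(is.numeric(scores), length(scores) >= 1L, tol >= 0)
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must carry unique node names")
  if (any(!is.finite(scores)))
    stop("non-finite score for node(s): ",
         paste(names(scores)[!is.finite(scores)], collapse = ", "))
  digits <- if (tol > 0) max(0L, as.integer(round(-log10(tol)))) else 15L
  key <- round(scores, digits)
  lev <- sort(unique(key), decreasing = TRUE)
  groups <- lapply(lev, function(k) sort(names(scores)[key == k]))
  structure(list(groups = groups,
                 sizes = vapply(groups, length, integer(1L)),
                 n = length(scores),
                 method = attr(scores, "method") %||% "scores"),
            class = "ranking_list")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ranking_list <- function(x, max_groups = 10L, ...) {
  cat(sprintf("<ranking_list: %s, %d nodes in %d rank group(s)>\n",
              x$method, x$n, length(x$groups)))
  for (i in seq_len(min(length(x$groups), max_groups)))
    cat(sprintf("  %d: {%s}\n", i, paste(x$groups[[i]], collapse = ", ")))
  if (length(x$groups) > max_groups)
    cat(sprintf("  ... %d more groups\n", length(x$groups) - max_groups))
  invisible(x)
}

#' Monotonicity of a ranking
#'
#' Measures how rarely a ranking places distinct nodes in the same rank:
#' `M(R) = (1 - sum_r n_r (n_r - 1) / (n (n - 1)))^2`, where `n_r` is the
#' size of tie group `r` and `n` the total number of nodes. `M = 1` when
#' every node has a unique rank and `M = 0` when all nodes share one rank.
#'
#' @param r a `ranking_list` (anything accepted by [make_ranking()]).
#' @param tol tie tolerance used if `r` still needs grouping.
#' @return A scalar in `[0, 1]`.
#' @export
monotonicity <- function(r, tol = 1e-10) {
  r <- make_ranking(r, tol = tol)
  n <- r$n
  if (n < 2) stop("monotonicity is undefined for fewer than 2 nodes")
  (1 - sum(r$sizes * (r$sizes - 1)) / (n * (n - 1)))^2
}

#' Complementary cumulative distribution of rank occupancy
#'
#' `CCDF(r) = (|V| - sum_{i <= r} n_i) / |V|`: the fraction of nodes placed
#' strictly below rank `r`. Non-increasing, reaching 0 at the last rank; a
#' slow decay indicates many small, well-separated tie groups.
#'
#' @inheritParams monotonicity
#' @return Data frame with columns `rank` and `ccdf`.
#' @export
ccdf <- function(r, tol = 1e-10) {
  r <- make_ranking(r, tol = tol)
  data.frame(rank = seq_along(r$sizes),
             ccdf = (r$n - cumsum(r$sizes)) / r$n)
}

#' Flatten a ranking into a deterministic node order
#' @noRd
.flatten_ranking <- function(r) unlist(r$groups, use.names = FALSE)

#' Overlap of the top-k nodes of two rankings
#'
#' Flattens each ranking's tie groups in the deterministic order (groups by
#' decreasing score, identifiers ascending within a group), takes the first
#' `k` nodes of each, and intersects.
#'
#' @param a,b `ranking_list`s (anything accepted by [make_ranking()]).
#' @param k number of top nodes to compare; at most either list's size.
#' @return List with `count` and the intersecting `nodes`.
#' @export
top_k_overlap <- function(a, b, k) {
  a <- make_ranking(a); b <- make_ranking(b)
  stopifnot(length(k) == 1L, k >= 1)
  if (k > a$n || k > b$n)
    stop(sprintf("k = %d exceeds a ranking's node count (%d, %d)", k, a$n, b$n))
  ta <- utils::head(.flatten_ranking(a), k)
  tb <- utils::head(.flatten_ranking(b), k)
  common <- sort(intersect(ta, tb))
  list(count = length(common), nodes = common)
}

#' Write a ranking table as TSV
#'
#' For an [emi()] fit the full component schema is written (`node`, `S_in`,
#' `S_out`, `S`, `I_in`, `I_out`, `I`, `MI`, `K`, `rank`); for a
#' [node_scores()] vector the columns are `node`, `score`, `rank`. Numeric
#' columns are formatted to 6 decimals; optional `header` lines are
#' prefixed with `#`.
#'
#' @param x an [emi()] fit or [node_scores()] vector.
#' @param path output path.
#' @param header optional character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(x, path, header = NULL) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  if (inherits(x, "emi")) {
    d <- x$scores
    out <- data.frame(node = d$node, lapply(d[c("S_in", "S_out", "S", "I_in",
                                                "I_out", "I", "MI", "K")], fmt),
                      rank = d$rank, stringsAsFactors = FALSE)
  } else if (inherits(x, "node_scores")) {
    ord <- order(-x, names(x))
    out <- data.frame(node = names(x)[ord], score = fmt(as.numeric(x)[ord]),
                      rank = seq_along(x), stringsAsFactors = FALSE)
  } else stop("x must be an 'emi' fit or a 'node_scores' vector")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking TSV back as node scores
#'
#' Reads files produced by [write_ranking_tsv()]; the score column is `K`
#' when present (EMI schema) and `score` otherwise.
#'
#' @param path file path.
#' @param method method name; defaults to the file name.
#' @return A [node_scores()] vector.
#' @export
read_ranking_tsv <- function(path, method = sub("\\.tsv$", "", basename(path))) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  col <- if ("K" %in% names(d)) "K" else if ("score" %in% names(d)) "score"
         else stop("no K or score column in ", path)
  node_scores(stats::setNames(as.numeric(d[[col]]), as.character(d$node)), method)
}
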