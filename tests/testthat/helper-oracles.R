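# Independent oracles kept deliberately naive: loop-based entropy, repeated
# pruning for shell indices, pairwise tie counting for monotonicity. They
# share no code with the implementation paths they check.

# entropy by explicit looping over the normalised multiset
entropy_oracle <- function(values, base = 10) {
  s <- sum(values)
  total <- 0
  for (v in values) {
    if (v > 0) {
      p <- v / s
      total <- total - p * log(p) / log(base)
    }
  }
  total
}

# shell indices by literal repeated pruning on total (in+out edge) degree
kshell_oracle <- function(net) {
  nodes <- net$nodes
  e <- net$edges
  endpoints <- c(e$from, e$to)           # each edge contributes to both ends
  shell <- stats::setNames(integer(length(nodes)), nodes)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  k <- 0L
  while (any(alive)) {
    repeat {
      live_edges <- alive[e$from] & alive[e$to]
      deg <- stats::setNames(numeric(length(nodes)), nodes)
      if (any(live_edges)) {
        tab <- table(c(e$from[live_edges], e$to[live_edges]))
        deg[names(tab)] <- as.numeric(tab)
      }
      low <- names(alive)[alive & deg <= k]
      if (!length(low)) break
      shell[low] <- k
      alive[low] <- FALSE
    }
    k <- k + 1L
  }
  shell
}

# monotonicity from pairwise tied-score counting (no tie-group structure)
monotonicity_oracle <- function(scores, digits = 10) {
  s <- round(scores, digits)
  n <- length(s)
  tied_ordered_pairs <- sum(outer(s, s, "==")) - n
  (1 - tied_ordered_pairs / (n * (n - 1)))^2
}

random_score_vector <- function(n, n_levels) {
  stats::setNames(sample(seq_len(n_levels), n, replace = TRUE) +
                    round(stats::runif(n), 2) * 0,
                  sprintf("n%03d", seq_len(n)))
}
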