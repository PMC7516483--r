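#' Configuration for SI spreading simulations
#'
#' @param beta infection probability per contact on unweighted networks,
#'   in `[0, 1]`.
#' @param alpha positive exponent for the weighted infection probability
#'   `(w / w_max)^alpha` (default 1).
#' @param steps maximum number of synchronous timesteps (default 100); the
#'   simulation also stops as soon as no susceptible node is adjacent to
#'   an infected one.
#' @param runs Monte-Carlo repetitions (default 100).
#' @param seed integer RNG seed; run `r` uses the derived stream
#'   `seed + r`, so results are bit-reproducible.
#' @return An object of class `si_config`.
#' @export
si_config <- function(beta = 0.1, alpha = 1, steps = 100L, runs = 100L,
                      seed = 1L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(steps), steps >= 1, is.numeric(runs), runs >= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(beta = beta, alpha = alpha, steps = as.integer(steps),
                 runs = as.integer(runs), seed = as.integer(seed)),
            class = "si_config")
}

#' Per-contact infection probability
#'
#' Probability that susceptible node `i` is infected through its infected
#' neighbor `j` in one timestep. On weighted networks this is
#' `(w_ji / w_max)^alpha` with `w_ji` the weight of the connecting edge
#' (`j -> i` for directed networks) and `w_max` the global maximum weight;
#' on unweighted networks it is the constant `beta`.
#'
#' @param net an [emi_network()].
#' @param i the susceptible node.
#' @param j the infected neighbor; the edge `j -> i` (or `j -- i`) must
#'   exist.
#' @param config an [si_config()].
#' @return A probability in `[0, 1]`.
#' @export
infection_probability <- function(net, i, j, config = si_config()) {
  i <- .check_node(net, i); j <- .check_node(net, j)
  e <- net$edges
  hit <- if (net$directed) e$from == j & e$to == i
         else (e$from == j & e$to == i) | (e$from == i & e$to == j)
  if (!any(hit)) stop(sprintf("no edge %s -> %s", j, i))
  if (!net$weighted) return(config$beta)
  (e$weight[which(hit)[1L]] / max(e$weight))^config$alpha
}

# out-adjacency (direction of spread) with per-contact probabilities,
# as integer indices into net$nodes
.spread_adjacency <- function(net, config) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  e <- net$edges
  from <- idx[e$from]; to <- idx[e$to]; w <- e$weight
  if (!net$directed) {
    tmp <- from
    from <- c(from, to); to <- c(to, tmp); w <- c(w, w)
  }
  prob <- if (net$weighted && length(w)) (w / max(net$edges$weight))^config$alpha
          else rep(config$beta, length(w))
  adj <- rep(list(integer(0)), length(net$nodes))
  probs <- rep(list(numeric(0)), length(net$nodes))
  if (length(from)) {
    sp <- split(seq_along(from), from)
    for (k in names(sp)) {
      adj[[as.integer(k)]] <- to[sp[[k]]]
      probs[[as.integer(k)]] <- prob[sp[[k]]]
    }
  }
  list(targets = adj, probs = probs)
}

#' Run a Monte-Carlo SI spreading experiment from a seed set
#'
#' Synchronous susceptible-infected dynamics: at every timestep each
#' infected node attempts to infect each of its susceptible out-neighbors
#' once, independently, with the per-contact probability of
#' [infection_probability()]. Nodes never recover, so the infected set
#' grows monotonically; a run stops at `config$steps` timesteps or as soon
#' as no susceptible node is adjacent to an infected one. Run `r` draws
#' from the RNG stream seeded with `config$seed + r`, making results
#' reproducible and allowing variance-paired comparisons across seed sets.
#' The global RNG state is left untouched.
#'
#' @param net an [emi_network()].
#' @param seeds non-empty character vector of initially infected nodes.
#' @param config an [si_config()].
#' @return An object of class `si_spread`: list with `seeds`,
#'   `mean_infected` (mean final infected count), `final_counts` (one per
#'   run), `trajectory` (mean infected count at timesteps `0..max`), and
#'   `config`.
#' @export
si_run <- function(net, seeds, config = si_config()) {
  stopifnot(inherits(net, "emi_network"), inherits(config, "si_config"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("empty seed set")
  if (!all(seeds %in% net$nodes))
    stop("unknown seed node(s): ",
         paste(setdiff(seeds, net$nodes), collapse = ", "))
  sp <- .spread_adjacency(net, config)
  n <- length(net$nodes)
  seed_idx <- match(seeds, net$nodes)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  finals <- integer(config$runs)
  trajs <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    set.seed((config$seed + r) %% .Machine$integer.max)
    inf <- logical(n)
    inf[seed_idx] <- TRUE
    traj <- sum(inf)
    step <- 0L
    while (step < config$steps) {
      targets <- integer(0); probs <- numeric(0)
      for (j in which(inf)) {
        nb <- sp$targets[[j]]
        if (!length(nb)) next
        keep <- !inf[nb]
        if (any(keep)) {
          targets <- c(targets, nb[keep])
          probs <- c(probs, sp$probs[[j]][keep])
        }
      }
      if (!length(targets)) break   # frontier exhausted
      hit <- stats::runif(length(probs)) < probs
      inf[targets[hit]] <- TRUE
      step <- step + 1L
      traj <- c(traj, sum(inf))
    }
    finals[r] <- sum(inf)
    trajs[[r]] <- traj
  }
  len <- max(lengths(trajs))
  padded <- vapply(trajs, function(t) c(t, rep(t[length(t)], len - length(t))),
                   numeric(len))
  structure(list(seeds = seeds, mean_infected = mean(finals),
                 final_counts = finals,
                 trajectory = if (len > 1) rowMeans(padded) else rep(mean(finals), 1L),
                 runs = config$runs, config = config),
            class = "si_spread")
}

#' @export
print.si_spread <- function(x, ...) {
  cat(sprintf("<si_spread: %d seed(s), %d runs, mean infected %.2f>\n",
              length(x$seeds), x$runs, x$mean_infected))
  invisible(x)
}

#' Compare ranked seed sets by spreading influence
#'
#' For every method and every `k`, seeds the SI process with the method's
#' top-`k` nodes and records the mean final infected count. All methods
#' share the same `config`, hence identical per-run RNG streams, so
#' differences between methods are variance-paired.
#'
#' @param net an [emi_network()].
#' @param rankings named list of rankings (anything [make_ranking()]
#'   accepts).
#' @param ks integer vector of seed-set sizes; at most the node count.
#' @param config an [si_config()].
#' @return Data frame with columns `method`, `k`, `mean_infected`, `sd`,
#'   `se`, `runs`.
#' @export
seed_set_experiment <- function(net, rankings, ks, config = si_config()) {
  stopifnot(is.list(rankings), length(rankings) >= 1L)
  if (is.null(names(rankings)) || any(names(rankings) == ""))
    stop("`rankings` must be a named list")
  if (max(ks) > length(net$nodes))
    stop(sprintf("k = %d exceeds the node count (%d)", max(ks), length(net$nodes)))
  rankings <- lapply(rankings, make_ranking)
  rows <- list()
  for (m in names(rankings)) {
    order_m <- .flatten_ranking(rankings[[m]])
    for (k in ks) {
      res <- si_run(net, utils::head(order_m, k), config)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, k = as.integer(k), mean_infected = res$mean_infected,
        sd = stats::sd(res$final_counts),
        se = stats::sd(res$final_counts) / sqrt(res$runs),
        runs = res$runs, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
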