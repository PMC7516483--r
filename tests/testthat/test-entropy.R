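test_that("multiset entropy follows the probability-normalised definition", {
  expect_equal(multiset_entropy(c(1, 1, 1)), log10(3), tolerance = 1e-12)
  # zeros contribute nothing (0 * log 0 convention)
  expect_equal(multiset_entropy(c(1, 1, 0)), log10(2), tolerance = 1e-12)
  expect_equal(multiset_entropy(5), 0)
  expect_equal(multiset_entropy(c(1, 1), base = 2), 1, tolerance = 1e-12)
  expect_error(multiset_entropy(c(0, 0)), "all-zero")
  expect_error(multiset_entropy(c(1, -1)), "non-negative")
})

test_that("multiset entropy agrees with the naive loop oracle on random multisets", {
  set.seed(42)
  for (i in 1:25) {
    v <- round(stats::runif(sample(2:12, 1), 0, 10), 3)
    v[sample(length(v), 1)] <- 0           # force a zero now and then
    if (sum(v) == 0) v[1] <- 1
    base <- sample(c(2, exp(1), 10), 1)
    expect_equal(multiset_entropy(v, base), entropy_oracle(v, base),
                 tolerance = 1e-12)
  }
})

test_that("structural entropy reproduces the worked example and closed forms", {
  net <- toy_network()
  sa <- structural_entropy(net, "a")
  expect_equal(round(sa[["S"]], 4), 0.7782)
  expect_equal(sa[["S_in"]], log10(3), tolerance = 1e-12)   # degrees {1,1,1}
  expect_equal(sa[["S_out"]], log10(2), tolerance = 1e-12)  # degrees {1,1,0}
  expect_equal(round(structural_entropy(net, "b")[["S"]], 4), 0.5775)

  # undirected star center: k uniform unit degrees
  star <- analytic_family("star", 8)
  expect_equal(structural_entropy(star, "v1")[["S"]], log10(7), tolerance = 1e-12)
  expect_true(is.na(structural_entropy(star, "v1")[["S_in"]]))
  # leaves see the single hub degree: no information
  expect_equal(structural_entropy(star, "v2")[["S"]], 0)

  iso <- emi_network(data.frame(from = "a", to = "b"), nodes = c("a", "b", "z"))
  expect_warning(sz <- structural_entropy(iso, "z"), "isolated")
  expect_equal(sz[["S"]], 0)
})

test_that("interactive entropy reproduces the worked example and the unit-weight identity", {
  net <- toy_network()
  expect_equal(round(interactive_entropy(net, "a")[["I"]], 4), 0.7073)
  expect_equal(round(interactive_entropy(net, "c")[["I"]], 4), 0.5040)
  expect_error(interactive_entropy(analytic_family("path", 4), "v2"),
               "not applicable")

  # all-unit weights: I must equal S for every node
  unet <- random_network(12, 0.3, directed = TRUE, seed = 5)
  wnet <- emi_network(unet$edges, nodes = unet$nodes, directed = TRUE,
                      weighted = TRUE)
  for (v in wnet$nodes) {
    s <- structural_entropy(wnet, v)
    i <- suppressWarnings(interactive_entropy(wnet, v))
    expect_equal(i[["I"]], s[["S"]], tolerance = 1e-12)
  }
})

test_that("mutual power matches the worked example, K3 and the formula oracle", {
  net <- toy_network()
  expect_equal(round(mutual_power(net, "a"), 5), -0.03876)
  expect_equal(round(mutual_power(net, "b"), 5), -0.05062)
  expect_equal(mutual_power(net, "d"), 0)

  # triangle: each neighbor pair shares exactly the third node
  k3 <- analytic_family("complete", 3)
  expect_equal(mutual_power(k3, "v1"), 2 * (1 / 4) * log10(3 / 4),
               tolerance = 1e-12)

  # non-positivity, and zero exactly when no neighbors are shared
  rnet <- random_network(20, 0.25, directed = TRUE, seed = 9)
  for (v in rnet$nodes) {
    mi <- mutual_power(rnet, v)
    expect_lte(mi, 0)
    nb <- neighbors_of(rnet, v)
    shares <- any(vapply(nb, function(j)
      length(intersect(nb, neighbors_of(rnet, j))) > 0, logical(1)))
    if (shares) expect_lt(mi, 0) else expect_equal(mi, 0)
  }
})

test_that("adding shared neighbors makes the hub penalty strictly worse", {
  mis <- vapply(0:5, function(s)
    mutual_power(overlap_pair_network(s, private_a = 5, private_b = 5), "hubA"),
    numeric(1))
  expect_equal(mis[1], 0)
  expect_true(all(diff(mis) < 0))
  # shared=1, no privates reduces to a triangle
  expect_equal(mutual_power(overlap_pair_network(1), "hubA"),
               mutual_power(analytic_family("complete", 3), "v1"),
               tolerance = 1e-12)
})

test_that("emi combines components per network type and sorts deterministically", {
  fit <- emi(toy_network())
  k <- coef(fit)
  expect_equal(names(k), c("a", "b", "c", "d"))           # ranking a > b > c > d
  expect_equal(round(unname(k[1:3]), 4), c(1.4467, 1.1064, 1.0309))
  expect_equal(unname(k["d"]), 0)                          # strict single-neighbor
  expect_equal(fit$scores$K,
               fit$scores$S + fit$scores$I + fit$scores$MI) # weighted combination

  # compat mode reproduces the published row for the leaf node
  kc <- coef(emi(toy_network(), emi_config(compat_single_neighbor = TRUE)))
  expect_equal(round(unname(kc["d"]), 4), 0.5976)
  expect_equal(names(kc), c("a", "b", "c", "d"))

  # single directed edge in strict mode: everything is zero
  ue <- emi_network(data.frame(from = "u", to = "v"), directed = TRUE)
  expect_equal(unname(coef(emi(ue))), c(0, 0))

  # unweighted: K = S + MI, I columns are NA
  fitu <- emi(analytic_family("star", 5))
  expect_true(all(is.na(fitu$scores$I)))
  expect_equal(fitu$scores$K, fitu$scores$S + fitu$scores$MI)

  # isolated nodes keep the ranking alive with K = 0
  iso <- emi_network(data.frame(from = "a", to = "b"), nodes = c("a", "b", "z"))
  expect_warning(fiti <- emi(iso), "isolated")
  expect_equal(unname(coef(fiti)["z"]), 0)
})

test_that("entropy components respect their log-size bounds", {
  nets <- list(random_network(15, 0.25, directed = TRUE, weighted = TRUE, seed = 21),
               random_network(15, 0.4, directed = FALSE, weighted = TRUE, seed = 22),
               random_network(15, 0.3, directed = TRUE, weighted = FALSE, seed = 23))
  for (net in nets) {
    fit <- suppressWarnings(emi(net))
    sc <- fit$scores
    sizes <- vapply(sc$node, function(v) length(neighbors_of(net, v)), integer(1))
    bound <- ifelse(sizes > 0, log10(sizes), 0)
    for (col in c("S_in", "S_out", "S", "I_in", "I_out", "I")) {
      vals <- sc[[col]]
      ok <- !is.na(vals)
      full_bound <- if (col %in% c("S", "I") && net$directed) 2 * bound else bound
      expect_true(all(vals[ok] >= -1e-12))
      expect_true(all(vals[ok] <= full_bound[ok] + 1e-12))
    }
  }
})

test_that("forcing unit weights onto an unweighted network doubles S in K", {
  unet <- random_network(14, 0.3, directed = TRUE, seed = 31)
  wnet <- emi_network(unet$edges, nodes = unet$nodes, directed = TRUE,
                      weighted = TRUE)
  fu <- suppressWarnings(emi(unet))
  fw <- suppressWarnings(emi(wnet))
  ku <- coef(fu)[sort(names(coef(fu)))]
  kw <- coef(fw)[sort(names(coef(fw)))]
  s <- stats::setNames(fu$scores$S, fu$scores$node)[names(ku)]
  expect_equal(kw, ku + s, tolerance = 1e-12)   # K_w = 2S + MI = K_u + S
  # the induced orders agree up to the extra S term's ties
  expect_equal(names(sort(-kw)), names(sort(-(ku + s))))
})

test_that("expert mutual-information reading only differs beyond one shared neighbor", {
  cfg2 <- emi_config(mi_terms = "common-squared")
  # worked example: all common-neighbor counts are 0 or 1, readings coincide
  net <- toy_network()
  for (v in net$nodes)
    expect_equal(mutual_power(net, v, cfg2), mutual_power(net, v))
  # two shared neighbors: the hub pair term (F = 2) is repeated F^2 = 4 times
  ov <- overlap_pair_network(2)
  # hubA neighbors {hubB, s1, s2}; hub pair shares {s1, s2}, each leaf pair shares {hubB}
  hub_term <- (2 / 6) * log10(4 / 6)
  leaf_term <- (1 / 5) * log10(4 / 5)
  expect_equal(mutual_power(ov, "hubA"), hub_term + 2 * leaf_term,
               tolerance = 1e-12)
  expect_equal(mutual_power(ov, "hubA", cfg2), 4 * hub_term + 2 * leaf_term,
               tolerance = 1e-12)
})
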