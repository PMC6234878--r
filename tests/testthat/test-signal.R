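test_that("the star-tree scenario is non-significant by construction", {
  tr <- simulate_bd_tree(1, 0, 20, seed = 51)
  Q <- sym_q(0.3 / tree_height(tr), 2)
  d <- simulate_mk(tr, Q, 1, seed = 52)
  res <- lambda_signal_test(tr, d, lambdas = 0, n_perm = 99, seed = 3)
  expect_equal(res$p, 1)
})

test_that("clustered characters yield small p at lambda = 1", {
  # strong clustering: low-rate simulation on a reasonably large tree,
  # skipping draws that come out nearly constant (no power by construction)
  hits_lam <- 0
  n_used <- 0
  i <- 0
  while (n_used < 5 && i < 20) {
    i <- i + 1
    tr <- simulate_bd_tree(1, 0, 60, seed = 60 + i)
    Q <- sym_q(0.35 / tree_height(tr), 2)
    d <- simulate_mk(tr, Q, 1, seed = 70 + i)
    if (min(table(d$state)) < 10) next
    n_used <- n_used + 1
    res <- lambda_signal_test(tr, d, lambdas = 1, n_perm = 199, seed = i)
    if (res$p <= 0.05) hits_lam <- hits_lam + 1
  }
  expect_equal(n_used, 5)
  expect_gte(hits_lam, 4)
})

test_that("a perfect two-clade split maximizes distance-test signal", {
  # two-state character split across the two root clades of a balanced tree
  tr <- ape::stree(16, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  root <- ape::Ntip(tr) + 1L
  kids <- tr$edge[tr$edge[, 1] == root, 2]
  left <- phyniche:::clade_tips(tr, kids[1])
  d <- char_from_vector(
    setNames(ifelse(tr$tip.label %in% left, "a", "b"), tr$tip.label),
    c("a", "b"))
  hits <- 0
  for (i in 1:10) {
    res <- tiptip_distance_test(tr, d, n_perm = 999, seed = 500 + i)
    # a permutation can reproduce the perfect split exactly (an exact tie),
    # so "below every permuted mean" allows p up to (1 + ties) / 1000
    if (res$p[res$state == "pooled"] <= 3 / 1000) hits <- hits + 1
  }
  expect_gte(hits, 9) # at least 95% of runs at the permutation floor
})

test_that("constant characters are flagged untestable", {
  tr <- simulate_bd_tree(1, 0, 12, seed = 81)
  d <- char_from_vector(setNames(rep("a", 12), tr$tip.label), c("a", "b"))
  res <- lambda_signal_test(tr, d, lambdas = c(0.5, 1), n_perm = 99, seed = 1)
  expect_true(all(res$untestable))
  res2 <- tiptip_distance_test(tr, d, n_perm = 99, seed = 1)
  expect_true(all(res2$untestable[res2$state %in% c("a", "pooled")]))
})

test_that("per-state distance statistic matches hand values and an exhaustive null", {
  # two sister tips carrying a private state: statistic = 2 x pendant depth
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:2,E:2):1,F:3);")
  d <- char_from_vector(c(A = "x", B = "x", C = "y", D = "y", E = "y", F = "y"),
                        c("x", "y"))
  res <- tiptip_distance_test(tr, d, n_perm = 999, seed = 2)
  expect_equal(unname(res$statistic[res$state == "x"]), 2)

  # exhaustive oracle: all C(6,2) = 15 placements of the x-pair
  D <- cophenetic_matrix(tr)
  null_stats <- utils::combn(rownames(D), 2, function(p) D[p[1], p[2]])
  p_exact <- mean(null_stats <= 2 + 1e-9)
  expect_lt(abs(res$p[res$state == "x"] - p_exact), 0.05)
})

test_that("signal tests are invariant to state relabeling", {
  tr <- simulate_bd_tree(1, 0, 25, seed = 91)
  Q <- sym_q(0.4 / tree_height(tr), 2)
  d <- simulate_mk(tr, Q, 1, seed = 92)
  relab <- d
  relab$state <- c(a = "zz", b = "aa")[relab$state]
  attr(relab, "states") <- c("zz", "aa")
  r1 <- lambda_signal_test(tr, d, lambdas = 1, n_perm = 99, seed = 7)
  r2 <- lambda_signal_test(tr, relab, lambdas = 1, n_perm = 99, seed = 7)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)

  s1 <- tiptip_distance_test(tr, d, n_perm = 99, seed = 7)
  s2 <- tiptip_distance_test(tr, relab, n_perm = 99, seed = 7)
  expect_equal(s1$p[s1$state == "pooled"], s2$p[s2$state == "pooled"])
})

test_that("multi-tree summaries report the fraction significant", {
  base <- simulate_bd_tree(1, 0, 30, seed = 95)
  trees <- simulate_posterior_set(base, 5, jitter = 0.05, seed = 6)
  Q <- sym_q(0.3 / tree_height(base), 2)
  d <- simulate_mk(base, Q, 1, seed = 96)
  stopifnot(length(unique(d$state)) == 2) # fixture sanity
  res <- lambda_signal_test(trees, d, lambdas = c(0, 1), n_perm = 99, seed = 8)
  expect_equal(nrow(res), 10)
  smry <- signal_summary(res)
  expect_equal(smry$n_trees, c(5, 5))
  expect_equal(smry$frac_significant[smry$lambda == 0], 0)
})
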