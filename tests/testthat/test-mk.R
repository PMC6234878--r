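test_that("model templates expose the expected free-parameter counts", {
  expect_equal(mk_model(2, "ER")$n_par, 1)
  expect_equal(mk_model(5, "SYM")$n_par, 10)
  expect_equal(mk_model(5, "ARD")$n_par, 20)
  expect_error(mk_model(5, "custom", mask = matrix(0L, 3, 3)),
               class = "phyniche_validation_error")
  # custom mask with an absorbing row is legal
  m <- matrix(0L, 3, 3)
  m[2, 1] <- 1L; m[2, 3] <- 2L; m[3, 1] <- 3L; m[3, 2] <- 4L
  expect_equal(mk_model(3, "custom", mask = m)$n_par, 4)
})

test_that("transition probabilities match closed forms and the semigroup law", {
  Q <- sym_q(0.4)
  expect_equal(transition_probabilities(Q, 0), diag(2), ignore_attr = TRUE)
  for (t in c(0.1, 0.9, 3.7)) {
    P <- transition_probabilities(Q, t)
    expect_equal(P[1, 1], 0.5 * (1 + exp(-2 * 0.4 * t)), tolerance = 1e-10)
    expect_equal(P[1, 2], 0.5 * (1 - exp(-2 * 0.4 * t)), tolerance = 1e-10)
    expect_equal(rowSums(P), c(a = 1, b = 1), tolerance = 1e-12)
  }
  # equal-rates 5-state chain forgets its origin
  P <- transition_probabilities(sym_q(0.5, 5), 50)
  expect_equal(as.vector(P), rep(0.2, 25), tolerance = 1e-8)

  withr::local_seed(42)
  for (i in 1:5) {
    Q <- random_q(4)
    t1 <- runif(1, 0.1, 1)
    t2 <- runif(1, 0.1, 1)
    expect_equal(transition_probabilities(Q, t1 + t2),
                 transition_probabilities(Q, t1) %*%
                   transition_probabilities(Q, t2),
                 tolerance = 1e-10)
  }
  expect_error(transition_probabilities(Q, -1),
               class = "phyniche_validation_error")
})

test_that("pruning likelihood handles limits, hand sums and polytomies", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  same <- char_from_vector(c(A = "a", B = "a"), c("a", "b"))
  expect_equal(prune_loglik(tr, same, sym_q(1e-12)), log(0.5),
               tolerance = 1e-6)

  diff <- char_from_vector(c(A = "a", B = "b"), c("a", "b"))
  P <- transition_probabilities(sym_q(0.5), 1)
  expect_equal(prune_loglik(tr, diff, sym_q(0.5)),
               log(sum(0.5 * P[, 1] * P[, 2])), tolerance = 1e-12)

  # polytomies natively (checked against the enumeration oracle)
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  withr::local_seed(7)
  Q <- random_q(3)
  d <- char_from_vector(c(A = "a", B = "b", C = "c", D = "a"), letters[1:3])
  expect_equal(prune_loglik(poly, d, Q),
               enum_loglik(poly, d, Q, letters[1:3]), tolerance = 1e-9)
  expect_lte(prune_loglik(poly, d, Q), 0)

  # missing tip in the character table is an error
  expect_error(prune_loglik(tr, char_from_vector(c(A = "a"), c("a", "b")),
                            sym_q(0.5)),
               class = "phyniche_validation_error")
})

test_that("likelihood is invariant to tip order and rerooting for ER/SYM", {
  withr::local_seed(13)
  tr <- simulate_bd_tree(1, 0, 10, seed = 2)
  states <- letters[1:3]
  d <- simulate_mk(tr, random_q(3), 1, seed = 3)
  Q <- sym_q(0.3, 3)

  shuffled <- d[sample.int(nrow(d)), ]
  expect_equal(prune_loglik(tr, d, Q), prune_loglik(tr, shuffled, Q))

  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(prune_loglik(tr, d, Q), prune_loglik(rot, d, Q),
               tolerance = 1e-12)

  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[5],
                        resolve.root = TRUE)
  expect_equal(prune_loglik(tr, d, Q), prune_loglik(rerooted, d, Q),
               tolerance = 1e-8)
})

test_that("ML fits respect nesting, box bounds and no-signal limits", {
  tr <- simulate_bd_tree(1, 0.2, 40, seed = 6)
  h <- tree_height(tr)
  d <- simulate_mk(tr, random_q(3, lo = 0.2 / h, hi = 0.5 / h), 1, seed = 10)
  skip_if(length(unique(d$state)) < 2)

  f_er <- fit_mk(tr, d, "ER", n_restarts = 3, seed = 1)
  f_sym <- fit_mk(tr, d, "SYM", n_restarts = 3, seed = 1)
  f_ard <- fit_mk(tr, d, "ARD", n_restarts = 3, seed = 1)
  expect_true(all(f_er$converged, f_sym$converged, f_ard$converged))
  expect_gte(f_sym$loglik, f_er$loglik - 1e-6)
  expect_gte(f_ard$loglik, f_sym$loglik - 1e-6)
  expect_equal(f_ard$AIC, 2 * 6 - 2 * f_ard$loglik)

  const <- char_from_vector(setNames(rep("a", 40), tr$tip.label),
                            c("a", "b", "c"))
  f0 <- fit_mk(tr, const, "ER")
  expect_lt(f0$rates, 1e-7) # pinned at the lower box bound
  expect_equal(f0$loglik, log(1 / 3), tolerance = 1e-4)
})

test_that("ER rate recovery works at simulation scale", {
  q_true <- 0.3
  hits <- 0
  for (i in 1:20) {
    tr <- simulate_bd_tree(1, 0, 200, seed = 100 + i)
    # scale the tree to height 1 so q is per unit height
    tr$edge.length <- tr$edge.length / tree_height(tr)
    d <- simulate_mk(tr, sym_q(q_true), 1, seed = 200 + i)
    if (length(unique(d$state)) < 2) next
    f <- fit_mk(tr, d, "ER")
    if (f$converged && f$rates >= 0.15 && f$rates <= 0.6) hits <- hits + 1
  }
  expect_gte(hits, 18) # >= 90% of 20 replicates
})

test_that("marginal reconstructions match Bayes and enumeration oracles", {
  # degenerate limit: constant data, vanishing rate
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  same <- char_from_vector(c(A = "a", B = "a", C = "a"), c("a", "b"))
  asr <- marginal_asr(tr, same, sym_q(1e-10))
  expect_true(all(asr$prob[asr$state == "a"] > 1 - 1e-6))

  # 2-tip tree: explicit Bayes computation over root states
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  d2 <- char_from_vector(c(A = "a", B = "b"), c("a", "b"))
  Q <- sym_q(0.5)
  P <- transition_probabilities(Q, 1)
  post <- c(0.5 * P[1, 1] * P[1, 2], 0.5 * P[2, 1] * P[2, 2])
  post <- post / sum(post)
  asr2 <- marginal_asr(tr2, d2, Q)
  expect_equal(asr2$prob, post, tolerance = 1e-10)

  # 5-tip tree, k = 3: every node against restricted enumeration
  withr::local_seed(31)
  tr5 <- simulate_bd_tree(1, 0, 5, seed = 44)
  Q3 <- random_q(3)
  d5 <- simulate_mk(tr5, Q3, 2, seed = 45)
  asr5 <- marginal_asr(tr5, d5, Q3)
  for (node in unique(asr5$node)) {
    expect_equal(asr5$prob[asr5$node == node],
                 enum_marginal(tr5, d5, Q3, letters[1:3], node),
                 tolerance = 1e-9)
  }
  sums <- tapply(asr5$prob, asr5$node, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("mk fits agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_bd_tree(1, 0, 30, seed = 77)
  d <- simulate_mk(tr, sym_q(0.5 / tree_height(tr), 3), 1, seed = 78)
  skip_if(length(unique(d$state)) < 2)
  x <- setNames(d$state, d$species)
  ref <- phytools::fitMk(tr, x[tr$tip.label], model = "ER", pi = "equal")
  f <- fit_mk(tr, d, "ER", states = sort(unique(d$state)))
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("no-switch enumeration yields absorbing-subset masks", {
  expect_length(enumerate_noswitch_models(2), 2)
  ms3 <- enumerate_noswitch_models(3)
  expect_length(ms3, 6)
  for (m in ms3) {
    S <- match(m$absorbing, m$states)
    expect_true(all(m$mask[S, ] == 0)) # constrained rows exactly zero
    free_rows <- setdiff(seq_len(3), S)
    for (r in free_rows) {
      expect_true(all(m$mask[r, -r] > 0)) # remaining rates all free
    }
  }
  # deterministic ordering: singletons first, lexicographic
  ids <- vapply(enumerate_noswitch_models(3, states = c("x", "y", "z")),
                function(m) m$id, character(1))
  expect_equal(ids[1:3], c("ns_x", "ns_y", "ns_z"))
  expect_equal(ids[4], "ns_x+y")
})

test_that("model masks survive a JSON round trip", {
  m <- enumerate_noswitch_models(4)[[7]]
  back <- model_from_json(model_to_json(m))
  expect_equal(back$mask, m$mask)
  expect_equal(back$id, m$id)
  expect_equal(back$n_par, m$n_par)
})
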