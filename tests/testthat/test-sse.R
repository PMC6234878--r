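test_that("parameter containers validate their invariants", {
  expect_error(musse_params(c(0, 1)), class = "phyniche_validation_error")
  expect_error(musse_params(1, mu = -0.1), class = "phyniche_validation_error")
  expect_error(musse_params(1, rho = 1.2), class = "phyniche_validation_error")
  p <- musse_params(c(0.1, 0.3), c(0.05, 0.1), q = 0.02,
                    states = c("x", "y"))
  expect_equal(unname(p$lambda - p$mu), c(0.05, 0.2))
})

test_that("sampling fractions enter the tip conditions", {
  tr <- simulate_bd_tree(1, 0, 20, seed = 161)
  Q <- sym_q(0.3 / tree_height(tr), 2)
  d <- simulate_mk(tr, Q, 1, seed = 162)
  p1 <- musse_params(c(0.5, 0.5), c(0.1, 0.1), 0.1, rho = 1,
                     states = c("a", "b"))
  p5 <- musse_params(c(0.5, 0.5), c(0.1, 0.1), 0.1, rho = 0.5,
                     states = c("a", "b"))
  expect_false(isTRUE(all.equal(musse_loglik(tr, d, p1),
                                musse_loglik(tr, d, p5))))
  # E(0) initial condition equals 1 - rho
  y <- phyniche:::sse_branch_cpp(c(0.5, 0.5, 1, 0), 0, c(0.5, 0.5),
                                 c(0.1, 0.1), matrix(c(0, .1, .1, 0), 2, 2),
                                 1e-8, 1e-10)
  expect_equal(y[1:2], c(0.5, 0.5))
})

test_that("polytomies and non-ultrametric trees are rejected", {
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  d <- char_from_vector(c(A = "a", B = "a", C = "b", D = "b"), c("a", "b"))
  p <- musse_params(c(0.5, 0.5), 0, 0.1, states = c("a", "b"))
  expect_error(musse_loglik(poly, d, p), class = "phyniche_validation_error")
  nonu <- ape::read.tree(text = "((A:1,B:2):1,D:2);")
  d2 <- char_from_vector(c(A = "a", B = "a", D = "b"), c("a", "b"))
  expect_error(musse_loglik(nonu, d2, p), class = "phyniche_validation_error")
})

test_that("likelihood responds smoothly to parameter perturbation", {
  tr <- simulate_bd_tree(1, 0, 25, seed = 171)
  Q <- sym_q(0.3 / tree_height(tr), 2)
  d <- simulate_mk(tr, Q, 1, seed = 172)
  ll_at <- function(lam1) {
    p <- musse_params(c(lam1, 0.4), c(0.05, 0.05), 0.05, states = c("a", "b"))
    musse_loglik(tr, d, p, rtol = 1e-10, atol = 1e-13)
  }
  # central finite differences at two step sizes agree (smooth surface)
  g1 <- (ll_at(0.3 + 1e-4) - ll_at(0.3 - 1e-4)) / 2e-4
  g2 <- (ll_at(0.3 + 5e-5) - ll_at(0.3 - 5e-5)) / 1e-4
  expect_equal(g1, g2, tolerance = 1e-3)
})

test_that("mu fixed at zero is respected exactly", {
  tr <- simulate_bd_tree(1, 0, 20, seed = 181)
  Q <- sym_q(0.3 / tree_height(tr), 2)
  d <- simulate_mk(tr, Q, 1, seed = 182)
  f <- fit_musse(tr, d, constraints = list(lambda = "free", mu = "zero",
                                           q = "free"),
                 n_restarts = 1, seed = 1)
  expect_true(f$converged)
  expect_true(all(f$params$mu == 0))
})

test_that("Mann-Whitney comparisons match enumeration and symmetry", {
  res <- compare_rates(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0, ignore_attr = TRUE)
  expect_equal(res$p, 0.1) # exact: 2 / C(6,3)
  same <- compare_rates(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8, ignore_attr = TRUE) # n^2 / 2
  expect_gt(same$p, 0.9)
  tied <- compare_rates(rep(2, 5), rep(2, 5))
  expect_equal(tied$p, 1)
  expect_match(tied$note, "tied")
  # large separated samples are decisively different
  withr::local_seed(3)
  expect_lt(compare_rates(rnorm(200), rnorm(200, 3))$p, 0.01)
})

test_that("pooled density bookkeeping and degenerate centering", {
  draws <- tibble::tibble(iteration = 1:50, lnL = 0,
                          lambda_a = runif(50, .4, .6),
                          lambda_b = runif(50, .4, .6))
  draws$mu_a <- draws$lambda_a # lambda = mu -> r = 0
  draws$mu_b <- draws$lambda_b
  class(draws) <- c("musse_posterior", class(draws))
  attr(draws, "states") <- c("a", "b")
  dens1 <- diversification_density(draws)
  expect_true(all(abs(dens1$summary$mean) < 1e-12))
  # pooling two samples of n1, n2 draws gives n1 + n2 pooled draws
  dens2 <- diversification_density(list(draws, draws[1:20, ]))
  expect_equal(unique(dens2$summary$n), 70)
})

test_that("MCMC chains are deterministic under a seed", {
  tr <- simulate_bd_tree(1, 0, 15, seed = 191)
  Q <- sym_q(0.3 / tree_height(tr), 2)
  d <- simulate_mk(tr, Q, 1, seed = 192)
  c1 <- musse_mcmc(tr, d, n_steps = 200, seed = 12, prior_only = TRUE)
  c2 <- musse_mcmc(tr, d, n_steps = 200, seed = 12, prior_only = TRUE)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("trait-independence scaffolding validates and reports per q", {
  tr <- simulate_bd_tree(1, 0, 16, seed = 201)
  expect_error(trait_independence_test(tr, 1, n_sims = 0),
               class = "phyniche_validation_error")
  expect_error(trait_independence_test(tr, -1, n_sims = 2),
               class = "phyniche_validation_error")
  res <- trait_independence_test(tr, q_values = c(0.5, 2), n_sims = 2,
                                 seed = 9, n_restarts = 1)
  expect_equal(res$q, c(0.5, 2))
  expect_true(all(res$rate >= 0 & res$rate <= 1))
})
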