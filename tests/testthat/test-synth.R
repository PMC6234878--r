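test_that("birth-death trees have the requested shape and are reproducible", {
  tr <- simulate_bd_tree(1, 0.3, 50, seed = 301)
  expect_equal(ape::Ntip(tr), 50)
  expect_equal(tr$Nnode, 49)
  expect_true(ape::is.binary.phylo(tr))
  expect_true(is_ultrametric(tr))
  expect_true(all(tr$edge.length > 0))
  tr2 <- simulate_bd_tree(1, 0.3, 50, seed = 301)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  cfg <- attr(tr, "sim_config")
  expect_equal(cfg$seed, 301)
  expect_error(simulate_bd_tree(0.2, 0.5, 10),
               class = "phyniche_validation_error")
})

test_that("Yule lineage counts match an independent forward simulator", {
  # statistic: number of lineages alive at half the tree height
  lineages_at_half <- function(tree) {
    h <- tree_height(tree)
    depth <- ape::node.depth.edgelength(tree)
    sum(depth[tree$edge[, 1]] <= h / 2 & depth[tree$edge[, 2]] > h / 2)
  }
  n_rep <- 150
  mine <- vapply(seq_len(n_rep), function(i) {
    lineages_at_half(simulate_bd_tree(1, 0, 20, seed = 1000 + i))
  }, numeric(1))

  # independent oracle: bare-bones forward Yule with the same stopping rule.
  # The reconstructed tree starts at the first split (the root stem is
  # absorbed), so lineages are counted at first_split + height / 2.
  oracle_one <- function() {
    birth <- c(0); death <- c(NA_real_); alive <- 1L
    tt <- 0; first_split <- NA_real_
    repeat {
      n <- length(alive)
      dt <- rexp(1, n * 1)
      if (n == 20L) {
        stop_t <- tt + runif(1) * dt
        tau <- first_split + (stop_t - first_split) / 2
        return(sum(birth <= tau & (is.na(death) | death > tau)))
      }
      tt <- tt + dt
      li <- alive[sample.int(n, 1)]
      if (is.na(first_split)) first_split <- tt
      death[li] <- tt
      birth <- c(birth, tt, tt)
      death <- c(death, NA, NA)
      alive <- c(setdiff(alive, li), length(birth) - 1L, length(birth))
    }
  }
  withr::local_seed(77)
  theirs <- vapply(seq_len(n_rep), function(i) oracle_one(), numeric(1))
  se <- sqrt(stats::var(mine) / n_rep + stats::var(theirs) / n_rep)
  expect_lt(abs(mean(mine) - mean(theirs)), 3 * se)
})

test_that("Mk simulation hits its closed-form flip probability", {
  # single branch of length t: P(tip differs from root) = (1 - e^(-2qt)) / 2
  q <- 0.4; t <- 1.3
  tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t, t))
  Q <- sym_q(q)
  n_rep <- 4000
  withr::local_seed(5)
  flips <- vapply(seq_len(n_rep), function(i) {
    d <- simulate_mk(tr, Q, 1)
    d$state[d$species == "A"] != "a"
  }, logical(1))
  p_true <- 0.5 * (1 - exp(-2 * q * t))
  se <- sqrt(p_true * (1 - p_true) / n_rep)
  expect_lt(abs(mean(flips) - p_true), 3 * se)

  # zero rates: everything stays in the root state
  tr10 <- simulate_bd_tree(1, 0, 10, seed = 311)
  d0 <- simulate_mk(tr10, sym_q(0), 2, seed = 1)
  expect_true(all(d0$state == "b"))
})

test_that("retained histories are consistent chains along each edge", {
  tr <- simulate_bd_tree(1, 0, 15, seed = 321)
  Q <- sym_q(1.2 / tree_height(tr), 3)
  d <- simulate_mk(tr, Q, 1, seed = 322, keep_history = TRUE)
  hist <- attr(d, "history")
  nodes <- attr(d, "node_states")
  po <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    ev <- hist[hist$edge == e, ]
    from <- nodes[po$edge[e, 1]]
    if (nrow(ev) > 0) {
      expect_equal(ev$from[1], from)
      if (nrow(ev) > 1) expect_equal(ev$from[-1], ev$to[-nrow(ev)])
      expect_equal(utils::tail(ev$to, 1), nodes[po$edge[e, 2]])
    } else {
      expect_equal(nodes[po$edge[e, 2]], from)
    }
  }
})

test_that("state-dependent simulation responds to rate asymmetry", {
  # neutral case: tip-state frequencies close to a plain Mk simulation
  p_neutral <- musse_params(c(0.3, 0.3), c(0, 0), q = 0.4,
                            states = c("a", "b"))
  freq_a <- vapply(1:30, function(i) {
    sim <- simulate_musse(p_neutral, 40, seed = 400 + i)
    mean(sim$data$state == "a")
  }, numeric(1))
  expect_gt(mean(freq_a), 0.35)
  expect_lt(mean(freq_a), 0.65)

  # high-lambda state overrepresented among tips
  p_asym <- musse_params(c(0.1, 0.4), c(0, 0), q = 0.02,
                         states = c("a", "b"))
  freq_b <- vapply(1:30, function(i) {
    sim <- simulate_musse(p_asym, 40, seed = 500 + i, root_state = 1)
    mean(sim$data$state == "b")
  }, numeric(1))
  expect_gt(mean(freq_b), 0.5)

  # rho subsampling thins roughly binomially
  p_rho <- musse_params(c(0.3, 0.3), c(0, 0), q = 0.3, rho = 0.5,
                        states = c("a", "b"))
  kept <- vapply(1:20, function(i) {
    ape::Ntip(simulate_musse(p_rho, 60, seed = 600 + i,
                             subsample = TRUE)$tree)
  }, numeric(1))
  expect_lt(abs(mean(kept) - 30), 3 * sqrt(60 * 0.25 / 20) + 1)
})

test_that("posterior-set emulation preserves tips, depth and toggles", {
  base <- simulate_bd_tree(1, 0.2, 25, seed = 331)
  # jitter = 0, no NNI: identical copies
  same <- simulate_posterior_set(base, 4, jitter = 0, nni_prop = 0, seed = 2)
  for (tr in same) expect_identical(ape::write.tree(tr), ape::write.tree(base))

  jit <- simulate_posterior_set(base, 10, jitter = 0.1, nni_prop = 0.2,
                                seed = 3)
  edited <- attr(jit, "edited")
  expect_equal(sum(edited), 2)
  for (i in seq_along(jit)) {
    expect_true(is_ultrametric(jit[[i]]))
    expect_setequal(jit[[i]]$tip.label, base$tip.label)
    if (!edited[i]) {
      expect_equal(suppressWarnings(ape::dist.topo(jit[[i]], base)), 0,
                   ignore_attr = TRUE)
    }
  }
  # depths vary under jitter
  depths <- vapply(jit, tree_height, numeric(1))
  expect_gt(stats::sd(depths), 0)
})

test_that("generators can be regenerated byte-identically from metadata", {
  tr <- simulate_bd_tree(1.2, 0.4, 30, seed = 341)
  cfg <- attr(tr, "sim_config")
  tr2 <- simulate_bd_tree(cfg$birth, cfg$death, cfg$n_tips, seed = cfg$seed)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  Q <- sym_q(0.5, 3)
  d <- simulate_mk(tr, Q, 2, seed = 342)
  cfg_d <- attr(d, "sim_config")
  d2 <- simulate_mk(tr, cfg_d$Q, cfg_d$root_state, seed = cfg_d$seed)
  expect_identical(d$state, d2$state)
})
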