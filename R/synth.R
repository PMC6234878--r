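# Forward Gillespie simulation of a (state-dependent) birth-death process.
# Shared core of simulate_bd_tree (k = 1) and simulate_musse. Simulates until
# the number of extant lineages first reaches n_tips, then extends all extant
# lineages by u * dt (u ~ U(0,1), dt the next exponential waiting time) so
# pendant edges are never zero; retries on total extinction.
sim_forward <- function(lambda, mu, Qo, root_state, n_tips, max_attempts = 1000) {
  k <- length(lambda)
  qout <- rowSums(Qo)
  for (attempt in seq_len(max_attempts)) {
    parent <- c(NA_integer_)
    t_birth <- c(0)
    t_end <- c(NA_real_)
    fate <- c(NA_integer_) # 1 split, 2 death, 3 extant
    state_now <- c(root_state)
    lineage_state <- c(root_state) # state at end of lineage
    active <- 1L
    tt <- 0
    repeat {
      n_active <- length(active)
      if (n_active == 0L) break # extinction; retry
      rates <- lambda[state_now[active]] + mu[state_now[active]] +
        qout[state_now[active]]
      total <- sum(rates)
      dt <- rexp(1, total)
      if (n_active == n_tips) {
        stop_t <- tt + runif(1) * dt
        t_end[active] <- stop_t
        fate[active] <- 3L
        lineage_state[active] <- state_now[active]
        return(list(parent = parent, t_birth = t_birth, t_end = t_end,
                    fate = fate, state = lineage_state, attempts = attempt))
      }
      tt <- tt + dt
      li <- active[sample.int(n_active, 1L, prob = rates)]
      s <- state_now[li]
      ev <- sample.int(3L, 1L, prob = c(lambda[s], mu[s], qout[s]))
      if (ev == 1L) { # speciation: two daughters
        for (d in 1:2) {
          parent <- c(parent, li)
          t_birth <- c(t_birth, tt)
          t_end <- c(t_end, NA_real_)
          fate <- c(fate, NA_integer_)
          state_now <- c(state_now, s)
          lineage_state <- c(lineage_state, s)
        }
        t_end[li] <- tt
        fate[li] <- 1L
        lineage_state[li] <- s
        active <- c(setdiff(active, li),
                    length(parent) - 1L, length(parent))
      } else if (ev == 2L) { # extinction
        t_end[li] <- tt
        fate[li] <- 2L
        lineage_state[li] <- s
        active <- setdiff(active, li)
      } else { # character transition
        w <- Qo[s, ]
        state_now[li] <- sample.int(k, 1L, prob = w)
      }
    }
  }
  abort(paste0("forward simulation went extinct ", max_attempts,
               " times before reaching ", n_tips, " tips"),
        class = "phyniche_simulation_error")
}

# Convert forward-simulation records to a pruned phylo + tip states.
sim_to_phylo <- function(sim) {
  n <- length(sim$parent)
  kids <- split(seq_len(n), sim$parent[seq_len(n)])
  extant <- which(sim$fate == 3L)
  # lineages with at least one extant descendant
  keep <- logical(n)
  keep[extant] <- TRUE
  for (i in rev(seq_len(n))) { # children have larger ids than parents
    if (keep[i] && !is.na(sim$parent[i])) keep[sim$parent[i]] <- TRUE
  }
  tip_count <- 0L
  tip_states <- integer(0)
  build <- function(i, t_start) {
    # follow unifurcations downward
    repeat {
      ch <- keep_children(i)
      if (sim$fate[i] == 3L) {
        tip_count <<- tip_count + 1L
        tip_states <<- c(tip_states, sim$state[i])
        return(paste0("t", tip_count, ":",
                      format(sim$t_end[i] - t_start, digits = 12)))
      }
      if (length(ch) == 2L) {
        left <- build(ch[1], sim$t_end[i])
        right <- build(ch[2], sim$t_end[i])
        return(paste0("(", left, ",", right, "):",
                      format(sim$t_end[i] - t_start, digits = 12)))
      }
      i <- ch[1] # unifurcation: absorb into the same edge
    }
  }
  keep_children <- function(i) {
    ch <- kids[[as.character(i)]]
    if (is.null(ch)) integer(0) else ch[keep[ch]]
  }
  root <- 1L
  # absorb the root stem: start from the first kept node with 2 kept children
  newick <- build(root, 0)
  # strip the trailing root branch length and close
  newick <- sub(":[0-9.eE+-]+$", ";", newick)
  tree <- ape::read.tree(text = newick)
  list(tree = tree, tip_states = tip_states)
}

#' Simulate an ultrametric birth-death tree
#'
#' Forward Gillespie simulation conditioned on the number of extant tips by
#' reject-and-retry; the returned tree is binary, ultrametric, with exactly
#' `n_tips` extant tips.
#'
#' @param birth Speciation rate (> 0, and > `death`).
#' @param death Extinction rate (>= 0).
#' @param n_tips Number of extant tips (>= 3).
#' @param seed Seed making the simulation reproducible.
#' @return A `phylo`, with the generating configuration (including seed and
#'   retry count) in `attr(, "sim_config")`.
#' @export
simulate_bd_tree <- function(birth, death = 0, n_tips, seed = NULL) {
  if (!(birth > death && death >= 0)) {
    abort("need birth > death >= 0", class = "phyniche_validation_error")
  }
  if (n_tips < 3) abort("n_tips must be >= 3", class = "phyniche_validation_error")
  sim <- with_seed(seed, sim_forward(birth, death, matrix(0, 1, 1), 1L, n_tips))
  res <- sim_to_phylo(sim)
  tree <- res$tree
  attr(tree, "sim_config") <- list(generator = "simulate_bd_tree",
                                   birth = birth, death = death,
                                   n_tips = n_tips, seed = seed,
                                   attempts = sim$attempts)
  tree
}

#' Simulate a discrete character along a tree
#'
#' Continuous-time Markov simulation of tip states given a rate matrix,
#' branch by branch from the root state. The full change history can be
#' retained for cross-checking transition counts.
#'
#' @param tree A `phylo`.
#' @param Q Rate matrix (rows sum to 0); state names from its dimnames.
#' @param root_state State name or index at the root.
#' @param seed Seed.
#' @param keep_history Attach the per-edge event list as
#'   `attr(, "history")`.
#' @return A `character_data` tibble (`species`, `state`); simulation
#'   configuration in `attr(, "sim_config")`.
#' @export
simulate_mk <- function(tree, Q, root_state = 1, seed = NULL,
                        keep_history = FALSE) {
  Q <- as.matrix(Q)
  k <- nrow(Q)
  states <- rownames(Q) %||% paste0("s", seq_len(k))
  if (is.character(root_state)) root_state <- match(root_state, states)
  if (is.na(root_state) || root_state < 1 || root_state > k) {
    abort("root_state outside the state space",
          class = "phyniche_validation_error")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  ntot <- ntip + tr$Nnode
  edge <- tr$edge
  elen <- tr$edge.length
  ne <- nrow(edge)
  root <- edge[ne, 1]

  res <- with_seed(seed, {
    node_state <- integer(ntot)
    node_state[root] <- root_state
    events <- list()
    for (e in rev(seq_len(ne))) { # pre-order
      s <- node_state[edge[e, 1]]
      tt <- 0
      repeat {
        rate <- -Q[s, s]
        if (rate <= 0) break
        wait <- rexp(1, rate)
        if (tt + wait > elen[e]) break
        tt <- tt + wait
        w <- Q[s, ]
        w[s] <- 0
        s2 <- sample.int(k, 1L, prob = w)
        if (keep_history) {
          events[[length(events) + 1L]] <-
            c(edge = e, time = tt, from = s, to = s2)
        }
        s <- s2
      }
      node_state[edge[e, 2]] <- s
    }
    list(node_state = node_state, events = events)
  })

  out <- character_data(
    tibble(species = tr$tip.label,
           state = states[res$node_state[seq_len(ntip)]]),
    states = states, name = "simulated")
  attr(out, "sim_config") <- list(generator = "simulate_mk", Q = Q,
                                  root_state = root_state, seed = seed)
  if (keep_history) {
    hist <- if (length(res$events)) {
      m <- do.call(rbind, res$events)
      tibble(edge = m[, "edge"], time = m[, "time"],
             from = states[m[, "from"]], to = states[m[, "to"]])
    } else {
      tibble(edge = integer(0), time = numeric(0),
             from = character(0), to = character(0))
    }
    attr(out, "history") <- hist
    attr(out, "node_states") <- states[res$node_state]
  }
  out
}

#' Jointly simulate a tree and character under state-dependent rates
#'
#' Forward simulation in which each lineage speciates, goes extinct and
#' switches character state at rates set by its current state; the
#' reconstructed tree of extant tips plus their states is returned.
#' Optional per-state subsampling emulates incomplete taxon sampling.
#'
#' @param params A `musse_params` (its `rho` is used when
#'   `subsample = TRUE`).
#' @param n_tips Number of extant tips before subsampling (>= 10).
#' @param seed Seed.
#' @param root_state State name or index at the root (default: first state).
#' @param subsample Drop each tip with probability `1 - rho[state]`.
#' @return List with `tree` (`phylo`) and `data` (`character_data`).
#' @export
simulate_musse <- function(params, n_tips, seed = NULL, root_state = 1,
                           subsample = FALSE) {
  stopifnot(inherits(params, "musse_params"))
  if (n_tips < 10) abort("n_tips must be >= 10", class = "phyniche_validation_error")
  if (is.character(root_state)) root_state <- match(root_state, params$states)
  res <- with_seed(seed, {
    sim <- sim_forward(unname(params$lambda), unname(params$mu),
                       unname(params$q), as.integer(root_state), n_tips)
    out <- sim_to_phylo(sim)
    out$attempts <- sim$attempts
    if (subsample) {
      states_by_tip <- setNames(out$tip_states, out$tree$tip.label)
      keep_p <- params$rho[out$tip_states]
      keep <- runif(length(keep_p)) < keep_p
      if (sum(keep) < 3) {
        abort("subsampling left fewer than 3 tips",
              class = "phyniche_simulation_error")
      }
      out$tree <- ape::drop.tip(out$tree, out$tree$tip.label[!keep])
      out$tip_states <- unname(states_by_tip[out$tree$tip.label])
    }
    out
  })
  data <- character_data(
    tibble(species = res$tree$tip.label,
           state = params$states[res$tip_states]),
    states = params$states, name = "simulated")
  cfg <- list(generator = "simulate_musse", params = params, n_tips = n_tips,
              seed = seed, root_state = root_state, subsample = subsample,
              attempts = res$attempts)
  attr(res$tree, "sim_config") <- cfg
  attr(data, "sim_config") <- cfg
  list(tree = res$tree, data = data)
}

#' Emulate a posterior sample of trees
#'
#' Produces `n_trees` variants of a base ultrametric tree: internal-node ages
#' are jittered by i.i.d. lognormal noise (sigma = `jitter`) with parent-child
#' ordering repaired, preserving ultrametricity; optionally, a proportion of
#' trees additionally receives one rooted nearest-neighbour-interchange move,
#' providing topological variation. All trees share the tip set.
#'
#' @param tree Base ultrametric `phylo`.
#' @param n_trees Number of trees.
#' @param jitter Lognormal sigma for node-age noise (>= 0).
#' @param nni_prop Proportion of trees receiving one NNI move.
#' @param seed Seed.
#' @return A `multiPhylo`; `attr(, "edited")` flags the NNI-edited trees and
#'   `attr(, "sim_config")` records the configuration.
#' @export
simulate_posterior_set <- function(tree, n_trees = 100, jitter = 0.1,
                                   nni_prop = 0, seed = NULL) {
  if (jitter < 0) abort("jitter must be >= 0", class = "phyniche_validation_error")
  if (!is_ultrametric(tree)) {
    abort("base tree must be ultrametric", class = "phyniche_validation_error")
  }
  seeds <- spawn_seeds(seed, n_trees)
  n_edit <- round(nni_prop * n_trees)
  edited <- rep(c(TRUE, FALSE), c(n_edit, n_trees - n_edit))
  trees <- purrr::map(seq_len(n_trees), function(i) {
    with_seed(seeds[i], {
      tr <- tree
      if (edited[i]) tr <- rooted_nni(tr)
      if (jitter > 0) tr <- jitter_node_ages(tr, jitter)
      tr
    })
  })
  out <- structure(trees, class = "multiPhylo")
  attr(out, "edited") <- edited
  attr(out, "sim_config") <- list(generator = "simulate_posterior_set",
                                  n_trees = n_trees, jitter = jitter,
                                  nni_prop = nni_prop, seed = seed)
  out
}

# Multiply internal-node ages by lognormal noise, repair ordering, rebuild
# edge lengths; ultrametric by construction.
jitter_node_ages <- function(tree, sigma) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ntip)])
  age <- h - depth
  age[seq_len(ntip)] <- 0
  if (sigma > 0) {
    age[(ntip + 1):ntot] <- age[(ntip + 1):ntot] * rlnorm(tree$Nnode, 0, sigma)
  }
  # pre-order repair: child age strictly below parent age
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    if (c > ntip && age[c] >= age[p]) age[c] <- 0.999 * age[p]
  }
  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  out
}

# One rooted NNI move: swap a randomly chosen internal node's child subtree
# with its sibling ("aunt-niece" exchange), then repair node ages.
rooted_nni <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  edge <- tree$edge
  # candidate edges: internal parent -> internal child (child not root)
  cand <- which(edge[, 2] > ntip)
  if (length(cand) == 0) return(tree)
  e <- cand[sample.int(length(cand), 1L)]
  p <- edge[e, 1]; c <- edge[e, 2]
  sibs <- which(edge[, 1] == p & edge[, 2] != c) # rows: p -> sibling(s)
  kids <- which(edge[, 1] == c) # rows: c -> its children
  if (length(sibs) == 0 || length(kids) == 0) return(tree)
  se <- sibs[sample.int(length(sibs), 1L)]
  ke <- kids[sample.int(length(kids), 1L)]
  # swap: sibling moves under c, the chosen child moves under p
  z <- edge[se, 2]; x <- edge[ke, 2]
  edge[se, 2] <- x
  edge[ke, 2] <- z
  out <- tree
  out$edge <- edge
  # ages are preserved per node; repair ordering and rebuild lengths
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ntip)])
  age <- h - depth
  age[seq_len(ntip)] <- 0
  po <- ape::reorder.phylo(out, "postorder")$edge
  for (i in rev(seq_len(nrow(po)))) {
    pp <- po[i, 1]; cc <- po[i, 2]
    if (cc > ntip && age[cc] >= age[pp]) age[cc] <- 0.999 * age[pp]
  }
  out$edge.length <- age[out$edge[, 1]] - age[out$edge[, 2]]
  out
}

#' Bundle a synthetic study dataset
#'
#' One call producing a dataset at the scale of a typical multi-tree
#' comparative study: a 100-tip birth-death base tree, a five-state substrate
#' character with strong phylogenetic clustering (low-rate Mk), a binary
#' generalist/specialist character, and a 100-tree jittered posterior set.
#'
#' @param n_tips,n_trees Dataset scale.
#' @param seed Master seed.
#' @param ps_rate,gs_rate Mk simulation rates for the two characters (in
#'   units of expected changes per unit tree height).
#' @param jitter,nni_prop Posterior-set emulation settings.
#' @return List: `base_tree`, `trees`, `ps`, `gs`.
#' @export
demo_dataset <- function(n_tips = 100, n_trees = 100, seed = 1,
                         ps_rate = 0.15, gs_rate = 0.3,
                         jitter = 0.1, nni_prop = 0) {
  seeds <- spawn_seeds(seed, 4)
  base <- simulate_bd_tree(1, 0.3, n_tips, seed = seeds[1])
  h <- tree_height(base)
  k <- 5
  Qps <- matrix(ps_rate / h / (k - 1), k, k,
                dimnames = list(ps_states(), ps_states()))
  diag(Qps) <- -ps_rate / h
  Qgs <- matrix(gs_rate / h, 2, 2, dimnames = list(gs_states(), gs_states()))
  diag(Qgs) <- -gs_rate / h
  ps <- simulate_mk(base, Qps, root_state = "rock", seed = seeds[2])
  gs <- simulate_mk(base, Qgs, root_state = "specialist", seed = seeds[3])
  attr(ps, "char_name") <- "PS"
  attr(gs, "char_name") <- "GS"
  trees <- simulate_posterior_set(base, n_trees, jitter = jitter,
                                  nni_prop = nni_prop, seed = seeds[4])
  list(base_tree = base, trees = trees, ps = ps, gs = gs)
}
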