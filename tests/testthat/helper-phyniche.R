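# Shared fixture builders. Everything is generated in code; no binary data.

# Small named rate matrix with equal off-diagonal rates.
sym_q <- function(q, k = 2, states = letters[seq_len(k)]) {
  Q <- matrix(q, k, k, dimnames = list(states, states))
  diag(Q) <- -(k - 1) * q
  Q
}

# Random valid rate matrix with all rates free.
random_q <- function(k, states = letters[seq_len(k)], lo = 0.05, hi = 0.6) {
  Q <- matrix(stats::runif(k * k, lo, hi), k, k, dimnames = list(states, states))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Two-column character tibble from a named state vector.
char_from_vector <- function(x, states) {
  character_data(tibble::tibble(species = names(x), state = unname(x)),
                 states = states)
}

# Balanced ultrametric tree with 2^m tips, unit-depth levels.
balanced_tree <- function(m) {
  nwk <- "A"
  tree <- ape::stree(2^m, type = "balanced")
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree <- ape::reorder.phylo(tree)
  # equalize depths (stree balanced is already depth-uniform with unit edges)
  tree
}

# Brute-force likelihood by summing over all internal-state assignments,
# with transition probabilities from Matrix::expm (independent of the
# package's own P(t) machinery).
enum_loglik <- function(tree, data, Q, states, prior = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(po)
  nnode <- po$Nnode
  k <- nrow(Q)
  prior <- prior %||% rep(1 / k, k)
  Pm <- lapply(seq_len(nrow(po$edge)), function(e) {
    as.matrix(Matrix::expm(Q * po$edge.length[e]))
  })
  tipst <- match(data$state[match(po$tip.label, data$species)], states)
  root <- po$edge[nrow(po$edge), 1]
  grid <- expand.grid(rep(list(seq_len(k)), nnode))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asn <- c(tipst, as.integer(grid[g, ]))
    pr <- prior[asn[root]]
    for (e in seq_len(nrow(po$edge))) {
      pr <- pr * Pm[[e]][asn[po$edge[e, 1]], asn[po$edge[e, 2]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# As enum_loglik but returning the marginal distribution of one node.
enum_marginal <- function(tree, data, Q, states, node, prior = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(po)
  nnode <- po$Nnode
  k <- nrow(Q)
  prior <- prior %||% rep(1 / k, k)
  Pm <- lapply(seq_len(nrow(po$edge)), function(e) {
    as.matrix(Matrix::expm(Q * po$edge.length[e]))
  })
  tipst <- match(data$state[match(po$tip.label, data$species)], states)
  root <- po$edge[nrow(po$edge), 1]
  grid <- expand.grid(rep(list(seq_len(k)), nnode))
  out <- numeric(k)
  for (g in seq_len(nrow(grid))) {
    asn <- c(tipst, as.integer(grid[g, ]))
    pr <- prior[asn[root]]
    for (e in seq_len(nrow(po$edge))) {
      pr <- pr * Pm[[e]][asn[po$edge[e, 1]], asn[po$edge[e, 2]]]
    }
    out[asn[node]] <- out[asn[node]] + pr
  }
  out / sum(out)
}
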