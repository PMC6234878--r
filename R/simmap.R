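#' Sample stochastic character maps
#'
#' Draws complete character histories conditional on the tip data and a rate
#' matrix: node states are sampled from their joint conditional distribution
#' (post-order likelihoods, pre-order sampling), then each branch history is
#' drawn conditional on its endpoint states by uniformization (Poissonization
#' with dominating rate `max |Q_ii|`), with a forward rejection-sampling
#' fallback when the dominating rate times the branch length is below 1e-8.
#'
#' @inheritParams prune_loglik
#' @param n_maps Number of histories to draw (>= 1).
#' @param seed Seed making the draw reproducible.
#' @return A `stoch_map_set`: list of `stoch_map` objects, each holding
#'   per-branch `(state, dwell)` segments, sampled node states, and a k x k
#'   transition-count matrix.
#' @export
sample_maps <- function(tree, data, Q, n_maps = 100, seed = NULL,
                        root_prior = "uniform", states = NULL) {
  if (n_maps < 1) abort("n_maps must be >= 1", class = "phyniche_validation_error")
  states <- char_states(data, states)
  k <- length(states)
  if (nrow(Q) != k) {
    abort("Q dimension does not match the state space",
          class = "phyniche_validation_error")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  ntot <- ntip + tr$Nnode
  tipL <- tip_state_matrix(tr, data, states)
  edge <- tr$edge
  elen <- tr$edge.length
  ne <- nrow(edge)
  Qm <- unname(as.matrix(Q))

  Pm <- lapply(seq_len(ne), function(e) mk_pmat_cpp(Qm, elen[e], -1))

  # post-order conditional likelihoods (shared across maps)
  L <- matrix(1, ntot, k)
  L[seq_len(ntip), ] <- tipL
  for (e in seq_len(ne)) {
    v <- as.vector(Pm[[e]] %*% L[edge[e, 2], ])
    L[edge[e, 1], ] <- L[edge[e, 1], ] * (v / max(v))
  }
  root <- edge[ne, 1]
  prior <- if (identical(root_prior, "fitzjohn")) {
    L[root, ] / sum(L[root, ])
  } else if (is.numeric(root_prior)) root_prior else root_prior_vector(Q, root_prior)

  omega <- max(-diag(Qm), 1e-300)
  Rmat <- diag(k) + Qm / omega
  rpow <- new.env(parent = emptyenv()) # cache of R^n
  assign("p0", diag(k), envir = rpow)

  tip_state <- apply(tipL, 1, which.max)

  seeds <- spawn_seeds(seed, n_maps)
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    maps[[m]] <- with_seed(seeds[m], {
      draw_one_map(edge, elen, ne, ntip, ntot, root, k, L, Pm, prior,
                   Qm, omega, Rmat, rpow, tip_state)
    })
    maps[[m]]$replicate <- m
    maps[[m]]$seed <- seeds[m]
  }
  structure(maps, class = "stoch_map_set", states = states)
}

rmat_pow <- function(rpow, Rmat, n) {
  key <- paste0("p", n)
  if (!exists(key, envir = rpow, inherits = FALSE)) {
    assign(key, rmat_pow(rpow, Rmat, n - 1L) %*% Rmat, envir = rpow)
  }
  get(key, envir = rpow, inherits = FALSE)
}

draw_one_map <- function(edge, elen, ne, ntip, ntot, root, k, L, Pm, prior,
                         Qm, omega, Rmat, rpow, tip_state) {
  node_state <- integer(ntot)
  g <- prior * L[root, ]
  node_state[root] <- sample.int(k, 1L, prob = g)
  # pre-order: children conditional on sampled parent states
  for (e in rev(seq_len(ne))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    w <- Pm[[e]][node_state[p], ] * L[c, ]
    if (sum(w) <= 0) {
      abort("conditioning infeasible: endpoint pair has zero probability under Q",
            class = "phyniche_sampling_error")
    }
    node_state[c] <- sample.int(k, 1L, prob = w)
  }
  node_state[seq_len(ntip)] <- tip_state # tips are fixed by data

  counts <- matrix(0L, k, k)
  segs <- vector("list", ne)
  for (e in seq_len(ne)) {
    a <- node_state[edge[e, 1]]
    b <- node_state[edge[e, 2]]
    path <- sample_branch_path(a, b, elen[e], Qm, omega, Rmat, rpow,
                               Pm[[e]][a, b])
    segs[[e]] <- path
    st <- path$state
    if (length(st) > 1) {
      for (j in seq_len(length(st) - 1L)) {
        counts[st[j], st[j + 1L]] <- counts[st[j], st[j + 1L]] + 1L
      }
    }
  }
  structure(list(node_state = node_state, segments = segs, counts = counts,
                 edge = edge, elen = elen),
            class = "stoch_map")
}

# Conditional path on one branch via uniformization; returns collapsed
# (state, dwell) runs with dwell summing to t.
sample_branch_path <- function(a, b, t, Qm, omega, Rmat, rpow, pab) {
  if (t <= 0 || omega * t < 1e-8) {
    if (a != b) {
      # near-zero rate-time with distinct endpoints: fall back to forward
      # rejection sampling; infeasible conditioning surfaces as an error
      return(reject_branch_path(a, b, t, Qm, max_tries = 10000L))
    }
    return(list(state = a, dwell = t))
  }
  if (!(pab > 0)) {
    abort("conditioning infeasible: endpoint pair has zero probability under Q",
          class = "phyniche_sampling_error")
  }
  # number of uniformized (virtual + real) jumps
  u <- runif(1) * pab
  n <- -1L
  acc <- 0
  lpois <- -omega * t
  term <- exp(lpois) # Pois(n) * R^n[a,b], n = 0 term
  repeat {
    n <- n + 1L
    rn <- if (n == 0L) (a == b) * 1 else rmat_pow(rpow, Rmat, n)[a, b]
    acc <- acc + exp(lpois + n * log(omega * t) - lfactorial(n)) * rn
    if (acc >= u || n > 10000L) break
  }
  if (n == 0L) return(list(state = a, dwell = t))
  times <- sort(runif(n)) * t
  z <- integer(n + 1L)
  z[1] <- a
  if (n > 1L) {
    for (i in 2:n) {
      rem <- rmat_pow(rpow, Rmat, n - i + 1L)[, b]
      w <- Rmat[z[i - 1L], ] * rem
      z[i] <- sample.int(length(w), 1L, prob = w)
    }
  }
  z[n + 1L] <- b
  # collapse virtual (self) jumps into dwell segments
  bounds <- c(0, times, t)
  state <- z[1]
  dwell <- bounds[2] - bounds[1]
  for (i in seq_len(n)) {
    s <- z[i + 1L]
    len <- bounds[i + 2L] - bounds[i + 1L]
    if (s == state[length(state)]) {
      dwell[length(dwell)] <- dwell[length(dwell)] + len
    } else {
      state <- c(state, s)
      dwell <- c(dwell, len)
    }
  }
  list(state = state, dwell = dwell)
}

reject_branch_path <- function(a, b, t, Qm, max_tries = 10000L) {
  k <- nrow(Qm)
  for (try in seq_len(max_tries)) {
    st <- a; tt <- 0; state <- a; dwell <- numeric(0)
    seg_start <- 0
    repeat {
      rate <- -Qm[st, st]
      wait <- if (rate > 0) rexp(1, rate) else Inf
      if (tt + wait >= t) {
        dwell <- c(dwell, t - seg_start)
        break
      }
      tt <- tt + wait
      dwell <- c(dwell, tt - seg_start)
      seg_start <- tt
      w <- Qm[st, ]; w[st] <- 0
      st <- sample.int(k, 1L, prob = w)
      state <- c(state, st)
    }
    if (st == b) return(list(state = state, dwell = dwell))
  }
  abort("conditioning infeasible: rejection sampler exhausted",
        class = "phyniche_sampling_error")
}

#' @export
print.stoch_map_set <- function(x, ...) {
  cat("<stoch_map_set>", length(x), "maps,",
      length(attr(x, "states")), "states\n")
  invisible(x)
}

#' Tidy event list of a map set
#'
#' @param x A `stoch_map_set`.
#' @param ... Unused.
#' @return Tibble with one row per dwell segment: `map`, `edge`, `segment`,
#'   `state`, `dwell`.
#' @export
tidy.stoch_map_set <- function(x, ...) {
  states <- attr(x, "states")
  purrr::map_dfr(seq_along(x), function(m) {
    sm <- x[[m]]
    purrr::map_dfr(seq_along(sm$segments), function(e) {
      sg <- sm$segments[[e]]
      tibble(map = m, edge = e, segment = seq_along(sg$state),
             state = states[sg$state], dwell = sg$dwell)
    })
  })
}

#' Count transitions across stochastic maps
#'
#' Cumulative k x k transition-count matrix, per-map counts, and
#' per-direction summaries. For binary characters the per-map counts by
#' direction (with their means) reproduce the switch-count histograms used
#' to compare generalist-to-specialist versus specialist-to-generalist
#' transitions.
#'
#' @param maps A `stoch_map_set`.
#' @return A `transition_summary`: list with `cumulative` (k x k matrix),
#'   `per_map` (tibble: `map`, `from`, `to`, `n`), and `direction_means`
#'   (tibble: `from`, `to`, `mean_n`).
#' @export
count_transitions <- function(maps) {
  if (!inherits(maps, "stoch_map_set")) {
    abort("count_transitions expects a stoch_map_set",
          class = "phyniche_validation_error")
  }
  states <- attr(maps, "states")
  k <- length(states)
  cum <- matrix(0, k, k, dimnames = list(states, states))
  rows <- vector("list", length(maps))
  for (m in seq_along(maps)) {
    cm <- maps[[m]]$counts
    if (!all(dim(cm) == k)) {
      abort("maps with mixed state spaces", class = "phyniche_validation_error")
    }
    cum <- cum + cm
    idx <- which(row(cm) != col(cm), arr.ind = TRUE)
    rows[[m]] <- tibble(map = m, from = states[idx[, 1]], to = states[idx[, 2]],
                        n = cm[idx])
  }
  per_map <- dplyr::bind_rows(rows)
  dmeans <- per_map |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(mean_n = mean(.data$n), total = sum(.data$n),
                     .groups = "drop")
  structure(list(cumulative = cum, per_map = per_map,
                 direction_means = dmeans, n_maps = length(maps),
                 states = states),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary>", x$n_maps, "maps; cumulative counts:\n")
  print(x$cumulative)
  invisible(x)
}

#' @export
tidy.transition_summary <- function(x, ...) x$per_map
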