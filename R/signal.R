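# Permutation p-values use the add-one estimator (never zero):
# p = (1 + #{null at least as extreme}) / (1 + n_perm).
perm_p <- function(null, obs, direction = c("ge", "le"), tol = 1e-7) {
  direction <- match.arg(direction)
  n_extreme <- if (direction == "ge") sum(null >= obs - tol) else sum(null <= obs + tol)
  (1 + n_extreme) / (1 + length(null))
}

#' Phylogenetic-signal test via Pagel's lambda scenarios
#'
#' For each tree and each lambda scenario, the tree is lambda-transformed,
#' an equal-rates Mk model is fitted to the observed character
#' (`lnL_obs`), and the fit is repeated on `n_perm` tip-label permutations to
#' build a null distribution. The one-sided p-value asks whether the observed
#' data fit better than permuted data. Under `lambda = 0` the transformed
#' tree is a star phylogeny, the statistic is permutation-invariant, and the
#' p-value is 1 by construction.
#'
#' @param trees A `multiPhylo` (or single `phylo`) of ultrametric trees.
#' @param data Character data covering all tips.
#' @param lambdas Vector of lambda scenarios in \[0, 1\].
#' @param n_perm Number of permutations (>= 99).
#' @param seed Master seed; per-tree streams are derived from it.
#' @param states Optional explicit state space.
#' @return A tibble with one row per tree x scenario: `tree`, `lambda`,
#'   `statistic` (observed lnL), `p`, `n_perm`, `untestable`.
#' @export
lambda_signal_test <- function(trees, data, lambdas = c(0, 0.25, 0.5, 0.75, 1),
                               n_perm = 999, seed = NULL, states = NULL) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (n_perm < 99) abort("use at least 99 permutations",
                         class = "phyniche_validation_error")
  states <- char_states(data, states)
  constant <- length(unique(data$state)) < 2L
  tree_seeds <- spawn_seeds(seed, length(trees))

  out <- purrr::map_dfr(seq_along(trees), function(ti) {
    tree <- trees[[ti]]
    po_tips <- ape::reorder.phylo(tree, "postorder")$tip.label
    purrr::map_dfr(lambdas, function(lam) {
      if (constant) {
        return(tibble(tree = ti, lambda = lam, statistic = NA_real_,
                      p = NA_real_, n_perm = n_perm, untestable = TRUE))
      }
      tlam <- lambda_transform(tree, lam)
      po <- postorder_edges(tlam)
      tipL <- tip_state_matrix(
        structure(list(tip.label = po$tip.label), class = "phylo"),
        data, states)
      obs <- er_fit_loglik(po, tipL, length(states))
      null <- with_seed(tree_seeds[ti] + round(1e6 * lam), {
        vapply(seq_len(n_perm), function(i) {
          er_fit_loglik(po, tipL[sample.int(nrow(tipL)), , drop = FALSE],
                        length(states))
        }, numeric(1))
      })
      tibble(tree = ti, lambda = lam, statistic = obs,
             p = perm_p(null, obs, "ge"), n_perm = n_perm, untestable = FALSE)
    })
  })
  out
}

# Fast ER fit (Brent in log-rate space, closed-form P(t) in the C++ core).
er_fit_loglik <- function(po, tipL, k) {
  prior <- rep(1 / k, k)
  Qdummy <- matrix(0, k, k)
  neg <- function(logq) {
    ll <- mk_prune_cpp(po$edge, po$elen, po$ntip, po$nnode, tipL, Qdummy,
                       prior, FALSE, exp(logq))$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  -optimize(neg, c(log(1e-9), log(1e3)), tol = 1e-5)$objective
}

#' Phylogenetic-signal test via same-state cophenetic distances
#'
#' Statistic: mean patristic (cophenetic) distance over all unordered tip
#' pairs sharing a state, per state and pooled over states. The null is the
#' same statistic under tip-label permutation; the one-sided p-value asks
#' whether same-state tips are closer than expected ("closely related
#' species are ecologically similar"). States with fewer than two tips are
#' skipped with a note; per-state tip counts are reported so low-power
#' states are visible.
#'
#' @inheritParams lambda_signal_test
#' @return A tibble with one row per tree x (state or `"pooled"`):
#'   `tree`, `state`, `statistic`, `p`, `n_perm`, `n_tips`, `untestable`.
#' @export
tiptip_distance_test <- function(trees, data, n_perm = 999, seed = NULL,
                                 states = NULL) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (n_perm < 99) abort("use at least 99 permutations",
                         class = "phyniche_validation_error")
  states <- char_states(data, states)
  tree_seeds <- spawn_seeds(seed, length(trees))

  purrr::map_dfr(seq_along(trees), function(ti) {
    tree <- trees[[ti]]
    D <- cophenetic_matrix(tree)
    st <- data$state[match(rownames(D), data$species)]
    if (anyNA(st)) {
      abort("tips missing from character data",
            class = "phyniche_validation_error")
    }
    tab <- table(factor(st, levels = states))
    testable_states <- names(tab)[tab >= 2]
    all_same <- length(unique(st)) < 2L

    stat_fun <- function(labels) {
      per_state <- vapply(testable_states, function(s) {
        i <- which(labels == s)
        mean(D[i, i][upper.tri(D[i, i])])
      }, numeric(1))
      n_pairs <- vapply(testable_states, function(s) {
        n <- sum(labels == s); n * (n - 1) / 2
      }, numeric(1))
      pooled <- sum(per_state * n_pairs) / sum(n_pairs)
      c(per_state, pooled = pooled)
    }

    obs <- stat_fun(st)
    null <- with_seed(tree_seeds[ti], {
      vapply(seq_len(n_perm), function(i) stat_fun(sample(st)),
             numeric(length(obs)))
    })
    if (length(obs) == 1L) null <- matrix(null, nrow = 1)

    rows <- purrr::map_dfr(seq_along(obs), function(j) {
      nm <- names(obs)[j]
      tibble(tree = ti,
             state = nm,
             statistic = obs[j],
             p = perm_p(null[j, ], obs[j], "le"),
             n_perm = n_perm,
             n_tips = if (nm == "pooled") sum(tab[testable_states])
                      else as.integer(tab[nm]),
             untestable = all_same)
    })
    skipped <- setdiff(states, c(testable_states))
    if (length(skipped) > 0) {
      rows <- dplyr::bind_rows(rows, tibble(
        tree = ti, state = skipped, statistic = NA_real_, p = NA_real_,
        n_perm = n_perm, n_tips = as.integer(tab[skipped]), untestable = TRUE))
    }
    rows
  })
}

#' Summarize per-tree signal tests across a tree set
#'
#' @param x A result tibble from [lambda_signal_test()] or
#'   [tiptip_distance_test()].
#' @param alpha Significance level.
#' @return A tibble grouped by scenario/state with the fraction of trees
#'   significant at `alpha`.
#' @export
signal_summary <- function(x, alpha = 0.05) {
  keys <- intersect(c("lambda", "state"), names(x))
  x |>
    dplyr::filter(!.data$untestable) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_trees = dplyr::n(),
                     frac_significant = mean(.data$p <= alpha),
                     .groups = "drop")
}
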