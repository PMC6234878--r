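#' Build an ensemble grid of method x model x root-prior combinations
#'
#' The ancestral-state ensemble votes over every combination of
#' reconstruction method (`"ml"` = marginal maximum-likelihood
#' reconstruction; `"simmap"` = modal sampled state over stochastic maps),
#' Mk model, and root prior, on every tree. The default grid is the full
#' product `{ml, simmap} x {ER, SYM, ARD} x {uniform, stationary, fitzjohn}`;
#' for binary characters `SYM` duplicates `ER` and is dropped. Grids are
#' plain tibbles and can be edited or replaced freely.
#'
#' @param k Number of character states.
#' @param methods Subset of `c("ml", "simmap")`.
#' @param models Model type names understood by [mk_model()].
#' @param root_priors Subset of `c("uniform", "stationary", "fitzjohn")`.
#' @return A tibble with columns `method`, `model`, `root_prior`, `cell`.
#' @export
ensemble_grid <- function(k, methods = c("ml", "simmap"),
                          models = c("ER", "SYM", "ARD"),
                          root_priors = c("uniform", "stationary", "fitzjohn")) {
  if (k == 2) models <- setdiff(models, "SYM")
  g <- tidyr::expand_grid(method = methods, model = models,
                          root_prior = root_priors)
  g$cell <- paste(g$method, tolower(g$model), g$root_prior, sep = "_")
  g
}

#' Run the ancestral-state ensemble over trees, models and methods
#'
#' For every tree and every grid cell, the Mk model is fitted by maximum
#' likelihood and a point ancestral state is taken at each anchored node
#' (argmax of the marginal reconstruction for `ml` cells; modal sampled node
#' state across stochastic maps for `simmap` cells). Votes are tallied per
#' node; cells whose fit fails to converge are excluded and logged in the
#' failure ledger, so vote totals plus failures always account for
#' `n_trees x n_cells`.
#'
#' @param trees A `multiPhylo`.
#' @param data Character data covering all tips.
#' @param grid A grid tibble from [ensemble_grid()].
#' @param anchors List of [node_anchor()] objects defining the focal nodes.
#' @param seed Master seed (controls fit restarts and map sampling).
#' @param n_maps Stochastic maps per `simmap` cell.
#' @param n_restarts Optimizer restarts per fit.
#' @return A `consensus_report`: list with `votes` (tibble: `anchor`,
#'   `method`, `model`, `root_prior`, `tree`, `state`), `monophyly`,
#'   `failures`, `grid`, `n_trees`, `states`.
#' @export
run_ensemble <- function(trees, data, grid = NULL, anchors, seed = NULL,
                         n_maps = 100, n_restarts = 2) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  states <- char_states(data, NULL)
  k <- length(states)
  grid <- grid %||% ensemble_grid(k)
  if (nrow(grid) == 0) abort("empty ensemble grid", class = "phyniche_validation_error")
  if (inherits(anchors, "node_anchor")) anchors <- list(anchors)

  tree_seeds <- spawn_seeds(seed, length(trees))
  votes <- list()
  failures <- list()
  mono <- list()

  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    res_anchor <- resolve_anchors(tree, anchors)
    mono[[ti]] <- dplyr::mutate(res_anchor, tree = ti)
    cell_seeds <- spawn_seeds(tree_seeds[ti], nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      cell <- grid[gi, ]
      fit <- fit_mk(tree, data, model = cell$model,
                    root_prior = cell$root_prior,
                    n_restarts = n_restarts, seed = cell_seeds[gi])
      if (!fit$converged) {
        failures[[length(failures) + 1L]] <-
          dplyr::mutate(cell, tree = ti, reason = "fit did not converge")
        next
      }
      node_states <- tryCatch({
        if (cell$method == "ml") {
          asr <- marginal_asr(tree, data, fit$Q, root_prior = cell$root_prior)
          pts <- asr_point_estimates(asr)
          setNames(pts$state, pts$node)
        } else {
          maps <- sample_maps(tree, data, fit$Q, n_maps = n_maps,
                              seed = cell_seeds[gi],
                              root_prior = cell$root_prior)
          modal_node_states(maps, states)
        }
      }, error = function(e) NULL)
      if (is.null(node_states)) {
        failures[[length(failures) + 1L]] <-
          dplyr::mutate(cell, tree = ti, reason = "reconstruction failed")
        next
      }
      votes[[length(votes) + 1L]] <- tibble(
        anchor = res_anchor$anchor,
        method = cell$method, model = cell$model, root_prior = cell$root_prior,
        tree = ti,
        state = unname(node_states[as.character(res_anchor$node)])
      )
    }
  }

  structure(
    list(votes = dplyr::bind_rows(votes),
         monophyly = dplyr::bind_rows(mono),
         failures = if (length(failures)) dplyr::bind_rows(failures) else
           tibble(method = character(), model = character(),
                  root_prior = character(), cell = character(),
                  tree = integer(), reason = character()),
         grid = grid, n_trees = length(trees), states = states,
         anchors = anchors),
    class = "consensus_report"
  )
}

# Modal sampled state per internal node across a map set.
modal_node_states <- function(maps, states) {
  ns <- vapply(maps, function(m) m$node_state, integer(length(maps[[1]]$node_state)))
  if (is.null(dim(ns))) ns <- matrix(ns, ncol = length(maps))
  modal <- apply(ns, 1, function(x) {
    tb <- tabulate(x, nbins = length(states))
    which.max(tb)
  })
  setNames(states[modal], seq_along(modal))
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report>", x$n_trees, "trees x", nrow(x$grid), "cells;",
      nrow(x$failures), "failed cells\n")
  invisible(x)
}

#' Per-node vote summary of an ensemble
#'
#' @param report A `consensus_report`.
#' @param node Anchor label. If `NULL`, all nodes are summarized.
#' @return Tibble per node: `anchor`, `winner` (majority state or `NA` on a
#'   tie), `tie`, `votes_winner`, `votes_total`, `margin`.
#' @export
summarize_node <- function(report, node = NULL) {
  votes <- report$votes
  if (!is.null(node)) {
    if (!node %in% votes$anchor) {
      abort(paste0("unknown node anchor: ", node),
            class = "phyniche_validation_error")
    }
    votes <- votes[votes$anchor == node, ]
  }
  votes |>
    dplyr::count(.data$anchor, .data$state, name = "votes") |>
    dplyr::group_by(.data$anchor) |>
    dplyr::summarise(
      votes_total = sum(.data$votes),
      votes_winner = max(.data$votes),
      tie = sum(.data$votes == max(.data$votes)) > 1L,
      winner = if (sum(.data$votes == max(.data$votes)) > 1L) NA_character_
               else .data$state[which.max(.data$votes)],
      .groups = "drop"
    ) |>
    dplyr::mutate(margin = .data$votes_winner / .data$votes_total)
}

#' @export
tidy.consensus_report <- function(x, ...) {
  x$votes |>
    dplyr::count(.data$anchor, .data$method, .data$state, name = "votes")
}

#' @export
glance.consensus_report <- function(x, ...) {
  tibble(n_trees = x$n_trees, n_cells = nrow(x$grid),
         n_votes = nrow(x$votes), n_failures = nrow(x$failures),
         frac_monophyletic = mean(x$monophyly$monophyletic))
}
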