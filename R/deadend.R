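#' Fit and AIC-rank constrained models across a tree set
#'
#' Every model is fitted to every tree by maximum likelihood; per tree,
#' converged fits are ranked by AIC (dense ranks, 1 = best; AIC values within
#' `tie_tol` share a rank, with listing order broken toward fewer parameters
#' then model order). Failed fits are excluded from that tree's ranking;
#' trees on which every model fails are dropped with a warning.
#'
#' @param trees A `multiPhylo` (or single `phylo`).
#' @param data Character data covering all tips.
#' @param models List of `mk_model` objects (e.g. from
#'   [enumerate_noswitch_models()]).
#' @param seed Master seed for optimizer restarts.
#' @param n_restarts Optimizer restarts per fit (large grids typically use 1).
#' @param root_prior Root prior passed to [fit_mk()].
#' @param tie_tol AIC difference below which two fits share a dense rank.
#' @return A `rank_table`: tibble with one row per attempted model x tree
#'   cell — `model`, `tree`, `lnL`, `K`, `AIC`, `converged`, `rank` — with
#'   the model list in `attr(, "models")`.
#' @export
rank_models <- function(trees, data, models, seed = NULL, n_restarts = 1,
                        root_prior = "uniform", tie_tol = 1e-6) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (length(models) == 0) {
    abort("empty model list", class = "phyniche_validation_error")
  }
  states <- char_states(data, NULL)
  for (m in models) {
    if (m$k != length(states)) {
      abort("models must share the data's state space",
            class = "phyniche_validation_error")
    }
  }
  ids <- vapply(models, function(m) m$id, character(1))
  Ks <- vapply(models, function(m) max(1L, m$n_par), integer(1))
  tree_seeds <- spawn_seeds(seed, length(trees))

  cells <- list()
  dropped <- integer(0)
  for (ti in seq_along(trees)) {
    fit_seeds <- spawn_seeds(tree_seeds[ti], length(models))
    rows <- purrr::map_dfr(seq_along(models), function(mi) {
      fit <- fit_mk(trees[[ti]], data, model = models[[mi]],
                    root_prior = root_prior, n_restarts = n_restarts,
                    seed = fit_seeds[mi])
      tibble(model = ids[mi], model_index = mi, tree = ti,
             lnL = fit$loglik, K = Ks[mi], AIC = fit$AIC,
             converged = fit$converged)
    })
    ok <- rows$converged
    rows$rank <- NA_integer_
    if (!any(ok)) {
      dropped <- c(dropped, ti)
      warn(paste0("all models failed on tree ", ti, "; tree dropped"))
    } else {
      rows$rank[ok] <- dense_aic_ranks(rows$AIC[ok], rows$K[ok],
                                       rows$model_index[ok], tie_tol)
    }
    cells[[ti]] <- rows
  }

  out <- dplyr::bind_rows(cells)
  out$model_index <- NULL
  class(out) <- c("rank_table", class(out))
  attr(out, "models") <- models
  attr(out, "dropped_trees") <- dropped
  attr(out, "n_trees") <- length(trees)
  out
}

# Dense AIC ranks: sort by (AIC, K, model order); AIC values within tol of
# the previous group share its rank.
dense_aic_ranks <- function(aic, K, model_order, tol = 1e-6) {
  o <- order(aic, K, model_order)
  r <- integer(length(aic))
  dense <- 1L
  last_aic <- aic[o[1]]
  r[o[1]] <- dense
  for (j in seq_along(o)[-1]) {
    if (aic[o[j]] - last_aic > tol) {
      dense <- dense + 1L
      last_aic <- aic[o[j]]
    }
    r[o[j]] <- dense
  }
  r
}

#' Rank-frequency histogram of a rank table
#'
#' For each model, how many trees put it at rank 1, 2, 3, ... — the data
#' behind "for how many trees a specific model would be the best, second
#' best" summaries.
#'
#' @param table A `rank_table`.
#' @return Tibble: `model`, `rank`, `n_trees`.
#' @export
rank_histogram <- function(table) {
  table |>
    dplyr::filter(.data$converged) |>
    dplyr::count(.data$model, .data$rank, name = "n_trees")
}

#' Models that stay in the top ranks across the majority of trees
#'
#' For each model, counts the trees on which its dense AIC rank is at most
#' `window`; models supported by strictly more than half of the non-dropped
#' trees are returned, best-supported first.
#'
#' @param table A `rank_table`.
#' @param window Rank window (default 5).
#' @return Tibble: `model`, `n_top` (trees with rank <= window), `n_trees`,
#'   `support` (= n_top / n_trees).
#' @export
top_models <- function(table, window = 5) {
  if (nrow(table) == 0) {
    abort("empty rank table", class = "phyniche_validation_error")
  }
  n_trees <- attr(table, "n_trees") %||% length(unique(table$tree))
  n_eff <- n_trees - length(attr(table, "dropped_trees") %||% integer(0))
  counts <- table |>
    dplyr::filter(.data$converged, .data$rank <= window) |>
    dplyr::count(.data$model, name = "n_top")
  counts |>
    dplyr::filter(.data$n_top > n_eff / 2) |>
    dplyr::arrange(dplyr::desc(.data$n_top)) |>
    dplyr::mutate(n_trees = n_eff, support = .data$n_top / n_eff)
}

#' @export
glance.rank_table <- function(x, ...) {
  tibble(
    n_models = length(unique(x$model)),
    n_trees = attr(x, "n_trees") %||% length(unique(x$tree)),
    n_cells = nrow(x),
    n_failed = sum(!x$converged),
    n_dropped_trees = length(attr(x, "dropped_trees") %||% integer(0))
  )
}
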