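# ggplot2 displays for each result type. These mirror the field's standard
# figures: null-distribution histograms for permutation tests, per-node vote
# bars for the ASR ensemble, switch-count histograms for binary characters,
# rank-frequency panels for the dead-end models, and pooled diversification-
# rate densities.

#' Plot per-node ensemble votes
#'
#' @param object A `consensus_report`.
#' @param ... Unused.
#' @return A ggplot: vote counts per state, faceted by anchored node.
#' @export
autoplot.consensus_report <- function(object, ...) {
  counts <- object$votes |>
    dplyr::count(.data$anchor, .data$state, name = "votes")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$state, y = .data$votes,
                                       fill = .data$state)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$anchor)) +
    ggplot2::labs(x = "ancestral state", y = "votes (trees x models)") +
    ggplot2::theme_minimal()
}

#' Plot switch-count distributions of a map set
#'
#' For binary characters this is the per-direction histogram of the number
#' of switches per map, with dashed lines at the means.
#'
#' @param object A `transition_summary`.
#' @param ... Unused.
#' @export
autoplot.transition_summary <- function(object, ...) {
  per <- dplyr::mutate(object$per_map,
                       direction = paste(.data$from, "→", .data$to))
  means <- dplyr::mutate(object$direction_means,
                         direction = paste(.data$from, "→", .data$to))
  ggplot2::ggplot(per, ggplot2::aes(x = .data$n, fill = .data$direction)) +
    ggplot2::geom_bar(position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean_n,
                                     colour = .data$direction),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "switches per map", y = "maps") +
    ggplot2::theme_minimal()
}

#' Plot a dead-end rank table
#'
#' Rank-frequency panels: for each model, the number of trees on which it
#' achieved each AIC rank.
#'
#' @param object A `rank_table`.
#' @param models Optional character vector restricting the panels.
#' @param ... Unused.
#' @export
autoplot.rank_table <- function(object, models = NULL, ...) {
  h <- rank_histogram(object)
  if (!is.null(models)) h <- h[h$model %in% models, ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$rank, y = .data$n_trees)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = "AIC rank (1 = best)", y = "number of trees") +
    ggplot2::theme_minimal()
}

#' Plot pooled diversification-rate densities
#'
#' @param object A `div_density`.
#' @param ... Unused.
#' @export
autoplot.div_density <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$r,
                                             colour = .data$state)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = expression(paste("diversification rate ",
                                       lambda - mu)),
                  y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot signal-test results across trees
#'
#' Histogram of per-tree permutation p-values by scenario (lambda value or
#' character state).
#'
#' @param x A result tibble from [lambda_signal_test()] or
#'   [tiptip_distance_test()].
#' @param alpha Reference level drawn as a dashed line.
#' @export
plot_signal <- function(x, alpha = 0.05) {
  key <- if ("lambda" %in% names(x)) "lambda" else "state"
  dat <- x[!x$untestable, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05)) +
    ggplot2::geom_vline(xintercept = alpha, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data[[key]])) +
    ggplot2::labs(x = "permutation p-value", y = "trees") +
    ggplot2::theme_minimal()
}
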