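#' Build an Mk rate-matrix model template
#'
#' A model is a k x k integer constraint mask over the off-diagonal cells of
#' the instantaneous rate matrix Q: `0` marks a cell fixed to zero, positive
#' integers index free parameters (equal indices tie cells to one rate).
#' `ER` uses one shared rate, `SYM` ties each pair of opposite cells
#' (k(k-1)/2 free rates), `ARD` frees every off-diagonal cell (k(k-1)).
#'
#' @param k Number of states (>= 2). Inferred from `states` or `mask` if
#'   missing.
#' @param type `"ER"`, `"SYM"`, `"ARD"` or `"custom"` (requires `mask`).
#' @param mask Integer k x k matrix for custom models (diagonal ignored).
#' @param states Optional state names used for dimnames and model ids.
#' @param id Optional model identifier.
#' @return An `mk_model`: list with `mask`, `k`, `n_par`, `states`, `id`.
#' @examples
#' mk_model(5, "ARD")$n_par  # 20
#' @export
mk_model <- function(k = NULL, type = c("ER", "SYM", "ARD", "custom"),
                     mask = NULL, states = NULL, id = NULL) {
  type <- match.arg(type)
  if (is.null(k)) k <- length(states) %||% nrow(mask)
  if (is.null(k) || k < 2) {
    abort("a model needs k >= 2 states", class = "phyniche_validation_error")
  }
  states <- states %||% paste0("s", seq_len(k))
  if (length(states) != k) {
    abort("length(states) must equal k", class = "phyniche_validation_error")
  }
  if (type == "custom") {
    if (is.null(mask)) {
      abort("custom models need a mask", class = "phyniche_validation_error")
    }
    mask <- as.matrix(mask)
    if (!all(dim(mask) == c(k, k))) {
      abort("mask shape mismatch", class = "phyniche_validation_error")
    }
    if (any(mask[row(mask) != col(mask)] < 0, na.rm = TRUE)) {
      abort("mask indices must be non-negative", class = "phyniche_validation_error")
    }
    diag(mask) <- 0L
    idx <- sort(unique(mask[mask > 0]))
    # renumber parameter indices densely to 1..n_par
    mask[] <- match(mask, idx, nomatch = 0L) # 0 stays 0
    mask <- matrix(as.integer(mask), k, k)
  } else {
    mask <- matrix(0L, k, k)
    off <- which(row(mask) != col(mask))
    if (type == "ER") {
      mask[off] <- 1L
    } else if (type == "ARD") {
      mask[off] <- seq_along(off)
    } else { # SYM
      p <- 0L
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          p <- p + 1L
          mask[i, j] <- p
          mask[j, i] <- p
        }
      }
    }
  }
  dimnames(mask) <- list(states, states)
  structure(
    list(mask = mask, k = as.integer(k),
         n_par = max(0L, max(mask)),
         states = states,
         id = id %||% tolower(type)),
    class = "mk_model"
  )
}

#' @export
print.mk_model <- function(x, ...) {
  cat("<mk_model>", x$id, "- k =", x$k, ", free rates =", x$n_par, "\n")
  print(x$mask)
  invisible(x)
}

#' Materialize a rate matrix from a model and free-rate vector
#'
#' @param model An `mk_model`.
#' @param rates Non-negative vector of length `model$n_par`.
#' @return A k x k rate matrix Q with rows summing to zero.
#' @export
rate_matrix <- function(model, rates) {
  stopifnot(inherits(model, "mk_model"))
  if (length(rates) != model$n_par) {
    abort(paste0("expected ", model$n_par, " rates, got ", length(rates)),
          class = "phyniche_validation_error")
  }
  if (any(rates < 0)) {
    abort("rates must be non-negative", class = "phyniche_validation_error")
  }
  Q <- matrix(0, model$k, model$k, dimnames = dimnames(model$mask))
  free <- model$mask > 0
  Q[free] <- rates[model$mask[free]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Eigendecomposition with a scaling-and-squaring fallback for defective
#' matrices (absorbing-state masks are frequently non-diagonalizable).
#'
#' @param Q A valid rate matrix (rows sum to 0, off-diagonals >= 0).
#' @param t Branch length (>= 0).
#' @return A stochastic k x k matrix; `t = 0` returns the identity.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    abort("t must be a single non-negative number",
          class = "phyniche_validation_error")
  }
  Q <- as.matrix(Q)
  P <- mk_pmat_cpp(unname(Q), t, -1)
  dimnames(P) <- dimnames(Q)
  P
}

#' Enumerate all "no-switch" (dead-end) constraint masks
#'
#' One model per non-empty proper subset S of the k states: every transition
#' out of every state in S is fixed to zero (the states in S are absorbing),
#' and all remaining off-diagonal rates are free, all-rates-different style.
#' Yields 2^k - 2 models, ordered by subset size, then lexicographically by
#' state index.
#'
#' @param k Number of states (>= 2).
#' @param states Optional state names (defaults to the PS alphabet when
#'   `k = 5`).
#' @return A list of `mk_model` objects; each carries `$absorbing` (the state
#'   subset) and an id of the form `"ns_rock+wood"`.
#' @examples
#' length(enumerate_noswitch_models(5))  # 30
#' @export
enumerate_noswitch_models <- function(k, states = NULL) {
  if (k < 2) abort("k must be >= 2", class = "phyniche_validation_error")
  states <- states %||% (if (k == 5) ps_states() else paste0("s", seq_len(k)))
  subsets <- list()
  for (size in seq_len(k - 1)) {
    cmb <- utils::combn(k, size)
    for (j in seq_len(ncol(cmb))) subsets <- c(subsets, list(cmb[, j]))
  }
  purrr::map(subsets, function(S) {
    mask <- matrix(0L, k, k)
    off <- row(mask) != col(mask)
    free_rows <- !(row(mask) %in% S)
    cells <- which(off & free_rows)
    mask[cells] <- seq_along(cells)
    m <- mk_model(k, "custom", mask = mask, states = states,
                  id = paste0("ns_", paste(states[S], collapse = "+")))
    m$absorbing <- states[S]
    m
  })
}

# Stationary distribution of Q (left null vector); may be non-unique for
# reducible (masked) matrices, in which case one non-negative null vector is
# returned; falls back to uniform when the solve is degenerate.
stationary_distribution <- function(Q) {
  k <- nrow(Q)
  ns <- tryCatch({
    e <- eigen(t(Q))
    i <- which.min(abs(e$values))
    v <- Re(e$vectors[, i])
    if (all(v <= 1e-12)) v <- -v
    v[v < 0] <- 0
    if (sum(v) <= 0) rep(1 / k, k) else v / sum(v)
  }, error = function(e) rep(1 / k, k))
  ns
}

root_prior_vector <- function(Q, root_prior) {
  k <- nrow(Q)
  switch(root_prior,
    uniform = rep(1 / k, k),
    stationary = stationary_distribution(Q),
    fitzjohn = rep(1 / k, k), # placeholder; fitzjohn handled via flag
    abort("unknown root prior", class = "phyniche_validation_error")
  )
}
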