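# Tree preprocessing shared by all pruning-based code: post-order edge list.
postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = matrix(as.integer(tr$edge), ncol = 2),
       elen = tr$edge.length,
       ntip = ape::Ntip(tr),
       nnode = tr$Nnode,
       tip.label = tr$tip.label)
}

mk_loglik_engine <- function(po, tipL, Q, root_prior, er_rate = -1) {
  fitzjohn <- identical(root_prior, "fitzjohn")
  prior <- if (fitzjohn) rep(0, nrow(Q)) else {
    if (is.numeric(root_prior)) root_prior else root_prior_vector(Q, root_prior)
  }
  res <- mk_prune_cpp(po$edge, po$elen, po$ntip, po$nnode, tipL, unname(Q),
                      prior, fitzjohn, er_rate)
  res$loglik
}

#' Pruning (Felsenstein) log-likelihood of a discrete character
#'
#' Post-order conditional-likelihood recursion; handles multifurcations and
#' zero-length branches natively. The result is invariant to tip ordering.
#'
#' @param tree A `phylo`.
#' @param data A `character_data` (or data frame with `species`, `state`)
#'   covering every tip of the tree.
#' @param Q A k x k rate matrix whose dimension matches the state space.
#' @param root_prior `"uniform"`, `"stationary"`, `"fitzjohn"` (data-
#'   conditional weights), or an explicit probability vector.
#' @param states Optional explicit state space (defaults to the one attached
#'   to `data`).
#' @return The log-likelihood (<= 0).
#' @export
prune_loglik <- function(tree, data, Q, root_prior = "uniform", states = NULL) {
  states <- char_states(data, states)
  if (nrow(Q) != length(states)) {
    abort("Q dimension does not match the state space",
          class = "phyniche_validation_error")
  }
  po <- postorder_edges(tree)
  tr <- tree
  tr$tip.label <- po$tip.label
  tipL <- tip_state_matrix(tr, data, states)
  mk_loglik_engine(po, tipL, Q, root_prior)
}

#' Fit an Mk model by maximum likelihood
#'
#' Multi-start local optimization in log-rate space with box constraints
#' \[1e-9, 1e3\] per rate. Single-rate models use Brent's method; larger
#' models use L-BFGS-B. A failed optimization (non-finite likelihood after
#' all restarts) is encoded in the convergence flag rather than an error, so
#' large model x tree grids can skip failed cells downstream.
#'
#' @inheritParams prune_loglik
#' @param model An `mk_model` (or a type string `"ER"`, `"SYM"`, `"ARD"`).
#' @param n_restarts Number of optimizer starts (jittered in log space).
#' @param seed Optional seed controlling the restart jitter.
#' @return An `mk_fit`: model id, fitted rates, `loglik`, parameter count
#'   `K`, `AIC = 2K - 2 lnL`, convergence flag.
#' @export
fit_mk <- function(tree, data, model = "ER", root_prior = "uniform",
                   n_restarts = 5, seed = NULL, states = NULL) {
  states <- char_states(data, states)
  if (is.character(model)) model <- mk_model(length(states), model, states = states)
  if (model$k != length(states)) {
    abort("model dimension does not match the state space",
          class = "phyniche_validation_error")
  }
  po <- postorder_edges(tree)
  tr <- tree
  tr$tip.label <- po$tip.label
  tipL <- tip_state_matrix(tr, data, states)

  lower <- log(1e-9)
  upper <- log(1e3)
  is_er <- model$n_par == 1L && all(model$mask[row(model$mask) != col(model$mask)] == 1L)

  negll <- function(logr) {
    r <- exp(logr)
    ll <- if (is_er) {
      mk_loglik_engine(po, tipL, er_q(model, r), root_prior, er_rate = r)
    } else {
      mk_loglik_engine(po, tipL, rate_matrix(model, r), root_prior)
    }
    if (!is.finite(ll)) 1e10 else -ll
  }

  # data-scaled initial rate: roughly one expected change per tree depth
  h <- max(ape::node.depth.edgelength(tree))
  base_start <- log(max(1e-6, 1 / max(h, 1e-8)))
  jitters <- with_seed(seed, matrix(rnorm(max(0L, (n_restarts - 1L)) * model$n_par),
                                    ncol = model$n_par))

  best <- NULL
  for (i in seq_len(max(1L, n_restarts))) {
    start <- rep(base_start, model$n_par)
    if (i > 1L) start <- pmin(pmax(start + jitters[i - 1L, ], lower), upper)
    res <- tryCatch({
      if (model$n_par == 1L) {
        o <- optimize(negll, c(lower, upper), tol = 1e-7)
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        optim(start, negll, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 500, factr = 1e8))
      }
    }, error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value < 1e9 &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }

  converged <- !is.null(best) && is.finite(best$value) && best$value < 1e9
  rates <- if (converged) exp(best$par) else rep(NA_real_, model$n_par)
  ll <- if (converged) -best$value else NA_real_
  K <- max(1L, model$n_par)
  structure(
    list(model = model, id = model$id, rates = rates, loglik = ll,
         K = K, AIC = if (converged) 2 * K - 2 * ll else NA_real_,
         converged = converged, root_prior = root_prior, states = states,
         Q = if (converged) rate_matrix(model, rates) else NULL),
    class = "mk_fit"
  )
}

er_q <- function(model, r) {
  Q <- matrix(r, model$k, model$k, dimnames = dimnames(model$mask))
  diag(Q) <- -(model$k - 1) * r
  Q
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("<mk_fit>", x$id, "lnL =", format(x$loglik), " AIC =", format(x$AIC),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' @export
tidy.mk_fit <- function(x, ...) {
  mask <- x$model$mask
  free <- which(mask > 0, arr.ind = TRUE)
  tibble(
    from = x$states[free[, 1]],
    to = x$states[free[, 2]],
    term = paste0(x$states[free[, 1]], "->", x$states[free[, 2]]),
    estimate = x$rates[mask[free]]
  )
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble(model = x$id, logLik = x$loglik, K = x$K, AIC = x$AIC,
         converged = x$converged)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, class = "logLik")
}

#' Marginal ancestral-state reconstruction
#'
#' Per-node marginal posterior probabilities over states via the standard
#' up-down (inside-outside) pass, integrating over the states of all other
#' nodes. Handles multifurcations.
#'
#' @inheritParams prune_loglik
#' @return An `asr` tibble: one row per internal node and state with columns
#'   `node` (ape node id), `state`, `prob`; the argmax per node is the point
#'   estimate.
#' @export
marginal_asr <- function(tree, data, Q, root_prior = "uniform", states = NULL) {
  states <- char_states(data, states)
  k <- length(states)
  if (nrow(Q) != k) {
    abort("Q dimension does not match the state space",
          class = "phyniche_validation_error")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  ntot <- ntip + nnode
  tipL <- tip_state_matrix(tr, data, states)
  edge <- tr$edge
  elen <- tr$edge.length
  ne <- nrow(edge)

  Pm <- lapply(seq_len(ne), function(e) mk_pmat_cpp(unname(as.matrix(Q)), elen[e], -1))

  # down (post-order) pass: conditional likelihoods and normalized messages
  L <- matrix(1, ntot, k)
  L[seq_len(ntip), ] <- tipL
  msg <- matrix(NA_real_, ne, k) # message from child of edge e to its parent
  for (e in seq_len(ne)) {
    p <- edge[e, 1]; c <- edge[e, 2]
    v <- as.vector(Pm[[e]] %*% L[c, ])
    v <- v / max(v)
    msg[e, ] <- v
    L[p, ] <- L[p, ] * v
  }
  root <- edge[ne, 1]

  fitzjohn <- identical(root_prior, "fitzjohn")
  prior <- if (fitzjohn) {
    w <- L[root, ] / sum(L[root, ])
    w
  } else if (is.numeric(root_prior)) root_prior else root_prior_vector(Q, root_prior)

  # up (pre-order) pass
  U <- matrix(NA_real_, ntot, k)
  U[root, ] <- prior
  children <- split(seq_len(ne), edge[, 1])
  for (e in rev(seq_len(ne))) { # reverse post-order = pre-order over edges
    p <- edge[e, 1]; c <- edge[e, 2]
    sib <- setdiff(children[[as.character(p)]], e)
    above <- U[p, ]
    for (s in sib) above <- above * msg[s, ]
    u <- as.vector(crossprod(Pm[[e]], above)) # sum_i P[i,j] * above[i]
    m <- max(u)
    U[c, ] <- if (m > 0) u / m else u
  }

  nodes <- (ntip + 1L):ntot
  probs <- t(vapply(nodes, function(v) {
    m <- U[v, ] * L[v, ]
    m / sum(m)
  }, numeric(k)))

  out <- tibble(
    node = rep(nodes, each = k),
    state = rep(states, times = length(nodes)),
    prob = as.vector(t(probs))
  )
  class(out) <- c("asr", class(out))
  attr(out, "states") <- states
  out
}

#' Point estimates from a marginal reconstruction
#'
#' @param asr Result of [marginal_asr()].
#' @return Tibble with one row per node: `node`, `state` (argmax), `prob`.
#' @export
asr_point_estimates <- function(asr) {
  dplyr::slice_max(dplyr::group_by(asr, .data$node), .data$prob,
                   n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}
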