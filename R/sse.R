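#' Construct and validate MuSSE parameters
#'
#' Per-state speciation rates `lambda` (> 0), extinction rates `mu` (>= 0),
#' off-diagonal transition-rate matrix `q` (>= 0), and per-state sampling
#' fractions `rho` in (0, 1\]. The derived diversification rate is
#' `lambda - mu`.
#'
#' @param lambda Numeric vector of per-state speciation rates.
#' @param mu Per-state extinction rates (recycled if scalar).
#' @param q k x k matrix of transition rates (diagonal ignored), or a single
#'   rate applied to every off-diagonal cell.
#' @param rho Per-state sampling fractions (recycled if scalar).
#' @param states Optional state names.
#' @return A `musse_params` object.
#' @export
musse_params <- function(lambda, mu = 0, q = 0, rho = 1, states = NULL) {
  k <- length(lambda)
  mu <- rep_len(mu, k)
  rho <- rep_len(rho, k)
  if (is.matrix(q)) {
    stopifnot(all(dim(q) == k))
  } else {
    q <- matrix(q, k, k)
  }
  diag(q) <- 0
  states <- states %||% paste0("s", seq_len(k))
  if (any(lambda <= 0)) abort("lambda must be > 0", class = "phyniche_validation_error")
  if (any(mu < 0)) abort("mu must be >= 0", class = "phyniche_validation_error")
  if (any(q < 0)) abort("q must be >= 0", class = "phyniche_validation_error")
  if (any(rho <= 0 | rho > 1)) {
    abort("rho must lie in (0, 1]", class = "phyniche_validation_error")
  }
  structure(list(lambda = setNames(lambda, states), mu = setNames(mu, states),
                 q = q, rho = setNames(rho, states), states = states, k = k),
            class = "musse_params")
}

#' @export
print.musse_params <- function(x, ...) {
  cat("<musse_params> k =", x$k, "\n")
  print(tibble(state = x$states, lambda = unname(x$lambda),
               mu = unname(x$mu), rho = unname(x$rho),
               r = unname(x$lambda - x$mu)))
  invisible(x)
}

check_sse_tree <- function(tree) {
  if (!ape::is.binary.phylo(tree)) {
    abort("SSE likelihoods require a fully bifurcating tree",
          class = "phyniche_validation_error")
  }
  if (!is_ultrametric(tree)) {
    abort("SSE likelihoods require an ultrametric tree",
          class = "phyniche_validation_error")
  }
  invisible(tree)
}

rho_vector <- function(rho, states) {
  if (is.data.frame(rho)) {
    idx <- match(states, rho$group)
    if (anyNA(idx)) {
      abort("sampling scheme missing fractions for some states",
            class = "phyniche_validation_error")
    }
    return(rho$fraction[idx])
  }
  rep_len(rho, length(states))
}

#' MuSSE log-likelihood
#'
#' Multi-state speciation-extinction likelihood of a tree plus tip character,
#' computed by integrating the coupled extinction/data ODE system along each
#' branch (adaptive Runge-Kutta, `rtol` 1e-8 / `atol` 1e-10) and multiplying
#' the per-state speciation rate at each node. Tip conditions are
#' `D_i = rho_i` for the observed state (0 otherwise) and `E_i(0) = 1 - rho_i`.
#'
#' @param tree An ultrametric, fully bifurcating `phylo`.
#' @param data Character data covering all tips.
#' @param params A `musse_params` whose dimension matches the state space.
#' @param condition_on_survival Divide the root D by
#'   `lambda_i (1 - E_i)^2` before weighting.
#' @param root `"fitzjohn"` (D-proportional weights, default), `"flat"`,
#'   or an explicit probability vector.
#' @param states Optional explicit state space.
#' @param rtol,atol ODE integrator tolerances.
#' @return The log-likelihood.
#' @export
musse_loglik <- function(tree, data, params, condition_on_survival = FALSE,
                         root = "fitzjohn", states = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  check_sse_tree(tree)
  states <- char_states(data, states)
  k <- length(states)
  if (params$k != k) {
    abort("params dimension does not match the state space",
          class = "phyniche_validation_error")
  }
  po <- postorder_edges(tree)
  tr <- structure(list(tip.label = po$tip.label), class = "phylo")
  ind <- tip_state_matrix(tr, data, states)
  tipD <- sweep(ind, 2, params$rho, `*`)
  tipE <- matrix(rep(1 - params$rho, each = po$ntip), nrow = po$ntip)
  root_mode <- if (identical(root, "fitzjohn")) 1L else 0L
  prior <- if (is.numeric(root)) root else rep(1 / k, k)
  res <- musse_prune_cpp(po$edge, po$elen, po$ntip, po$nnode, tipD, tipE,
                         unname(params$lambda), unname(params$mu),
                         unname(params$q), root_mode, prior,
                         condition_on_survival, rtol, atol)
  res$loglik
}

#' Constant-rate birth-death log-likelihood
#'
#' Single-state special case of the SSE machinery (k = 1); used directly and
#' as the factor in equal-rates reductions of the multi-state likelihood.
#'
#' @param tree An ultrametric, fully bifurcating `phylo`.
#' @param lambda Speciation rate (> 0).
#' @param mu Extinction rate (>= 0).
#' @param rho Sampling fraction in (0, 1].
#' @param condition_on_survival As in [musse_loglik()].
#' @param rtol,atol ODE integrator tolerances (tight by default; the
#'   single-state system is cheap).
#' @return The log-likelihood.
#' @export
bd_loglik <- function(tree, lambda, mu = 0, rho = 1,
                      condition_on_survival = FALSE,
                      rtol = 1e-11, atol = 1e-14) {
  check_sse_tree(tree)
  po <- postorder_edges(tree)
  tipD <- matrix(rho, po$ntip, 1)
  tipE <- matrix(1 - rho, po$ntip, 1)
  res <- musse_prune_cpp(po$edge, po$elen, po$ntip, po$nnode, tipD, tipE,
                         lambda, mu, matrix(0, 1, 1), 0L, 1,
                         condition_on_survival, rtol, atol)
  res$loglik
}

# --- parameter blocks for constrained ML fitting -------------------------

# constraints: list(lambda = "free"|"equal", mu = "free"|"equal"|"zero",
#                   q = "free"|"equal")
sse_par_template <- function(k, constraints) {
  lam_n <- switch(constraints$lambda, free = k, equal = 1L,
                  abort("bad lambda constraint", class = "phyniche_validation_error"))
  mu_n <- switch(constraints$mu, free = k, equal = 1L, zero = 0L,
                 abort("bad mu constraint", class = "phyniche_validation_error"))
  q_n <- if (k == 1) 0L else switch(constraints$q, free = k * (k - 1L), equal = 1L,
                                    abort("bad q constraint", class = "phyniche_validation_error"))
  list(lam_n = lam_n, mu_n = mu_n, q_n = q_n, n = lam_n + mu_n + q_n, k = k)
}

sse_par_expand <- function(theta, tmpl, states) {
  k <- tmpl$k
  lam <- exp(theta[seq_len(tmpl$lam_n)])
  if (tmpl$lam_n == 1L) lam <- rep(lam, k)
  off <- tmpl$lam_n
  mu <- if (tmpl$mu_n == 0L) rep(0, k) else {
    m <- exp(theta[off + seq_len(tmpl$mu_n)])
    if (tmpl$mu_n == 1L) rep(m, k) else m
  }
  off <- off + tmpl$mu_n
  q <- matrix(0, k, k)
  if (tmpl$q_n > 0L) {
    qv <- exp(theta[off + seq_len(tmpl$q_n)])
    if (tmpl$q_n == 1L) {
      q[row(q) != col(q)] <- qv
    } else {
      q[which(row(q) != col(q))] <- qv
    }
  }
  musse_params(lam, mu, q, rho = 1, states = states)
}

#' Fit a MuSSE model by maximum likelihood
#'
#' Box-constrained multi-start optimization in log-parameter space.
#' `constraints` tie or fix parameter blocks: e.g.
#' `list(lambda = "equal", mu = "equal", q = "free")` is the
#' character-independent null used in trait-independence testing, and
#' `mu = "zero"` fixes every extinction rate at exactly zero.
#'
#' @inheritParams musse_loglik
#' @param rho Sampling fractions: scalar, per-state vector, or a
#'   [sampling_fractions()] tibble keyed by state.
#' @param constraints List with entries `lambda`, `mu`, `q` (see Details).
#' @param n_restarts Optimizer starts.
#' @param seed Seed for restart jitter.
#' @return A `musse_fit`: fitted `params`, `loglik`, `K`, `AIC`,
#'   convergence flag.
#' @export
fit_musse <- function(tree, data, rho = 1,
                      constraints = list(lambda = "free", mu = "free", q = "free"),
                      condition_on_survival = FALSE, root = "fitzjohn",
                      n_restarts = 3, seed = NULL, states = NULL,
                      rtol = 1e-8, atol = 1e-10) {
  check_sse_tree(tree)
  states <- char_states(data, states)
  k <- length(states)
  rho_v <- rho_vector(rho, states)
  tmpl <- sse_par_template(k, constraints)
  po <- postorder_edges(tree)
  tr <- structure(list(tip.label = po$tip.label), class = "phylo")
  ind <- tip_state_matrix(tr, data, states)
  tipD <- sweep(ind, 2, rho_v, `*`)
  tipE <- matrix(rep(1 - rho_v, each = po$ntip), nrow = po$ntip)
  root_mode <- if (identical(root, "fitzjohn")) 1L else 0L
  prior <- if (is.numeric(root)) root else rep(1 / k, k)

  negll <- function(theta) {
    p <- sse_par_expand(theta, tmpl, states)
    ll <- musse_prune_cpp(po$edge, po$elen, po$ntip, po$nnode, tipD, tipE,
                          unname(p$lambda), unname(p$mu), unname(p$q),
                          root_mode, prior, condition_on_survival, rtol, atol)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }

  # data-scaled starts: Yule-style speciation estimate, modest extinction,
  # one expected character change per tree depth
  h <- tree_height(tree)
  ntip <- po$ntip
  lam0 <- max((ntip - 1) / max(sum(tree$edge.length), 1e-8), 1e-4)
  start <- c(rep(log(lam0), tmpl$lam_n),
             rep(log(lam0 / 5), tmpl$mu_n),
             rep(log(1 / max(h, 1e-8)), tmpl$q_n))
  lower <- rep(log(1e-9), tmpl$n)
  upper <- rep(log(1e3), tmpl$n)
  jit <- with_seed(seed, matrix(rnorm(max(0L, n_restarts - 1L) * tmpl$n, sd = 0.7),
                                ncol = tmpl$n))

  best <- NULL
  for (i in seq_len(max(1L, n_restarts))) {
    s <- if (i == 1L) start else pmin(pmax(start + jit[i - 1L, ], lower), upper)
    res <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e8)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value < 1e9 &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }

  converged <- !is.null(best) && is.finite(best$value) && best$value < 1e9
  params <- if (converged) {
    p <- sse_par_expand(best$par, tmpl, states)
    p$rho <- setNames(rho_v, states)
    p
  } else NULL
  K <- tmpl$n
  ll <- if (converged) -best$value else NA_real_
  structure(
    list(params = params, loglik = ll, K = K,
         AIC = if (converged) 2 * K - 2 * ll else NA_real_,
         converged = converged, constraints = constraints,
         states = states, root = root,
         condition_on_survival = condition_on_survival),
    class = "musse_fit"
  )
}

#' @export
print.musse_fit <- function(x, ...) {
  cat("<musse_fit> lnL =", format(x$loglik), " K =", x$K,
      if (!x$converged) " (NOT converged)" else "", "\n")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' @export
tidy.musse_fit <- function(x, ...) {
  if (is.null(x$params)) return(tibble(state = x$states, lambda = NA_real_,
                                       mu = NA_real_, r = NA_real_))
  tibble(state = x$states,
         lambda = unname(x$params$lambda),
         mu = unname(x$params$mu),
         r = unname(x$params$lambda - x$params$mu))
}

#' @export
glance.musse_fit <- function(x, ...) {
  tibble(logLik = x$loglik, K = x$K, AIC = x$AIC, converged = x$converged)
}

#' Metropolis-Hastings sampler over MuSSE parameters
#'
#' Random-walk Metropolis on log-parameters with independent exponential
#' priors on the natural scale; the proposal scale adapts toward a 30%
#' acceptance rate during burn-in only. With `prior_only = TRUE` the
#' likelihood term is dropped, giving a direct check that the sampler
#' recovers its prior.
#'
#' @inheritParams fit_musse
#' @param n_steps Total chain length.
#' @param burnin Fraction of the chain discarded (and used for adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param prior_mean Mean of the exponential prior, recycled over parameters.
#' @param prior_only Sample the prior alone (no data term).
#' @param init Optional initial `musse_params`-style start (defaults to a
#'   short ML polish of the prior mean).
#' @return A `musse_posterior` tibble of draws (columns `iteration`, `lnL`,
#'   `lambda_*`, `mu_*`, `q_*`), with chain metadata in attributes.
#' @export
musse_mcmc <- function(tree, data, rho = 1, n_steps = 10000, burnin = 0.1,
                       thin = 1, prior_mean = 1, seed = NULL,
                       constraints = list(lambda = "free", mu = "free", q = "free"),
                       condition_on_survival = FALSE, root = "fitzjohn",
                       prior_only = FALSE, states = NULL,
                       rtol = 1e-8, atol = 1e-10) {
  states <- char_states(data, states)
  k <- length(states)
  tmpl <- sse_par_template(k, constraints)
  pm <- rep_len(prior_mean, tmpl$n)

  if (prior_only) {
    loglik_fun <- function(theta) 0
  } else {
    check_sse_tree(tree)
    rho_v <- rho_vector(rho, states)
    po <- postorder_edges(tree)
    tr <- structure(list(tip.label = po$tip.label), class = "phylo")
    ind <- tip_state_matrix(tr, data, states)
    tipD <- sweep(ind, 2, rho_v, `*`)
    tipE <- matrix(rep(1 - rho_v, each = po$ntip), nrow = po$ntip)
    root_mode <- if (identical(root, "fitzjohn")) 1L else 0L
    prior_vec <- if (is.numeric(root)) root else rep(1 / k, k)
    loglik_fun <- function(theta) {
      p <- sse_par_expand(theta, tmpl, states)
      musse_prune_cpp(po$edge, po$elen, po$ntip, po$nnode, tipD, tipE,
                      unname(p$lambda), unname(p$mu), unname(p$q),
                      root_mode, prior_vec, condition_on_survival,
                      rtol, atol)$loglik
    }
  }

  # log target on the log-parameter scale (exp prior + Jacobian)
  logpost <- function(theta) {
    ll <- loglik_fun(theta)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(-exp(theta) / pm + theta)
  }

  n_burn <- floor(n_steps * burnin)
  draws <- with_seed(seed, {
    theta <- log(pm)
    lp <- logpost(theta)
    scale <- 0.5
    acc <- 0L
    keep <- list()
    for (it in seq_len(n_steps)) {
      prop <- theta + rnorm(tmpl$n, sd = scale)
      lp2 <- logpost(prop)
      if (is.finite(lp2) && log(runif(1)) < lp2 - lp) {
        theta <- prop
        lp <- lp2
        acc <- acc + 1L
      }
      if (it <= n_burn && it %% 50L == 0L) {
        rate <- acc / it
        scale <- scale * exp(0.6 * (rate - 0.3))
        scale <- min(max(scale, 1e-3), 10)
      }
      if (it > n_burn && ((it - n_burn) %% thin == 0L)) {
        keep[[length(keep) + 1L]] <- c(it, lp, exp(theta))
      }
    }
    list(mat = do.call(rbind, keep), acc_rate = acc / n_steps, scale = scale)
  })

  par_names <- sse_par_names(tmpl, states)
  out <- as_tibble(as.data.frame(draws$mat))
  names(out) <- c("iteration", "lnL", par_names)
  class(out) <- c("musse_posterior", class(out))
  attr(out, "acceptance_rate") <- draws$acc_rate
  attr(out, "n_steps") <- n_steps
  attr(out, "burnin") <- n_burn
  attr(out, "thin") <- thin
  attr(out, "seed") <- seed
  attr(out, "states") <- states
  attr(out, "constraints") <- constraints
  attr(out, "prior_mean") <- pm
  if (draws$acc_rate < 0.01) {
    warn("MCMC acceptance rate below 1% after adaptation")
  }
  out
}

sse_par_names <- function(tmpl, states) {
  k <- tmpl$k
  lam <- if (tmpl$lam_n == 1L) "lambda" else paste0("lambda_", states)
  mu <- if (tmpl$mu_n == 0L) character(0)
        else if (tmpl$mu_n == 1L) "mu" else paste0("mu_", states)
  qn <- character(0)
  if (tmpl$q_n == 1L) {
    qn <- "q"
  } else if (tmpl$q_n > 1L) {
    idx <- which(matrix(TRUE, k, k) & (row(diag(k)) != col(diag(k))))
    qn <- paste0("q_", states[((idx - 1) %% k) + 1], "_",
                 states[((idx - 1) %/% k) + 1])
  }
  c(lam, mu, qn)
}

#' Pooled diversification-rate densities
#'
#' Pools posterior draws (optionally across trees), derives per-state
#' diversification rates `lambda - mu`, and summarizes them as kernel
#' densities and quantiles.
#'
#' @param samples A `musse_posterior`, or a list of them (one per tree) to
#'   pool.
#' @return A `div_density`: list with `draws` (tibble: `state`, `r`,
#'   `source`) and `summary` (tibble of means and quantiles per state).
#' @export
diversification_density <- function(samples) {
  if (inherits(samples, "musse_posterior")) samples <- list(samples)
  if (length(samples) == 0) {
    abort("no posterior samples", class = "phyniche_validation_error")
  }
  draws <- purrr::map_dfr(seq_along(samples), function(i) {
    s <- samples[[i]]
    states <- attr(s, "states")
    lam_cols <- if ("lambda" %in% names(s)) {
      matrix(s$lambda, nrow(s), length(states))
    } else {
      as.matrix(s[paste0("lambda_", states)])
    }
    mu_cols <- if ("mu" %in% names(s)) {
      matrix(s$mu, nrow(s), length(states))
    } else if (all(paste0("mu_", states) %in% names(s))) {
      as.matrix(s[paste0("mu_", states)])
    } else {
      matrix(0, nrow(s), length(states))
    }
    r <- lam_cols - mu_cols
    tibble(source = i,
           state = rep(states, each = nrow(s)),
           r = as.vector(r))
  })
  summary <- draws |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$r),
                     q025 = quantile(.data$r, 0.025),
                     q50 = quantile(.data$r, 0.5),
                     q975 = quantile(.data$r, 0.975), .groups = "drop")
  structure(list(draws = draws, summary = summary), class = "div_density")
}

#' @export
print.div_density <- function(x, ...) {
  cat("<div_density> pooled diversification-rate draws\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.div_density <- function(x, ...) x$summary

#' Mann-Whitney comparison of two rate samples
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact enumeration for
#' small tie-free samples (n <= 8 each), tie-corrected normal approximation
#' otherwise. Degenerate all-tied samples return p = 1 with a note.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return A one-row tibble: `U`, `p`, `n_x`, `n_y`, `note`.
#' @export
compare_rates <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each sample needs at least 2 values",
          class = "phyniche_validation_error")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(tibble(U = length(x) * length(y) / 2, p = 1,
                  n_x = length(x), n_y = length(y),
                  note = "degenerate: all values tied"))
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  tibble(U = unname(wt$statistic), p = wt$p.value,
         n_x = length(x), n_y = length(y), note = NA_character_)
}

#' @rdname compare_rates
#' @param density A `div_density` (all unordered state pairs are compared).
#' @export
compare_all_rates <- function(density) {
  stopifnot(inherits(density, "div_density"))
  states <- unique(density$draws$state)
  pairs <- utils::combn(states, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- compare_rates(density$draws$r[density$draws$state == a],
                         density$draws$r[density$draws$state == b])
    dplyr::bind_cols(tibble(state_i = a, state_j = b), res)
  })
}

#' Trait-independence (type-1 error) check for state-dependent models
#'
#' Simulates neutral binary characters on a fixed tree under a symmetric Mk
#' model at each transition rate in `q_values`, fits the character-dependent
#' model (per-state speciation and extinction) against the
#' character-independent null (rates tied across states, transitions free),
#' and records how often the dependent model is preferred by a likelihood-
#' ratio test at level `alpha`. On a tree with no true rate heterogeneity
#' this is the false-positive rate of the state-dependent machinery.
#'
#' @param tree An ultrametric, fully bifurcating `phylo`.
#' @param q_values Positive Mk transition rates to simulate under.
#' @param n_sims Simulated characters per rate (>= 1).
#' @param seed Master seed.
#' @param alpha Test level for the chi-squared likelihood-ratio test.
#' @param n_restarts Optimizer restarts per fit.
#' @return Tibble per rate: `q`, `n_sims`, `n_positive`, `rate`, `ci_lo`,
#'   `ci_hi` (95% binomial confidence interval).
#' @export
trait_independence_test <- function(tree, q_values, n_sims, seed = NULL,
                                    alpha = 0.05, n_restarts = 2) {
  if (length(n_sims) != 1 || n_sims < 1) {
    abort("n_sims must be >= 1", class = "phyniche_validation_error")
  }
  if (any(q_values <= 0)) {
    abort("q_values must be positive", class = "phyniche_validation_error")
  }
  check_sse_tree(tree)
  states <- c("a", "b")
  q_seeds <- spawn_seeds(seed, length(q_values))

  purrr::map_dfr(seq_along(q_values), function(qi) {
    q <- q_values[qi]
    Q <- matrix(c(-q, q, q, -q), 2, 2, byrow = TRUE,
                dimnames = list(states, states))
    sim_seeds <- spawn_seeds(q_seeds[qi], n_sims)
    hits <- vapply(seq_len(n_sims), function(si) {
      data <- with_seed(sim_seeds[si], {
        # resample until both states are represented (a constant character
        # carries no information about state dependence)
        for (try in 1:200) {
          root_state <- sample(states, 1)
          d <- simulate_mk(tree, Q, root_state = root_state)
          if (length(unique(d$state)) == 2L) break
        }
        d
      })
      dep <- fit_musse(tree, data, n_restarts = n_restarts,
                       seed = sim_seeds[si],
                       constraints = list(lambda = "free", mu = "free", q = "free"))
      indep <- fit_musse(tree, data, n_restarts = n_restarts,
                         seed = sim_seeds[si] + 1L,
                         constraints = list(lambda = "equal", mu = "equal", q = "free"))
      if (!dep$converged || !indep$converged) return(NA)
      lrt <- max(0, 2 * (dep$loglik - indep$loglik))
      df <- dep$K - indep$K
      pchisq(lrt, df = df, lower.tail = FALSE) < alpha
    }, logical(1))
    n_ok <- sum(!is.na(hits))
    n_pos <- sum(hits, na.rm = TRUE)
    ci <- stats::binom.test(n_pos, max(n_ok, 1))$conf.int
    tibble(q = q, n_sims = n_ok, n_positive = n_pos,
           rate = n_pos / max(n_ok, 1), ci_lo = ci[1], ci_hi = ci[2])
  })
}
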