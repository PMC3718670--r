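#' Scaled forward-backward pass
#'
#' Runs the scaled forward and backward recursions over every chain
#' (chromosome block) of the observation set and collects the standard
#' Baum-Welch expectations: per-site state posteriors `gamma_t(i)`,
#' per-transition pair posteriors `xi_t(i, j)` and the total data
#' log-likelihood. The forward and an independently scaled backward
#' recursion both produce the log-likelihood; they are required to agree to
#' 1e-8 relative.
#'
#' @param obs An [snv_obs] observation set.
#' @param params An [hmm_parameters()] object.
#' @param logB Optional precomputed [emission_table()] (recomputed when
#'   `NULL`).
#' @return An object of class `hmm_trellis`: list with `state_posterior`
#'   (T x 3), `log_likelihood`, `log_likelihood_backward`, and per-chain
#'   components `chains` (each holding scaled `alpha`, `beta`, `log_scale`,
#'   `gamma`, `xi` as a (T_c - 1) x 9 matrix with j varying fastest, and the
#'   site indices `idx`). For a single-chain set, `pair_posterior` is the
#'   (T - 1) x 3 x 3 array of `xi`.
#' @export
forward_backward <- function(obs, params, logB = NULL) {
  stopifnot(inherits(obs, "snv_obs"), inherits(params, "hmm_parameters"))
  if (is.null(logB)) logB <- emission_table(obs, params$u)
  chains <- split(seq_len(length(obs)), obs$chain)
  res <- vector("list", length(chains))
  for (k in seq_along(chains)) {
    idx <- chains[[k]]
    r <- .fb_chain(logB[idx, , drop = FALSE], params$pi, params$A)
    rel <- abs(r$loglik - r$loglik_backward) /
      max(1, abs(r$loglik))
    if (!is.finite(rel) || rel > 1e-8)
      stop("forward and backward log-likelihoods disagree (relative ",
           format(rel), ")")
    r$idx <- idx
    res[[k]] <- r
  }
  gamma <- do.call(rbind, lapply(res, `[[`, "gamma"))
  colnames(gamma) <- STATE_LABELS
  out <- structure(list(
    chains = res,
    state_posterior = gamma,
    log_likelihood = sum(vapply(res, `[[`, numeric(1), "loglik")),
    log_likelihood_backward =
      sum(vapply(res, `[[`, numeric(1), "loglik_backward"))
  ), class = "hmm_trellis")
  if (length(res) == 1L && nrow(res[[1]]$xi) > 0L) {
    # xi rows store (i, j) with j varying fastest; reshape to [t, i, j]
    T_ <- length(obs)
    out$pair_posterior <- aperm(array(res[[1]]$xi, dim = c(T_ - 1L, 3L, 3L)),
                                c(1L, 3L, 2L))
  }
  out
}

#' @export
print.hmm_trellis <- function(x, ...) {
  cat(sprintf("<hmm_trellis> %d sites in %d chain(s), log-likelihood %.4f\n",
              nrow(x$state_posterior), length(x$chains), x$log_likelihood))
  invisible(x)
}

#' Baum-Welch update of the initial state distribution
#'
#' The maximizer of the first term of the EM objective: the posterior of the
#' first state, `pi_i = gamma_1(i)`, averaged over chains when the set has
#' several chromosomes.
#'
#' @param cache An `hmm_trellis` from [forward_backward()].
#' @param hyper,map_updates When `map_updates` is `TRUE` the Dirichlet
#'   pseudocounts `delta - 1` are added before normalization.
#' @return A probability 3-vector.
#' @export
update_initial <- function(cache, hyper = NULL, map_updates = FALSE) {
  stopifnot(inherits(cache, "hmm_trellis"))
  g1 <- colMeans(do.call(rbind, lapply(cache$chains,
                                       function(ch) ch$gamma[1L, ])))
  if (map_updates && !is.null(hyper)) g1 <- g1 + (hyper$delta - 1) /
      sum(vapply(cache$chains, function(ch) 1, numeric(1)))
  g1 <- pmax(g1, 0)
  setNames(g1 / sum(g1), STATE_LABELS)
}

#' Baum-Welch update of the transition matrix
#'
#' `A[i, j] = sum_t xi_t(i, j) / sum_t gamma_t(i)` over `t = 1..T-1`, pooled
#' across chains, with each row renormalized to sum exactly to 1. A state
#' with zero expected occupancy keeps its previous row (from `A_prev`) and a
#' warning is raised.
#'
#' @param cache An `hmm_trellis`.
#' @param A_prev Previous transition matrix used for zero-occupancy rows.
#' @inheritParams update_initial
#' @return A row-stochastic 3x3 matrix.
#' @export
update_transitions <- function(cache, A_prev = NULL, hyper = NULL,
                               map_updates = FALSE) {
  stopifnot(inherits(cache, "hmm_trellis"))
  num <- matrix(0, N_STATES, N_STATES)
  den <- numeric(N_STATES)
  any_trans <- FALSE
  for (ch in cache$chains) {
    T_c <- nrow(ch$gamma)
    if (T_c < 2L) next
    any_trans <- TRUE
    num <- num + matrix(colSums(ch$xi), N_STATES, N_STATES, byrow = TRUE)
    den <- den + colSums(ch$gamma[seq_len(T_c - 1L), , drop = FALSE])
  }
  if (!any_trans) stop("transition update needs at least one chain with T >= 2")
  if (map_updates && !is.null(hyper)) {
    num <- num + (hyper$gamma - 1)
    den <- den + rowSums(hyper$gamma - 1)
  }
  A <- num / den
  zero <- den <= 0 | !is.finite(den)
  if (any(zero)) {
    warning("state(s) ", paste(STATE_LABELS[zero], collapse = ", "),
            " have zero expected occupancy; keeping previous transition row")
    for (i in which(zero))
      A[i, ] <- if (is.null(A_prev)) rep(1 / N_STATES, N_STATES) else A_prev[i, ]
  }
  A <- A / rowSums(A)
  dimnames(A) <- list(STATE_LABELS, STATE_LABELS)
  A
}

# Expected log-emission term of the EM objective for one state, as a
# function of u, plus its first two derivatives.  g is the per-read
# posterior weight gamma_t(i) of the read's site.  Concave in u: log of an
# affine function.
u_objective <- function(u, a, b, match, g) {
  p <- a + b * u
  lp <- numeric(length(p))
  lp[match] <- log(p[match])
  lp[!match] <- log1p(-p[!match])
  sum(g * lp)
}

u_derivs <- function(u, a, b, match, g) {
  p <- a + b * u
  w <- ifelse(match, b / p, -b / (1 - p))
  d1 <- sum(g * w)
  d2 <- -sum(g * w * w)
  c(d1, d2)
}

#' Newton update of the per-state reference-allele probabilities
#'
#' Maximizes, separately for each state i, the expected log-emission
#' `Q3(u_i) = sum_t gamma_t(i) log f(o_t; u_i)` with damped Newton steps on
#' the analytic first and second derivatives. Because each read contributes
#' the log of an affine function of `u`, `Q3` is concave and damped Newton
#' converges to the global maximizer. Steps are halved until the objective
#' does not decrease; the result is clamped to
#' `[u_clamp_eps, 1 - u_clamp_eps]`.
#'
#' @param obs An [snv_obs] observation set.
#' @param cache The aligned `hmm_trellis`.
#' @param u_old Current 3-vector of `u` values.
#' @param config A [train_config()].
#' @return The updated 3-vector.
#' @export
update_u_newton <- function(obs, cache, u_old, config = train_config()) {
  stopifnot(inherits(obs, "snv_obs"), inherits(cache, "hmm_trellis"))
  if (nrow(cache$state_posterior) != length(obs))
    stop("trellis cache is not aligned with the observation sequence")
  eps <- config$u_clamp_eps
  clamp <- function(x) min(max(x, eps), 1 - eps)
  u_new <- u_old
  for (i in seq_len(N_STATES)) {
    g <- cache$state_posterior[obs$site_of_read, i]
    u <- clamp(u_old[i])
    f0 <- u_objective(u, obs$a, obs$b, obs$match, g)
    for (step in seq_len(config$newton_steps)) {
      d <- u_derivs(u, obs$a, obs$b, obs$match, g)
      if (!all(is.finite(d))) {
        bad <- which(!is.finite(ifelse(obs$match,
                                       obs$b / (obs$a + obs$b * u),
                                       obs$b / (1 - obs$a - obs$b * u))))[1]
        stop(sprintf("non-finite derivative for state %s at position %s",
                     STATE_LABELS[i],
                     obs$sites$pos[obs$site_of_read[bad]]))
      }
      if (abs(d[1]) < 1e-12) break
      delta <- if (d[2] < 0) -d[1] / d[2] else sign(d[1]) * 0.1
      repeat {
        u_try <- clamp(u + delta)
        f_try <- u_objective(u_try, obs$a, obs$b, obs$match, g)
        if (is.finite(f_try) && f_try >= f0 - 1e-12) break
        delta <- delta / 2
        if (abs(delta) < 1e-14) { u_try <- u; f_try <- f0; break }
      }
      moved <- abs(u_try - u)
      u <- u_try; f0 <- f_try
      if (moved < 1e-12) break
    }
    u_new[i] <- u
  }
  setNames(u_new, STATE_LABELS)
}

#' Train the genotype HMM by Baum-Welch
#'
#' Iterates [forward_backward()], [update_initial()],
#' [update_transitions()] and [update_u_newton()] until the absolute change
#' in total log-likelihood drops below `config$tol` or `config$max_iter`
#' iterations are done. With damped Newton sub-steps the log-likelihood
#' trace is non-decreasing up to numerical tolerance. The priors enter only
#' through the initialization (unless `config$map_updates` adds their
#' pseudocounts to the `pi`/`A` updates).
#'
#' @param obs An [snv_obs] observation set.
#' @param init Optional starting [hmm_parameters()]; when `NULL`,
#'   [init_from_priors()] is called with `config$init_mode`/`config$seed`.
#' @param hyper A [prior_hyperparameters()].
#' @param config A [train_config()].
#' @return An object of class `hmm_fit`: list with `params`, `loglik_trace`
#'   (log-likelihood evaluated at the parameters entering each iteration),
#'   `converged`, `n_iter`, `hyper` and `config`.
#' @export
baum_welch_train <- function(obs, init = NULL,
                             hyper = prior_hyperparameters(),
                             config = train_config()) {
  stopifnot(inherits(obs, "snv_obs"))
  params <- if (is.null(init))
    init_from_priors(hyper, config$init_mode, config$seed)
  else init
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    cache <- forward_backward(obs, params)
    trace <- c(trace, cache$log_likelihood)
    pi_new <- update_initial(cache, hyper, config$map_updates)
    A_new <- update_transitions(cache, params$A, hyper, config$map_updates)
    u_new <- update_u_newton(obs, cache, params$u, config)
    params <- hmm_parameters(pi = pi_new, A = A_new, u = u_new)
    if (abs(cache$log_likelihood - ll_prev) <= config$tol) {
      converged <- TRUE
      break
    }
    ll_prev <- cache$log_likelihood
  }
  structure(list(params = params, loglik_trace = trace,
                 converged = converged, n_iter = iter,
                 hyper = hyper, config = config),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d iteration(s), %sconverged, final log-likelihood %.4f\n",
              x$n_iter, if (x$converged) "" else "NOT ",
              x$loglik_trace[length(x$loglik_trace)]))
  print(x$params)
  invisible(x)
}

#' Viterbi decoding of the genotype path
#'
#' Returns the jointly most probable genotype state path given the
#' parameters, decoded independently per chain (chromosome). Ties are
#' broken toward the lower state index (aa < ab < bb).
#'
#' @param obs An [snv_obs] observation set.
#' @param params An [hmm_parameters()] object.
#' @return A list with `path` (integer vector in 1..3, one per site, with
#'   `STATE_LABELS` names available via `states`), `states` (factor of
#'   aa/ab/bb) and `log_prob` (total log-probability of the decoded path,
#'   summed over chains).
#' @export
viterbi_decode <- function(obs, params) {
  stopifnot(inherits(obs, "snv_obs"), inherits(params, "hmm_parameters"))
  logB <- emission_table(obs, params$u)
  path <- integer(length(obs))
  logp <- 0
  for (idx in split(seq_len(length(obs)), obs$chain)) {
    r <- .viterbi_chain(logB[idx, , drop = FALSE], params$pi, params$A)
    path[idx] <- r$path
    logp <- logp + r$log_prob
  }
  list(path = path,
       states = factor(STATE_LABELS[path], levels = STATE_LABELS),
       log_prob = logp)
}
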