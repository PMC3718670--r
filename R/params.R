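U_EPS <- 1e-6

#' HMM parameter set
#'
#' Bundles the three parameter blocks of the genotype HMM: the initial state
#' distribution `pi` over (aa, ab, bb), the row-stochastic 3x3 transition
#' matrix `A`, and the per-state reference-allele probabilities `u` (near 1
#' for aa, near 0.5 for ab, near 0 for bb).
#'
#' @param pi Numeric 3-vector summing to 1.
#' @param A Numeric 3x3 matrix with rows summing to 1.
#' @param u Numeric 3-vector; each entry is clamped to
#'   `[1e-6, 1 - 1e-6]`.
#' @return An object of class `hmm_parameters`.
#' @export
hmm_parameters <- function(pi, A, u) {
  pi <- as.numeric(pi); u <- as.numeric(u); A <- as.matrix(A)
  if (length(pi) != 3L || length(u) != 3L || !all(dim(A) == c(3L, 3L)))
    stop("pi and u must have length 3 and A must be 3x3")
  if (any(pi < 0) || any(A < 0)) stop("probabilities must be non-negative")
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-9)) stop("rows of A must sum to 1")
  u <- pmin(pmax(u, U_EPS), 1 - U_EPS)
  dimnames(A) <- list(STATE_LABELS, STATE_LABELS)
  structure(list(pi = setNames(pi, STATE_LABELS), A = A,
                 u = setNames(u, STATE_LABELS)),
            class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat("<hmm_parameters>\n  pi:", sprintf("%.6f", x$pi), "\n  u: ",
      sprintf("%.6f", x$u), "\n  A:\n")
  print(round(x$A, 6))
  invisible(x)
}

#' Prior hyperparameters for the genotype HMM
#'
#' Dirichlet prior on the initial distribution (`delta`), Beta priors on the
#' per-state reference-allele probabilities (`alpha`, `beta`), and a
#' Dirichlet prior on each transition-matrix row (`gamma`). The defaults
#' encode that most genomic positions are homozygous reference, that `u` is
#' near 1 for aa, 1/2 for ab and 0 for bb, and that genotype runs are
#' sticky: `delta = (1000, 100, 100)`, `alpha = (1000, 500, 1)`,
#' `beta = (1, 500, 1000)`, `gamma` rows `(1000, 100, 100)`,
#' `(100, 1000, 100)`, `(100, 100, 1000)`.
#'
#' @param delta Dirichlet hyperparameters for `pi` (positive 3-vector).
#' @param alpha,beta Beta hyperparameters for each `u[i]` (positive
#'   3-vectors).
#' @param gamma 3x3 matrix; row i holds the Dirichlet hyperparameters of
#'   transition row i.
#' @return An object of class `prior_hyperparameters`.
#' @export
prior_hyperparameters <- function(delta = c(1000, 100, 100),
                                  alpha = c(1000, 500, 1),
                                  beta = c(1, 500, 1000),
                                  gamma = rbind(c(1000, 100, 100),
                                                c(100, 1000, 100),
                                                c(100, 100, 1000))) {
  delta <- as.numeric(delta); alpha <- as.numeric(alpha)
  beta <- as.numeric(beta); gamma <- as.matrix(gamma)
  if (length(delta) != 3L || length(alpha) != 3L || length(beta) != 3L ||
      !all(dim(gamma) == c(3L, 3L)))
    stop("delta/alpha/beta must have length 3 and gamma must be 3x3")
  if (any(c(delta, alpha, beta, gamma) <= 0))
    stop("all hyperparameters must be positive")
  structure(list(delta = delta, alpha = alpha, beta = beta, gamma = gamma),
            class = "prior_hyperparameters")
}

#' Initialize HMM parameters from the priors
#'
#' `prior_mean` (default) sets every block to its prior mean:
#' `pi` proportional to `delta`, row i of `A` proportional to `gamma[i, ]`,
#' and `u[i] = alpha[i] / (alpha[i] + beta[i])`. `prior_sample` draws `pi`
#' and the rows of `A` from their Dirichlet distributions and each `u[i]`
#' from `Beta(alpha[i], beta[i])`; a seed is mandatory in this mode.
#'
#' @param hyper A [prior_hyperparameters()].
#' @param mode `"prior_mean"` or `"prior_sample"`.
#' @param seed Integer RNG seed (required for `"prior_sample"`).
#' @return An [hmm_parameters()] object.
#' @examples
#' init_from_priors()  # pi = (1000,100,100)/1200, u ~ (0.999, 0.5, 0.001)
#' @export
init_from_priors <- function(hyper = prior_hyperparameters(),
                             mode = c("prior_mean", "prior_sample"),
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(hyper, "prior_hyperparameters"))
  if (mode == "prior_mean") {
    pi <- hyper$delta / sum(hyper$delta)
    A <- hyper$gamma / rowSums(hyper$gamma)
    u <- hyper$alpha / (hyper$alpha + hyper$beta)
  } else {
    if (is.null(seed)) stop("a seed is mandatory in prior_sample mode")
    set.seed(as.integer(seed))
    rdirichlet1 <- function(a) { g <- rgamma(length(a), shape = a); g / sum(g) }
    pi <- rdirichlet1(hyper$delta)
    A <- t(apply(hyper$gamma, 1L, rdirichlet1))
    A <- A / rowSums(A)
    u <- rbeta(3L, hyper$alpha, hyper$beta)
  }
  hmm_parameters(pi = pi, A = A, u = u)
}

#' Training configuration for Baum-Welch
#'
#' @param max_iter Maximum number of EM iterations.
#' @param tol Absolute change in total log-likelihood below which training
#'   stops and is flagged converged.
#' @param newton_steps Maximum damped Newton steps per state per EM
#'   iteration for the `u` update (the objective is concave in `u`, so a
#'   handful suffices).
#' @param u_clamp_eps `u` is clamped to `[u_clamp_eps, 1 - u_clamp_eps]`.
#' @param seed Integer seed used by `prior_sample` initialization.
#' @param init_mode Passed to [init_from_priors()].
#' @param map_updates If `TRUE`, the `pi` and `A` updates add the Dirichlet
#'   pseudocounts `(delta - 1)` and `(gamma[i,] - 1)` (MAP-style
#'   regularization); the default `FALSE` uses the pure maximum-likelihood
#'   updates.
#' @return A `train_config` object.
#' @export
train_config <- function(max_iter = 50L, tol = 1e-2, newton_steps = 8L,
                         u_clamp_eps = U_EPS, seed = NULL,
                         init_mode = c("prior_mean", "prior_sample"),
                         map_updates = FALSE) {
  init_mode <- match.arg(init_mode)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (!is.infinite(tol) && tol <= 0) stop("tol must be > 0")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 newton_steps = as.integer(newton_steps),
                 u_clamp_eps = u_clamp_eps, seed = seed,
                 init_mode = init_mode, map_updates = isTRUE(map_updates)),
            class = "train_config")
}

#' Serialize / deserialize trained parameters as plain text
#'
#' A flat, deterministic `key<TAB>values` format carrying `pi`, the rows of
#' `A`, `u`, and optional metadata (hyperparameters, iteration count, final
#' log-likelihood). Numbers are written with full precision (`%.17g`).
#'
#' @param params An [hmm_parameters()] object.
#' @param path Output (input) file path.
#' @param hyper Optional [prior_hyperparameters()] to record.
#' @param n_iter,log_likelihood,converged Optional training metadata.
#' @return `write_hmm_parameters` returns `path` invisibly;
#'   `read_hmm_parameters` returns an [hmm_parameters()] with any metadata
#'   attached as attributes `n_iter`, `log_likelihood` and `converged`.
#' @export
write_hmm_parameters <- function(params, path, hyper = NULL, n_iter = NULL,
                                 log_likelihood = NULL, converged = NULL) {
  stopifnot(inherits(params, "hmm_parameters"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  out <- c(
    "# hmmsnv parameter file v1",
    paste0("pi\t", num(params$pi)),
    paste0("A1\t", num(params$A[1, ])),
    paste0("A2\t", num(params$A[2, ])),
    paste0("A3\t", num(params$A[3, ])),
    paste0("u\t", num(params$u)))
  if (!is.null(hyper))
    out <- c(out,
             paste0("delta\t", num(hyper$delta)),
             paste0("alpha\t", num(hyper$alpha)),
             paste0("beta\t", num(hyper$beta)),
             paste0("gamma1\t", num(hyper$gamma[1, ])),
             paste0("gamma2\t", num(hyper$gamma[2, ])),
             paste0("gamma3\t", num(hyper$gamma[3, ])))
  if (!is.null(n_iter)) out <- c(out, paste0("n_iter\t", n_iter))
  if (!is.null(log_likelihood))
    out <- c(out, paste0("log_likelihood\t", num(log_likelihood)))
  if (!is.null(converged))
    out <- c(out, paste0("converged\t", as.integer(converged)))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_hmm_parameters
#' @export
read_hmm_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed parameter file: ", path)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- lapply(kv, function(x) as.numeric(strsplit(x[[2]], " ", fixed = TRUE)[[1]]))
  names(vals) <- keys
  need <- c("pi", "A1", "A2", "A3", "u")
  if (!all(need %in% keys) || anyNA(unlist(vals[need])))
    stop("malformed parameter file: ", path)
  params <- hmm_parameters(pi = vals$pi,
                           A = rbind(vals$A1, vals$A2, vals$A3),
                           u = vals$u)
  for (meta in c("n_iter", "log_likelihood", "converged"))
    if (meta %in% keys) attr(params, meta) <- vals[[meta]]
  params
}
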