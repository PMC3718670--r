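# Shared fixtures and independent oracles.  The brute-force enumerator and
# the grid-search maximizer deliberately share no code with the package's
# trellis / Newton implementations.

# Random observation set on one chromosome.
random_obs <- function(T_, mean_depth = 3) {
  L <- pmax(1L, rpois(T_, mean_depth))
  site <- rep.int(seq_len(T_), L)
  match <- runif(sum(L)) < runif(1, 0.2, 0.8)
  P <- as.integer(rowsum(as.numeric(match), site)[, 1])
  new_snv_obs(
    data.frame(chrom = "c1", pos = seq_len(T_), ref = "A", alt = "T",
               L = L, P = P, stringsAsFactors = FALSE),
    match, runif(sum(L), 0.5, 1), runif(sum(L), 0.5, 1))
}

random_params <- function() {
  rdir <- function(n) { x <- rgamma(n, 1) + 1e-3; x / sum(x) }
  hmm_parameters(pi = rdir(3), A = t(replicate(3, rdir(3))),
                 u = runif(3, 0.05, 0.95))
}

# Exhaustive enumeration over all 3^T state paths: total log-likelihood,
# per-site posteriors, expected transition counts, Viterbi path and score.
brute_force_hmm <- function(obs, params) {
  T_ <- length(obs)
  lB <- emission_table(obs, params$u)
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  lp <- unname(log(params$pi[paths[, 1]])) + lB[cbind(1L, paths[, 1])]
  if (T_ > 1)
    for (t in 2:T_)
      lp <- lp + log(params$A[cbind(paths[, t - 1], paths[, t])]) +
        lB[cbind(t, paths[, t])]
  M <- max(lp)
  ll <- M + log(sum(exp(lp - M)))
  w <- exp(lp - ll)
  post <- sapply(1:3, function(i)
    sapply(1:T_, function(t) sum(w * (paths[, t] == i))))
  post <- matrix(post, nrow = T_)
  trans_num <- matrix(0, 3, 3)
  if (T_ > 1)
    for (t in 2:T_)
      for (i in 1:3) for (j in 1:3)
        trans_num[i, j] <- trans_num[i, j] +
          sum(w * (paths[, t - 1] == i & paths[, t] == j))
  best <- which.max(lp)
  list(loglik = ll, posterior = post, trans_num = trans_num,
       viterbi = unname(paths[best, ]), viterbi_loglik = lp[best])
}

# Dense grid-search maximizer of the expected log-emission in u.
grid_search_u <- function(obs, weights, step = 1e-5) {
  u_grid <- seq(step, 1 - step, by = step)
  g <- weights[obs$site_of_read]
  q3 <- numeric(length(u_grid))
  for (k in seq_along(obs$match)) {
    p <- obs$a[k] + obs$b[k] * u_grid
    q3 <- q3 + g[k] * (if (obs$match[k]) log(p) else log1p(-p))
  }
  u_grid[which.max(q3)]
}

# True parameters of the simulation world used across EM/recovery tests:
# a sticky genotype chain with mostly homozygous-reference sites and
# reference-allele probabilities near 1, 1/2 and 0.
world_params <- function() {
  hmm_parameters(pi = c(0.90, 0.07, 0.03),
                 A = rbind(c(0.980, 0.015, 0.005),
                           c(0.050, 0.900, 0.050),
                           c(0.010, 0.040, 0.950)),
                 u = c(0.99, 0.5, 0.01))
}

obs_from_sim <- function(n_sites, mean_depth, seed,
                         params = world_params(), third = 0) {
  cfg <- simulation_config(n_sites = n_sites, mean_depth = mean_depth,
                           true_params = params,
                           error_third_allele_rate = third, seed = seed)
  states <- simulate_truth_path(params, n_sites, seed)
  pil <- tempfile(fileext = ".pileup"); tru <- tempfile(fileext = ".tsv")
  sim <- simulate_pileup(states, cfg, pil, tru)
  list(obs = read_pileup(pil, filter_config(0L, 0L, 0L)),
       states = states, sim = sim, pileup = pil, truth = tru)
}
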