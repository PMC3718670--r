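test_that("init_from_priors reproduces the prior means and seeds samples", {
  p <- init_from_priors()
  expect_equal(unname(p$pi), c(1000, 100, 100) / 1200)
  expect_equal(unname(p$u), c(1000 / 1001, 0.5, 1 / 1001), tolerance = 1e-9)
  expect_equal(unname(p$A[2, ]), c(100, 1000, 100) / 1200)
  s1 <- init_from_priors(mode = "prior_sample", seed = 9)
  s2 <- init_from_priors(mode = "prior_sample", seed = 9)
  expect_equal(s1, s2)
  expect_equal(sum(s1$pi), 1)
  expect_equal(unname(rowSums(s1$A)), rep(1, 3))
  expect_error(init_from_priors(mode = "prior_sample"), "seed")
  expect_error(prior_hyperparameters(alpha = c(0, 1, 1)), "positive")
})

test_that("forward-backward and Viterbi match exhaustive enumeration", {
  set.seed(101)
  for (k in 1:30) {
    T_ <- sample(1:6, 1)
    obs <- random_obs(T_)
    params <- random_params()
    b <- brute_force_hmm(obs, params)
    fb <- forward_backward(obs, params)
    expect_equal(fb$log_likelihood, b$loglik, tolerance = 1e-12)
    expect_lt(max(abs(fb$state_posterior - b$posterior)), 1e-10)
    v <- viterbi_decode(obs, params)
    expect_equal(v$path, b$viterbi)
    expect_equal(v$log_prob, b$viterbi_loglik, tolerance = 1e-12)
    # forward vs independent backward recursion
    expect_equal(fb$log_likelihood, fb$log_likelihood_backward,
                 tolerance = 1e-8)
  }
})

test_that("trellis posterior identities hold", {
  set.seed(113)
  obs <- random_obs(40)
  fb <- forward_backward(obs, random_params())
  expect_equal(unname(rowSums(fb$state_posterior)), rep(1, 40))
  expect_equal(apply(fb$pair_posterior, 1, sum), rep(1, 39))
  # summing xi over the destination state recovers gamma at t
  marg <- apply(fb$pair_posterior, c(1, 2), sum)
  expect_lt(max(abs(marg - fb$state_posterior[1:39, ])), 1e-9)
})

test_that("degenerate closed forms: T = 1 and constant emissions", {
  obs1 <- random_obs(1)
  params <- random_params()
  fb <- forward_backward(obs1, params)
  lB <- emission_table(obs1, params$u)
  expect_equal(fb$log_likelihood, log(sum(params$pi * exp(lB[1, ]))))
  v <- viterbi_decode(obs1, params)
  expect_equal(v$path, unname(which.max(params$pi * exp(lB[1, ]))))

  # constant emission rows marginalize the paths away: loglik = sum log c
  obs <- random_obs(7)
  lB_const <- matrix(log(0.3), 7, 3)
  fb2 <- forward_backward(obs, params, logB = lB_const)
  expect_equal(fb2$log_likelihood, 7 * log(0.3))
})

test_that("emission scaling leaves posteriors and the Viterbi path unchanged", {
  set.seed(131)
  obs <- random_obs(15)
  params <- random_params()
  lB <- emission_table(obs, params$u)
  fb1 <- forward_backward(obs, params, logB = lB)
  fb2 <- forward_backward(obs, params, logB = lB + 7.3)
  expect_equal(fb1$state_posterior, fb2$state_posterior, tolerance = 1e-12)
  expect_equal(fb2$log_likelihood - fb1$log_likelihood, 15 * 7.3)
  b1 <- brute_force_hmm(obs, params)
  v <- viterbi_decode(obs, params)
  expect_equal(v$path, b1$viterbi)
})

test_that("viterbi ties break toward the lower state index", {
  obs <- random_obs(5)
  params <- hmm_parameters(pi = rep(1, 3) / 3,
                           A = matrix(1 / 3, 3, 3), u = c(0.9, 0.5, 0.1))
  lB <- matrix(log(0.2), 5, 3)
  # symmetric model, identical emissions: every path ties; expect all aa
  r <- hmmsnv:::.viterbi_chain(lB, params$pi, params$A)
  expect_equal(r$path, rep(1L, 5))
})

test_that("update_initial and update_transitions follow the expected counts", {
  # degenerate posterior along the path aa, aa, ab, aa
  path <- c(1L, 1L, 2L, 1L)
  gamma <- diag(3)[path, ]
  xi <- matrix(0, 3, 9)
  for (t in 1:3) xi[t, (path[t] - 1) * 3 + path[t + 1]] <- 1
  cache <- structure(list(chains = list(list(gamma = gamma, xi = xi,
                                             loglik = 0, loglik_backward = 0)),
                          state_posterior = gamma),
                     class = "hmm_trellis")
  expect_equal(unname(update_initial(cache)), c(1, 0, 0))
  A <- suppressWarnings(update_transitions(cache))  # bb never occupied
  expect_equal(unname(A[1, ]), c(0.5, 0.5, 0))   # aa: one to aa, one to ab
  expect_equal(unname(A[2, ]), c(1, 0, 0))        # ab -> aa
  expect_equal(unname(rowSums(A)), rep(1, 3))
  # bb never occupied: keeps the supplied previous row
  A_prev <- matrix(c(0.2, 0.3, 0.5), 3, 3, byrow = TRUE)
  expect_warning(A2 <- update_transitions(cache, A_prev), "zero expected")
  expect_equal(unname(A2[3, ]), c(0.2, 0.3, 0.5))

  # random instance vs brute-force expected transition counts
  set.seed(151)
  obs <- random_obs(4)
  params <- random_params()
  b <- brute_force_hmm(obs, params)
  fb <- forward_backward(obs, params)
  A_hat <- update_transitions(fb, params$A)
  A_oracle <- b$trans_num / rowSums(b$trans_num)
  expect_lt(max(abs(A_hat - A_oracle)), 1e-10)
  expect_lt(max(abs(update_initial(fb) - b$posterior[1, ])), 1e-10)
})

test_that("the Newton u-update finds the grid-search maximizer", {
  set.seed(163)
  cfg <- train_config(newton_steps = 50L)
  for (k in 1:10) {
    obs <- random_obs(sample(3:6, 1))
    params <- random_params()
    fb <- forward_backward(obs, params)
    u_new <- update_u_newton(obs, fb, params$u, cfg)
    for (i in 1:3) {
      u_star <- grid_search_u(obs, fb$state_posterior[, i], step = 1e-5)
      expect_lt(abs(u_new[i] - u_star), 1e-4)
    }
  }
})

test_that("Newton respects stationary points and clamps monotone objectives", {
  # Every read has match probability exactly 1/4 at u = 1/2, so matches
  # weigh 1/p = 4 and mismatches 1/(1-p) = 4/3 in the score: a site with
  # one match and three mismatches of equal (r, q) is stationary at 1/2.
  obs <- new_snv_obs(
    data.frame(chrom = "c", pos = 1L, ref = "A", alt = "T",
               L = 4L, P = 1L, stringsAsFactors = FALSE),
    match = c(TRUE, FALSE, FALSE, FALSE), r = rep(0.9, 4), q = rep(0.8, 4))
  cache <- structure(list(chains = list(), state_posterior = matrix(1, 1, 3)),
                     class = "hmm_trellis")
  u <- update_u_newton(obs, cache, c(0.5, 0.5, 0.5), train_config())
  expect_equal(unname(u), rep(0.5, 3))
  # and Newton converges to the same point from elsewhere
  u_far <- update_u_newton(obs, cache, c(0.2, 0.8, 0.35),
                           train_config(newton_steps = 50L))
  expect_equal(unname(u_far), rep(0.5, 3), tolerance = 1e-8)
  # all matches with perfect qualities: Q3 increasing in u, clamps at 1 - eps
  obs2 <- new_snv_obs(
    data.frame(chrom = "c", pos = 1L, ref = "A", alt = NA_character_,
               L = 3L, P = 3L, stringsAsFactors = FALSE),
    match = rep(TRUE, 3), r = rep(1, 3), q = rep(1, 3))
  u2 <- update_u_newton(obs2, cache, c(0.5, 0.5, 0.5),
                        train_config(newton_steps = 50L))
  expect_equal(unname(u2), rep(1 - 1e-6, 3))
})

test_that("baum_welch_train honors its iteration and tolerance contracts", {
  set.seed(173)
  sim <- obs_from_sim(400, 6, seed = 19)
  one <- baum_welch_train(sim$obs, config = train_config(max_iter = 1L))
  expect_equal(one$n_iter, 1L)
  expect_length(one$loglik_trace, 1L)
  expect_false(one$converged)
  inf_tol <- baum_welch_train(sim$obs, config = train_config(tol = Inf))
  expect_equal(inf_tol$n_iter, 1L)
  expect_true(inf_tol$converged)

  fit <- baum_welch_train(sim$obs,
                          config = train_config(max_iter = 15L, tol = 1e-4))
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
})

test_that("multi-chromosome sets train and decode per chain", {
  f <- withr::local_tempfile(fileext = ".pileup")
  set.seed(181)
  lines <- c(sprintf("chr1\t%d\tA\t2\t..\t%s\t]]", 1:30,
                     strrep(intToUtf8(sample(30:40, 1) + 33L), 2)),
             sprintf("chr2\t%d\tA\t2\tTT\tII\t]]", 1:30))
  writeLines(lines, f)
  obs <- read_pileup(f, filter_config(0L, 0L, 0L))
  expect_equal(sort(unique(obs$chain)), 1:2)
  fit <- baum_welch_train(obs, config = train_config(max_iter = 5L))
  v <- viterbi_decode(obs, fit$params)
  expect_length(v$path, 60L)
  fb <- forward_backward(obs, fit$params)
  expect_equal(nrow(fb$state_posterior), 60L)
  expect_null(fb$pair_posterior)  # only defined for single-chain sets
})

test_that("parameter files round-trip exactly", {
  params <- random_params()
  f <- withr::local_tempfile()
  write_hmm_parameters(params, f, hyper = prior_hyperparameters(),
                       n_iter = 7L, log_likelihood = -123.456,
                       converged = TRUE)
  back <- read_hmm_parameters(f)
  expect_equal(back$pi, params$pi)
  expect_equal(back$A, params$A)
  expect_equal(back$u, params$u)
  expect_equal(attr(back, "n_iter"), 7)
  expect_equal(attr(back, "log_likelihood"), -123.456)
  expect_error(read_hmm_parameters(withr::local_tempfile()), "not found")
  f2 <- withr::local_tempfile()
  writeLines("pi\t0.5 0.5", f2)
  expect_error(read_hmm_parameters(f2), "malformed")
})

test_that("hmm_parameters validates its invariants", {
  expect_error(hmm_parameters(c(0.5, 0.5, 0.1), diag(3), c(0.9, 0.5, 0.1)),
               "sum to 1")
  A_bad <- rbind(c(0.5, 0.5, 0.1), c(0, 1, 0), c(0, 0, 1))
  expect_error(hmm_parameters(c(1, 0, 0), A_bad, c(0.9, 0.5, 0.1)),
               "rows of A")
  p <- hmm_parameters(c(1, 0, 0), diag(3), c(1, 0.5, 0))  # u clamped
  expect_equal(unname(p$u), c(1 - 1e-6, 0.5, 1e-6))
})
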