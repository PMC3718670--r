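#' Simulation configuration
#'
#' Describes a synthetic genome of covered sites whose genotype states
#' follow the three-state Markov chain and whose reads are generated by the
#' same per-read model the caller inverts. Defaults emulate a 10X
#' resequencing run: zero-truncated Poisson depth with mean
#' `mean_depth`, uniform integer Phred base qualities in
#' `base_qual_range` and mapping qualities in `map_qual_range`, and the
#' prior-mean parameters as the true model. `error_third_allele_rate` is
#' the per-read probability of showing a third allele (neither reference
#' nor the site's alternate), emulating the rare errors that the caller's
#' top-2 allele rule removes.
#'
#' @param n_sites Number of covered sites.
#' @param mean_depth Mean sequencing depth (10 and 40 mirror the two
#'   benchmark regimes).
#' @param true_params True [hmm_parameters()] generating the data; default
#'   is the prior mean ([init_from_priors()]).
#' @param base_qual_range,map_qual_range Integer Phred ranges (inclusive).
#' @param error_third_allele_rate Per-read third-allele error probability.
#' @param seed Mandatory integer seed.
#' @param chrom Chromosome name written to the pileup.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_sites, mean_depth = 10,
                              true_params = init_from_priors(),
                              base_qual_range = c(10L, 40L),
                              map_qual_range = c(20L, 60L),
                              error_third_allele_rate = 0.005,
                              seed, chrom = "sim1") {
  stopifnot(n_sites >= 1L, mean_depth > 0,
            inherits(true_params, "hmm_parameters"),
            length(base_qual_range) == 2L, length(map_qual_range) == 2L,
            base_qual_range[1] >= 0L, base_qual_range[1] <= base_qual_range[2],
            map_qual_range[1] >= 0L, map_qual_range[1] <= map_qual_range[2],
            error_third_allele_rate >= 0, error_third_allele_rate < 1)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for simulation")
  structure(list(n_sites = as.integer(n_sites), mean_depth = mean_depth,
                 true_params = true_params,
                 base_qual_range = as.integer(base_qual_range),
                 map_qual_range = as.integer(map_qual_range),
                 error_third_allele_rate = error_third_allele_rate,
                 seed = as.integer(seed), chrom = chrom),
            class = "simulation_config")
}

#' Simulate a genotype state path from the Markov chain
#'
#' `s_1 ~ pi`, `s_(t+1) ~ A[s_t, ]`; seeded and reproducible.
#'
#' @param params An [hmm_parameters()] object.
#' @param n_sites Path length.
#' @param seed Integer seed.
#' @return Integer vector of states in 1..3.
#' @export
simulate_truth_path <- function(params, n_sites, seed) {
  stopifnot(inherits(params, "hmm_parameters"), n_sites >= 1L)
  set.seed(as.integer(seed))
  s <- integer(n_sites)
  s[1] <- sample.int(N_STATES, 1L, prob = params$pi)
  if (n_sites > 1L) {
    un <- runif(n_sites - 1L)
    cumA <- t(apply(params$A, 1L, cumsum))
    for (t in 2:n_sites)
      s[t] <- findInterval(un[t - 1L], cumA[s[t - 1L], ]) + 1L
  }
  s
}

#' Simulate a pileup file with known ground truth
#'
#' Per site: depth is drawn zero-truncated Poisson; each read gets uniform
#' integer Phred base and mapping qualities in the configured ranges, which
#' are converted to correctness probabilities `q` and `r`; the read shows
#' the reference base with probability [per_read_match_prob()]`(r, q, u_s)`
#' -- the identical expression the emission model evaluates -- and the
#' site's alternate base otherwise; independently, a read is replaced by a
#' third allele with probability `error_third_allele_rate`. Reference and
#' alternate bases are drawn uniformly per site. Writes a 7-column
#' SAMtools-style pileup (`.` for reference matches, explicit base letters
#' otherwise, Phred+33 qualities) plus a truth TSV, both byte-reproducible
#' under a fixed seed.
#'
#' @param states Integer state path (e.g. from [simulate_truth_path()]).
#' @param config A [simulation_config()]; its seed drives all read-level
#'   randomness (offset so it does not replay the path seed).
#' @param pileup_path,truth_path Output files.
#' @return Invisibly, a list with `pileup_path`, `truth_path` and a
#'   bookkeeping data frame `sites` (`pos`, `state`, `ref`, `alt`, `depth`,
#'   `L`, `P`, `n_third`), where `L`/`P` count non-third-allele reads and
#'   reference matches among them.
#' @export
simulate_pileup <- function(states, config, pileup_path, truth_path) {
  stopifnot(inherits(config, "simulation_config"),
            all(states %in% 1:3))
  n <- length(states)
  set.seed(config$seed + 1L)
  depth <- rpois(n, config$mean_depth)
  while (any(depth == 0L))
    depth[depth == 0L] <- rpois(sum(depth == 0L), config$mean_depth)
  bases4 <- c("A", "C", "G", "T")
  ref <- sample(bases4, n, replace = TRUE)
  alt_off <- sample.int(3L, n, replace = TRUE)     # alt != ref, uniform
  alt <- bases4[(match(ref, bases4) - 1L + alt_off) %% 4L + 1L]

  total <- sum(depth)
  site <- rep.int(seq_len(n), depth)
  draw <- function(rng, n) {   # guard the degenerate single-value range
    v <- seq.int(rng[1], rng[2])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  bq <- draw(config$base_qual_range, total)
  mq <- draw(config$map_qual_range, total)
  q <- phred_to_prob(bq)
  r <- phred_to_prob(mq)
  u_read <- config$true_params$u[states[site]]
  is_match <- runif(total) < per_read_match_prob(r, q, u_read)
  is_third <- runif(total) < config$error_third_allele_rate
  # third-allele errors: a base that is neither ref nor alt at the site
  third_off <- sample.int(2L, total, replace = TRUE)
  read_base <- ifelse(is_match, ref[site], alt[site])
  if (any(is_third)) {
    ri <- match(ref[site], bases4) - 1L
    ai <- match(alt[site], bases4) - 1L
    other <- vapply(which(is_third), function(k) {
      cand <- setdiff(0:3, c(ri[k], ai[k]))
      cand[third_off[k]]
    }, integer(1))
    read_base[is_third] <- bases4[other + 1L]
  }
  shown <- ifelse(read_base == ref[site], ".", read_base)

  chunk <- function(x) split(x, site)
  base_str <- vapply(chunk(shown), paste0, character(1), collapse = "")
  bq_str <- vapply(chunk(intToUtf8(bq + 33L, multiple = TRUE)),
                   paste0, character(1), collapse = "")
  mq_str <- vapply(chunk(intToUtf8(mq + 33L, multiple = TRUE)),
                   paste0, character(1), collapse = "")
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%s\t%s",
                   config$chrom, seq_len(n), ref, depth,
                   base_str, bq_str, mq_str)
  writeLines(lines, pileup_path)
  writeLines(sprintf("%s\t%d\t%s", config$chrom, seq_len(n),
                     STATE_LABELS[states]), truth_path)

  keep <- !is_third
  L <- as.integer(rowsum(as.numeric(keep), site, reorder = FALSE)[, 1])
  P <- as.integer(rowsum(as.numeric(keep & is_match), site, reorder = FALSE)[, 1])
  invisible(list(
    pileup_path = pileup_path, truth_path = truth_path,
    sites = data.frame(pos = seq_len(n), state = states, ref = ref,
                       alt = alt, depth = depth, L = L, P = P,
                       n_third = depth - L, stringsAsFactors = FALSE)))
}

#' Parameter-recovery experiment
#'
#' The end-to-end validation harness: simulate a pileup from known
#' parameters, write and re-parse it, train from the default priors, and
#' compare the trained parameters and the decoded path with the truth.
#'
#' @param config A [simulation_config()].
#' @param tconfig A [train_config()].
#' @param hyper A [prior_hyperparameters()] used for initialization.
#' @param filt A [filter_config()]; the default disables the MQ/BQ
#'   thresholds so that training sees exactly the generated reads.
#' @param dir Directory for the intermediate files (a fresh temporary
#'   directory by default).
#' @return An object of class `recovery_report`: list with `fit`,
#'   `max_u_error`, `max_A_error`, `max_pi_error`, `state_accuracy`
#'   (Viterbi vs truth), `n_sites` and the true parameters.
#' @export
recovery_experiment <- function(config, tconfig = train_config(),
                                hyper = prior_hyperparameters(),
                                filt = filter_config(mq_min = 0L, bq_min = 0L,
                                                     mvc = 0L),
                                dir = tempfile("recovery")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states <- simulate_truth_path(config$true_params, config$n_sites, config$seed)
  sim <- simulate_pileup(states, config,
                         file.path(dir, "sim.pileup"),
                         file.path(dir, "truth.tsv"))
  obs <- read_pileup(sim$pileup_path, filt)
  fit <- baum_welch_train(obs, hyper = hyper, config = tconfig)
  dec <- viterbi_decode(obs, fit$params)
  truth_states <- states[obs$sites$pos]
  structure(list(
    fit = fit,
    true_params = config$true_params,
    max_u_error = max(abs(fit$params$u - config$true_params$u)),
    max_A_error = max(abs(fit$params$A - config$true_params$A)),
    max_pi_error = max(abs(fit$params$pi - config$true_params$pi)),
    state_accuracy = mean(dec$path == truth_states),
    n_sites = length(obs)), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("<recovery_report> %d sites: max|u - u*| = %.4f, ",
                     "max|A - A*| = %.4f, state accuracy %.4f\n"),
              x$n_sites, x$max_u_error, x$max_A_error, x$state_accuracy))
  invisible(x)
}
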