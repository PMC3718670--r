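#' Log emission likelihood of one site under a genotype state
#'
#' The emission distribution is a generalized binomial over the retained
#' reads: with per-read reference-match probability
#' `p_j(u) = 0.25 (1 - r_j) + 0.5 r_j (q_j u + (1 - q_j)(1 - u))`
#' (see [per_read_match_prob()]), the site likelihood is
#' `choose(L, P) * prod_match p_j(u) * prod_mismatch (1 - p_j(u))`,
#' where `L` is the retained coverage and `P` the reference-match count.
#' Computed and returned in log space; the binomial coefficient uses
#' log-gamma.
#'
#' @param r,q Numeric vectors of per-read mapping / base-call correctness
#'   probabilities (length `L`; may be empty).
#' @param match Logical vector: does the read base equal the reference?
#' @param u Reference-allele probability of the state, strictly in (0, 1).
#' @return The log-likelihood (a single finite or `-Inf` value; `0` -- i.e.
#'   likelihood 1 -- for an empty observation).
#' @examples
#' exp(site_emission(r = 1, q = 1, match = TRUE, u = 1 - 1e-12))  # ~0.5
#' @export
site_emission <- function(r, q, match, u) {
  if (length(u) != 1L || !is.finite(u) || u <= 0 || u >= 1)
    stop("u must be a single value strictly inside (0, 1)")
  L <- length(match)
  if (length(r) != L || length(q) != L)
    stop("r, q and match must have equal length")
  if (L == 0L) return(0)
  p <- per_read_match_prob(r, q, u)
  lchoose(L, sum(match)) + sum(log(p[match])) + sum(log1p(-p[!match]))
}

#' Log emission table for an observation sequence
#'
#' Evaluates [site_emission()] at every site for each of the three genotype
#' states, vectorized over the flattened read representation.
#'
#' @param obs An [snv_obs] observation set.
#' @param u Numeric 3-vector of per-state reference-allele probabilities.
#' @return A `T x 3` matrix of log emission likelihoods (columns aa, ab,
#'   bb).
#' @export
emission_table <- function(obs, u) {
  stopifnot(inherits(obs, "snv_obs"))
  if (length(u) != 3L || any(u <= 0) || any(u >= 1))
    stop("u must be a 3-vector strictly inside (0, 1)")
  T_ <- length(obs)
  if (!T_) stop("empty observation sequence")
  out <- matrix(0, T_, N_STATES, dimnames = list(NULL, STATE_LABELS))
  m <- obs$match
  for (i in seq_len(N_STATES)) {
    p <- obs$a + obs$b * u[i]
    lp <- numeric(length(p))
    lp[m] <- log(p[m])
    lp[!m] <- log1p(-p[!m])
    out[, i] <- rowsum(lp, obs$site_of_read, reorder = FALSE)[, 1]
  }
  out + obs$logC
}
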