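#' Per-site observation sets
#'
#' An `snv_obs` object holds an ordered sequence of per-site observations in
#' a column-oriented layout: a `sites` data frame (one row per covered
#' position, in chain order) and flattened per-read vectors. Per read the
#' model only needs the mapping-correctness probability `r`, the
#' base-call-correctness probability `q` and whether the read base matches
#' the reference allele; the affine coefficients of the per-read match
#' probability, `p(u) = a + b * u`, are precomputed once.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`, `L`
#'   (retained coverage) and `P` (reference-match count).
#' @param match Logical vector, one entry per retained read, flattened in
#'   site order.
#' @param r,q Numeric vectors of per-read correctness probabilities,
#'   parallel to `match`.
#' @return An object of class `snv_obs`.
#' @name snv_obs
#' @export
new_snv_obs <- function(sites, match, r, q) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "L", "P") %in% names(sites)))
  if (length(match) != sum(sites$L) || length(r) != length(match) ||
      length(q) != length(match))
    stop("read vectors are not aligned with site coverages")
  if (any(sites$L < 1L)) stop("snv_obs sites must have coverage >= 1")
  if (any(sites$P < 0L | sites$P > sites$L))
    stop("P must lie in [0, L] at every site")
  site_of_read <- rep.int(seq_len(nrow(sites)), sites$L)
  P_check <- rowsum(as.numeric(match), site_of_read, reorder = FALSE)[, 1]
  if (any(P_check != sites$P))
    stop("P does not equal the number of matching reads at some site")
  ab <- per_read_coefs(r, q)
  chain <- rep.int(seq_along(rle(sites$chrom)$lengths), rle(sites$chrom)$lengths)
  structure(list(
    sites = sites,
    site_of_read = site_of_read,
    match = as.logical(match),
    r = as.numeric(r), q = as.numeric(q),
    a = ab$a, b = ab$b,
    logC = lchoose(sites$L, sites$P),
    chain = as.integer(chain)
  ), class = "snv_obs")
}

#' @export
length.snv_obs <- function(x) nrow(x$sites)

#' @export
print.snv_obs <- function(x, ...) {
  cat(sprintf("<snv_obs> %d sites on %d chromosome(s), %d retained reads (mean depth %.2f)\n",
              length(x), length(unique(x$sites$chrom)), length(x$match),
              mean(x$sites$L)))
  invisible(x)
}

#' Extract a contiguous subset of sites
#'
#' @param x An `snv_obs`.
#' @param i Integer vector of site indices (must be sorted, typically a
#'   contiguous range).
#' @param ... Unused.
#' @export
`[.snv_obs` <- function(x, i, ...) {
  i <- sort(unique(as.integer(i)))
  keep <- x$site_of_read %in% i
  new_snv_obs(x$sites[i, , drop = FALSE],
              x$match[keep], x$r[keep], x$q[keep])
}

# Affine coefficients of the per-read reference-match probability:
#   p(u) = 0.25 (1 - r) + 0.5 r (q u + (1 - q)(1 - u)) = a + b u
per_read_coefs <- function(r, q) {
  list(a = 0.25 * (1 - r) + 0.5 * r * (1 - q),
       b = 0.5 * r * (2 * q - 1))
}

#' Per-read reference-match probability
#'
#' The probability that a read shows the reference base, given the state's
#' reference-allele frequency `u`: a misplaced read (probability `1 - r`)
#' matches a uniform base with probability 1/4; a correctly placed read
#' contributes `0.5 * r` times the probability that the sequenced base is
#' called as the reference, i.e. `q u + (1 - q)(1 - u)`. This exact
#' expression is shared between the emission model ([site_emission()]) and
#' the generative simulator ([simulate_pileup()]), so the two cannot drift
#' apart.
#'
#' @param r,q Per-read mapping / base-call correctness probabilities.
#' @param u Reference-allele probability of the genotype state, in (0, 1).
#' @return Numeric vector of match probabilities in `[0, 0.75]`.
#' @export
per_read_match_prob <- function(r, q, u) {
  ab <- per_read_coefs(r, q)
  ab$a + ab$b * u
}
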