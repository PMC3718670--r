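---
title: "hmmsnv: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hmmsnv: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Tumor resequencing data often has shallow, uneven coverage, and callers
that classify one position at a time lose both sensitivity and
specificity when only a handful of reads cover a site. `hmmsnv` treats
the genotype sequence along the genome as a three-state hidden Markov
chain — aa (homozygous reference), ab (heterozygous), bb (homozygous
non-reference) — so that each position is called in the context of its
neighbours and of the genome-wide genotype composition. Two modelling
assumptions carry all of the machinery:

1. **Markov context.** Non-variant stretches are long and variants
   cluster; a first-order chain over {aa, ab, bb} with sticky transition
   rows captures this at negligible cost. Consecutive *covered* sites are
   treated as chain neighbours regardless of the genomic gap between
   them; chains break only at chromosome boundaries. (Gap-aware
   transition scaling would be a refinement; with the very sticky
   transition rows used here the practical effect of gaps is small.)
2. **Quality-aware emissions.** Each retained read contributes through
   two Phred-derived correctness probabilities: `r` (the read is mapped
   to the right place) and `q` (the base was called correctly). Given the
   state's reference-allele probability `u`, a read shows the reference
   base with probability

   ```
   p(u) = 1/4 (1 - r) + 1/2 r (q u + (1 - q)(1 - u))
   ```

   and the site emission is the generalized binomial
   `choose(L, P) * prod_match p_j(u) * prod_mismatch (1 - p_j(u))`, where
   `P` of `L` retained reads match the reference.

### The emission grouping, made explicit

The per-read factor above is a *screening* model, not a literal
read-generating mechanism: a misplaced read (probability `1 - r`) matches
a uniform base with probability 1/4, and a well-placed read contributes
with an additional factor 1/2. A consequence worth knowing is that
`p(u) <= 3/4` always, and `p(1/2) = 1/4` for *every* read regardless of
its qualities. The three genotype states therefore map to per-read match
probabilities near 1/2, 1/4 and 0 (for high-quality reads), which keeps
them well separated, and because the simulator draws reads from exactly
the same `p(u)` (one shared function, `per_read_match_prob()`), inference
and generation cannot drift apart. But the grouping has a second, less
obvious consequence: matches enter the score with weight `1/p = 4` at
`u = 1/2` while mismatches enter with `1/(1-p) = 4/3`, so a site is
stationary at `u = 1/2` when matches and mismatches are balanced 1:3 —
not 1:1. The unit tests pin this down. The grouping — `p` for matching
reads, `1 - p` for mismatching reads, with the binomial coefficient — is
isolated in `site_emission()` so that a different reading can be swapped
in at one place.

`u` is defined against the *reference* allele (`P` counts
reference-matching reads), so aa sits near `u = 1`, ab near `1/2`, bb
near `0`. An alternative convention — `u` as the frequency of the
site-majority allele — breaks the correspondence between `P` and `u`
whenever the majority allele is non-reference, and was rejected for that
reason.

## Estimation

Training is Baum–Welch. The E-step runs scaled forward–backward
recursions (compiled C++; per-step renormalization plus a per-row
`max`-shift of the log emissions, so chains of millions of sites cannot
underflow); the total log-likelihood is the sum of log scale factors, and
an independently scaled backward recursion recomputes it as a built-in
cross-check (required agreement: 1e-8 relative). The M-step is:

* `pi <- gamma_1` (averaged over chains when several chromosomes are
  present);
* `A[i, ] <- sum_t xi_t(i, .) / sum_t gamma_t(i)`, rows renormalized;
  a state with zero expected occupancy keeps its previous row instead of
  producing `NaN`;
* `u_i <- argmax of Q3(u) = sum_t gamma_t(i) log f(o_t; u)`. `Q3` has no
  closed-form maximizer, but each read contributes the log of an affine
  function of `u`, so `Q3` is strictly concave and a damped Newton
  iteration on the analytic derivatives (step halved until the objective
  does not decrease, result clamped to `[1e-6, 1 - 1e-6]`) converges to
  the global maximizer; the tests verify agreement with a dense grid
  search to 1e-4.

The Dirichlet/Beta priors (`delta = (1000, 100, 100)`,
`alpha = (1000, 500, 1)`, `beta = (1, 500, 1000)`, sticky `gamma` rows)
are used for **initialization only**: `prior_mean` (the default,
deterministic) starts from the prior means, `prior_sample` draws a seeded
random start. The `pi`/`A` updates are pure maximum likelihood, matching
the update formulas above; `train_config(map_updates = TRUE)` optionally
adds the `(delta - 1)` / `(gamma - 1)` pseudocounts for users who want
regularized updates. Decoding is Viterbi in log space with ties broken
toward the lower state index (aa before ab before bb), a deliberate
conservative bias: in an exact tie the non-variant interpretation wins.

Convergence is declared when the absolute change in total log-likelihood
falls below `tol` (default 1e-2 — at the 1e5-site scale this is a
relative change around 1e-7; tighten for small inputs) or after
`max_iter` (default 50) iterations.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mq_min` | 50 | minimum Phred mapping quality per read |
| `bq_min` | 20 | minimum Phred base quality per base call |
| `mvc` | 4 | least retained reads for an SNV to be *reported* |
| `default_mq` | 30 | mapping quality assumed when the pileup has no 7th column |
| `qual_offset` | 33 | ASCII offset (64 for legacy Illumina encodings) |
| `max_iter` / `tol` | 50 / 1e-2 | EM stopping rule (absolute log-likelihood change) |
| `newton_steps` | 8 | Newton iterations per state per EM step |

MQ/BQ defaults are the reference setting of the benchmark comparison this
model family was evaluated under; MVC is best chosen as 15–25% of the
mean depth (2–5 at 10X, 6–9 at 40X) — too small admits calls supported by
almost nothing, too large discards confidently covered sites. The MVC
gate is applied **after** decoding: low-coverage sites still contribute
context to their neighbours, they are just never reported as SNVs.

## The synthetic world

The simulator emits exactly what the parser consumes (7-column
SAMtools-style pileup plus a truth TSV) and generates from the model
itself: states from the chain, depth from a zero-truncated Poisson
(standard coverage model) with configurable mean (10X/40X mirror the two
benchmark regimes), uniform integer Phred qualities (defaults: base
10–40, mapping 20–60, chosen to exercise the quality-weighting code
across its realistic range), reference match per read from the shared
`p(u)`, and a small third-allele error rate (default 0.005, the order of
magnitude of residual miscalls) that the caller's top-2 rule should
remove. The recovery experiments use as "true" parameters a genome-like
sticky chain (`pi = (0.90, 0.07, 0.03)`, diagonal of `A` =
(0.980, 0.900, 0.950), `u = (0.99, 0.5, 0.01)`) rather than the prior
means, so that training actually has to move the parameters.

What a green simulation test establishes: the estimation stack inverts
the generative model it claims to invert, at realistic sizes, from the
documented starting point. What it does not establish: performance on
real tumor data — alignment artifacts, strand bias, mapping-position
correlation, ploidy shifts and tumor cellularity are all outside the
generator (and the external benchmark datasets are not shipped). The
published benchmark confusion counts are therefore used only to verify
the *metric* formulas, and the recovery suite stands in for end-to-end
validation.

## Numerical and degenerate-input choices

* All trellis math in log space with per-step scaling; binomial
  coefficients via `lchoose` (log-gamma).
* `u` clamped to `[1e-6, 1 - 1e-6]`; emission evaluation at the clamp is
  finite for every admissible read.
* A site whose emission row is zero in all three states aborts with the
  position named (it signals a corrupt observation).
* Zero-coverage pileup lines, reference-`N` sites and all-filtered sites
  are dropped before the chain is formed; an empty file or a file with no
  surviving site is an error, not an empty result.
* Pileup input must be position-sorted with contiguous chromosome
  blocks; violations are errors, silently reordering would change the
  chain.
* `pi` is estimated from one first-position posterior per chromosome;
  with a single chain it is weakly identified and tends to a vertex.
  This is expected EM behaviour, does not affect `u`/`A` recovery, and is
  why the recovery criteria are stated on `u` and `A` only.
* Bulk (vectorized) pileup decoding and the one-record reference parser
  are both kept, and property-tested against each other; lines using the
  extended grammar (`^`, `$`, indels, `*`) take the reference path.

## Known limitations

* Indels are consumed and discarded; only substitutions are modelled.
* One sample, one chain of genotypes: no somatic/germline joint calling,
  no multi-sample genotyping, no ploidy model.
* The Maq pileup dialect is a best-effort mapping onto the SAMtools
  column layout (optional `@` base-column prefix), as the exact legacy
  layout varies.
* VCF output is a minimal convenience subset (GT + DP, QUAL from the
  posterior); no genotype likelihoods, no multi-allelic records.
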