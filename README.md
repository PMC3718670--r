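# hmmsnv

Genotype calling and single-nucleotide-variant (SNV) detection from
SAMtools-style pileup text, aimed at tumor sequencing data where coverage
is low and per-site Bayesian callers lose power. Instead of classifying
each position in isolation, `hmmsnv` models the genotype sequence along the
genome as a discrete hidden Markov model, so that every call borrows
strength from its neighbours and from the genome-wide genotype
composition.

## The model

Each covered position *t* has a hidden genotype state
*s<sub>t</sub>* ∈ {aa, ab, bb} (homozygous reference, heterozygous,
homozygous non-reference); ab and bb are SNVs. The observation at *t* is
the set of retained reads with their mapping-correctness probabilities
*r<sub>jt</sub>* and base-call-correctness probabilities *q<sub>jt</sub>*
(decoded from Phred mapping and base qualities), of which
*P<sub>t</sub>* out of *L<sub>t</sub>* match the reference base. The
emission distribution is a quality-aware generalized binomial

> b<sub>i</sub>(o<sub>t</sub>) = C(L<sub>t</sub>, P<sub>t</sub>)
> ∏<sub>match</sub> p<sub>j</sub>(u<sub>i</sub>)
> ∏<sub>mismatch</sub> (1 − p<sub>j</sub>(u<sub>i</sub>)),
> &nbsp;&nbsp; p<sub>j</sub>(u) = ¼(1 − r<sub>j</sub>) +
> ½ r<sub>j</sub>(q<sub>j</sub>u + (1 − q<sub>j</sub>)(1 − u)),

where *u<sub>i</sub>* is the reference-allele probability of state *i*
(near 1, ½, 0 for aa, ab, bb). The chain is governed by an initial
distribution π and a 3×3 transition matrix **A**. Parameters
λ = (π, **A**, **u**) are initialized from Dirichlet/Beta priors that
encode "most of the genome is homozygous reference"
(δ = (1000, 100, 100), α = (1000, 500, 1), β = (1, 500, 1000), sticky
Dirichlet rows for **A**), estimated by Baum–Welch — with a damped Newton
sub-step for **u**, whose expected log-emission is concave — and decoded
by Viterbi. Calls are filtered by minimum mapping quality (MQ), minimum
base quality (BQ), a top-2 allele rule (rarer third alleles are treated
as sequencing errors), and a minimum-valid-coverage gate (MVC): an ab/bb
site is only reported as an SNV when at least MVC retained reads support
it. Recommended MVC is 15–25% of mean depth (≈2–5 at 10X, ≈6–9 at 40X).

## Worked example

Simulate a 20,000-site pileup at mean depth 10X with known ground truth,
self-train the model from the priors, decode, call, and score:

```r
library(hmmsnv)
pileup <- tempfile(); truth <- tempfile()
run_simulate(pileup, truth, n_sites = 20000, mean_depth = 10, seed = 42)

obs  <- read_pileup(pileup, filter_config(mq_min = 0, bq_min = 0))
fit  <- baum_welch_train(obs)         # default priors, prior-mean start
dec  <- viterbi_decode(obs, fit$params)
cache <- forward_backward(obs, fit$params)
calls <- call_sites(obs, dec$path, cache, filter_config(0, 0, mvc = 2))

ct <- confusion_counts(calls, read_truth_tsv(truth))
compute_metrics(ct)
```

which prints (as produced by this code):

```
<hmm_fit> 9 iteration(s), converged, final log-likelihood -33268.3786
<hmm_parameters>
  pi: 0.000000 0.000000 1.000000
  u:  0.990257 0.491293 0.000679
  ...
   TP    FP    TN    FN
12399   683  6143   775
sensitivity 94.12%  specificity 89.99%  accuracy 92.71%  F-score 0.9445
```

The trained `u` lands on the generating values (≈1, ≈½, ≈0): the aa/ab/bb
interpretation of the three states is recovered from the data, and 94% of
true SNVs are found at 90% specificity at 10X depth. (π concentrates on
the state the first position happens to be in — with a single chain the
initial distribution is only informed by one site.)

The same pipeline is available as subcommands:

```sh
Rscript -e 'hmmsnv::cli_main()' train    --pileup tumor.pileup --out params.txt --mq 50 --bq 20
Rscript -e 'hmmsnv::cli_main()' call     --pileup tumor.pileup --params params.txt \
                                         --out-tsv calls.tsv --out-vcf calls.vcf --mvc 4
Rscript -e 'hmmsnv::cli_main()' evaluate --calls calls.tsv --truth truth.tsv
Rscript -e 'hmmsnv::cli_main()' sweep    --pileup tumor.pileup --truth truth.tsv --grid grid.tsv
```

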