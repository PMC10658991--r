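# reosig

Rank-based gene-pair prognostic signatures for recurrence risk, built on
**relative expression orderings** (REO): within one sample, the only thing
that matters is whether gene *i* is expressed above gene *j*. A signature is
a small set of oriented pairs; each pair votes "high-risk" when its ordering
holds, and a sample is called high-risk when a strict majority of pairs vote
so. Because the classifier consumes within-sample orderings only, its calls
are invariant to any per-sample strictly increasing transformation of the
expression values — normalization choices and experimental batch effects
included — and it applies to one patient at a time, with no reference to a
cohort distribution.

The package is written for transcriptomics researchers who want to discover
such signatures from two independent survival cohorts (the motivating use
case is relapse-free survival in early-onset colorectal cancer, EOCRC,
diagnosed before age 50), and for anyone who wants a tested, reproducible
implementation of the top-scoring-pair family of survival classifiers.

## The method

Given two training cohorts with expression, age at diagnosis and
relapse-free survival (time `t`, event `δ`):

1. **Age-related genes.** Genes differentially expressed between the
   early-onset (< 50 y) and late-onset (> 60 y) strata by two-sided Wilcoxon
   rank-sum test, *p* < 0.05 in **both** cohorts.
2. **Pair encoding.** For every pair (*G*<sub>i</sub>, *G*<sub>j</sub>) of
   age-related genes, the per-sample indicator
   **1**{*G*<sub>i</sub> > *G*<sub>j</sub>}.
3. **Cox screening.** Univariate Cox proportional-hazards fit of each
   indicator on survival in each cohort's surgery-only population; pairs
   with Wald *p* < 0.05 are kept and re-oriented so HR > 1 ("gene_high >
   gene_low votes high-risk").
4. **Consistency.** Pairs significant with the *same* orientation in both
   cohorts.
5. **De-redundancy.** Scanning pairs by ascending worse-cohort *p*, a pair
   is kept iff neither gene already occurs in a kept pair.
6. **Forward-stepwise selection.** Starting from the pair whose one-pair
   classifier has the largest Harrell C-index on the selection population
   (surgery-only early-onset samples), pairs are added greedily while the
   C-index strictly increases. The result is the *k*-gene-pair signature
   (k-GPS) with the strict-majority rule: high-risk iff votes > k/2.

A synthetic-data module generates two-cohort survival studies with planted
age-related genes and planted prognostic pairs (known ground truth), so the
whole funnel is testable end to end, including under per-cohort batch
distortions.

## Worked example

```r
library(reosig)

cfg <- reo_sim_config(seed = 42, n_samples_per_cohort = 200, n_genes = 120,
                      n_age_de_genes = 20, n_planted_pairs = 4)
study <- simulate_study(cfg)

sig <- reo_signature(study$train_a$cohort, study$train_b$cohort)
print(sig)
#> REO gene-pair signature: k = 4 pair(s), high-risk iff votes > 2
#>   training C-index: 0.7290
#>   pairs (gene_high > gene_low votes high-risk):
#>     G0001|G0002
#>     G0005|G0006
#>     G0003|G0004
#>     G0007|G0008

sig$funnel
#>                stage count
#> 1       genes_shared   120
#> 2        deg_cohortA    35
#> 3        deg_cohortB    34
#> 4  age_related_genes    28
#> 5    candidate_pairs   378
#> 6   screened_cohortA    38
#> 7   screened_cohortB    35
#> 8   consistent_pairs     9
#> 9  deredundant_pairs     4
#> 10   signature_pairs     4

evaluate_signature(sig, study$validation$cohort)
#> Signature evaluation on cohort 'validation' (n = 200, events = 163)
#>   risk groups: HIGH 53, LOW 147
#>   high- vs low-risk: HR = 4.50 (95% CI 3.06-6.62), Wald p = 2.32e-14
#>   log-rank: chi-square = 68.199, p = 1.48e-16
#>   C-index of risk label: 0.6251
```

The generator planted 4 prognostic pairs; the funnel narrows 120 genes to 28
age-related genes, 378 candidate pairs to 4 gene-disjoint candidates, and
the stepwise search selects exactly the 4 planted pairs (`G0001|G0002`, ...
are the planted ids). On the held-out validation cohort the signature
separates a high-risk group with a hazard ratio of 4.5 for recurrence.
`plot(sig, study$validation$cohort)` draws the two Kaplan-Meier curves with
the log-rank p-value; `predict(sig, cohort)` returns per-sample votes and
labels; `write_signature()` / `read_signature()` freeze a signature as JSON.

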