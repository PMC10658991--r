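---
title: "Discovering REO gene-pair recurrence signatures"
author: "reosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering REO gene-pair recurrence signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The model

A relative-expression-ordering (REO) signature classifies one sample at a
time from qualitative, within-sample information: for an oriented gene pair
(gene_high, gene_low), the pair *votes* high-risk in a sample exactly when
`expression(gene_high) > expression(gene_low)` there. A signature of `k`
gene-disjoint pairs labels the sample high-risk iff strictly more than `k/2`
pairs vote so (for `k = 6`: votes > 3). Ties in expression vote low: the
ordering is strict, and on continuous values exact ties have measure zero.

Two properties make this family attractive for prognosis from expression
data. First, any per-sample strictly increasing transformation — scaling,
log, quantile shifts, rank replacement, monotone batch distortion — leaves
every within-sample ordering unchanged, so the classifier's calls are
*bit-identical* across such distortions. Second, no cohort-level reference
(means, quantiles) enters at prediction time, so the rule is applicable to
an individual patient.

## The discovery funnel and its assumptions

Discovery uses two independent training cohorts with expression, age at
diagnosis, a survival endpoint (`endpoint_time` in months,
`endpoint_event`) and a treatment arm, and proceeds in six stages
(`reo_signature()`):

1. **Age-related genes** — two-sided Wilcoxon rank-sum between the
   early-onset (< 50 y) and late-onset (> 60 y) strata, `alpha_deg = 0.05`,
   required in *both* cohorts. Both age cut-offs are strict; ages in
   [50, 60] belong to neither stratum and are excluded from this contrast.
2. **Pair encoding** — all `choose(m, 2)` ordering indicators of the `m`
   age-related genes, pairs taken in a fixed (lexicographic, C-locale)
   gene order.
3. **Cox screening** — a univariate proportional-hazards fit of each binary
   indicator on the screening population (default: surgery-only samples of
   both age strata, the stratum definition the age contrast used), Wald
   `p < alpha_cox = 0.05`. The proportional-hazards form is exactly what
   this stage tests; no functional form is assumed for expression itself.
   Orientation is then canonicalized so every reported hazard ratio exceeds
   1; for a binary indicator the flip is exact (the coefficient negates,
   the p-value is unchanged).
4. **Consistency** — pairs significant in both cohorts *with the same
   orientation*.
5. **De-redundancy** — pairs are scanned in ascending ranking p (we rank by
   the *worse* of the two cohorts' p-values, i.e. by guaranteed
   significance; ties break on lexicographic pair id) and kept iff neither
   gene occurs in an already-kept pair. The output is gene-disjoint.
6. **Forward-stepwise selection** — greedy maximization of Harrell's
   C-index of the voting classifier on the selection population (default:
   surgery-only early-onset samples of the first training cohort), stopping
   when no addition strictly increases the C-index.

No multiple-testing correction is applied anywhere: each stage filters on
raw p-values, the cross-cohort consistency requirement provides the
replication control, and the final subset is chosen by concordance rather
than significance.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha_deg` | 0.05 | per-cohort DEG cut-off (raw p) |
| `alpha_cox` | 0.05 | per-cohort Cox screening cut-off (raw Wald p) |
| `screen_filter` | surgery-only, both strata | population for stage 3 |
| `selection_filter` | surgery-only, early-onset | population for stage 6 |
| `ties` | `"efron"` | Cox tie handling; `"breslow"` available |
| `cindex_on` | `"votes"` | risk score during selection (see below) |

Efron's tie approximation is the default because it is the default of
mainstream survival software and is more accurate under tied event times;
Breslow is retained because under it the Cox score test at `beta = 0` for a
binary covariate equals the log-rank statistic exactly, an identity the test
suite asserts to 1e-8.

**Selection score.** The C-index during stepwise selection is computed on
the raw vote count by default, not on the binary majority label. The two
options agree about the final classifier's quality, but as a *search
criterion* the binary label is too coarse: an added pair that improves the
risk ordering of many samples without flipping any sample across the
majority threshold leaves the label-based C-index unchanged, so a
label-scored greedy search stalls after one or two rounds. In simulation the
label-scored search recovers 1–3 of 5 planted pairs, the vote-scored search
3–5 of 5, with identical voting rules at prediction time.
`cindex_on = "label"` remains available.

**Numerical choices.** "Failed to increase" in the stepwise stop rule is
strict with a 1e-12 floating-point guard. Ties between candidate additions
break on smaller de-redundancy ranking p, then lexicographic pair id, so the
selected signature is independent of candidate input order. Pairs whose Cox
fit diverges (monotone partial likelihood: the two indicator groups' event
times perfectly separated) are excluded from candidacy with a warning rather
than entering with an effectively infinite hazard ratio — such estimates are
artifacts of small strata. Constant indicators are skipped as
non-identifiable. In Harrell's C, comparable pairs require `t_i < t_j` with
an observed event at `t_i`; pairs with exactly equal times are skipped, and
score ties credit 1/2.

## What the synthetic generator emulates

`reo_sim_config()` / `simulate_study()` generate the data structure the
funnel assumes, with known ground truth:

- two age strata per cohort (`frac_eocrc = 0.35` early-onset, ages drawn in
  28–49 vs 61–88 — early-onset cases are the minority in practice, and the
  default still leaves a usable selection stratum of ~105 samples at the
  default `n_samples_per_cohort = 300`);
- gene-intrinsic baseline levels (`gene_mean_sd = 2`, drawn once per
  configuration and shared by all its cohorts, as real cohorts share each
  gene's characteristic level). A planted pair's two genes share one
  baseline, mirroring the comparable-level gene pairs REO signatures are
  built from; pairs of genes with well-separated baselines have
  near-constant orderings and carry no information, exactly as in real
  data;
- age-related genes: an additive shift (`age_effect_size = 1` noise-sd, sign
  alternating across genes) in the early-onset stratum. Planted-pair genes
  receive the shift too — both genes of a pair with the same sign, so the
  within-pair ordering stays age-independent — because the funnel only
  pairs age-related genes, and a prognostic pair must be age-related to be
  discoverable;
- planted prognostic pairs (`n_planted_pairs = 5`): the per-sample count of
  pairs in their high-risk ordering (centered) forms the linear predictor
  of an exponential proportional-hazards model
  (`planted_log_hr = log(3)`, `baseline_hazard = 0.02` events/month, a
  median time to recurrence of roughly three years at the null);
- right-censoring: uniform on `(0, tau)` with the horizon `tau` solved
  numerically (uniroot on the closed-form censoring probability) so the
  expected censored fraction matches `censoring_rate_target = 0.2`;
- optional batch distortions (`apply_batch_transform()`): affine, log,
  power, rank, or random strictly increasing piecewise-linear maps, drawn
  per sample or fixed cohort-wide.

Because planted pairs act through orderings, the ground truth is invariant
to batch transforms by construction. Survival times are continuous and in
months throughout; the unit is a convention, never converted.

The generator does *not* emulate gene–gene correlation structure, pathway
co-regulation, probe-level microarray noise, missing values (the package
rejects them rather than imputing — an absent value has no defined
ordering), or informative censoring. Passing tests therefore demonstrate
that the pipeline recovers the structure it assumes; they say nothing about
biological validity on real cohorts, where effect sizes, confounding and
correlation are less benign.

## Batch invariance: what is and is not invariant

The pair-level stages — encoding, Cox screening, consistency, de-redundancy,
classification — consume within-sample orderings only and are bit-identical
under arbitrary *per-sample* strictly increasing distortions; the test suite
checks this across five transform families. The age-DEG stage is different
in kind: it ranks each gene *across* samples, so it is invariant to a
distortion shared by a cohort's samples (ranks are preserved) but not to
independent per-sample distortions, which degrade any cross-sample analysis.
This matches practice: batch effects are platform- or lab-level, i.e.
cohort-wide, and the end-to-end recovery test applies a different
cohort-common distortion to each of its three cohorts, while the
classification-invariance test uses fully per-sample distortions.

## Degenerate inputs

Cohorts require at least two samples and fully finite expression; screening
requires at least 10 samples and one event, selection at least two events;
an all-censored group, a constant covariate, collinear covariates, or a
zero margin in an association table are errors with named causes. When a
funnel stage comes up empty (e.g. no consistent pairs under a null dataset),
`reo_signature()` signals a structured condition naming the stage and
`run_discover()` converts it into an `"empty"` outcome rather than an error
— an empty funnel is a result, not a failure.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to keep the full run in a
few minutes while leaving each check well-powered: invariance across 50
cohorts of 50 samples x 12 genes; 200 C-index instances up to n = 30 against
the brute-force oracle; 100 exact Wilcoxon enumerations at group sizes up to
8; 100 score-test/log-rank identities; end-to-end recovery over 25 seeds at
the default study conditions (300 samples/cohort, 5 planted pairs at HR 3,
20% censoring, per-cohort batch distortions); null calibration over 20 seeds
of 2000 genes; and exhaustive best-subset comparisons over 255 subsets on 20
instances.

## Known limitations

- The de-redundancy ranking (worse-cohort p) and the selection score
  (votes) are documented choices among defensible alternatives; both are
  exposed as parameters or flags.
- The stepwise search is greedy and can be beaten by the exhaustive best
  subset (the suite only asserts it is never *better*, as any correct
  greedy search must be).
- No cross-validation: like the design it implements, selection uses a
  single training split, and the training C-index is optimistically biased;
  judge a signature on held-out cohorts.
- Probe-to-gene collapsing, normalization and download of public cohorts
  are out of scope; expression is assumed pre-normalized (REO results are
  unaffected by per-sample monotone normalization in any case).
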