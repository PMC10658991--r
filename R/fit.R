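#' Fit an REO gene-pair recurrence-risk signature
#'
#' Runs the full discovery funnel on two independent training cohorts:
#' \enumerate{
#'   \item age-related genes: Wilcoxon rank-sum screen (early-onset vs
#'     late-onset) at `alpha_deg` in each cohort, intersected;
#'   \item pair encoding: all `choose(m, 2)` ordering indicators of the
#'     age-related genes;
#'   \item Cox screening: per-pair univariate proportional-hazards fits on
#'     the screening population of each cohort, retaining pairs with Wald
#'     p < `alpha_cox` in canonical (HR > 1) orientation;
#'   \item consistency: pairs significant in both cohorts with the same
#'     orientation;
#'   \item de-redundancy: the most significant pair per gene;
#'   \item forward-stepwise selection maximizing Harrell's C-index of the
#'     strict-majority voting classifier on the selection population of one
#'     training cohort.
#' }
#' No multiple-testing correction is applied at any stage; every stage
#' filters on raw p-values, and the final subset is chosen by concordance,
#' not significance.
#'
#' @param train_a,train_b two [reo_cohort()]s with both age strata.
#' @param alpha_deg per-cohort differential-expression cut-off.
#' @param alpha_cox per-cohort Cox screening cut-off.
#' @param screen_filter screening population (default surgery-only samples of
#'   both age strata).
#' @param selection_filter selection population (default surgery-only
#'   early-onset samples).
#' @param selection_cohort which training cohort the stepwise selection runs
#'   on, `"a"` (default) or `"b"`.
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param cindex_on score the selection C-index on raw `"votes"` (default;
#'   see [forward_stepwise()]) or on the binary majority `"label"`.
#' @return an `reo_signature` with the discovery `funnel` (stage counts in
#'   funnel order) and selection `trace` attached.
#' @seealso [classify()], [evaluate_signature()], [run_discover()]
#' @export
reo_signature <- function(train_a, train_b,
                          alpha_deg = 0.05, alpha_cox = 0.05,
                          screen_filter = cohort_filter(),
                          selection_filter = cohort_filter(age_groups = "EOCRC"),
                          selection_cohort = c("a", "b"),
                          ties = c("efron", "breslow"),
                          cindex_on = c("votes", "label")) {
  selection_cohort <- match.arg(selection_cohort)
  ties <- match.arg(ties)
  cindex_on <- match.arg(cindex_on)
  cl <- match.call()

  age_genes <- age_related_genes(train_a, train_b, alpha = alpha_deg)
  p_a <- attr(age_genes, "p_a")
  p_b <- attr(age_genes, "p_b")
  stage <- function(name, count) data.frame(stage = name, count = count,
                                            stringsAsFactors = FALSE)
  funnel <- rbind(
    stage("genes_shared", length(p_a)),
    stage(sprintf("deg_%s", train_a$name), sum(p_a < alpha_deg)),
    stage(sprintf("deg_%s", train_b$name), sum(p_b < alpha_deg)),
    stage("age_related_genes", length(age_genes)))
  if (length(age_genes) < 2) {
    stop_empty("age_related_genes",
               sprintf("only %d age-related gene(s) at alpha_deg = %g; cannot form pairs",
                       length(age_genes), alpha_deg))
  }
  funnel <- rbind(funnel,
                  stage("candidate_pairs", choose(length(age_genes), 2)))

  screen_a <- screen_cohort(train_a, age_genes, alpha = alpha_cox,
                            filter = screen_filter, ties = ties)
  screen_b <- screen_cohort(train_b, age_genes, alpha = alpha_cox,
                            filter = screen_filter, ties = ties)
  funnel <- rbind(funnel,
                  stage(sprintf("screened_%s", train_a$name), nrow(screen_a)),
                  stage(sprintf("screened_%s", train_b$name), nrow(screen_b)))
  if (nrow(screen_a) == 0 || nrow(screen_b) == 0) {
    stop_empty("cox_screen", "no pair passed the Cox screen in one of the cohorts")
  }

  consistent <- consistent_pairs(screen_a, screen_b)
  funnel <- rbind(funnel, stage("consistent_pairs", nrow(consistent)))
  if (nrow(consistent) == 0) {
    stop_empty("consistent_pairs",
               "no pair is significant with the same orientation in both cohorts")
  }

  candidates <- deredundant(consistent)
  funnel <- rbind(funnel, stage("deredundant_pairs", nrow(candidates)))

  training <- if (selection_cohort == "a") train_a else train_b
  sig <- forward_stepwise(candidates, training, filter = selection_filter,
                          cindex_on = cindex_on)
  funnel <- rbind(funnel, stage("signature_pairs", sig$k))
  sig$funnel <- funnel
  sig$call <- cl
  sig
}
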