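# Stage 1 of the discovery funnel: age-related DEGs, REO pair encoding,
# univariate Cox screening of pair indicators, cross-cohort consistency,
# redundancy removal.

surv_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(p_value), method = method),
            class = "reo_test")
}

#' @export
print.reo_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g\n", x$method,
              format(x$statistic), format(x$df), x$p_value))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact null distribution when both groups have at most 25
#' observations and the pooled data contain no ties; otherwise the normal
#' approximation with tie and continuity correction. If every value in both
#' groups is identical the test is vacuous: p = 1 with a warning.
#'
#' @param x,y numeric vectors for the two groups.
#' @return an `reo_test` with the rank-sum statistic (Mann-Whitney U for
#'   `x`) and two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop_reo("both groups must be non-empty")
  }
  check_finite_numeric(x, "x")
  check_finite_numeric(y, "y")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both groups; p = 1")
    return(surv_test_result(length(x) * length(y) / 2, NA_integer_, 1,
                            "wilcoxon_rank_sum"))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(x) <= 25 && length(y) <= 25
  wt <- wilcox.test(x, y, exact = exact, correct = TRUE)
  surv_test_result(wt$statistic, NA_integer_, wt$p.value,
                   if (exact) "wilcoxon_rank_sum_exact" else "wilcoxon_rank_sum_normal")
}

# per-gene Wilcoxon p-values, early-onset vs late-onset stratum
deg_pvalues <- function(cohort, genes = rownames(cohort$expression)) {
  grp <- cohort$clinical$age_group
  eo <- grp == "EOCRC"
  lo <- grp == "LOCRC"
  if (!any(eo) || !any(lo)) {
    stop_reo(sprintf("cohort '%s' lacks an age stratum (EOCRC: %d, LOCRC: %d)",
                     cohort$name, sum(eo), sum(lo)))
  }
  x <- cohort$expression[genes, , drop = FALSE]
  vapply(seq_along(genes), function(i) {
    wilcoxon_rank_sum(x[i, eo], x[i, lo])$p_value
  }, numeric(1)) |> setNames(genes)
}

#' Age-related genes: dual-cohort differential-expression screen
#'
#' A gene is age-related when its expression differs between the early-onset
#' and late-onset strata (two-sided Wilcoxon rank-sum, p < `alpha`) in *both*
#' cohorts, each tested independently. Only genes present in both cohorts are
#' considered.
#'
#' @param cohort_a,cohort_b two [reo_cohort()]s, each containing both age
#'   strata.
#' @param alpha per-cohort significance cut-off (raw p-values, no
#'   multiple-testing correction — each later funnel stage provides its own
#'   filtering).
#' @return character vector of gene ids, with per-cohort p-value vectors
#'   attached as attributes `p_a` and `p_b`.
#' @export
age_related_genes <- function(cohort_a, cohort_b, alpha = 0.05) {
  shared <- intersect(rownames(cohort_a$expression),
                      rownames(cohort_b$expression))
  if (length(shared) == 0) {
    stop_reo("cohorts share no genes")
  }
  p_a <- deg_pvalues(cohort_a, shared)
  p_b <- deg_pvalues(cohort_b, shared)
  hits <- shared[p_a < alpha & p_b < alpha]
  structure(hits, p_a = p_a, p_b = p_b)
}

#' Binary within-sample ordering indicator
#'
#' Returns 1 where `expr_i` strictly exceeds `expr_j`, else 0. Ties yield 0:
#' the ordering is strict, and on continuous expression values exact ties
#' have measure zero.
#'
#' @param expr_i,expr_j finite numeric vectors (recycled as usual).
#' @return integer vector of 0/1 indicators.
#' @export
reo_indicator <- function(expr_i, expr_j) {
  check_finite_numeric(expr_i, "expr_i")
  check_finite_numeric(expr_j, "expr_j")
  as.integer(expr_i > expr_j)
}

#' Encode all gene-pair ordering indicators for a cohort
#'
#' For every unordered pair of the given genes — taken in canonical
#' lexicographic order, first gene vs second — the per-sample strict-ordering
#' indicator is computed, giving a `choose(m, 2)`-row binary matrix. Being a
#' pure function of within-sample orderings, the encoding is invariant to any
#' per-sample strictly increasing transform of the expression values.
#'
#' @param cohort an [reo_cohort()].
#' @param genes at least two gene ids, all present in the cohort.
#' @return integer 0/1 matrix, one row per pair (rownames
#'   `"<first>|<second>"`), one column per sample.
#' @export
encode_pairs <- function(cohort, genes) {
  if (length(genes) < 2) {
    stop_reo("need at least 2 genes to form pairs")
  }
  absent <- setdiff(genes, rownames(cohort$expression))
  if (length(absent) > 0) {
    stop_reo(sprintf("gene(s) absent from cohort '%s': %s", cohort$name,
                     paste(absent, collapse = ", ")))
  }
  gs <- lex_sort(genes)
  idx <- combn(length(gs), 2)
  x <- cohort$expression[gs, , drop = FALSE]
  m <- (x[idx[1, ], , drop = FALSE] > x[idx[2, ], , drop = FALSE]) * 1L
  rownames(m) <- pair_id(gs[idx[1, ]], gs[idx[2, ]])
  m
}

# lean single-binary-covariate Cox fit used by the screening loop; returns
# NULL for a monotone-likelihood (divergent) fit
fit_pair_cox <- function(ind, y, ties) {
  diverged <- FALSE
  fit <- withCallingHandlers(
    coxph(y ~ ind, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  if (diverged || !is.finite(beta) || abs(beta) > 15) {
    return(NULL)
  }
  list(log_hr = beta, se = se, hr = exp(beta),
       p = 2 * pnorm(-abs(beta / se)), score = fit$score)
}

#' Univariate Cox screen of one pair indicator
#'
#' Fits relapse-free survival on the binary ordering indicator by maximum
#' partial likelihood and reports Wald statistics. A constant indicator is
#' non-identifiable; a monotone likelihood (the two indicator groups' event
#' times perfectly separated) is flagged as divergent rather than assigned an
#' infinite hazard ratio.
#'
#' @param indicator 0/1 vector per sample.
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @return an object of class `reo_cox`; see [cox_fit()].
#' @export
cox_screen_pair <- function(indicator, times, events,
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!all(indicator %in% c(0, 1))) {
    stop_reo("indicator must be 0/1")
  }
  if (length(unique(indicator)) < 2) {
    stop_reo("indicator is constant: hazard ratio non-identifiable")
  }
  cox_fit(data.frame(indicator = indicator), times, events, ties = ties)
}

#' Screen all pairs of a gene set against survival in one cohort
#'
#' Encodes every pair indicator on the filtered population (by default
#' surgery-only samples of both age strata), fits a univariate Cox model per
#' pair, keeps pairs with Wald p < `alpha`, and canonicalizes orientation so
#' the reported hazard ratio always exceeds 1: when the fitted HR for
#' "first > second" is below 1 the genes are swapped and the HR inverted
#' (exact for a binary indicator). Pairs with constant indicators are
#' skipped; pairs with divergent (monotone-likelihood) fits are discarded
#' with a warning.
#'
#' @param cohort an [reo_cohort()].
#' @param genes gene ids to pair (typically from [age_related_genes()]).
#' @param alpha Wald p-value cut-off.
#' @param filter screening population, an [cohort_filter()]; must leave at
#'   least 10 samples and 1 event.
#' @param ties Cox tie handling.
#' @return data.frame with columns `gene_high`, `gene_low`, `log_hr`, `hr`,
#'   `p`, `n`, attribute `cohort` = cohort name.
#' @export
screen_cohort <- function(cohort, genes, alpha = 0.05,
                          filter = cohort_filter(),
                          ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  sub <- filter_cohort(cohort, filter, quiet = TRUE)
  times <- sub$clinical$endpoint_time
  events <- sub$clinical$endpoint_event
  if (nrow(sub$clinical) < 10 || sum(events) < 1) {
    stop_reo(sprintf("cohort '%s': screening population too small (%d samples, %d events)",
                     cohort$name, nrow(sub$clinical), sum(events)))
  }
  pm <- encode_pairs(sub, genes)
  y <- Surv(times, events)
  n <- ncol(pm)
  n_diverged <- 0L
  keep <- vector("list", nrow(pm))
  for (r in seq_len(nrow(pm))) {
    ind <- pm[r, ]
    s <- sum(ind)
    if (s == 0L || s == n) next  # constant indicator: not screenable
    fit <- fit_pair_cox(ind, y, ties)
    if (is.null(fit)) {
      n_diverged <- n_diverged + 1L
      next
    }
    if (fit$p < alpha) {
      keep[[r]] <- c(r, fit$log_hr, fit$p)
    }
  }
  if (n_diverged > 0) {
    warning(sprintf("cohort '%s': %d pair(s) discarded for monotone likelihood",
                    cohort$name, n_diverged))
  }
  kept <- do.call(rbind, keep)
  if (is.null(kept)) {
    out <- data.frame(gene_high = character(), gene_low = character(),
                      log_hr = numeric(), hr = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  } else {
    ids <- strsplit(rownames(pm)[kept[, 1]], "|", fixed = TRUE)
    first <- vapply(ids, `[`, character(1), 1)
    second <- vapply(ids, `[`, character(1), 2)
    log_hr <- kept[, 2]
    flip <- log_hr < 0
    out <- data.frame(
      gene_high = ifelse(flip, second, first),
      gene_low = ifelse(flip, first, second),
      log_hr = abs(log_hr),
      hr = exp(abs(log_hr)),
      p = kept[, 3],
      n = n,
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "cohort") <- cohort$name
  attr(out, "n_events") <- sum(events)
  out
}

#' Cross-cohort consistent pairs
#'
#' Keeps pairs screened in both cohorts with the *same* canonical
#' orientation — a pair whose risk-conferring ordering points one way in one
#' cohort and the other way in the second is inconsistent and dropped. Both
#' cohorts' statistics are attached, along with `ranking_p`, the worse
#' (larger) of the two p-values, used downstream to rank pairs by their
#' guaranteed significance.
#'
#' @param screen_a,screen_b outputs of [screen_cohort()] on two cohorts.
#' @return data.frame with columns `gene_high`, `gene_low`,
#'   `{log_hr,hr,p,n}_a`, `{log_hr,hr,p,n}_b`, `ranking_p`; attribute
#'   `cohorts` maps suffixes to cohort names.
#' @export
consistent_pairs <- function(screen_a, screen_b) {
  key_a <- pair_id(screen_a$gene_high, screen_a$gene_low)
  key_b <- pair_id(screen_b$gene_high, screen_b$gene_low)
  m <- match(key_a, key_b)
  hit <- !is.na(m)
  a <- screen_a[hit, , drop = FALSE]
  b <- screen_b[m[hit], , drop = FALSE]
  out <- data.frame(gene_high = a$gene_high, gene_low = a$gene_low,
                    log_hr_a = a$log_hr, hr_a = a$hr, p_a = a$p, n_a = a$n,
                    log_hr_b = b$log_hr, hr_b = b$hr, p_b = b$p, n_b = b$n,
                    ranking_p = pmax(a$p, b$p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cohorts") <- c(a = attr(screen_a, "cohort") %||% "a",
                            b = attr(screen_b, "cohort") %||% "b")
  out
}

#' Remove gene redundancy among candidate pairs
#'
#' A gene may sit in many significant pairs; to avoid redundancy only the
#' most significant pair per gene is kept. Pairs are scanned in ascending
#' ranking-p order (ties broken by lexicographic pair id) and a pair is kept
#' iff neither of its genes appears in an already-kept pair — so the output
#' is gene-disjoint, and a pair blocked only by *dropped* pairs survives.
#'
#' @param pairs data.frame of pairs; the ranking p-value is taken from a
#'   `ranking_p` column if present (as produced by [consistent_pairs()]),
#'   else from `p`.
#' @return the gene-disjoint subset, in ranking order, attributes preserved.
#' @export
deredundant <- function(pairs) {
  ranking <- pairs$ranking_p %||% pairs$p
  if (is.null(ranking)) {
    stop_reo("pairs need a 'ranking_p' or 'p' column to rank by")
  }
  ord <- lex_order(ranking, pair_id(pairs$gene_high, pairs$gene_low))
  used <- character()
  keep <- integer()
  for (i in ord) {
    g <- c(pairs$gene_high[i], pairs$gene_low[i])
    if (!any(g %in% used)) {
      keep <- c(keep, i)
      used <- c(used, g)
    }
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cohorts") <- attr(pairs, "cohorts")
  out
}
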