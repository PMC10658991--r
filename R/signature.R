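# The voting classifier and forward-stepwise C-index selection.

#' Strict-majority vote threshold
#'
#' A sample is high-risk iff strictly more than half of the signature's pairs
#' vote high-risk, i.e. `votes > floor(k / 2)`. For a 6-pair signature the
#' rule reads "votes > 3".
#'
#' @param k number of pairs (>= 1).
#' @return the integer threshold `floor(k / 2)`.
#' @export
vote_threshold <- function(k) {
  if (any(k < 1) || any(k != round(k))) {
    stop_reo("k must be a positive integer")
  }
  as.integer(floor(k / 2))
}

#' Strict-majority voting rule
#'
#' `HIGH` iff `votes > k / 2` (strict): for even `k`, exactly `k / 2` votes
#' is `LOW`.
#'
#' @param votes integer vote counts in `[0, k]`.
#' @param k number of pairs.
#' @return character vector over `{"HIGH", "LOW"}`.
#' @export
majority_vote <- function(votes, k) {
  thr <- vote_threshold(k)
  if (any(votes < 0) || any(votes > k) || any(votes != round(votes))) {
    stop_reo(sprintf("votes must be integers in [0, %d]", k))
  }
  ifelse(votes > thr, "HIGH", "LOW")
}

#' Classify cohort samples with a frozen signature
#'
#' Per sample, a pair votes high-risk when the expression of its `gene_high`
#' strictly exceeds that of its `gene_low`; the sample is labeled by the
#' strict-majority rule. Because only within-sample orderings are consulted,
#' the calls are invariant to any per-sample strictly increasing transform of
#' the expression matrix.
#'
#' @param cohort an [reo_cohort()] or gene-by-sample expression matrix.
#' @param sig an `reo_signature`.
#' @return data.frame of class `reo_risk` with columns `sample_id`, `votes`,
#'   `k`, `label`.
#' @export
classify <- function(cohort, sig) {
  if (!inherits(sig, "reo_signature")) {
    stop_reo("sig must be an reo_signature object")
  }
  expr <- if (inherits(cohort, "reo_cohort")) cohort$expression else cohort
  validate_expression(expr)
  genes <- unique(c(sig$pairs$gene_high, sig$pairs$gene_low))
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0) {
    stop_reo(sprintf("signature gene(s) absent from expression: %s",
                     paste(absent, collapse = ", ")))
  }
  hi <- expr[sig$pairs$gene_high, , drop = FALSE]
  lo <- expr[sig$pairs$gene_low, , drop = FALSE]
  votes <- as.integer(colSums(hi > lo))
  out <- data.frame(sample_id = colnames(expr),
                    votes = votes,
                    k = sig$k,
                    label = majority_vote(votes, sig$k),
                    stringsAsFactors = FALSE)
  class(out) <- c("reo_risk", "data.frame")
  out
}

#' Harrell's concordance index
#'
#' Over comparable pairs — sample `i` experienced the event and `t_i < t_j` —
#' credit 1 when `score_i > score_j`, 0.5 on a score tie, 0 otherwise. Pairs
#' with exactly equal times are non-comparable and skipped.
#'
#' @param score per-sample risk score (higher = predicted to fail earlier);
#'   here typically the 0/1 risk label or the vote count.
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @return concordance in \[0, 1\].
#' @export
cindex <- function(score, times, events) {
  check_survival_inputs(times, events)
  check_finite_numeric(score, "score")
  if (length(score) != length(times)) {
    stop_reo("score and survival data must have equal length")
  }
  earlier <- outer(times, times, `<`)     # t_i < t_j
  earlier[events == 0, ] <- FALSE         # i must be an observed event
  n_comp <- sum(earlier)
  if (n_comp == 0) {
    stop_reo("no comparable pairs (e.g. all samples censored)")
  }
  gt <- outer(score, score, `>`)
  eq <- outer(score, score, `==`)
  (sum(gt & earlier) + 0.5 * sum(eq & earlier)) / n_comp
}

# risk score per the selection flag: binary majority label or raw vote count
selection_score <- function(votes, k, cindex_on) {
  if (cindex_on == "label") {
    as.integer(votes > vote_threshold(k))
  } else {
    votes
  }
}

#' Forward-stepwise signature selection by C-index
#'
#' Greedy search over candidate pairs on a training population (by default
#' surgery-only early-onset samples): the seed is the single pair whose
#' one-pair voting classifier has the largest C-index; each round every
#' remaining candidate is tentatively added and the one yielding the largest
#' strictly increased C-index is adopted; the search stops when no addition
#' increases the C-index (strictly, with a 1e-12 floating-point guard). Ties
#' between candidate additions are broken by smaller ranking p-value, then
#' lexicographic pair id, so the result does not depend on candidate input
#' order. Candidates sharing a gene with an already-selected pair are skipped
#' to keep the signature gene-disjoint.
#'
#' @param candidates data.frame of oriented pairs (from [deredundant()] or
#'   hand-built with columns `gene_high`, `gene_low`; an optional
#'   `ranking_p` column feeds the tie-break).
#' @param training an [reo_cohort()].
#' @param filter selection population, an [cohort_filter()]; must leave at
#'   least 2 events.
#' @param cindex_on score the selection C-index on the raw vote count
#'   (`"votes"`, default) or on the binary majority `"label"`. The vote
#'   count is the finer-grained risk score: a label-scored search cannot
#'   reward an added pair that improves risk ordering without flipping any
#'   majority label, and stalls after one or two rounds.
#' @param tol minimum C-index improvement counted as an increase.
#' @return an `reo_signature` with the achieved `training_cindex` and a
#'   per-round selection `trace`.
#' @export
forward_stepwise <- function(candidates, training,
                             filter = cohort_filter(age_groups = "EOCRC"),
                             cindex_on = c("votes", "label"),
                             tol = 1e-12) {
  cindex_on <- match.arg(cindex_on)
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop_reo("no candidate pairs to select from")
  }
  sub <- filter_cohort(training, filter, quiet = TRUE)
  times <- sub$clinical$endpoint_time
  events <- sub$clinical$endpoint_event
  if (sum(events) < 2) {
    stop_reo(sprintf("selection population too small: %d samples, %d event(s)",
                     nrow(sub$clinical), sum(events)))
  }
  genes <- unique(c(candidates$gene_high, candidates$gene_low))
  absent <- setdiff(genes, rownames(sub$expression))
  if (length(absent) > 0) {
    stop_reo(sprintf("candidate gene(s) absent from training cohort: %s",
                     paste(absent, collapse = ", ")))
  }
  ind <- (sub$expression[candidates$gene_high, , drop = FALSE] >
          sub$expression[candidates$gene_low, , drop = FALSE]) * 1L
  ranking <- candidates$ranking_p %||% candidates$p %||%
    rep(Inf, nrow(candidates))
  ranking[is.na(ranking)] <- Inf
  ids <- pair_id(candidates$gene_high, candidates$gene_low)

  eval_c <- function(votes, k) {
    cindex(selection_score(votes, k, cindex_on), times, events)
  }
  pick_best <- function(open, cvals) {
    # largest C-index; ties by smaller ranking p, then lexicographic pair id
    open[lex_order(-cvals, ranking[open], ids[open])[1]]
  }

  m <- nrow(candidates)
  open <- seq_len(m)
  seed_c <- vapply(open, function(j) eval_c(ind[j, ], 1L), numeric(1))
  best <- pick_best(open, seed_c)
  selected <- best
  votes <- ind[best, ]
  current_c <- seed_c[match(best, open)]
  trace <- data.frame(round = 1L, pair = ids[best], cindex = current_c,
                      stringsAsFactors = FALSE)
  open <- setdiff(open, best)

  repeat {
    used <- c(candidates$gene_high[selected], candidates$gene_low[selected])
    open <- open[!(candidates$gene_high[open] %in% used |
                   candidates$gene_low[open] %in% used)]
    if (length(open) == 0) break
    k_next <- length(selected) + 1L
    cvals <- vapply(open, function(j) eval_c(votes + ind[j, ], k_next),
                    numeric(1))
    if (max(cvals) <= current_c + tol) break
    best <- pick_best(open, cvals)
    selected <- c(selected, best)
    votes <- votes + ind[best, ]
    current_c <- cvals[match(best, open)]
    trace <- rbind(trace, data.frame(round = k_next, pair = ids[best],
                                     cindex = current_c,
                                     stringsAsFactors = FALSE))
    open <- setdiff(open, best)
  }

  pairs <- candidates[selected, , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "cohorts") <- attr(candidates, "cohorts")
  new_reo_signature(
    pairs,
    training_cindex = current_c,
    training_population = list(cohort = training$name,
                               filter = filter_label(filter),
                               n = nrow(sub$clinical),
                               n_events = sum(events),
                               cindex_on = cindex_on),
    trace = trace)
}

# low-level constructor; validates the signature invariants
new_reo_signature <- function(pairs, training_cindex = NA_real_,
                              training_population = NULL, funnel = NULL,
                              trace = NULL, call = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop_reo("a signature needs at least one pair")
  }
  if (any(pairs$gene_high == pairs$gene_low)) {
    stop_reo("a pair cannot repeat the same gene")
  }
  genes <- c(pairs$gene_high, pairs$gene_low)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop_reo(sprintf("gene(s) appearing in more than one pair: %s",
                     paste(dup, collapse = ", ")))
  }
  if (!is.na(training_cindex) &&
      (training_cindex < 0 || training_cindex > 1)) {
    stop_reo("training_cindex must lie in [0, 1]")
  }
  structure(list(pairs = pairs,
                 k = nrow(pairs),
                 vote_rule = "strict_majority",
                 training_cindex = training_cindex,
                 training_population = training_population,
                 funnel = funnel,
                 trace = trace,
                 call = call),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("REO gene-pair signature: k = %d pair(s), high-risk iff votes > %d\n",
              x$k, vote_threshold(x$k)))
  if (!is.na(x$training_cindex)) {
    cat(sprintf("  training C-index: %.4f\n", x$training_cindex))
  }
  cat("  pairs (gene_high > gene_low votes high-risk):\n")
  cat(paste0("    ", pair_id(x$pairs$gene_high, x$pairs$gene_low),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.reo_signature <- function(object, ...) {
  structure(list(sig = object), class = "summary.reo_signature")
}

#' @export
print.summary.reo_signature <- function(x, ...) {
  sig <- x$sig
  print(sig)
  cohorts <- attr(sig$pairs, "cohorts")
  stat_cols <- intersect(
    c("log_hr_a", "hr_a", "p_a", "log_hr_b", "hr_b", "p_b", "ranking_p"),
    names(sig$pairs))
  if (length(stat_cols) > 0) {
    cat("\nPer-cohort screening statistics",
        if (!is.null(cohorts)) {
          sprintf(" (%s)", paste(names(cohorts), unname(cohorts),
                                 sep = " = ", collapse = ", "))
        },
        ":\n", sep = "")
    print(cbind(sig$pairs[c("gene_high", "gene_low")],
                sig$pairs[stat_cols]), digits = 3)
  }
  if (!is.null(sig$trace)) {
    cat("\nSelection trace:\n")
    print(sig$trace, row.names = FALSE, digits = 4)
  }
  if (!is.null(sig$funnel)) {
    cat("\nDiscovery funnel:\n")
    print(sig$funnel, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.reo_signature <- function(object, ...) {
  cols <- grep("^log_hr_", names(object$pairs), value = TRUE)
  if (length(cols) == 0) return(NULL)
  m <- as.matrix(object$pairs[, cols, drop = FALSE])
  cohorts <- attr(object$pairs, "cohorts")
  colnames(m) <- if (!is.null(cohorts)) {
    unname(cohorts[sub("^log_hr_", "", cols)])
  } else {
    sub("^log_hr_", "", cols)
  }
  rownames(m) <- pair_id(object$pairs$gene_high, object$pairs$gene_low)
  m
}

#' @export
predict.reo_signature <- function(object, newdata,
                                  type = c("label", "votes"), ...) {
  type <- match.arg(type)
  calls <- classify(newdata, object)
  if (type == "votes") setNames(calls$votes, calls$sample_id) else calls
}

#' @export
plot.reo_signature <- function(x, cohort, ...) {
  ev <- evaluate_signature(x, cohort)
  plot(ev, ...)
  invisible(x)
}
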