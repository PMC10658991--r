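# Survival and association statistics: Kaplan-Meier, log-rank, Cox
# proportional hazards (via the survival package), Fisher's exact test.

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: samples censored exactly at an event time are counted
#' at risk at that time. Times are months by convention and are never
#' converted.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @return object of class `reo_km`: `time` (ascending unique observed
#'   times), `survival`, `at_risk`, `n_event`.
#' @export
km_estimate <- function(times, events) {
  check_survival_inputs(times, events)
  if (length(times) < 1) stop_reo("need at least one sample")
  sf <- survfit(Surv(times, events) ~ 1)
  structure(list(time = sf$time, survival = sf$surv, at_risk = sf$n.risk,
                 n_event = sf$n.event, n = length(times)),
            class = "reo_km")
}

#' @export
print.reo_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate, n = %d, events = %d\n",
              x$n, sum(x$n_event)))
  print(data.frame(time = x$time, at_risk = x$at_risk,
                   n_event = x$n_event, survival = x$survival),
        row.names = FALSE, digits = 4)
  invisible(x)
}

# survival probability at time t (right-continuous step function)
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i) == 0) 1 else km$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Chi-square statistic (df = 1) from the usual observed-minus-expected /
#' hypergeometric-variance construction, two-sided p-value.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param group two-level grouping vector.
#' @return an `reo_test`.
#' @export
logrank_test <- function(times, events, group) {
  check_survival_inputs(times, events)
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2) {
    stop_reo("log-rank test requires exactly two non-empty groups")
  }
  if (sum(events) < 1) {
    stop_reo("log-rank test requires at least one event")
  }
  sd <- survdiff(Surv(times, events) ~ g)
  stat <- unname(sd$chisq)
  surv_test_result(stat, 1L, pchisq(stat, df = 1, lower.tail = FALSE),
                   "logrank")
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood with Wald per-covariate statistics. Numeric
#' covariates enter as-is; character/factor covariates are reference-coded
#' with the most frequent level as reference. Rows with missing values are
#' dropped (complete-case analysis). A monotone likelihood (divergent
#' coefficient) is flagged via `converged = FALSE` rather than reported as a
#' finite estimate.
#'
#' @param covariates numeric vector, matrix, or data.frame of covariates.
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param ties `"efron"` (default, matching mainstream survival software) or
#'   `"breslow"` (under which the score test at beta = 0 for a binary
#'   covariate equals the log-rank statistic).
#' @return object of class `reo_cox`: `coefficients` (log hazard ratios),
#'   `se`, `hr`, `ci95` (two-column matrix, `exp(coef +- 1.96 se)`), `p`
#'   (Wald), `score_stat` (global score test at beta = 0), `n`, `n_events`,
#'   `ties_method`, `converged`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.vector(covariates) && !is.list(covariates)) {
    covariates <- data.frame(x = covariates)
  }
  if (is.matrix(covariates)) {
    covariates <- as.data.frame(covariates)
  }
  if (nrow(covariates) != length(times)) {
    stop_reo("covariates and survival data must have equal length")
  }
  # reference-code categoricals against the most frequent level
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) {
      f <- droplevels(as.factor(v))
      covariates[[nm]] <- relevel(f, ref = names(which.max(table(f))))
    }
  }
  cc <- complete.cases(covariates) & !is.na(times) & !is.na(events)
  if (sum(!cc) > 0) {
    message(sprintf("cox_fit: dropped %d incomplete case(s)", sum(!cc)))
  }
  covariates <- covariates[cc, , drop = FALSE]
  times <- times[cc]
  events <- events[cc]
  check_survival_inputs(times, events)
  if (sum(events) < 1) stop_reo("Cox fit requires at least one event")
  constant <- vapply(covariates, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant)) {
    stop_reo(sprintf("constant covariate(s): %s",
                     paste(names(covariates)[constant], collapse = ", ")))
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  diverged <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(.time, .event) ~ ., data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular|rank", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- fit$coefficients
  if (anyNA(beta)) {
    stop_reo(sprintf("collinear covariate(s): %s",
                     paste(names(beta)[is.na(beta)], collapse = ", ")))
  }
  se <- sqrt(diag(fit$var))
  names(se) <- names(beta)
  if (any(abs(beta) > 15)) diverged <- TRUE
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  structure(list(coefficients = beta,
                 se = se,
                 hr = exp(beta),
                 ci95 = ci,
                 p = 2 * pnorm(-abs(beta / se)),
                 score_stat = unname(fit$score),
                 loglik = fit$loglik,
                 n = length(times),
                 n_events = sum(events),
                 ties_method = ties,
                 converged = !diverged),
            class = "reo_cox")
}

#' @export
print.reo_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties), n = %d, events = %d%s\n",
              x$ties_method, x$n, x$n_events,
              if (x$converged) "" else "  [DIVERGED: monotone likelihood]"))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$ci95[, "lower"], upper95 = x$ci95[, "upper"],
                    se = x$se, p = x$p)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.reo_cox <- function(object, ...) object$coefficients

#' Fisher's exact test for a 2-row contingency table
#'
#' Two-sided p-value by probability-mass ordering (the convention of
#' mainstream implementations): the sum of all table probabilities no larger
#' than the observed table's. Accepts 2xK tables; every margin must be
#' positive.
#'
#' @param table 2-row matrix of non-negative integer counts.
#' @return an `reo_test`; for 2x2 tables the statistic is the conditional
#'   odds-ratio estimate.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2) {
    stop_reo("fisher_exact expects a 2xK table with K >= 2")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop_reo("table entries must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_reo("every margin of the table must be positive")
  }
  ft <- tryCatch(
    fisher.test(table),
    error = function(e) {
      # exact enumeration infeasible for this table: Monte-Carlo p with a
      # fixed, restored seed so results stay deterministic
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(20231120)
      fisher.test(table, simulate.p.value = TRUE, B = 100000)
    })
  stat <- if (all(dim(table) == c(2, 2))) unname(ft$estimate) else NA_real_
  surv_test_result(stat, NA_integer_, ft$p.value, "fisher_exact")
}
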