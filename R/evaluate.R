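#' Evaluate a signature on a cohort
#'
#' Classifies the cohort, then summarizes the risk stratification:
#' Kaplan-Meier curves per risk group, the two-group log-rank test, a
#' univariate Cox fit of the high-risk indicator (hazard ratio with 95%
#' confidence interval and Wald p), the C-index of the risk label, an
#' optional multivariate Cox fit adjusting for clinical covariates, and
#' optional Fisher's exact tests associating the risk group with categorical
#' clinical features.
#'
#' @param sig an `reo_signature`.
#' @param cohort an [reo_cohort()].
#' @param filter optional [cohort_filter()] restricting the evaluation
#'   population.
#' @param adjust_for character vector of clinical column names for the
#'   multivariate Cox fit.
#' @param associate character vector of categorical clinical column names to
#'   cross-tabulate against the risk group.
#' @param ties Cox tie handling.
#' @return an object of class `reo_eval`.
#' @export
evaluate_signature <- function(sig, cohort, filter = NULL,
                               adjust_for = NULL, associate = NULL,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!is.null(filter)) cohort <- filter_cohort(cohort, filter)
  calls <- classify(cohort, sig)
  clin <- cohort$clinical
  stopifnot(identical(calls$sample_id, clin$sample_id))
  times <- clin$endpoint_time
  events <- clin$endpoint_event
  risk <- as.integer(calls$label == "HIGH")

  both_groups <- length(unique(risk)) == 2
  km <- lapply(split(seq_along(risk), calls$label), function(i) {
    km_estimate(times[i], events[i])
  })
  logrank <- NULL
  cox <- NULL
  cidx <- NA_real_
  if (both_groups) {
    logrank <- logrank_test(times, events, calls$label)
    cox <- cox_fit(data.frame(high_risk = risk), times, events, ties = ties)
    cidx <- cindex(risk, times, events)
  } else {
    message(sprintf("all samples classified %s: no group comparison possible",
                    calls$label[1]))
  }

  cox_adjusted <- NULL
  if (both_groups && !is.null(adjust_for)) {
    missing_cols <- setdiff(adjust_for, names(clin))
    if (length(missing_cols) > 0) {
      stop_reo(sprintf("clinical table lacks covariate(s): %s",
                       paste(missing_cols, collapse = ", ")))
    }
    covs <- cbind(data.frame(high_risk = risk),
                  clin[, adjust_for, drop = FALSE])
    cox_adjusted <- cox_fit(covs, times, events, ties = ties)
  }

  fisher <- NULL
  if (both_groups && !is.null(associate)) {
    missing_cols <- setdiff(associate, names(clin))
    if (length(missing_cols) > 0) {
      stop_reo(sprintf("clinical table lacks feature(s): %s",
                       paste(missing_cols, collapse = ", ")))
    }
    fisher <- lapply(setNames(associate, associate), function(nm) {
      tab <- table(calls$label, as.character(clin[[nm]]))
      list(table = tab, test = fisher_exact(tab))
    })
  }

  structure(list(cohort = cohort$name, n = nrow(clin),
                 n_events = sum(events), calls = calls, km = km,
                 logrank = logrank, cox = cox, cindex = cidx,
                 cox_adjusted = cox_adjusted, fisher = fisher,
                 times = times, events = events),
            class = "reo_eval")
}

#' @export
print.reo_eval <- function(x, ...) {
  tab <- table(factor(x$calls$label, levels = c("HIGH", "LOW")))
  cat(sprintf("Signature evaluation on cohort '%s' (n = %d, events = %d)\n",
              x$cohort, x$n, x$n_events))
  cat(sprintf("  risk groups: HIGH %d, LOW %d\n", tab[["HIGH"]], tab[["LOW"]]))
  if (!is.null(x$cox)) {
    cat(sprintf("  high- vs low-risk: HR = %.2f (95%% CI %.2f-%.2f), Wald p = %.3g\n",
                x$cox$hr[1], x$cox$ci95[1, "lower"], x$cox$ci95[1, "upper"],
                x$cox$p[1]))
    cat(sprintf("  log-rank: chi-square = %.3f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p_value))
    cat(sprintf("  C-index of risk label: %.4f\n", x$cindex))
  }
  if (!is.null(x$cox_adjusted)) {
    cat("  adjusted Cox fit:\n")
    print(x$cox_adjusted)
  }
  if (!is.null(x$fisher)) {
    for (nm in names(x$fisher)) {
      cat(sprintf("  risk group vs %s: Fisher p = %.3g\n",
                  nm, x$fisher[[nm]]$test$p_value))
    }
  }
  invisible(x)
}

#' @export
plot.reo_eval <- function(x, main = NULL,
                          col = c(HIGH = "firebrick", LOW = "steelblue"),
                          xlab = "Time (months)",
                          ylab = "Relapse-free survival", ...) {
  grp <- factor(x$calls$label, levels = c("HIGH", "LOW"))
  sf <- survfit(Surv(x$times, x$events) ~ grp)
  main <- main %||% sprintf("Risk stratification, cohort '%s'", x$cohort)
  plot(sf, col = col[levels(droplevels(grp))], lwd = 2, mark.time = TRUE,
       xlab = xlab, ylab = ylab, main = main, ...)
  lab <- sprintf("%s (n = %d)", levels(droplevels(grp)),
                 table(droplevels(grp)))
  legend_text <- if (!is.null(x$logrank)) {
    c(lab, sprintf("log-rank p = %.3g", x$logrank$p_value))
  } else {
    lab
  }
  legend("bottomleft", legend = legend_text,
         col = c(col[levels(droplevels(grp))], NA), lwd = c(2, 2, NA)[seq_along(legend_text)],
         bty = "n")
  invisible(x)
}
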