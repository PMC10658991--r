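# Independent brute-force oracles, kept deliberately naive and separate from
# the package's code paths.

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments; doubles the smaller tail of the null distribution of U
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(length(pooled), nx)
  u_null <- apply(combos, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  lower <- mean(u_null <= u_obs)
  upper <- mean(u_null >= u_obs)
  min(1, 2 * min(lower, upper))
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  p_obs <- dhyper(tab[1, 1], m, n, k)
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Harrell's C by a double loop: comparable iff t_i < t_j and event_i = 1
oracle_cindex <- function(score, times, events) {
  num <- 0
  den <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (events[i] == 1 && times[i] < times[j]) {
        den <- den + 1
        if (score[i] > score[j]) num <- num + 1
        else if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# log-rank chi-square via the per-event-time O/E/hypergeometric-variance sums
oracle_logrank <- function(times, events, group) {
  g <- as.integer(factor(group))
  o <- 0
  e <- 0
  v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o <- o + d1
    e <- e + d * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d) / (n_tot - 1)
    }
  }
  (o - e)^2 / v
}

# Cox partial log-likelihood for one covariate, Breslow or Efron ties
oracle_cox_loglik <- function(beta, z, times, events, ties = "breslow") {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    dead <- which(times == t & events == 1)
    risk <- which(times >= t)
    d <- length(dead)
    s_risk <- sum(exp(beta * z[risk]))
    s_dead <- sum(exp(beta * z[dead]))
    ll <- ll + beta * sum(z[dead])
    if (ties == "breslow") {
      ll <- ll - d * log(s_risk)
    } else {
      for (l in seq_len(d) - 1) {
        ll <- ll - log(s_risk - (l / d) * s_dead)
      }
    }
  }
  ll
}

# maximum-partial-likelihood coefficient by golden-section/optimize
oracle_cox_beta <- function(z, times, events, ties = "breslow") {
  optimize(function(b) -oracle_cox_loglik(b, z, times, events, ties),
           interval = c(-8, 8), tol = 1e-10)$minimum
}

# exhaustive best-subset search over the strict-majority voting classifier
oracle_best_subset_cindex <- function(ind, times, events,
                                      score = c("votes", "label")) {
  score <- match.arg(score)
  m <- nrow(ind)
  best <- -Inf
  for (mask in seq_len(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    k <- length(sel)
    votes <- colSums(ind[sel, , drop = FALSE])
    s <- if (score == "label") as.integer(votes > floor(k / 2)) else votes
    cc <- tryCatch(reosig::cindex(s, times, events), error = function(e) NA)
    if (!is.na(cc) && cc > best) best <- cc
  }
  best
}

# ---- fixture builders ------------------------------------------------------

make_clinical <- function(sample_ids, ages = NULL, times = NULL,
                          events = NULL, treatment = "SURGERY_ONLY") {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             age_years = ages %||% rep(45, n),
             endpoint_time = times %||% seq_len(n),
             endpoint_event = events %||% rep(1L, n),
             treatment = rep_len(treatment, n),
             stringsAsFactors = FALSE)
}

make_cohort <- function(expr, ages = NULL, times = NULL, events = NULL,
                        treatment = "SURGERY_ONLY", name = "test") {
  reo_cohort(expr, make_clinical(colnames(expr), ages, times, events,
                                 treatment), name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random censored survival instance with a binary group
random_surv_instance <- function(n, seed) {
  set.seed(seed)
  repeat {
    times <- round(rexp(n, 0.1) + 0.1, 3)
    events <- rbinom(n, 1, 0.7)
    group <- rbinom(n, 1, 0.5)
    if (sum(events) >= 2 && length(unique(group)) == 2 &&
        sum(events[group == 0]) >= 1 && sum(events[group == 1]) >= 1) {
      return(list(times = times, events = events, group = group))
    }
  }
}

pair_ids <- function(pairs) paste(pairs$gene_high, pairs$gene_low, sep = "|")

# a small signature built by hand from oriented pairs
make_signature <- function(gene_high, gene_low, ...) {
  reosig:::new_reo_signature(
    data.frame(gene_high = gene_high, gene_low = gene_low,
               stringsAsFactors = FALSE), ...)
}
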