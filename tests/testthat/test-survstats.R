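test_that("Kaplan-Meier worked examples", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  # product-limit by hand: S(1) = 2/3, censoring at 2 leaves S unchanged,
  # the last subject fails at 3
  expect_equal(reosig:::km_survival_at(km, c(1, 2, 2.9, 3)),
               c(2 / 3, 2 / 3, 2 / 3, 0))
  expect_equal(km$survival[km$time == 3], 0)

  all_cens <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))

  single <- km_estimate(5, 1)
  expect_equal(single$survival, 0)
  expect_equal(single$time, 5)

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(12)
  times <- round(rexp(40, 0.1) + 0.01, 2)
  km <- km_estimate(times, rep(1, 40))
  for (t in km$time) {
    expect_equal(reosig:::km_survival_at(km, t), mean(times > t))
  }
})

test_that("log-rank worked examples and symmetry", {
  # groups fully separated in time: O_A = 2, E_A = 5/6, V = 17/36
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)
  expect_equal(lr$statistic, 2.882, tolerance = 1e-3)

  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 0, 1, 0), c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "two")
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "event")

  # label swap and common monotone time transforms change nothing
  inst <- random_surv_instance(30, seed = 5)
  a <- logrank_test(inst$times, inst$events, inst$group)
  b <- logrank_test(inst$times, inst$events, 1 - inst$group)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  c2 <- logrank_test(exp(inst$times / 10), inst$events, inst$group)
  expect_equal(a$statistic, c2$statistic, tolerance = 1e-12)
})

test_that("log-rank agrees with an independent O/E/V computation", {
  for (s in 1:30) {
    inst <- random_surv_instance(sample(10:50, 1), seed = 100 + s)
    got <- logrank_test(inst$times, inst$events, inst$group)$statistic
    want <- oracle_logrank(inst$times, inst$events, inst$group)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("Cox worked example matches the analytic score-equation root", {
  fit <- cox_fit(c(1, 0, 1, 0), c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(unname(fit$coefficients), log((1 + sqrt(17)) / 2),
               tolerance = 1e-6)
  expect_equal(unname(fit$ci95[1, ]),
               unname(exp(fit$coefficients + c(-1.96, 1.96) * fit$se)))
  expect_error(cox_fit(rep(0, 4), c(1, 2, 3, 4), c(1, 1, 1, 1)), "constant")
})

test_that("Cox coefficients agree with an independent partial-likelihood maximizer", {
  for (s in 1:30) {
    inst <- random_surv_instance(sample(10:50, 1), seed = 200 + s)
    for (ties in c("breslow", "efron")) {
      fit <- cox_fit(inst$group, inst$times, inst$events, ties = ties)
      if (!fit$converged) next
      want <- oracle_cox_beta(inst$group, inst$times, inst$events, ties)
      expect_equal(unname(fit$coefficients), want, tolerance = 1e-5,
                   info = sprintf("seed %d ties %s", s, ties))
    }
  }
})

test_that("binary-covariate Cox flips sign exactly under label swap", {
  inst <- random_surv_instance(40, seed = 9)
  f1 <- cox_fit(inst$group, inst$times, inst$events)
  f2 <- cox_fit(1 - inst$group, inst$times, inst$events)
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients),
               tolerance = 1e-9)
  expect_equal(unname(f1$hr), 1 / unname(f2$hr), tolerance = 1e-9)
  expect_equal(unname(f1$p), unname(f2$p), tolerance = 1e-9)
})

test_that("Cox score test at beta = 0 (Breslow) is the log-rank statistic", {
  for (s in 1:25) {
    inst <- random_surv_instance(sample(10:40, 1), seed = 300 + s)
    fit <- suppressWarnings(
      cox_fit(inst$group, inst$times, inst$events, ties = "breslow"))
    lr <- logrank_test(inst$times, inst$events, inst$group)
    expect_equal(fit$score_stat, lr$statistic, tolerance = 1e-8)
  }
})

test_that("multivariate Cox handles categoricals, NAs and collinearity", {
  set.seed(33)
  n <- 80L
  stage <- sample(c("II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  z <- rbinom(n, 1, 0.4)
  times <- round(rexp(n, 0.05 * exp(0.8 * z + 0.5 * (stage == "IV"))) + 0.01, 3)
  events <- rbinom(n, 1, 0.8)
  covs <- data.frame(risk = z, stage = stage)
  fit <- cox_fit(covs, times, events)
  # most frequent stage level ("II") is the reference
  expect_setequal(names(fit$coefficients),
                  c("risk", "stageIII", "stageIV"))
  expect_gt(unname(fit$coefficients["risk"]), 0)

  covs_na <- covs
  covs_na$risk[1:5] <- NA
  expect_message(fit_na <- cox_fit(covs_na, times, events),
                 "dropped 5 incomplete")
  expect_identical(fit_na$n, n - 5L)

  covs_col <- cbind(covs, risk2 = z)
  expect_error(cox_fit(covs_col, times, events), "collinear")
})

test_that("Fisher worked examples match hypergeometric enumeration", {
  # 34 of the 70 equally likely tables are at most as probable as [[3,1],[1,3]]
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab)$p_value, 34 / 70, tolerance = 1e-9)
  expect_equal(oracle_fisher_2x2(tab), 34 / 70, tolerance = 1e-12)
  # the balanced table is the mode of its margin distribution
  expect_equal(fisher_exact(matrix(2, 2, 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(0, 0, 1, 1), 2, byrow = TRUE)),
               "margin")
})

test_that("Fisher two-sided p equals enumeration on random 2x2 tables", {
  set.seed(13)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 4) + 1, 2, 2)
    got <- fisher_exact(tab)$p_value
    expect_equal(got, oracle_fisher_2x2(tab), tolerance = 1e-9)
    expect_equal(fisher_exact(t(tab))$p_value, got, tolerance = 1e-9)
  }
})

test_that("evaluate_signature summarizes a stratified cohort", {
  sim <- simulate_cohort(reo_sim_config(seed = 61, n_samples_per_cohort = 150L,
                                        n_genes = 20L, n_age_de_genes = 4L,
                                        n_planted_pairs = 3L), "ev")
  sig <- make_signature(sim$truth$planted_pairs$gene_high,
                        sim$truth$planted_pairs$gene_low)
  ev <- evaluate_signature(sig, sim$cohort)
  expect_s3_class(ev, "reo_eval")
  expect_named(ev$km, c("HIGH", "LOW"), ignore.order = TRUE)
  expect_lt(ev$logrank$p_value, 0.05)
  expect_gt(ev$cox$hr[1], 1)
  expect_gt(ev$cindex, 0.5)
  expect_output(print(ev), "HR =")
  # plotting runs silently to a null device
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(ev))
})

test_that("evaluation can adjust for and associate clinical covariates", {
  sim <- simulate_cohort(reo_sim_config(seed = 62, n_samples_per_cohort = 150L,
                                        n_genes = 20L, n_age_de_genes = 4L,
                                        n_planted_pairs = 3L), "ev2")
  co <- sim$cohort
  set.seed(4)
  co$clinical$stage <- sample(c("II", "III"), nrow(co$clinical),
                              replace = TRUE)
  sig <- make_signature(sim$truth$planted_pairs$gene_high,
                        sim$truth$planted_pairs$gene_low)
  ev <- evaluate_signature(sig, co, adjust_for = "stage",
                           associate = "stage")
  expect_named(ev$cox_adjusted$coefficients[1], "high_risk")
  expect_named(ev$fisher, "stage")
  expect_true(ev$fisher$stage$test$p_value >= 0 &&
              ev$fisher$stage$test$p_value <= 1)
  expect_error(evaluate_signature(sig, co, adjust_for = "nope"), "nope")
})
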