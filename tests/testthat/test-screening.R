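test_that("Wilcoxon worked examples match exact enumeration", {
  # x below every y: 2 of the 20 assignments are as extreme in either tail
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  # observed statistic at the center of the null distribution
  expect_equal(wilcoxon_rank_sum(c(1, 4), c(2, 3))$p_value, 1.0)
  expect_error(wilcoxon_rank_sum(numeric(), 1), "non-empty")
  expect_warning(p <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))$p_value,
                 "identical")
  expect_equal(p, 1)
})

test_that("exact Wilcoxon p equals full permutation enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- round(rnorm(nx), 4)
    y <- round(rnorm(ny, sample(c(0, 1), 1)), 4)
    if (anyDuplicated(c(x, y))) next
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-12)
  }
})

test_that("dual-cohort age-related screen recovers planted DE genes", {
  # planted shift of 2 noise-sd, 200 samples per cohort: essentially every
  # planted gene should clear p < 0.05 in both cohorts
  hits <- vapply(1:20, function(s) {
    cfg <- reo_sim_config(seed = s, n_samples_per_cohort = 200L,
                          n_genes = 100L, n_age_de_genes = 40L,
                          n_planted_pairs = 0L, age_effect_size = 2)
    a <- simulate_cohort(cfg, "a", seed = cfg$seed)
    b <- simulate_cohort(cfg, "b", seed = cfg$seed + 1L)
    planted <- a$truth$age_de_gene_ids
    found <- age_related_genes(a$cohort, b$cohort, alpha = 0.05)
    mean(planted %in% found)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("age-related screen edge cases", {
  cfg <- reo_sim_config(seed = 2, n_samples_per_cohort = 40L, n_genes = 20L,
                        n_age_de_genes = 4L, n_planted_pairs = 0L)
  a <- simulate_cohort(cfg, "a", seed = 2)
  b <- simulate_cohort(cfg, "b", seed = 3)
  expect_length(age_related_genes(a$cohort, b$cohort, alpha = 0), 0)

  # a cohort lacking one age stratum is unusable
  eo_only <- a$cohort
  keep <- eo_only$clinical$age_group == "EOCRC"
  eo_only$expression <- eo_only$expression[, keep]
  eo_only$clinical <- eo_only$clinical[keep, ]
  expect_error(age_related_genes(eo_only, b$cohort), "lacks an age stratum")
})

test_that("the ordering indicator is 1 iff strictly greater", {
  expect_identical(reo_indicator(5, 3), 1L)
  expect_identical(reo_indicator(3, 5), 0L)
  expect_identical(reo_indicator(4, 4), 0L)  # ties vote low by convention
  expect_identical(reo_indicator(c(1, 2, 3), c(2, 2, 2)), c(0L, 0L, 1L))
  expect_error(reo_indicator(NA_real_, 1), "non-finite")
  expect_error(reo_indicator(Inf, 1), "non-finite")
})

test_that("pair encoding enumerates canonical pairs and is order-invariant", {
  m <- matrix(c(3, 2, 1, 1, 2, 3), nrow = 3,
              dimnames = list(c("GB", "GA", "GC"), c("S1", "S2")))
  co <- make_cohort(m)
  pm <- encode_pairs(co, c("GB", "GA", "GC"))
  expect_identical(rownames(pm), c("GA|GB", "GA|GC", "GB|GC"))
  expect_identical(nrow(pm), 3L)
  # GA=2,GB=3,GC=1 in S1; GA=2,GB=2? no: S2 has GB=1,GA=2,GC=3
  expect_identical(pm[, "S1"], c("GA|GB" = 0L, "GA|GC" = 1L, "GB|GC" = 1L))
  expect_identical(pm[, "S2"], c("GA|GB" = 1L, "GA|GC" = 0L, "GB|GC" = 0L))
  # input gene order is irrelevant: pairs use the fixed lexicographic order
  expect_identical(encode_pairs(co, c("GC", "GA", "GB")), pm)
  expect_error(encode_pairs(co, c("GA", "GX")), "GX")
  expect_error(encode_pairs(co, "GA"), "at least 2")
})

test_that("pair count is choose(m, 2) at the study's gene-set scale", {
  genes <- sprintf("AR%03d", 1:247)
  set.seed(1)
  m <- matrix(rnorm(247 * 4), nrow = 247,
              dimnames = list(genes, paste0("S", 1:4)))
  pm <- encode_pairs(make_cohort(m), genes)
  expect_equal(nrow(pm), choose(247, 2))
  expect_identical(nrow(pm), 30381L)
})

test_that("per-pair Cox screen matches the analytic score-equation root", {
  fit <- cox_screen_pair(c(1, 0, 1, 0), c(1, 2, 3, 4), c(1, 1, 1, 1))
  beta_exact <- log((1 + sqrt(17)) / 2)
  expect_equal(unname(fit$coefficients), beta_exact, tolerance = 1e-6)
  expect_equal(unname(fit$hr), (1 + sqrt(17)) / 2, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("degenerate per-pair Cox fits are flagged", {
  # all exposed events precede all unexposed: monotone likelihood
  fit <- suppressWarnings(
    cox_screen_pair(c(1, 1, 0, 0), c(1, 2, 3, 4), c(1, 1, 1, 1)))
  expect_false(fit$converged)
  expect_error(cox_screen_pair(c(0, 0, 0, 0), c(1, 2, 3, 4), c(1, 1, 1, 1)),
               "constant")
})

test_that("screening canonicalizes orientation to hazard ratio > 1", {
  # build a cohort where GA > GB is protective, so the emitted pair must be
  # flipped to (gene_high = GB, gene_low = GA) with the reciprocal HR
  set.seed(8)
  n <- 120
  ind <- rbinom(n, 1, 0.5)
  times <- rexp(n, 0.05 * exp(ifelse(ind == 1, -1.2, 0)))
  expr <- rbind(GA = ifelse(ind == 1, 2, 0), GB = rep(1, n),
                GC = rnorm(n), GD = rnorm(n))
  colnames(expr) <- sprintf("S%03d", 1:n)
  co <- make_cohort(expr, ages = rep(45, n), times = times,
                    events = rep(1L, n))
  scr <- screen_cohort(co, c("GA", "GB"), alpha = 0.05)
  expect_identical(nrow(scr), 1L)
  expect_identical(scr$gene_high, "GB")
  expect_identical(scr$gene_low, "GA")
  expect_gt(scr$hr, 1)

  # the reciprocal is exact: refitting the swapped indicator negates log-HR
  direct <- cox_screen_pair(as.integer(expr["GA", ] > expr["GB", ]),
                            times, rep(1L, n))
  expect_equal(scr$log_hr, -unname(direct$coefficients), tolerance = 1e-12)
  expect_equal(scr$p, unname(direct$p), tolerance = 1e-12)
})

test_that("screening respects alpha and the population filter", {
  sim <- simulate_cohort(reo_sim_config(seed = 5, n_samples_per_cohort = 80L,
                                        n_genes = 12L, n_age_de_genes = 4L,
                                        n_planted_pairs = 2L), "scr")
  genes <- sim$truth$age_de_gene_ids
  expect_identical(nrow(screen_cohort(sim$cohort, genes, alpha = 0)), 0L)
  tiny <- cohort_filter(treatment = "ACT")
  expect_error(screen_cohort(sim$cohort, genes, filter = tiny),
               "no sample satisfies")
})

test_that("consistency requires the same orientation in both cohorts", {
  a <- data.frame(gene_high = c("A", "C", "E"), gene_low = c("B", "D", "F"),
                  log_hr = c(0.9, 0.8, 0.7), hr = exp(c(0.9, 0.8, 0.7)),
                  p = c(0.001, 0.01, 0.02), n = 100L,
                  stringsAsFactors = FALSE)
  attr(a, "cohort") <- "trainA"
  # C|D flipped in cohort b; E|F absent
  b <- data.frame(gene_high = c("A", "D"), gene_low = c("B", "C"),
                  log_hr = c(0.5, 0.6), hr = exp(c(0.5, 0.6)),
                  p = c(0.03, 0.001), n = 60L,
                  stringsAsFactors = FALSE)
  attr(b, "cohort") <- "trainB"
  cons <- consistent_pairs(a, b)
  expect_identical(cons$gene_high, "A")
  expect_identical(cons$gene_low, "B")
  expect_equal(cons$ranking_p, 0.03)  # the worse of the two p-values
  expect_identical(attr(cons, "cohorts"), c(a = "trainA", b = "trainB"))
})

test_that("de-redundancy keeps the most significant pair per gene, greedily", {
  ps <- data.frame(gene_high = c("A", "A", "D"), gene_low = c("B", "C", "E"),
                   ranking_p = c(0.001, 0.01, 0.02), stringsAsFactors = FALSE)
  out <- deredundant(ps)
  expect_identical(pair_ids(out), c("A|B", "D|E"))

  # a pair blocked only by dropped pairs survives: chain A-B, B-C, C-D
  chain <- data.frame(gene_high = c("A", "B", "C"),
                      gene_low = c("B", "C", "D"),
                      ranking_p = c(0.001, 0.005, 0.01),
                      stringsAsFactors = FALSE)
  out <- deredundant(chain)
  expect_identical(pair_ids(out), c("A|B", "C|D"))

  disjoint <- data.frame(gene_high = c("A", "C"), gene_low = c("B", "D"),
                         ranking_p = c(0.02, 0.01), stringsAsFactors = FALSE)
  expect_identical(sort(pair_ids(deredundant(disjoint))),
                   sort(pair_ids(disjoint)))
  expect_error(deredundant(data.frame(gene_high = "A", gene_low = "B")),
               "ranking_p")
})

test_that("every screening stage is invariant to monotone distortions", {
  cfg <- reo_sim_config(seed = 21, n_samples_per_cohort = 60L, n_genes = 14L,
                        n_age_de_genes = 4L, n_planted_pairs = 2L)
  a <- simulate_cohort(cfg, "a", seed = 21)
  b <- simulate_cohort(cfg, "b", seed = 22)
  genes <- a$truth$age_de_gene_ids
  base_a <- suppressWarnings(screen_cohort(a$cohort, genes, alpha = 0.2))
  base_b <- suppressWarnings(screen_cohort(b$cohort, genes, alpha = 0.2))
  base_cons <- consistent_pairs(base_a, base_b)
  ta <- apply_batch_transform(a$cohort, "piecewise", seed = 9)
  tb <- apply_batch_transform(b$cohort, "log", seed = 10)
  tr_a <- suppressWarnings(screen_cohort(ta, genes, alpha = 0.2))
  tr_b <- suppressWarnings(screen_cohort(tb, genes, alpha = 0.2))
  expect_identical(tr_a, base_a)
  expect_identical(tr_b, base_b)
  expect_identical(consistent_pairs(tr_a, tr_b), base_cons)
  expect_identical(deredundant(consistent_pairs(tr_a, tr_b)),
                   deredundant(base_cons))
})
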