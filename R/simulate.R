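#' Configuration for the synthetic two-cohort survival simulator
#'
#' The generator emulates the data structure the discovery funnel assumes:
#' two age strata with a subset of genes differentially expressed between
#' them, a small set of gene-disjoint planted pairs whose within-sample
#' ordering carries a proportional-hazards effect on recurrence, exponential
#' event times with uniform right-censoring calibrated to a target rate, and
#' optional per-sample strictly increasing batch distortions.
#'
#' Planted-pair genes also receive the age-group shift (the same shift for
#' both genes of a pair, so the within-pair ordering stays age-independent):
#' the funnel only pairs age-related genes, so prognostic pairs must be
#' age-related to be discoverable at all.
#'
#' @param seed integer; together with the config it fully determines output.
#' @param n_samples_per_cohort samples per simulated cohort.
#' @param frac_eocrc fraction of samples in the early-onset stratum.
#' @param n_genes total genes.
#' @param n_age_de_genes genes (beyond planted-pair genes) carrying the
#'   age-group expression shift.
#' @param age_effect_size additive shift (log-scale expression units) between
#'   age strata, in units of `noise_sd`.
#' @param n_planted_pairs number of planted prognostic gene pairs.
#' @param planted_log_hr log hazard ratio attached to the high-risk ordering
#'   of each planted pair.
#' @param baseline_hazard events per month for a sample with centered linear
#'   predictor zero.
#' @param censoring_rate_target desired fraction of censored samples in
#'   \[0, 1); the uniform censoring horizon is solved for numerically.
#' @param noise_sd per-gene expression standard deviation.
#' @param gene_mean_sd spread of gene-intrinsic baseline expression levels.
#'   Baselines are drawn once per configuration (from `config$seed`), so
#'   every cohort of a study shares them — as real cohorts share each gene's
#'   characteristic expression level. The two genes of a planted pair share
#'   one baseline, mirroring the comparable-level gene pairs REO signatures
#'   are built from; pairs of genes with well-separated baselines have
#'   near-constant orderings and carry no information, as in real data.
#' @param high_risk_fraction target probability that a planted pair sits in
#'   its high-risk ordering within a sample; controls the mean offset between
#'   the pair's two genes.
#' @param batch_transform per-sample monotone distortion applied after
#'   simulation; see [apply_batch_transform()]. Default `"none"`.
#' @return an object of class `reo_sim_config`.
#' @export
reo_sim_config <- function(seed = 1L,
                           n_samples_per_cohort = 300L,
                           frac_eocrc = 0.35,
                           n_genes = 200L,
                           n_age_de_genes = 30L,
                           age_effect_size = 1,
                           n_planted_pairs = 5L,
                           planted_log_hr = log(3),
                           baseline_hazard = 0.02,
                           censoring_rate_target = 0.2,
                           noise_sd = 1,
                           gene_mean_sd = 2,
                           high_risk_fraction = 0.5,
                           batch_transform = "none") {
  cfg <- list(seed = as.integer(seed),
              n_samples_per_cohort = as.integer(n_samples_per_cohort),
              frac_eocrc = frac_eocrc,
              n_genes = as.integer(n_genes),
              n_age_de_genes = as.integer(n_age_de_genes),
              age_effect_size = age_effect_size,
              n_planted_pairs = as.integer(n_planted_pairs),
              planted_log_hr = planted_log_hr,
              baseline_hazard = baseline_hazard,
              censoring_rate_target = censoring_rate_target,
              noise_sd = noise_sd,
              gene_mean_sd = gene_mean_sd,
              high_risk_fraction = high_risk_fraction,
              batch_transform = batch_transform)
  if (cfg$n_samples_per_cohort < 2) {
    stop_reo("n_samples_per_cohort must be at least 2")
  }
  if (cfg$frac_eocrc <= 0 || cfg$frac_eocrc >= 1) {
    stop_reo("frac_eocrc must lie in (0, 1)")
  }
  if (2L * cfg$n_planted_pairs + cfg$n_age_de_genes > cfg$n_genes) {
    stop_reo(sprintf("infeasible gene budget: 2*%d planted + %d age-DE genes > %d genes",
                     cfg$n_planted_pairs, cfg$n_age_de_genes, cfg$n_genes))
  }
  if (cfg$baseline_hazard <= 0 || cfg$noise_sd <= 0) {
    stop_reo("baseline_hazard and noise_sd must be positive")
  }
  if (cfg$gene_mean_sd < 0) {
    stop_reo("gene_mean_sd must be non-negative")
  }
  if (cfg$censoring_rate_target < 0 || cfg$censoring_rate_target >= 1) {
    stop_reo("censoring_rate_target must lie in [0, 1)")
  }
  if (cfg$high_risk_fraction <= 0 || cfg$high_risk_fraction >= 1) {
    stop_reo("high_risk_fraction must lie in (0, 1)")
  }
  structure(cfg, class = "reo_sim_config")
}

#' Read a simulator configuration from YAML
#'
#' Keys mirror the arguments of [reo_sim_config()]; absent keys take the
#' defaults.
#'
#' @param path path to a YAML file.
#' @return an `reo_sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(reo_sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop_reo(sprintf("unknown simulator config key(s): %s",
                     paste(bad, collapse = ", ")))
  }
  if (identical(vals$planted_log_hr, "log(3)")) vals$planted_log_hr <- log(3)
  do.call(reo_sim_config, vals)
}

# Uniform-censoring horizon tau such that the expected censored fraction over
# the realized per-sample hazard rates equals the target:
# P(censored | rate, tau) = (1 - exp(-rate*tau)) / (rate*tau).
censoring_horizon <- function(rates, target) {
  f <- function(log_tau) {
    tau <- exp(log_tau)
    mean((1 - exp(-rates * tau)) / (rates * tau)) - target
  }
  exp(uniroot(f, lower = log(1e-8), upper = log(1e10), tol = 1e-10)$root)
}

#' Simulate one cohort with known ground truth
#'
#' Expression is i.i.d. Gaussian noise per gene; age-DE genes (and
#' planted-pair genes) receive an additive shift in the early-onset stratum;
#' each planted pair's first gene receives a mean offset so its high-risk
#' ordering occurs in a `high_risk_fraction` of samples. Event times are
#' exponential under a proportional-hazards model whose linear predictor is
#' `planted_log_hr` times the centered count of planted pairs in their
#' high-risk state; censoring is uniform with a numerically calibrated
#' horizon. All samples are treatment `SURGERY_ONLY`.
#'
#' @param config an [reo_sim_config()].
#' @param label cohort name; also prefixes sample ids.
#' @param seed RNG seed for this cohort (defaults to `config$seed`).
#' @return a list of class `reo_sim` with elements `cohort` (an
#'   [reo_cohort()]) and `truth` (class `reo_truth`: `age_de_gene_ids`,
#'   `planted_pairs`, `states` pair-by-sample 0/1 matrix,
#'   `linear_predictor`).
#' @export
simulate_cohort <- function(config, label = "cohort", seed = config$seed) {
  stopifnot(inherits(config, "reo_sim_config"))
  n <- config$n_samples_per_cohort
  g <- config$n_genes
  p <- config$n_planted_pairs
  gene_ids <- sprintf("G%04d", seq_len(g))
  sample_ids <- sprintf("%s_S%03d", label, seq_len(n))

  # gene-intrinsic baseline levels, drawn from the configuration seed so all
  # cohorts of one study share them; a planted pair's genes share a baseline
  set.seed(config$seed)
  mu <- rnorm(g, 0, config$gene_mean_sd)
  if (p > 0) {
    mu[seq_len(p) * 2L] <- mu[seq_len(p) * 2L - 1L]
  }

  set.seed(as.integer(seed))

  n_eo <- max(1L, min(n - 1L, round(config$frac_eocrc * n)))
  stratum <- sample(rep(c("EOCRC", "LOCRC"), c(n_eo, n - n_eo)))
  ages <- ifelse(stratum == "EOCRC", runif(n, 28, 49), runif(n, 61, 88))
  is_eo <- stratum == "EOCRC"

  expr <- mu + matrix(rnorm(g * n, mean = 0, sd = config$noise_sd), nrow = g)
  dimnames(expr) <- list(gene_ids, sample_ids)

  planted_high <- if (p > 0) gene_ids[seq_len(p) * 2L - 1L] else character()
  planted_low <- if (p > 0) gene_ids[seq_len(p) * 2L] else character()
  de_only <- if (config$n_age_de_genes > 0) {
    gene_ids[2L * p + seq_len(config$n_age_de_genes)]
  } else character()

  # age-group shift: alternating sign across genes; both genes of a planted
  # pair share the pair's sign so the within-pair ordering carries no age
  # information
  if (p > 0) {
    pair_sign <- rep_len(c(1, -1), p) * config$age_effect_size
    for (i in seq_len(p)) {
      expr[c(planted_high[i], planted_low[i]), is_eo] <-
        expr[c(planted_high[i], planted_low[i]), is_eo] + pair_sign[i]
    }
  }
  if (length(de_only) > 0) {
    de_sign <- rep_len(c(1, -1), length(de_only)) * config$age_effect_size
    expr[de_only, is_eo] <- expr[de_only, is_eo] +
      matrix(de_sign, nrow = length(de_only), ncol = sum(is_eo))
  }

  # offset so P(high > low) = high_risk_fraction for a planted pair
  offset <- sqrt(2) * config$noise_sd * qnorm(config$high_risk_fraction)
  if (p > 0 && offset != 0) {
    expr[planted_high, ] <- expr[planted_high, ] + offset
  }

  if (p > 0) {
    states <- (expr[planted_high, , drop = FALSE] >
               expr[planted_low, , drop = FALSE]) * 1L
    rownames(states) <- pair_id(planted_high, planted_low)
    lp <- config$planted_log_hr *
      (colSums(states) - p * config$high_risk_fraction)
  } else {
    states <- matrix(integer(), nrow = 0, ncol = n,
                     dimnames = list(NULL, sample_ids))
    lp <- rep(0, n)
  }

  rates <- config$baseline_hazard * exp(lp)
  t_event <- rexp(n) / rates
  if (config$censoring_rate_target > 0) {
    tau <- censoring_horizon(rates, config$censoring_rate_target)
    t_cens <- runif(n, 0, tau)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }

  clinical <- data.frame(sample_id = sample_ids,
                         age_years = ages,
                         endpoint_time = time,
                         endpoint_event = event,
                         treatment = "SURGERY_ONLY",
                         stringsAsFactors = FALSE)
  cohort <- reo_cohort(expr, clinical, name = label)
  if (!identical(config$batch_transform, "none")) {
    cohort <- apply_batch_transform(cohort, config$batch_transform,
                                    seed = seed)
  }
  truth <- structure(
    list(age_de_gene_ids = c(planted_high, planted_low, de_only),
         planted_pairs = data.frame(gene_high = planted_high,
                                    gene_low = planted_low,
                                    stringsAsFactors = FALSE),
         states = states,
         linear_predictor = setNames(lp, sample_ids)),
    class = "reo_truth")
  structure(list(cohort = cohort, truth = truth), class = "reo_sim")
}

#' Simulate a dual-training plus validation study
#'
#' Generates two training cohorts and one validation cohort from the same
#' configuration with consecutive seeds (`seed`, `seed + 1`, `seed + 2`), so
#' they share the planted structure but are otherwise independent — the
#' dual-cohort design the discovery funnel expects. Per-cohort batch
#' distortions may differ, emulating cohorts measured on different platforms.
#'
#' @param config an [reo_sim_config()].
#' @param transforms optional named list with entries `a`, `b`, `validation`
#'   overriding `config$batch_transform` per cohort.
#' @return list with elements `train_a`, `train_b`, `validation`, each an
#'   `reo_sim` (cohort + ground truth).
#' @export
simulate_study <- function(config, transforms = NULL) {
  stopifnot(inherits(config, "reo_sim_config"))
  one <- function(label, offs, key) {
    cfg <- config
    if (!is.null(transforms) && !is.null(transforms[[key]])) {
      cfg$batch_transform <- transforms[[key]]
    }
    simulate_cohort(cfg, label = label, seed = config$seed + offs)
  }
  list(train_a = one("cohortA", 0L, "a"),
       train_b = one("cohortB", 1L, "b"),
       validation = one("validation", 2L, "validation"))
}

# ---- batch transforms ------------------------------------------------------

#' Apply a per-sample strictly increasing batch distortion
#'
#' Replaces every sample's expression column by a strictly increasing
#' function of it, leaving clinical data untouched. Within-sample orderings —
#' and therefore every REO quantity downstream — are unchanged by
#' construction; these distortions exist so tests can exercise that
#' robustness.
#'
#' Transform families (`transform` may be the family name, or a list with a
#' `type` element plus parameters):
#' \describe{
#'   \item{`none`}{identity.}
#'   \item{`affine`}{`x -> slope * x + offset` with `slope > 0`. With no
#'     parameters given, per-sample slopes in (0.5, 2) and offsets in (-5, 5)
#'     are drawn from `seed`.}
#'   \item{`log`}{`x -> log(x - min(x) + c)` per sample, `c` drawn in
#'     (0.5, 2); or, with a `shift` parameter, the cohort-common map
#'     `x -> log(x + shift)`.}
#'   \item{`power`}{`x -> (x - min(x) + 1)^gamma` per sample, `gamma` drawn
#'     in (0.5, 3); or, with a `shift` parameter, the cohort-common map
#'     `x -> (x + shift)^gamma`.}
#'   \item{`rank`}{within-sample ranks.}
#'   \item{`piecewise`}{random strictly increasing piecewise-linear map with
#'     per-sample breakpoints and positive segment slopes.}
#' }
#'
#' @param cohort an [reo_cohort()].
#' @param transform family name or parameter list; see Details.
#' @param seed RNG seed for randomly drawn per-sample parameters.
#' @return the cohort with transformed expression.
#' @export
apply_batch_transform <- function(cohort, transform, seed = 1L) {
  stopifnot(inherits(cohort, "reo_cohort"))
  if (is.character(transform)) transform <- list(type = transform)
  type <- transform$type
  if (is.null(type)) stop_reo("transform must name a type")
  x <- cohort$expression
  n <- ncol(x)
  set.seed(as.integer(seed))
  out <- switch(
    type,
    none = x,
    affine = {
      slope <- transform$slope %||% runif(n, 0.5, 2)
      offset <- transform$offset %||% runif(n, -5, 5)
      slope <- rep_len(slope, n)
      offset <- rep_len(offset, n)
      if (any(slope <= 0)) {
        stop_reo("affine transform requires strictly positive slope")
      }
      sweep(sweep(x, 2, slope, `*`), 2, offset, `+`)
    },
    log = {
      if (!is.null(transform$shift)) {
        # cohort-common variant: one strictly increasing map for all samples
        if (min(x) + transform$shift <= 0) {
          stop_reo("log transform shift must exceed -min(expression)")
        }
        log(x + transform$shift)
      } else {
        shift <- rep_len(transform$offset %||% runif(n, 0.5, 2), n)
        if (any(shift <= 0)) {
          stop_reo("log transform requires a positive offset")
        }
        mins <- apply(x, 2, min)
        log(sweep(x, 2, mins - shift, `-`))
      }
    },
    power = {
      if (!is.null(transform$shift)) {
        gamma <- transform$gamma %||% 2
        if (length(gamma) != 1 || gamma <= 0) {
          stop_reo("power transform requires a single positive exponent")
        }
        if (min(x) + transform$shift <= 0) {
          stop_reo("power transform shift must exceed -min(expression)")
        }
        (x + transform$shift)^gamma
      } else {
        gamma <- rep_len(transform$gamma %||% runif(n, 0.5, 3), n)
        if (any(gamma <= 0)) {
          stop_reo("power transform requires a positive exponent")
        }
        mins <- apply(x, 2, min)
        sweep(sweep(x, 2, mins - 1, `-`), 2, gamma, `^`)
      }
    },
    rank = apply(x, 2, rank),
    piecewise = {
      n_breaks <- transform$n_breaks %||% 5L
      vapply(seq_len(n), function(s) {
        col <- x[, s]
        lo <- min(col) - 1
        hi <- max(col) + 1
        knots <- c(lo, sort(runif(n_breaks, lo, hi)), hi)
        slopes <- runif(n_breaks + 1, 0.2, 3)
        heights <- c(0, cumsum(slopes * diff(knots)))
        approx(knots, heights, xout = col)$y
      }, numeric(nrow(x)))
    },
    stop_reo(sprintf("unknown or non-monotone transform type '%s'", type))
  )
  dimnames(out) <- dimnames(x)
  cohort$expression <- out
  cohort
}
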