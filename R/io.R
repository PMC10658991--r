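#' Validate a gene-by-sample expression matrix
#'
#' Checks the container invariants every pipeline stage relies on: unique,
#' non-empty gene and sample identifiers and fully finite values. Missing
#' values are rejected rather than imputed: the within-sample ordering of an
#' absent value is undefined and no imputation rule is part of the method.
#'
#' @param values numeric matrix, one row per gene, one column per sample;
#'   rownames are gene ids, colnames are sample ids.
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_reo("expression must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || any(!nzchar(gene_ids))) {
    stop_reo("expression matrix must have non-empty gene ids as rownames")
  }
  if (is.null(sample_ids) || any(!nzchar(sample_ids))) {
    stop_reo("expression matrix must have non-empty sample ids as colnames")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stop_reo(sprintf("duplicate gene id(s): %s",
                     paste(unique(dup), collapse = ", ")))
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0) {
    stop_reo(sprintf("duplicate sample id(s): %s",
                     paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_reo(sprintf("non-finite or missing expression value at gene '%s', sample '%s'",
                     gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  invisible(values)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds row identifiers and
#' whose header row holds column identifiers. With
#' `orientation = "genes_in_rows"` (the default) rows are genes and columns
#' samples; with `"samples_in_rows"` the file is transposed on read so the
#' returned matrix is always gene-by-sample.
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` or `"samples_in_rows"`.
#' @return numeric gene-by-sample matrix with ids as dimnames.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop_reo(sprintf("file not found: %s", path))
  }
  nf <- count.fields(path, sep = "\t", quote = "\"", comment.char = "")
  if (length(nf) < 2) {
    stop_reo(sprintf("expression file %s must have a header row and at least one data row", path))
  }
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop_reo(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                     path, bad, nf[bad], nf[1]), class = "reo_parse_error")
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "")
  row_ids <- df[[1]]
  cell_chr <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cell_chr), dim = dim(cell_chr)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_reo(sprintf("non-numeric or missing cell in %s: row id '%s', column '%s' (value '%s')",
                     path, row_ids[bad[1]], colnames(cell_chr)[bad[2]],
                     cell_chr[bad[1], bad[2]]))
  }
  dimnames(vals) <- list(row_ids, colnames(cell_chr))
  if (orientation == "samples_in_rows") {
    vals <- t(vals)
  }
  validate_expression(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' @param values gene-by-sample numeric matrix.
#' @param path output path.
#' @param orientation layout to write; see [read_expression()].
#' @param id_column header label for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path,
                             orientation = c("genes_in_rows", "samples_in_rows"),
                             id_column = "gene_id") {
  orientation <- match.arg(orientation)
  validate_expression(values)
  m <- if (orientation == "genes_in_rows") values else t(values)
  if (orientation == "samples_in_rows" && identical(id_column, "gene_id")) {
    id_column <- "sample_id"
  }
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign the age-of-onset stratum
#'
#' Early-onset (`EOCRC`) means strictly younger than 50 years at diagnosis;
#' late-onset (`LOCRC`) strictly older than 60. Ages in the closed interval
#' \[50, 60\] belong to neither analysis stratum and map to `EXCLUDED`; both
#' cut-offs are strict by definition.
#'
#' @param age_years non-negative numeric vector of ages in years.
#' @return character vector over `{"EOCRC","LOCRC","EXCLUDED"}`.
#' @export
age_group <- function(age_years) {
  check_finite_numeric(age_years, "age_years")
  if (any(age_years < 0)) {
    stop_reo("age_years must be non-negative")
  }
  ifelse(age_years < 50, "EOCRC", ifelse(age_years > 60, "LOCRC", "EXCLUDED"))
}

.treatments <- c("SURGERY_ONLY", "ACT", "OTHER_UNKNOWN")

#' Read a clinical table from TSV
#'
#' Mandatory columns: `sample_id`, `age_years`, `endpoint_time` (months,
#' positive), `endpoint_event` (0/1, 1 = recurrence observed) and `treatment`
#' (`SURGERY_ONLY`, `ACT` or `OTHER_UNKNOWN`). Any further columns are kept
#' as free-form covariates. The age stratum is always derived from
#' `age_years` via [age_group()], never read from the file.
#'
#' @param path file path.
#' @return data.frame of clinical records with a derived `age_group` column.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) {
    stop_reo(sprintf("file not found: %s", path))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_clinical(df, where = path)
}

validate_clinical <- function(df, where = "clinical table") {
  mandatory <- c("sample_id", "age_years", "endpoint_time",
                 "endpoint_event", "treatment")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop_reo(sprintf("%s lacks mandatory column(s): %s",
                     where, paste(missing_cols, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop_reo(sprintf("%s has duplicate sample_id(s)", where))
  }
  check_finite_numeric(df$age_years, "age_years")
  if (any(df$age_years < 0)) {
    stop_reo("age_years must be non-negative")
  }
  check_finite_numeric(df$endpoint_time, "endpoint_time")
  if (any(df$endpoint_time <= 0)) {
    stop_reo("endpoint_time must be positive")
  }
  if (!all(df$endpoint_event %in% c(0, 1))) {
    stop_reo("endpoint_event must be 0 or 1")
  }
  df$endpoint_event <- as.integer(df$endpoint_event)
  bad_trt <- setdiff(unique(df$treatment), .treatments)
  if (length(bad_trt) > 0) {
    stop_reo(sprintf("unknown treatment value(s): %s (allowed: %s)",
                     paste(bad_trt, collapse = ", "),
                     paste(.treatments, collapse = ", ")))
  }
  df$age_group <- age_group(df$age_years)
  # canonical column order: mandatory + derived stratum, then covariates
  extras <- setdiff(names(df), c(mandatory, "age_group"))
  df <- df[, c(mandatory[1:2], "age_group", mandatory[3:5], extras),
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a clinical table to TSV
#'
#' @param clinical data.frame as returned by [read_clinical()]; the derived
#'   `age_group` column is dropped on write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical[, setdiff(names(clinical), "age_group"), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a cohort from expression and clinical data
#'
#' Restricts both inputs to the samples they share (preserving the column
#' order of the expression matrix) and reports every dropped sample. An empty
#' intersection is an error.
#'
#' @param expression gene-by-sample numeric matrix.
#' @param clinical clinical data.frame (see [read_clinical()]).
#' @param name cohort label used in screening statistics and reports.
#' @return an object of class `reo_cohort`: a list with elements
#'   `expression`, `clinical`, `name`.
#' @export
reo_cohort <- function(expression, clinical, name = "cohort") {
  validate_expression(expression)
  clinical <- validate_clinical(clinical, where = sprintf("cohort '%s'", name))
  shared <- intersect(colnames(expression), clinical$sample_id)
  if (length(shared) == 0) {
    stop_reo(sprintf("cohort '%s': expression and clinical tables share no sample", name))
  }
  drop_expr <- ncol(expression) - length(shared)
  drop_clin <- nrow(clinical) - length(shared)
  if (drop_expr > 0 || drop_clin > 0) {
    message(sprintf("cohort '%s': dropped %d expression-only and %d clinical-only sample(s)",
                    name, drop_expr, drop_clin))
  }
  keep <- colnames(expression)[colnames(expression) %in% shared]
  expression <- expression[, keep, drop = FALSE]
  clinical <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  if (length(keep) < 2) {
    stop_reo(sprintf("cohort '%s' needs at least 2 samples", name))
  }
  structure(list(expression = expression, clinical = clinical, name = name),
            class = "reo_cohort")
}

#' @export
print.reo_cohort <- function(x, ...) {
  tab <- table(factor(x$clinical$age_group,
                      levels = c("EOCRC", "LOCRC", "EXCLUDED")))
  cat(sprintf("REO cohort '%s': %d genes x %d samples\n",
              x$name, nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  age strata: EOCRC %d, LOCRC %d, excluded %d\n",
              tab[["EOCRC"]], tab[["LOCRC"]], tab[["EXCLUDED"]]))
  cat(sprintf("  events: %d / %d\n",
              sum(x$clinical$endpoint_event), nrow(x$clinical)))
  invisible(x)
}

#' Sample filter for screening and selection populations
#'
#' The screening stage uses surgery-only samples of both age strata; the
#' selection stage restricts further to early-onset samples. Either component
#' may be `NULL` to impose no restriction.
#'
#' @param treatment allowed treatment arms, or `NULL` for any.
#' @param age_groups allowed age strata, or `NULL` for any.
#' @return an object of class `reo_filter`.
#' @export
cohort_filter <- function(treatment = "SURGERY_ONLY",
                          age_groups = c("EOCRC", "LOCRC")) {
  if (!is.null(treatment)) {
    bad <- setdiff(treatment, .treatments)
    if (length(bad) > 0) {
      stop_reo(sprintf("unknown treatment value(s): %s", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(age_groups)) {
    bad <- setdiff(age_groups, c("EOCRC", "LOCRC", "EXCLUDED"))
    if (length(bad) > 0) {
      stop_reo(sprintf("unknown age group(s): %s", paste(bad, collapse = ", ")))
    }
  }
  structure(list(treatment = treatment, age_groups = age_groups),
            class = "reo_filter")
}

filter_label <- function(filter) {
  if (is.null(filter)) return("all samples")
  paste0("treatment in {",
         paste(filter$treatment %||% "any", collapse = ","),
         "}, age group in {",
         paste(filter$age_groups %||% "any", collapse = ","), "}")
}

#' Restrict a cohort to a sample population
#'
#' @param cohort an [reo_cohort()].
#' @param filter an [cohort_filter()], or `NULL` for no restriction.
#' @param quiet suppress the exclusion-count message.
#' @return the restricted `reo_cohort`.
#' @export
filter_cohort <- function(cohort, filter, quiet = FALSE) {
  if (is.null(filter)) return(cohort)
  keep <- rep(TRUE, nrow(cohort$clinical))
  if (!is.null(filter$treatment)) {
    keep <- keep & cohort$clinical$treatment %in% filter$treatment
  }
  if (!is.null(filter$age_groups)) {
    keep <- keep & cohort$clinical$age_group %in% filter$age_groups
  }
  if (!any(keep)) {
    stop_reo(sprintf("cohort '%s': no sample satisfies filter (%s)",
                     cohort$name, filter_label(filter)))
  }
  if (!quiet && sum(!keep) > 0) {
    message(sprintf("cohort '%s': filter (%s) excluded %d of %d sample(s)",
                    cohort$name, filter_label(filter), sum(!keep), length(keep)))
  }
  out <- cohort
  out$expression <- cohort$expression[, keep, drop = FALSE]
  out$clinical <- cohort$clinical[keep, , drop = FALSE]
  rownames(out$clinical) <- NULL
  out
}

# ---- signature JSON serialization -----------------------------------------

sig_to_list <- function(sig) {
  cohorts <- attr(sig$pairs, "cohorts")
  pair_list <- lapply(seq_len(nrow(sig$pairs)), function(i) {
    row <- sig$pairs[i, , drop = FALSE]
    stats <- list()
    if (!is.null(cohorts)) {
      for (j in seq_along(cohorts)) {
        sfx <- names(cohorts)[j]
        stats[[unname(cohorts[j])]] <- list(
          log_hr = row[[paste0("log_hr_", sfx)]],
          hr = row[[paste0("hr_", sfx)]],
          p = row[[paste0("p_", sfx)]],
          n = row[[paste0("n_", sfx)]]
        )
      }
    }
    out <- list(gene_high = row$gene_high, gene_low = row$gene_low,
                stats_per_cohort = stats)
    if (!is.null(row$ranking_p)) out$ranking_p <- row$ranking_p
    out
  })
  list(pairs = pair_list,
       k = sig$k,
       vote_rule = sig$vote_rule,
       training_cindex = sig$training_cindex,
       training_population = sig$training_population)
}

#' Write a signature to JSON
#'
#' The JSON schema is
#' `{pairs:[{gene_high, gene_low, stats_per_cohort:{<cohort>:{log_hr,hr,p,n}}}],
#'  k, vote_rule, training_cindex, training_population}` and round-trips
#' losslessly through [read_signature()].
#'
#' @param sig an `reo_signature` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  if (!inherits(sig, "reo_signature")) {
    stop_reo("sig must be an reo_signature object")
  }
  jsonlite::write_json(sig_to_list(sig), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a signature from JSON
#'
#' Validates the schema and every signature invariant (gene-disjoint pairs,
#' `k` matching the pair count, positive hazard ratios, known vote rule,
#' C-index in \[0, 1\]) before constructing the object.
#'
#' @param path path to a JSON file written by [write_signature()].
#' @return an `reo_signature` object.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("pairs", "k", "vote_rule")) {
    if (is.null(obj[[field]])) {
      stop_reo(sprintf("signature JSON missing field '%s'", field))
    }
  }
  if (!identical(obj$vote_rule, "strict_majority")) {
    stop_reo(sprintf("unknown vote_rule '%s'", obj$vote_rule))
  }
  if (length(obj$pairs) != obj$k) {
    stop_reo(sprintf("field 'k' (%s) does not match number of pairs (%d)",
                     obj$k, length(obj$pairs)))
  }
  cohort_names <- NULL
  rows <- lapply(obj$pairs, function(p) {
    if (is.null(p$gene_high) || is.null(p$gene_low)) {
      stop_reo("signature JSON pair missing field 'gene_high' or 'gene_low'")
    }
    row <- list(gene_high = p$gene_high, gene_low = p$gene_low)
    stats <- p$stats_per_cohort
    if (length(stats) > 0) {
      if (is.null(cohort_names)) {
        cohort_names <<- names(stats)
      } else if (!identical(names(stats), cohort_names)) {
        stop_reo("field 'stats_per_cohort': inconsistent cohort names across pairs")
      }
      for (j in seq_along(stats)) {
        st <- stats[[j]]
        if (!is.null(st$hr) && st$hr <= 0) {
          stop_reo("field 'hr' must be positive")
        }
        sfx <- letters[j]
        row[[paste0("log_hr_", sfx)]] <- st$log_hr %||% NA_real_
        row[[paste0("hr_", sfx)]] <- st$hr %||% NA_real_
        row[[paste0("p_", sfx)]] <- st$p %||% NA_real_
        row[[paste0("n_", sfx)]] <- as.integer(st$n %||% NA_integer_)
      }
    }
    if (!is.null(p$ranking_p)) row$ranking_p <- p$ranking_p
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (!is.null(cohort_names)) {
    attr(pairs, "cohorts") <- setNames(cohort_names,
                                       letters[seq_along(cohort_names)])
  }
  tc <- obj$training_cindex
  if (!is.null(tc) && (tc < 0 || tc > 1)) {
    stop_reo("field 'training_cindex' must lie in [0, 1]")
  }
  new_reo_signature(pairs,
                    training_cindex = tc %||% NA_real_,
                    training_population = obj$training_population)
}

#' Write per-sample risk calls to TSV
#'
#' Columns: `sample_id`, `votes`, `k`, `label`.
#'
#' @param calls data.frame of risk calls from [classify()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_risk_calls <- function(calls, path) {
  needed <- c("sample_id", "votes", "k", "label")
  if (!all(needed %in% names(calls))) {
    stop_reo("risk calls must have columns sample_id, votes, k, label")
  }
  write.table(calls[, needed], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read per-sample risk calls from TSV
#'
#' @param path path to a file written by [write_risk_calls()].
#' @return data.frame of risk calls (class `reo_risk`).
#' @export
read_risk_calls <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  needed <- c("sample_id", "votes", "k", "label")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_reo(sprintf("risk call file lacks column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  if (!all(df$label %in% c("HIGH", "LOW"))) {
    stop_reo("risk call labels must be HIGH or LOW")
  }
  df$sample_id <- as.character(df$sample_id)
  df$votes <- as.integer(df$votes)
  df$k <- as.integer(df$k)
  class(df) <- c("reo_risk", "data.frame")
  df
}
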