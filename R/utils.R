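# Internal helpers: structured conditions and small utilities.

# Validation failures carry class "reo_validation_error"; empty pipeline
# stages carry "reo_empty_result" with a `stage` field so orchestration can
# distinguish a bad input from an honest no-result outcome.
stop_reo <- function(message, class = "reo_validation_error", ...) {
  cond <- structure(
    class = c(class, "reo_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
  stop(cond)
}

stop_empty <- function(stage, message) {
  stop_reo(message, class = "reo_empty_result", stage = stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pair_id <- function(gene_high, gene_low) {
  paste(gene_high, gene_low, sep = "|")
}

# Locale-independent lexicographic order for gene ids; the pipeline's
# "fixed total order on gene ids" everywhere.
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

check_finite_numeric <- function(x, what) {
  if (!is.numeric(x)) {
    stop_reo(sprintf("%s must be numeric", what))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_reo(sprintf("%s contains missing or non-finite values", what))
  }
  invisible(x)
}

check_survival_inputs <- function(times, events) {
  check_finite_numeric(times, "survival times")
  if (any(times <= 0)) {
    stop_reo("survival times must be positive")
  }
  check_finite_numeric(events, "event indicators")
  if (!all(events %in% c(0, 1))) {
    stop_reo("event indicators must be 0 or 1")
  }
  if (length(times) != length(events)) {
    stop_reo("times and events must have equal length")
  }
  invisible(NULL)
}
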