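#' @keywords internal
"_PACKAGE"

#' @useDynLib ecrfpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rbinom rlnorm runif t.test qt setNames
#' @importFrom utils read.delim write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed clinical tables round half up,
#' so 96.845 must become 96.85, not 96.84.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent change implied by a log-scale mean difference
#'
#' Converts a mean difference of natural-log-transformed outcomes into the
#' integer-rounded percent change of the geometric mean, the convention used
#' in headline statements such as "an increase of 15%".
#'
#' @param md mean difference on the log scale.
#' @return integer percent change (negative for a reduction).
#' @export
percent_change_from_md <- function(md) {
  as.integer(round_half_up((exp(md) - 1) * 100, 0))
}

## Leveled logging to stderr: "INFO [stage] message". Kept as plain
## condition-free writes so pipelines never fail on logging.
.log_level <- new.env(parent = emptyenv())
.log_level$current <- "info"

#' Set pipeline log level
#' @param level one of "debug", "info", "warn", "error", "off".
#' @return previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error", "off")) {
  level <- match.arg(level)
  old <- .log_level$current
  .log_level$current <- level
  invisible(old)
}

log_msg <- function(level, stage, msg) {
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4, off = 5)
  if (ranks[[level]] >= ranks[[.log_level$current]]) {
    cat(sprintf("%s [%s] %s\n", toupper(level), stage, msg), file = stderr())
  }
  invisible(NULL)
}

## shared enumerations
CATEGORIES <- c("medical_problem", "test", "treatment", "body_structure",
                "observable", "qualifier", "value")
DOC_TYPES <- c("admission_record", "imaging_report")
SECTION_KINDS <- c("true_false_I", "true_false_II", "multiple_choice",
                   "fill_in_blank")
ELEMENT_KINDS <- c("true_false", "multiple_choice", "fill_in_blank")
TRI_STATE <- c("true", "false", "not_mentioned")
ENTRY_MODES <- c("prepopulated", "manual", "modified")

#' Read documents from JSON Lines
#'
#' One JSON object per line with keys `case_id`, `doc_type`, `text`.
#'
#' @param path path to a JSONL file.
#' @return list of `ecrf_document` objects.
#' @export
read_documents_jsonl <- function(path) {
  if (!file.exists(path)) stop("document file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    new_document(x$case_id, x$doc_type, x$text %||% "")
  })
}

#' Write documents to JSON Lines
#' @param docs list of `ecrf_document`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_documents_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(list(case_id = d$case_id, doc_type = d$doc_type,
                          text = d$text), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
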