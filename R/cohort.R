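# Scored-cohort data model, validation and file I/O.
#
# A cohort is an ordinary tibble with columns:
#   case_id     character, unique
#   score       double in [0, 1] (closed interval; exact 0 and 1 are legal)
#   label       integer 0 (negative class) / 1 (positive class)
#   reader_call optional integer 0/1, NA allowed (rows without a reader call
#               are excluded from reader stratification only)

LABEL_LEVELS <- list(
  positive = c("1", "pos", "positive", "c1", "case", "true", "yes"),
  negative = c("0", "neg", "negative", "c0", "control", "false", "no")
)

.normalize_binary <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(v))
  out[v %in% LABEL_LEVELS$positive] <- 1L
  out[v %in% LABEL_LEVELS$negative] <- 0L
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop_validation(sprintf(
      "Column '%s' contains unrecognized values: %s",
      column, paste(unique(v[bad]), collapse = ", ")
    ))
  }
  out
}

#' Coerce a data frame to a validated scored cohort
#'
#' Normalizes column names via `column_map`, recodes labels given as
#' `{0,1}`, `{neg,pos}` or `{C0,C1}` to integer 0/1, and validates scores
#' and case identifiers.
#'
#' @param data A data frame with one row per case.
#' @param column_map Optional named character vector mapping canonical names
#'   (`case_id`, `score`, `label`, `reader_call`) to the column names used in
#'   `data`, e.g. `c(score = "probability")`.
#' @return A tibble with columns `case_id`, `score`, `label` and, when
#'   present, `reader_call`.
#' @examples
#' as_cohort(data.frame(case_id = c("a", "b"), score = c(0.2, 0.9),
#'                      label = c("neg", "pos")))
#' @export
as_cohort <- function(data, column_map = NULL) {
  if (!is.data.frame(data)) stop_usage("`data` must be a data frame.")
  df <- tibble::as_tibble(data)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), c("case_id", "score", "label", "reader_call"))
    if (length(unknown) > 0) {
      stop_usage(paste0("Unknown column_map entries: ", paste(unknown, collapse = ", ")))
    }
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src) > 0) {
      stop_usage(paste0("Mapped columns not found in data: ", paste(missing_src, collapse = ", ")))
    }
    for (canonical in names(column_map)) {
      names(df)[names(df) == column_map[[canonical]]] <- canonical
    }
  }
  required <- c("case_id", "score", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_usage(paste0("Missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    case_id = as.character(df$case_id),
    score = suppressWarnings(as.numeric(df$score)),
    label = .normalize_binary(df$label, "label")
  )
  if ("reader_call" %in% names(df)) {
    out$reader_call <- .normalize_binary(df$reader_call, "reader_call")
  }
  check_cohort(out)
}

#' Validate a scored cohort
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param require_both_classes If `TRUE`, require at least one positive and
#'   one negative case (needed for any zone or ROC computation).
#' @return The validated cohort, invisibly unchanged.
#' @export
check_cohort <- function(cohort, require_both_classes = FALSE) {
  if (!is.data.frame(cohort)) stop_usage("`cohort` must be a data frame.")
  missing_cols <- setdiff(c("case_id", "score", "label"), names(cohort))
  if (length(missing_cols) > 0) {
    stop_usage(paste0("Missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cohort) == 0) stop_validation("Cohort is empty.")
  if (anyDuplicated(cohort$case_id)) {
    dup <- unique(cohort$case_id[duplicated(cohort$case_id)])
    stop_validation(paste0("Duplicate case_id values: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.numeric(cohort$score) || anyNA(cohort$score)) {
    bad <- cohort$case_id[is.na(suppressWarnings(as.numeric(cohort$score)))]
    stop_validation(paste0(
      "Scores must be numeric and non-missing; offending case_id: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  out_of_range <- cohort$score < 0 | cohort$score > 1
  if (any(out_of_range)) {
    stop_validation(paste0(
      "Scores must lie in [0, 1]; offending case_id: ",
      paste(head(cohort$case_id[out_of_range], 5), collapse = ", ")
    ))
  }
  if (!all(cohort$label %in% c(0L, 1L))) {
    stop_validation("Labels must be 0 (negative) or 1 (positive).")
  }
  if (require_both_classes && (sum(cohort$label == 1L) == 0 || sum(cohort$label == 0L) == 0)) {
    stop_validation("Cohort must contain at least one positive and one negative case.")
  }
  invisible(tibble::as_tibble(cohort))
}

#' Read a scored cohort from a delimited file
#'
#' @param path Path to a CSV or TSV file with one row per case.
#' @param dialect `"auto"` (by file extension, default), `"csv"` or `"tsv"`.
#' @param column_map Optional mapping of canonical to file column names,
#'   see [as_cohort()].
#' @return A validated cohort tibble; row order is preserved.
#' @export
read_cohort <- function(path, dialect = c("auto", "csv", "tsv"), column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_io(paste0("File not found: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE,
               col_types = readr::cols(.default = readr::col_character()))
  as_cohort(df, column_map = column_map)
}

#' Summarize a scored cohort
#'
#' @param cohort A cohort tibble.
#' @return A one-row tibble with `n`, `n_pos`, `n_neg`, `prevalence`
#'   (`n_pos / n`, exactly), score range, and `zone_computable`, which is
#'   `FALSE` for single-class cohorts where zone and ROC computations are
#'   unavailable.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- check_cohort(cohort)
  n <- nrow(cohort)
  n_pos <- sum(cohort$label == 1L)
  tibble::tibble(
    n = n,
    n_pos = n_pos,
    n_neg = n - n_pos,
    prevalence = n_pos / n,
    score_min = min(cohort$score),
    score_max = max(cohort$score),
    n_reader_calls = if ("reader_call" %in% names(cohort)) sum(!is.na(cohort$reader_call)) else 0L,
    zone_computable = n_pos > 0 && n_pos < n
  )
}

#' Derive reader outcomes from reader calls and reference labels
#'
#' Classifies each case with a human-reader call as TP/TN/FP/FN against the
#' reference-standard label.
#'
#' @param cohort A cohort tibble containing a `reader_call` column.
#' @return The cohort with an added `reader_outcome` factor
#'   (`TP`, `TN`, `FP`, `FN`; `NA` where `reader_call` is missing).
#' @export
reader_outcomes <- function(cohort) {
  cohort <- check_cohort(cohort)
  if (!"reader_call" %in% names(cohort)) {
    stop_usage("Cohort has no `reader_call` column.")
  }
  out <- dplyr::mutate(
    cohort,
    reader_outcome = dplyr::case_when(
      .data$reader_call == 1L & .data$label == 1L ~ "TP",
      .data$reader_call == 0L & .data$label == 0L ~ "TN",
      .data$reader_call == 1L & .data$label == 0L ~ "FP",
      .data$reader_call == 0L & .data$label == 1L ~ "FN"
    )
  )
  out$reader_outcome <- factor(out$reader_outcome, levels = c("TP", "TN", "FP", "FN"))
  out
}

#' Write an analysis result to disk
#'
#' Writes cohorts, zone partitions, safety profiles and operating policies
#' in deterministic, round-trippable form: tabular objects as CSV with full
#' double precision, policies as JSON.
#'
#' @param x Object to write.
#' @param path Output file path; the format is chosen by extension
#'   (`.csv`/`.tsv`/`.json`) unless `format` is given.
#' @param format Optional explicit format, `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  UseMethod("write_results")
}

.resolve_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

.check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(paste0("Directory does not exist: ", dir))
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, format = NULL) {
  .check_writable(path)
  fmt <- .resolve_format(path, format)
  if (fmt == "json") {
    jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA, na = "null")
  } else {
    readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  }
  invisible(path)
}

#' @export
write_results.sa_partition <- function(x, path, format = NULL) {
  write_results(tidy(x), path, format)
}

#' @export
write_results.sa_profile <- function(x, path, format = NULL) {
  write_results(tibble::as_tibble(x), path, format)
}

#' @export
write_results.sa_policy <- function(x, path, format = NULL) {
  .check_writable(path)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}
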