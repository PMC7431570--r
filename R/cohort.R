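# Cohort data model ------------------------------------------------------

#' Build a monitoring cohort
#'
#' A cohort holds one row per collared animal: an opaque `animal_id`, the
#' collaring date, the end date (death, last telemetry contact for LTF, or
#' administrative censoring) and the endpoint label from the seven-label
#' taxonomy ([cr_taxonomy()]). Optional flags: `found_later` (LTF animal later
#' recovered by non-telemetry means; the end date stays at last telemetry
#' contact) and `unresolved` (record censored with a missing endpoint, a
#' candidate for [apply_imputation()]).
#'
#' @param df Data frame with columns `animal_id`, `collar_date`, `end_date`,
#'   `endpoint`, and optionally `found_later`, `unresolved`.
#' @return The cohort as a `cr_cohort` data frame with coerced column types.
#' @export
as_cohort <- function(df) {
  need <- c("animal_id", "collar_date", "end_date", "endpoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    .cr_stop(paste("cohort missing column(s):", paste(miss, collapse = ", ")),
      class = "wolfcr_cohort_error"
    )
  }
  out <- data.frame(
    animal_id = as.character(df$animal_id),
    collar_date = as.Date(df$collar_date),
    end_date = as.Date(df$end_date),
    endpoint = as.character(df$endpoint),
    found_later = if ("found_later" %in% names(df)) as.logical(df$found_later) else FALSE,
    unresolved = if ("unresolved" %in% names(df)) as.logical(df$unresolved) else FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cr_cohort", "data.frame")
  out
}

#' Read and write cohort CSV files
#'
#' Cohort CSVs carry columns `animal_id`, `collar_date`, `end_date`,
#' `endpoint` (lowercase taxonomy labels), plus optional `found_later` and
#' `unresolved` logical flags; dates in ISO 8601.
#'
#' @param path Path to a CSV file.
#' @return `read_cohort()` returns a `cr_cohort` data frame.
#' @export
read_cohort <- function(path) {
  as_cohort(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param cohort Cohort data frame to write.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$collar_date <- format(out$collar_date, "%Y-%m-%d")
  out$end_date <- format(out$end_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a cohort
#'
#' Accounting for every individual at risk is essential for unbiased hazard
#' and incidence estimates, so validation is strict: the report lists
#' duplicated ids, records whose end date precedes (or equals) the collaring
#' date, endpoint labels outside the taxonomy, and tabulates the endpoint mix
#' with proportions.
#'
#' @param records A `cr_cohort` (or coercible data frame).
#' @param window Optional Date vector of length 2; records must fall inside.
#' @return A `cr_validation` report list with elements `n`, `duplicates`,
#'   `date_violations`, `bad_endpoints`, `window_violations`, `tabulation`
#'   and `ok`.
#' @export
validate_cohort <- function(records, window = NULL) {
  records <- as_cohort(records)
  dup <- unique(records$animal_id[duplicated(records$animal_id)])
  datev <- records$animal_id[records$end_date <= records$collar_date]
  bad <- unique(records$endpoint[!records$endpoint %in% cr_taxonomy()])
  winv <- character(0)
  if (!is.null(window)) {
    winv <- records$animal_id[records$collar_date < window[1] |
      records$end_date > window[2]]
  }
  tab <- table(factor(records$endpoint, levels = cr_taxonomy()))
  tabulation <- data.frame(
    endpoint = names(tab),
    n = as.integer(tab),
    proportion = as.numeric(tab) / nrow(records),
    stringsAsFactors = FALSE
  )
  out <- list(
    n = nrow(records),
    duplicates = dup,
    date_violations = datev,
    bad_endpoints = bad,
    window_violations = winv,
    tabulation = tabulation,
    ok = length(dup) == 0 && length(datev) == 0 && length(bad) == 0 &&
      length(winv) == 0
  )
  class(out) <- "cr_validation"
  out
}

#' @export
print.cr_validation <- function(x, ...) {
  cat("Cohort validation:", x$n, "records -",
    if (x$ok) "OK" else "FAILED", "\n")
  if (length(x$duplicates)) {
    cat("  duplicated ids:", paste(x$duplicates, collapse = ", "), "\n")
  }
  if (length(x$date_violations)) {
    cat("  end <= collar date:", paste(x$date_violations, collapse = ", "), "\n")
  }
  if (length(x$bad_endpoints)) {
    cat("  unknown endpoints:", paste(x$bad_endpoints, collapse = ", "), "\n")
  }
  if (length(x$window_violations)) {
    cat("  outside study window:", paste(x$window_violations, collapse = ", "), "\n")
  }
  cat("Endpoint mix:\n")
  tab <- x$tabulation
  tab$proportion <- sprintf("%.1f%%", 100 * tab$proportion)
  print(tab, row.names = FALSE)
  invisible(x)
}
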