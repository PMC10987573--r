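#' Interquartile-range outlier fences
#'
#' Quartiles are computed by linear interpolation of order statistics
#' (quantile type 7); the fences are `Q1 - 1.5 * IQR` and `Q3 + 1.5 * IQR`.
#' Values strictly outside the fences are considered outliers; values exactly
#' on a fence are not.
#'
#' @param values numeric vector with at least 4 non-missing values.
#' @return list with `q1`, `q3`, `iqr`, `lower_fence`, `upper_fence`.
#' @export
iqr_fences <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 4) .stopf("need at least 4 non-missing values, got %d", length(x))
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], iqr = iqr,
       lower_fence = q[1] - 1.5 * iqr, upper_fence = q[2] + 1.5 * iqr)
}

#' Remove outlying regions by the 1.5-IQR rule
#'
#' Single pass: fences are computed per variable on the data as given, then a
#' region (row) is removed if any of the listed variables lies strictly
#' outside its fences. Missing values never flag a row. Surviving rows keep
#' their order.
#'
#' @param table a `community_table`.
#' @param variables names of the numeric variables to screen.
#' @return list with `table` (the cleaned `community_table`) and `report`, a
#'   `cleaning_report` holding per-variable fences plus `kept_ids` and
#'   `removed_ids`.
#' @export
remove_outliers <- function(table, variables) {
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars))
    .stopf("variables not in table: %s", paste(missing_vars, collapse = ", "))
  non_num <- variables[!vapply(table[variables], is.numeric, logical(1))]
  if (length(non_num))
    .stopf("non-numeric variables: %s", paste(non_num, collapse = ", "))
  fences <- lapply(table[variables], iqr_fences)
  flag <- rep(FALSE, nrow(table))
  for (v in variables) {
    x <- table[[v]]
    f <- fences[[v]]
    flag <- flag | (!is.na(x) & (x < f$lower_fence | x > f$upper_fence))
  }
  if (all(flag)) .stopf("cleaning annihilated dataset (all %d rows removed)", nrow(table))
  report <- structure(list(fences = fences,
                           kept_ids = table$region_id[!flag],
                           removed_ids = table$region_id[flag]),
                      class = "cleaning_report")
  cleaned <- table[!flag, , drop = FALSE]
  rownames(cleaned) <- NULL
  class(cleaned) <- c("community_table", "data.frame")
  list(table = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Outlier cleaning: %d kept, %d removed",
              length(x$kept_ids), length(x$removed_ids)))
  if (length(x$removed_ids))
    cat(sprintf(" (%s)", paste(x$removed_ids, collapse = ", ")))
  cat("\n")
  for (v in names(x$fences)) {
    f <- x$fences[[v]]
    cat(sprintf("  %s: Q1=%s Q3=%s fences [%s, %s]\n", v, .fmt(f$q1),
                .fmt(f$q3), .fmt(f$lower_fence), .fmt(f$upper_fence)))
  }
  invisible(x)
}
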