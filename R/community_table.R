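#' Community-area variable tables
#'
#' A community table is the unit of all analysis in this package: one row per
#' geographic region (for example one of Chicago's 77 community areas), a
#' character `region_id` column holding unique region identifiers, and any
#' number of numeric (rates, percentages) or categorical columns. Missing
#' values are stored as `NA`.
#'
#' @param data a data.frame containing an id column plus variable columns.
#' @param id_column name of the column holding region identifiers.
#' @return an object of class `community_table` (a data.frame whose first
#'   column is the character `region_id`).
#' @examples
#' community_table(data.frame(region = c("A", "B"), poverty = c(10, 20)),
#'                 id_column = "region")
#' @export
community_table <- function(data, id_column = "region_id") {
  if (!is.data.frame(data)) .stopf("`data` must be a data.frame")
  if (!id_column %in% names(data))
    .stopf("id column '%s' not found", id_column)
  ids <- trimws(as.character(data[[id_column]]))
  if (anyNA(ids) || any(ids == ""))
    .stopf("region ids must be non-empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .stopf("duplicate region ids: %s", paste(dup, collapse = ", "))
  vars <- data[setdiff(names(data), id_column)]
  bad <- vapply(vars, function(v) is.numeric(v) && any(!is.finite(v) & !is.na(v)),
                logical(1))
  if (any(bad))
    .stopf("non-finite values (Inf/NaN) in: %s; use NA for missing",
           paste(names(vars)[bad], collapse = ", "))
  out <- cbind(data.frame(region_id = ids, stringsAsFactors = FALSE), vars)
  rownames(out) <- NULL
  class(out) <- c("community_table", "data.frame")
  out
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: %d regions, %d numeric and %d categorical variables\n",
              nrow(x), length(numeric_vars(x)), length(categorical_vars(x))))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Names of the numeric / categorical variables of a community table
#' @param table a `community_table`.
#' @return character vector of column names.
#' @export
numeric_vars <- function(table) {
  v <- setdiff(names(table), "region_id")
  v[vapply(table[v], is.numeric, logical(1))]
}

#' @rdname numeric_vars
#' @export
categorical_vars <- function(table) {
  v <- setdiff(names(table), "region_id")
  v[!vapply(table[v], is.numeric, logical(1))]
}

#' Read a community table from CSV
#'
#' Reads an RFC 4180 CSV with a header row. Columns whose non-missing cells
#' all parse as numbers become numeric; empty cells, `NA` and `NaN`
#' (case-insensitive) are treated as missing. Region ids are stripped of
#' surrounding whitespace and must be unique and non-empty.
#'
#' @param path path to the CSV file.
#' @param id_column name of the region-id column (default `"region_id"`).
#' @return a [community_table()].
#' @export
read_community_csv <- function(path, id_column = "region_id") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!id_column %in% names(raw))
    .stopf("id column '%s' not found in %s", id_column, path)
  parsed <- raw
  for (v in setdiff(names(raw), id_column)) parsed[[v]] <- .parse_column(raw[[v]])
  community_table(parsed, id_column = id_column)
}

#' Write a community table to CSV
#'
#' Inverse of [read_community_csv()]: finite values round-trip exactly
#' (written with full precision), missing values are written as empty cells.
#'
#' @param table a `community_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community_csv <- function(table, path) {
  out <- as.data.frame(table)
  for (v in names(out)) {
    if (is.numeric(out[[v]])) {
      s <- vapply(out[[v]], function(x)
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE,
                                     trim = TRUE), character(1))
      out[[v]] <- s
    } else out[[v]][is.na(out[[v]])] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
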