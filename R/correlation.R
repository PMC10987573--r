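.new_correlation_result <- function(method, label, r, n_eff, k_adj = 0L) {
  df <- n_eff - 2L - k_adj
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  se_z <- 1 / sqrt(n_eff - 3L - k_adj)
  ci <- tanh(atanh(r) + c(-1, 1) * 1.96 * se_z)
  structure(list(method = method, label = label, r = r,
                 n_effective = n_eff, k_adjusted = k_adj, df = df,
                 t_statistic = t, p_value = p, ci95 = ci),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation (%s): r = %s, 95%% CI [%s, %s], t = %s, p = %s, n = %d\n",
              .cap(x$method), x$label, .fmt(x$r, 3),
              .fmt(x$ci95[1], 3), .fmt(x$ci95[2], 3), .fmt(x$t_statistic, 4),
              .fmt(x$p_value, 4), x$n_effective))
  invisible(x)
}

#' Correlation between two community-level variables
#'
#' Pearson product-moment or Spearman rank correlation on complete pairs,
#' with a t test of significance (`t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom, two-sided) and a Fisher-z 95% confidence
#' interval `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`. Spearman is computed as
#' Pearson correlation of average ranks, with the same t approximation.
#'
#' @param x,y paired numeric vectors; pairs with any missing value are
#'   dropped (at least 5 complete pairs required).
#' @param method `"pearson"` or `"spearman"`.
#' @param label label carried into reports (default `"Raw Data"`).
#' @return a `correlation_result` with fields `r`, `n_effective`,
#'   `t_statistic`, `p_value`, `ci95`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman"),
                             label = "Raw Data") {
  method <- match.arg(method)
  if (length(x) != length(y)) .stopf("x and y must be the same length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) .stopf("need at least 5 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stopf("degenerate variable (zero variance)")
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  r <- stats::cor(x, y)
  .new_correlation_result(method, label, r, n)
}

#' Crude and cleaned correlation between two variables
#'
#' Runs the full univariate pipeline: the raw correlation on untouched
#' complete pairs, then the same correlation after selecting a best-fit
#' normality transform for each variable ([select_transform()]) and removing
#' IQR outliers on both transformed variables ([remove_outliers()]). The two
#' results are labelled "Raw Data" and "Using Statistical Intelligence".
#'
#' @param table a `community_table`.
#' @param primary,secondary names of two numeric variables.
#' @inheritParams correlation_test
#' @return list of class `intelligent_correlation` with elements `raw`,
#'   `intelligent` (both `correlation_result`), `transforms` (per-variable
#'   `transform_report`) and `cleaning` (a `cleaning_report`).
#' @export
correlate_intelligent <- function(table, primary, secondary,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  for (v in c(primary, secondary)) {
    if (!v %in% names(table)) .stopf("variable '%s' not in table", v)
    if (!is.numeric(table[[v]])) .stopf("variable '%s' is not numeric", v)
  }
  ok <- !is.na(table[[primary]]) & !is.na(table[[secondary]])
  sub <- table[ok, , drop = FALSE]
  raw <- correlation_test(sub[[primary]], sub[[secondary]], method,
                          label = "Raw Data")
  transforms <- list()
  trans_tab <- data.frame(region_id = sub$region_id, stringsAsFactors = FALSE)
  for (v in c(primary, secondary)) {
    rep <- select_transform(sub[[v]])
    transforms[[v]] <- rep
    trans_tab[[v]] <- rep$transformed_values
  }
  trans_tab <- community_table(trans_tab)
  cleaned <- remove_outliers(trans_tab, c(primary, secondary))
  intelligent <- correlation_test(cleaned$table[[primary]],
                                  cleaned$table[[secondary]], method,
                                  label = "Using Statistical Intelligence")
  structure(list(raw = raw, intelligent = intelligent,
                 transforms = transforms, cleaning = cleaned$report,
                 table = cleaned$table),
            class = "intelligent_correlation")
}

# one result as a Table-1-style row
.corr_row <- function(res) {
  data.frame(
    Method = paste0(.cap(res$method),
                    if (res$method == "pearson") "'s product-moment correlation"
                    else "'s rank correlation"),
    Label = res$label,
    Correlation = round(res$r, 3),
    `95% CI` = sprintf("[%s %s]", round(res$ci95[1], 3), round(res$ci95[2], 3)),
    t = round(res$t_statistic, 3),
    `p-value` = round(res$p_value, 4),
    check.names = FALSE)
}

#' @export
print.intelligent_correlation <- function(x, ...) {
  print(rbind(.corr_row(x$raw), .corr_row(x$intelligent)), row.names = FALSE)
  sel <- vapply(x$transforms, `[[`, character(1), "transform_name")
  cat(sprintf("Transforms: %s\n",
              paste(names(sel), sel, sep = " -> ", collapse = ", ")))
  if (length(x$cleaning$removed_ids))
    cat(sprintf("Outliers removed: %s\n",
                paste(x$cleaning$removed_ids, collapse = ", ")))
  invisible(x)
}
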