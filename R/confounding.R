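#' Screen candidate confounders by the correlation matrix
#'
#' A confounder must be associated with both the outcome (primary variable)
#' and the exposure (secondary variable). A candidate passes the screen when
#' the magnitude of its correlation with each of them reaches `threshold`.
#'
#' @param table a `community_table`.
#' @param primary,secondary names of the outcome and exposure variables.
#' @param candidates names of numeric candidate variables (must not include
#'   primary or secondary).
#' @param threshold correlation magnitude required on both arms (default 0.3).
#' @return character vector of screened candidate names (possibly empty),
#'   with the candidate-by-arm correlations attached as attribute `"arms"`.
#' @export
screen_candidates <- function(table, primary, secondary, candidates,
                              threshold = 0.3) {
  candidates <- setdiff(candidates, c(primary, secondary))
  if (!length(candidates)) return(character())
  arms <- t(vapply(candidates, function(cand) {
    c(with_primary = stats::cor(table[[cand]], table[[primary]],
                                use = "complete.obs"),
      with_secondary = stats::cor(table[[cand]], table[[secondary]],
                                  use = "complete.obs"))
  }, numeric(2)))
  keep <- abs(arms[, 1]) >= threshold & abs(arms[, 2]) >= threshold
  structure(candidates[keep], arms = arms)
}

#' Change-in-estimate confounding rule
#'
#' The standard epidemiological 10 percent rule: confounding is suspected
#' when the exposure coefficient moves by more than 10 percent upon
#' adjustment. The change is measured on absolute values, so a sign flip
#' always flags.
#'
#' @param beta_crude exposure coefficient from the unadjusted model (nonzero).
#' @param beta_adjusted exposure coefficient after adding the candidates.
#' @param threshold flag when percent change exceeds this (default 10).
#' @return list with `percent_change` (`100 * |adj - crude| / |crude|`) and
#'   logical `flagged`.
#' @export
coefficient_change <- function(beta_crude, beta_adjusted, threshold = 10) {
  if (beta_crude == 0) .stopf("crude effect is zero; percent change undefined")
  pc <- 100 * abs(beta_adjusted - beta_crude) / abs(beta_crude)
  list(percent_change = pc, flagged = pc > threshold)
}

# residualize y on the columns of Z (with intercept) by least squares
.residualize <- function(y, Z) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Z), y)
  fit$residuals
}

#' Partial correlation with confounders removed
#'
#' Residualizes both variables on the adjustment set by least squares (with
#' intercept) and correlates the residuals. Inference accounts for the k
#' partialled-out variables: `t = r * sqrt((n - 2 - k) / (1 - r^2))` on
#' `n - 2 - k` degrees of freedom, and the Fisher-z 95% interval uses
#' `sqrt(n - 3 - k)`. With an empty adjustment set this is exactly
#' [correlation_test()].
#'
#' @param x,y paired numeric vectors.
#' @param z adjustment set: a numeric matrix / data.frame with one column per
#'   confounder, or NULL / zero columns for none.
#' @param label report label (default `"Confounding Removed"`).
#' @return a `correlation_result` with `k_adjusted = ncol(z)`.
#' @export
partial_correlation <- function(x, y, z = NULL, label = "Confounding Removed") {
  if (is.null(z) || NCOL(z) == 0 || (is.list(z) && !length(z))) {
    out <- correlation_test(x, y, "pearson", label = label)
    return(out)
  }
  Z <- as.matrix(as.data.frame(z))
  if (length(x) != length(y) || nrow(Z) != length(x))
    .stopf("x, y and z must have the same number of rows")
  ok <- !is.na(x) & !is.na(y) & stats::complete.cases(Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  k <- ncol(Z)
  n <- length(x)
  if (n < k + 5) .stopf("need at least %d complete cases for %d confounders, got %d",
                        k + 5, k, n)
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < k + 1) {
    dep <- colnames(Z)[qrz$pivot[-seq_len(qrz$rank)] - 1L]
    .stopf("collinear adjustment set; dependent columns: %s",
           paste(dep, collapse = ", "))
  }
  rx <- .residualize(x, Z)
  ry <- .residualize(y, Z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    .stopf("degenerate variable (zero residual variance)")
  r <- stats::cor(rx, ry)
  .new_correlation_result("pearson", label, r, n, k_adj = as.integer(k))
}

#' Assess confounding of a bivariate association
#'
#' Implements the two-step confounder check. First, candidates are screened
#' on the correlation matrix ([screen_candidates()]). Second, a crude linear
#' model `primary ~ secondary` is compared with the adjusted model
#' `primary ~ secondary + screened candidates`; if the exposure coefficient
#' changes by more than 10 percent ([coefficient_change()]) the screened set
#' is declared confounding. The adjusted association is then reported as the
#' partial correlation given the confounder set. Expects the variables to
#' have already been through any transform/cleaning pipeline the caller uses.
#'
#' @param table a `community_table` (all involved variables numeric).
#' @param primary,secondary outcome and exposure variable names.
#' @param metadata names of candidate confounder variables.
#' @param threshold screening correlation magnitude (default 0.3).
#' @param change_threshold percent-change cutoff (default 10).
#' @return a `confounder_report`: crude and adjusted coefficients with the
#'   percent change and flag, per-candidate one-at-a-time changes, the
#'   correlation matrix over all involved variables, the named
#'   `confounder_set`, and `adjusted_result` (a `correlation_result` labelled
#'   "Confounding Removed"; the crude correlation when no confounding found).
#' @export
assess_confounding <- function(table, primary, secondary, metadata,
                               threshold = 0.3, change_threshold = 10) {
  metadata <- setdiff(metadata, c(primary, secondary))
  vars <- c(primary, secondary, metadata)
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars))
    .stopf("variables not in table: %s", paste(missing_vars, collapse = ", "))
  cmat <- stats::cor(as.matrix(table[vars]), use = "pairwise.complete.obs")
  screened <- screen_candidates(table, primary, secondary, metadata, threshold)

  cc <- stats::complete.cases(table[c(primary, secondary, as.character(screened))])
  sub <- table[cc, , drop = FALSE]
  crude_fit <- stats::lm(stats::reformulate(secondary, response = primary),
                         data = sub)
  beta_crude <- unname(stats::coef(crude_fit)[secondary])
  if (is.na(beta_crude) || beta_crude == 0)
    .stopf("degenerate crude model: exposure coefficient is %s",
           if (is.na(beta_crude)) "undefined" else "zero")

  per_candidate <- NULL
  if (length(metadata)) {
    per_candidate <- do.call(rbind, lapply(metadata, function(cand) {
      cci <- stats::complete.cases(table[c(primary, secondary, cand)])
      fit1 <- stats::lm(stats::reformulate(secondary, response = primary),
                        data = table[cci, ])
      fit2 <- stats::lm(stats::reformulate(c(secondary, cand), response = primary),
                        data = table[cci, ])
      b1 <- unname(stats::coef(fit1)[secondary])
      b2 <- unname(stats::coef(fit2)[secondary])
      ch <- coefficient_change(b1, b2, change_threshold)
      data.frame(candidate = cand,
                 cor_with_primary = cmat[cand, primary],
                 cor_with_secondary = cmat[cand, secondary],
                 screened = cand %in% screened,
                 beta_adjusted_alone = b2,
                 percent_change_alone = ch$percent_change)
    }))
    rownames(per_candidate) <- NULL
  }

  if (length(screened)) {
    adj_fit <- stats::lm(stats::reformulate(c(secondary, as.character(screened)),
                                            response = primary), data = sub)
    beta_adjusted <- unname(stats::coef(adj_fit)[secondary])
    change <- coefficient_change(beta_crude, beta_adjusted, change_threshold)
  } else {
    beta_adjusted <- beta_crude
    change <- list(percent_change = 0, flagged = FALSE)
  }
  confounder_set <- if (change$flagged) as.character(screened) else character()
  adjusted_result <- partial_correlation(sub[[primary]], sub[[secondary]],
                                         sub[confounder_set])
  structure(list(primary = primary, secondary = secondary,
                 beta_crude = beta_crude, beta_adjusted = beta_adjusted,
                 percent_change = change$percent_change, flagged = change$flagged,
                 screened = as.character(screened), confounder_set = confounder_set,
                 per_candidate = per_candidate, correlation_matrix = cmat,
                 adjusted_result = adjusted_result, n = nrow(sub)),
            class = "confounder_report")
}

#' @export
print.confounder_report <- function(x, ...) {
  cat(sprintf("Confounding assessment for %s ~ %s (n = %d)\n",
              x$primary, x$secondary, x$n))
  cat(sprintf("  crude beta %s -> adjusted beta %s (change %s%%): %s\n",
              .fmt(x$beta_crude), .fmt(x$beta_adjusted), .fmt(x$percent_change, 3),
              if (x$flagged) "confounding flagged" else "no confounding flagged"))
  if (length(x$confounder_set))
    cat(sprintf("  confounders: %s\n", paste(x$confounder_set, collapse = ", ")))
  print(.corr_row(x$adjusted_result), row.names = FALSE)
  invisible(x)
}
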