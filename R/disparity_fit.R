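#' Fit a health-disparity model over community areas
#'
#' The package's front end. The formula names the primary outcome on the left
#' and the secondary variables on the right, e.g.
#' `mortality ~ poverty` or `mortality ~ poverty + safety + females`.
#'
#' With a single secondary variable the univariate path runs: the crude
#' correlation, the "statistical intelligence" correlation (best-fit
#' normality transform per variable, then 1.5-IQR outlier removal), and a
#' confounder assessment over the `metadata` candidates (correlation-matrix
#' screen plus the 10 percent change-in-estimate rule), ending in the
#' confounder-adjusted partial correlation.
#'
#' With two or more secondaries the multivariate path runs: per-variable
#' transform selection, outlier removal, standardization, then a linear,
#' logistic or lasso model (chosen automatically from the data shape unless
#' forced) with percent-contribution importance ranking.
#'
#' @param formula `primary ~ secondary` or `primary ~ s1 + s2 + ...`.
#' @param data a [community_table()] (or a data.frame with a `region_id`
#'   column, which is converted).
#' @param method `"auto"` (default) or one of `"pearson"`, `"spearman"`
#'   (univariate), `"ols"`, `"logistic"`, `"lasso"` (multivariate).
#' @param metadata candidate-confounder variable names for the univariate
#'   path; defaults to all other numeric variables in the table.
#' @param transform,clean logical switches for the transform-selection and
#'   outlier-removal stages (both on by default).
#' @param conf_threshold screening correlation magnitude for confounder
#'   candidates (default 0.3).
#' @param seed seed used where a stage is stochastic (lasso CV folds).
#' @return an object of class `disparity_fit` with, depending on the path,
#'   components `correlation` (an `intelligent_correlation`), `confounding`
#'   (a `confounder_report`), or `model` (a `regression_result`) and
#'   `ranking` (an `importance_ranking`), plus `transforms` and `cleaning`.
#' @examples
#' tab <- generate_confounded_table(confounding_scenario(n = 120, seed = 7))
#' fit <- disparity_fit(primary ~ secondary, tab)
#' summary(fit)
#' @export
disparity_fit <- function(formula, data,
                          method = c("auto", "pearson", "spearman",
                                     "ols", "logistic", "lasso"),
                          metadata = NULL, transform = TRUE, clean = TRUE,
                          conf_threshold = 0.3, seed = 1) {
  method <- match.arg(method)
  if (!inherits(data, "community_table")) data <- community_table(data)
  vars <- all.vars(formula)
  primary <- vars[1]
  secondaries <- attr(stats::terms(formula, data = data), "term.labels")
  if (primary %in% secondaries)
    .stopf("primary variable must not appear among the secondaries")
  missing_vars <- setdiff(c(primary, secondaries), names(data))
  if (length(missing_vars))
    .stopf("variables not in table: %s", paste(missing_vars, collapse = ", "))
  call <- match.call()

  if (length(secondaries) == 1L) {
    cor_method <- if (method %in% c("pearson", "spearman")) method else "pearson"
    if (method %in% c("ols", "logistic", "lasso"))
      .stopf("method '%s' needs at least two secondary variables", method)
    res <- .fit_univariate(data, primary, secondaries, cor_method, metadata,
                           transform, clean, conf_threshold)
  } else {
    if (method %in% c("pearson", "spearman"))
      .stopf("method '%s' applies to a single secondary variable", method)
    res <- .fit_multivariate(data, primary, secondaries, method,
                             transform, clean, seed)
  }
  res$call <- call
  res$primary <- primary
  res$secondaries <- secondaries
  class(res) <- "disparity_fit"
  res
}

.fit_univariate <- function(data, primary, secondary, cor_method, metadata,
                            transform, clean, conf_threshold) {
  if (is.null(metadata))
    metadata <- setdiff(numeric_vars(data), c(primary, secondary))
  if (transform && clean) {
    ic <- correlate_intelligent(data, primary, secondary, cor_method)
    analysis_tab <- ic$table  # transformed + cleaned rows
  } else {
    raw <- correlation_test(data[[primary]], data[[secondary]], cor_method)
    ic <- structure(list(raw = raw, intelligent = raw, transforms = list(),
                         cleaning = NULL, table = data),
                    class = "intelligent_correlation")
    analysis_tab <- data
  }
  # carry metadata candidates (raw scale) into the analysis rows
  meta_cols <- data[match(analysis_tab$region_id, data$region_id), metadata,
                    drop = FALSE]
  conf_tab <- community_table(cbind(analysis_tab[c("region_id", primary, secondary)],
                                    meta_cols))
  confounding <- if (length(metadata))
    assess_confounding(conf_tab, primary, secondary, metadata,
                       threshold = conf_threshold)
  else NULL
  list(kind = "univariate", correlation = ic, confounding = confounding,
       transforms = ic$transforms, cleaning = ic$cleaning,
       analysis_table = analysis_tab)
}

.fit_multivariate <- function(data, primary, secondaries, method,
                              transform, clean, seed) {
  vars <- c(primary, secondaries)
  cc <- stats::complete.cases(data[vars])
  tab <- data[cc, c("region_id", vars)]
  class(tab) <- c("community_table", "data.frame")
  binary_primary <- length(unique(tab[[primary]])) <= 2
  transforms <- list()
  trans_vars <- if (binary_primary) secondaries else vars
  if (transform) {
    for (v in trans_vars) {
      rep <- select_transform(tab[[v]])
      transforms[[v]] <- rep
      tab[[v]] <- rep$transformed_values
    }
  }
  cleaning <- NULL
  if (clean) {
    cleaned <- remove_outliers(tab, trans_vars)
    tab <- cleaned$table
    cleaning <- cleaned$report
  }
  std_vars <- if (binary_primary) secondaries else vars
  tab <- standardize(tab, std_vars)
  kind <- if (method == "auto") auto_select_method(tab, primary, secondaries)
  else method
  y <- tab[[primary]]
  X <- as.matrix(tab[secondaries])
  model <- switch(as.character(kind),
                  ols = fit_ols(y, X),
                  logistic = fit_logistic(y, X),
                  lasso = fit_lasso(y, X, seed = seed))
  list(kind = "multivariate", model = model, ranking = rank_factors(model),
       method_reason = attr(kind, "reason"), transforms = transforms,
       cleaning = cleaning, analysis_table = tab,
       scaling = list(centers = attr(tab, "centers"), scales = attr(tab, "scales")))
}

#' @export
print.disparity_fit <- function(x, ...) {
  cat("Health-disparity fit:", deparse(x$call$formula), "\n")
  if (x$kind == "univariate") {
    print(x$correlation)
    if (!is.null(x$confounding)) print(x$confounding)
  } else {
    if (!is.null(x$method_reason))
      cat(sprintf("Model chosen automatically: %s (%s)\n",
                  x$model$model_kind, x$method_reason))
    print(x$model)
  }
  invisible(x)
}

#' Summarise a disparity fit as report tables
#'
#' The univariate path yields the crude/cleaned correlation rows and, when a
#' confounder assessment ran, the adjusted row; the multivariate path yields
#' the per-feature coefficient/contribution table.
#'
#' @param object a `disparity_fit`.
#' @param ... unused.
#' @return a list of data.frames of class `summary.disparity_fit`.
#' @export
summary.disparity_fit <- function(object, ...) {
  out <- list(kind = object$kind, formula = object$call$formula)
  if (object$kind == "univariate") {
    rows <- rbind(.corr_row(object$correlation$raw),
                  .corr_row(object$correlation$intelligent))
    if (!is.null(object$confounding))
      out$adjusted <- .corr_row(object$confounding$adjusted_result)
    out$correlations <- rows
    if (!is.null(object$confounding)) {
      out$confounders <- object$confounding$confounder_set
      out$percent_change <- object$confounding$percent_change
    }
  } else {
    out$model <- regression_table(object$model)
    out$ranking <- as.data.frame(object$ranking)
  }
  class(out) <- "summary.disparity_fit"
  out
}

#' @export
print.summary.disparity_fit <- function(x, ...) {
  cat("Disparity analysis:", deparse(x$formula), "\n\n")
  if (x$kind == "univariate") {
    print(x$correlations, row.names = FALSE)
    if (!is.null(x$adjusted)) {
      cat("\nAfter removing potential confounders",
          if (length(x$confounders))
            sprintf("(%s)", paste(x$confounders, collapse = ", ")) else "(none flagged)",
          "\n")
      print(x$adjusted, row.names = FALSE)
    }
  } else {
    print(x$model, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.disparity_fit <- function(object, ...) {
  if (object$kind == "multivariate") object$model$coefficients
  else c(raw = object$correlation$raw$r,
         intelligent = object$correlation$intelligent$r,
         adjusted = if (!is.null(object$confounding))
           object$confounding$adjusted_result$r else NA_real_)
}

#' @export
residuals.disparity_fit <- function(object, ...) {
  if (object$kind != "multivariate")
    .stopf("residuals are defined for the multivariate path")
  object$model$residuals
}

#' Predict from a multivariate disparity fit
#'
#' Applies the stored standardization to `newdata` (which must be on the same
#' scale as the analysis table, i.e. after any transforms) and evaluates the
#' linear predictor; logistic fits return response-scale probabilities.
#'
#' @param object a multivariate `disparity_fit`.
#' @param newdata data.frame with the secondary variables; defaults to the
#'   analysis table.
#' @param ... unused.
#' @return numeric predictions, on the primary variable's standardized scale
#'   for ols/lasso and the probability scale for logistic.
#' @export
predict.disparity_fit <- function(object, newdata = NULL, ...) {
  if (object$kind != "multivariate")
    .stopf("predict is defined for the multivariate path")
  m <- object$model
  if (is.null(newdata)) {
    X <- as.matrix(object$analysis_table[object$secondaries])
  } else {
    X <- as.matrix(as.data.frame(newdata)[object$secondaries])
    ctr <- object$scaling$centers[object$secondaries]
    scl <- object$scaling$scales[object$secondaries]
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  eta <- drop(m$intercept + X %*% m$coefficients)
  if (m$model_kind == "logistic") stats::plogis(eta) else eta
}

#' Plot a disparity fit
#'
#' Multivariate fits draw the horizontal feature-importance bar chart
#' (percent contribution, most important at the top); univariate fits draw
#' the cleaned scatter with the least-squares line.
#'
#' @param x a `disparity_fit`.
#' @param ... passed to the underlying graphics call.
#' @export
plot.disparity_fit <- function(x, ...) {
  if (x$kind == "multivariate") {
    rk <- x$ranking
    op <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(op))
    graphics::barplot(rev(rk$contribution), names.arg = rev(rk$feature),
                      horiz = TRUE, las = 1, col = "#6A51A3",
                      xlab = "Percent contribution",
                      main = "Feature importance", ...)
  } else {
    tab <- x$analysis_table
    graphics::plot(tab[[x$secondaries]], tab[[x$primary]],
                   xlab = x$secondaries, ylab = x$primary,
                   pch = 19, col = "#6A51A3", ...)
    graphics::abline(stats::lm(tab[[x$primary]] ~ tab[[x$secondaries]]),
                     col = "#3F007D")
  }
  invisible(x)
}
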