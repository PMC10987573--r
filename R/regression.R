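#' Standardize variables of a community table
#'
#' Centers each named variable to mean 0 and scales to standard deviation 1
#' (over non-missing values). Standardization makes regression coefficients
#' unit-comparable, which is what the percent-contribution importance scores
#' assume.
#'
#' @param table a `community_table`.
#' @param variables numeric variable names to standardize.
#' @return the table with those columns replaced by z-scores; the centers and
#'   scales are attached as attributes `"centers"` and `"scales"`.
#' @export
standardize <- function(table, variables) {
  centers <- scales <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    x <- table[[v]]
    if (!is.numeric(x)) .stopf("variable '%s' is not numeric", v)
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) .stopf("variable '%s' has zero variance", v)
    table[[v]] <- (x - m) / s
    centers[v] <- m; scales[v] <- s
  }
  attr(table, "centers") <- centers
  attr(table, "scales") <- scales
  table
}

#' Percent-contribution feature importance
#'
#' The importance of feature k in a standardized model is its share of the
#' total absolute coefficient mass: `100 * |beta_k| / sum_j |beta_j|`, the
#' intercept excluded. Contributions sum to 100 whenever any coefficient is
#' nonzero.
#'
#' @param coefficients named numeric vector of non-intercept coefficients.
#' @return named percentages.
#' @examples
#' percent_contributions(c(a = 0.432, b = 0.398, c = -0.238))
#' @export
percent_contributions <- function(coefficients) {
  tot <- sum(abs(coefficients))
  if (tot == 0) .stopf("all coefficients are zero; contributions undefined")
  100 * abs(coefficients) / tot
}

.new_regression_result <- function(kind, coefficients, intercept, t_values,
                                   p_values, r2_adjusted, n, lambda = NULL,
                                   fitted = NULL, residuals = NULL) {
  pc <- if (sum(abs(coefficients)) > 0) percent_contributions(coefficients)
  else stats::setNames(rep(0, length(coefficients)), names(coefficients))
  structure(list(model_kind = kind, coefficients = coefficients,
                 intercept = intercept, percent_contribution = pc,
                 t_values = t_values, p_values = p_values,
                 r2_adjusted = r2_adjusted, n = n, lambda = lambda,
                 fitted = fitted, residuals = residuals),
            class = "regression_result")
}

#' Summarise a fitted multivariate model as a results table
#'
#' One row per feature in the layout used throughout the package's reports:
#' feature, Coefficients, Coeff (%) contribution, t.value, P.value,
#' R2 adjusted. Display rounding is one decimal for contributions,
#' round-half-away-from-zero.
#'
#' @param result a `regression_result`.
#' @return a data.frame.
#' @export
regression_table <- function(result) {
  stopifnot(inherits(result, "regression_result"))
  # round half away from zero, as in printed report tables
  rhafz <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
  df <- data.frame(
    feature = names(result$coefficients),
    Coefficients = rhafz(result$coefficients, 3),
    `Coeff (%) contribution` = rhafz(result$percent_contribution, 1),
    check.names = FALSE)
  if (!is.null(result$t_values)) {
    df$t.value <- rhafz(result$t_values, 3)
    df$P.value <- rhafz(result$p_values, 4)
  }
  if (!is.null(result$r2_adjusted))
    df$`R2 adjusted` <- rhafz(result$r2_adjusted, 3)
  rownames(df) <- NULL
  df
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s model, n = %d%s%s\n",
              switch(x$model_kind, ols = "Linear regression",
                     logistic = "Logistic regression", lasso = "Lasso regression"),
              x$n,
              if (!is.null(x$r2_adjusted))
                sprintf(", adjusted R^2 = %s", .fmt(x$r2_adjusted, 3)) else "",
              if (!is.null(x$lambda))
                sprintf(", lambda = %s", .fmt(x$lambda, 4)) else ""))
  print(regression_table(x), row.names = FALSE)
  invisible(x)
}

.as_feature_matrix <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Ordinary least squares with contribution scores
#'
#' Fits `y ~ X` by least squares, reporting per-feature coefficients, percent
#' contributions, t statistics and two-sided p values on `n - p - 1` degrees
#' of freedom, and the adjusted R-squared
#' `1 - (1 - R^2) * (n - 1) / (n - p - 1)`. Feed standardized inputs if the
#' contributions are to be comparable across features.
#'
#' @param y numeric response vector.
#' @param X numeric feature matrix or data.frame with named columns.
#' @return a `regression_result` with `model_kind = "ols"`.
#' @export
fit_ols <- function(y, X) {
  X <- .as_feature_matrix(X)
  if (nrow(X) != length(y)) .stopf("y and X must have the same number of rows")
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  p <- ncol(X)
  if (length(y) <= p + 1) .stopf("need n > p + 1 (n = %d, p = %d)", length(y), p)
  fit <- stats::lm(y ~ X)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    dropped <- sub("^X", "", names(beta)[is.na(beta)])
    .stopf("rank-deficient design; collinear columns: %s",
           paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  coefs <- stats::setNames(cf[-1, 1], colnames(X))
  .new_regression_result("ols", coefs, cf[1, 1],
                         t_values = stats::setNames(cf[-1, 3], colnames(X)),
                         p_values = stats::setNames(cf[-1, 4], colnames(X)),
                         r2_adjusted = sm$adj.r.squared, n = length(y),
                         fitted = unname(stats::fitted(fit)),
                         residuals = unname(stats::residuals(fit)))
}

#' Logistic regression with contribution scores
#'
#' Fits a binomial GLM by iteratively reweighted least squares and reports
#' Wald z statistics and p values in place of t. Perfect separation
#' (diverging coefficients) is an error; a penalized model is the remedy.
#'
#' @param y binary response (0/1), both classes present.
#' @param X numeric feature matrix or data.frame with named columns.
#' @return a `regression_result` with `model_kind = "logistic"`.
#' @export
fit_logistic <- function(y, X) {
  X <- .as_feature_matrix(X)
  if (nrow(X) != length(y)) .stopf("y and X must have the same number of rows")
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (!all(y %in% c(0, 1))) .stopf("y must be coded 0/1")
  if (length(unique(y)) < 2) .stopf("both classes must be present in y")
  fit <- withCallingHandlers(
    stats::glm(y ~ X, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    .stopf("rank-deficient design; collinear columns: %s",
           paste(sub("^X", "", names(beta)[is.na(beta)]), collapse = ", "))
  # separation: the IRLS iterates diverge, or the deviance collapses to zero
  # with every fitted probability pinned at 0/1
  mu <- stats::fitted(fit)
  if (!fit$converged || max(abs(beta)) > 15 ||
      (fit$deviance < 1e-6 && all(mu < 1e-4 | mu > 1 - 1e-4)))
    .stopf("perfect or quasi-perfect separation detected; use the lasso or drop features")
  cf <- summary(fit)$coefficients
  coefs <- stats::setNames(cf[-1, 1], colnames(X))
  .new_regression_result("logistic", coefs, cf[1, 1],
                         t_values = stats::setNames(cf[-1, 3], colnames(X)),
                         p_values = stats::setNames(cf[-1, 4], colnames(X)),
                         r2_adjusted = NULL, n = length(y),
                         fitted = unname(stats::fitted(fit)),
                         residuals = unname(stats::residuals(fit, type = "response")))
}

# lasso coordinate descent on standardized X, centered y:
# minimize (1/(2n)) ||y - b0 - X b||^2 + lambda * ||b||_1
.lasso_cd <- function(y, X, lambda, tol = 1e-7, maxit = 10000L) {
  n <- nrow(X); p <- ncol(X)
  b0 <- mean(y)
  r <- y - b0
  beta <- numeric(p)
  xss <- colSums(X^2) / n
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      zj <- sum(X[, j] * r) / n + xss[j] * bj_old
      bj <- soft(zj, lambda) / xss[j]
      if (bj != bj_old) {
        r <- r - X[, j] * (bj - bj_old)
        delta <- max(delta, abs(bj - bj_old))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
  }
  list(beta = stats::setNames(beta, colnames(X)), intercept = b0,
       residuals = r, iterations = it)
}

#' Lasso regression with contribution scores
#'
#' L1-penalized least squares, `(1/(2n)) * RSS + lambda * ||beta||_1`, solved
#' by cyclic coordinate descent to a coefficient-change tolerance of 1e-7.
#' If `lambda` is omitted it is chosen by 5-fold cross-validation over a
#' 50-point log grid from `lambda_max` (the smallest penalty that zeroes all
#' coefficients) down to `lambda_max / 1000`, with a seeded fold assignment.
#' No t or p values are reported: naive inference after L1 selection is not
#' valid.
#'
#' @param y numeric response (centered internally via the intercept).
#' @param X standardized feature matrix or data.frame with named columns.
#' @param lambda penalty (>= 0), or NULL to cross-validate.
#' @param seed seed for the cross-validation fold assignment.
#' @return a `regression_result` with `model_kind = "lasso"` and the `lambda`
#'   used; the CV curve (if run) is attached as attribute `"cv"`.
#' @export
fit_lasso <- function(y, X, lambda = NULL, seed = 1) {
  X <- .as_feature_matrix(X)
  if (nrow(X) != length(y)) .stopf("y and X must have the same number of rows")
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- nrow(X)
  cv <- NULL
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
    grid <- exp(seq(log(lambda_max), log(lambda_max / 1000), length.out = 50))
    folds <- .with_seed(seed, sample(rep_len(seq_len(5), n)))
    cv_err <- vapply(grid, function(l) {
      errs <- vapply(seq_len(5), function(f) {
        tr <- folds != f
        fit <- .lasso_cd(y[tr], X[tr, , drop = FALSE], l)
        pred <- fit$intercept + X[!tr, , drop = FALSE] %*% fit$beta
        mean((y[!tr] - pred)^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    lambda <- grid[which.min(cv_err)]
    cv <- data.frame(lambda = grid, mse = cv_err)
  }
  if (lambda < 0) .stopf("lambda must be non-negative")
  fit <- .lasso_cd(y, X, lambda)
  out <- .new_regression_result("lasso", fit$beta, fit$intercept,
                                t_values = NULL, p_values = NULL,
                                r2_adjusted = NULL, n = n, lambda = lambda,
                                fitted = unname(y - fit$residuals),
                                residuals = unname(fit$residuals))
  attr(out, "cv") <- cv
  out
}

#' Automatic model selection
#'
#' Chooses the multivariate model family from the data shape: a binary
#' outcome (at most two distinct values) gets logistic regression; a wide
#' problem (`p >= n/2`) or strongly collinear secondaries (any pairwise
#' `|r| > 0.9`) gets the lasso; otherwise ordinary least squares.
#'
#' @param table a `community_table`.
#' @param primary outcome variable name.
#' @param secondaries feature variable names.
#' @return `"ols"`, `"logistic"` or `"lasso"`, with the reason as attribute
#'   `"reason"`.
#' @export
auto_select_method <- function(table, primary, secondaries) {
  yv <- table[[primary]]
  if (length(unique(yv[!is.na(yv)])) <= 2)
    return(structure("logistic", reason = "binary outcome"))
  p <- length(secondaries); n <- sum(!is.na(yv))
  if (p >= n / 2)
    return(structure("lasso", reason = sprintf("wide problem (p = %d, n = %d)", p, n)))
  if (p >= 2) {
    cm <- stats::cor(as.matrix(table[secondaries]), use = "pairwise.complete.obs")
    mx <- max(abs(cm[upper.tri(cm)]))
    if (!is.na(mx) && mx > 0.9)
      return(structure("lasso",
                       reason = sprintf("collinear secondaries (max |r| = %.3f)", mx)))
  }
  structure("ols", reason = "continuous outcome, moderate dimension")
}

#' Rank features by percent contribution
#'
#' @param result a `regression_result`.
#' @return an `importance_ranking`: a data.frame of features and
#'   contributions in descending order; ties keep input order.
#' @export
rank_factors <- function(result) {
  stopifnot(inherits(result, "regression_result"))
  pc <- result$percent_contribution
  ord <- order(-pc)  # base order is stable: ties keep input order
  structure(data.frame(feature = names(pc)[ord],
                       contribution = unname(pc[ord]),
                       coefficient = unname(result$coefficients[ord])),
            class = c("importance_ranking", "data.frame"))
}

#' Fit a model by family name through the model registry
#'
#' The registry currently implements `ols`, `logistic` and `lasso`. Gradient
#' boosting (`gbm`) and neural networks (`nn`) are reserved extension points:
#' requesting them raises a clear not-implemented error.
#'
#' @param kind model family name.
#' @param y,X response and feature matrix, passed to the family's fit.
#' @param ... further arguments (for example `lambda` for the lasso).
#' @return a `regression_result`.
#' @export
fit_model <- function(kind, y, X, ...) {
  fitters <- list(ols = fit_ols, logistic = fit_logistic, lasso = fit_lasso)
  if (kind %in% c("gbm", "nn"))
    .stopf("model family '%s' is a reserved extension point and is not implemented", kind)
  f <- fitters[[kind]]
  if (is.null(f)) .stopf("unknown model family '%s'", kind)
  f(y, X, ...)
}
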