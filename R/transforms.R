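#' Pearson chi-square normality ratio
#'
#' Goodness-of-fit of a sample to the normal distribution with estimated mean
#' and standard deviation, using `k = ceiling(2 * n^0.4)` equal-probability
#' classes. The statistic is `P = sum((O_i - n/k)^2 / (n/k))` over the
#' observed class counts `O_i`, with `k - 3` degrees of freedom (two
#' estimated parameters plus one). The selection criterion used throughout
#' the package is the ratio `P / dof`: values near 1 indicate good fit.
#'
#' @param values numeric vector with at least 10 non-missing values.
#' @return list with `p_statistic`, `dof`, `ratio`.
#' @export
pearson_normality_ratio <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 10) .stopf("need at least 10 non-missing values, got %d", n)
  s <- stats::sd(x)
  if (s == 0) .stopf("degenerate variable (zero variance)")
  k <- ceiling(2 * n^0.4)
  breaks <- stats::qnorm(seq_len(k - 1) / k, mean = mean(x), sd = s)
  counts <- tabulate(findInterval(x, breaks) + 1L, nbins = k)
  expected <- n / k
  P <- sum((counts - expected)^2 / expected)
  dof <- k - 3L
  list(p_statistic = P, dof = dof, ratio = P / dof)
}

# -------- transform family -----------------------------------------------

.lambda_grid <- seq(-5, 5, by = 0.01)

# profile log-likelihood Box-Cox fit on the fixed lambda grid; x > 0.
# var((x^l - 1)/l) = var(x^l)/l^2, so the whole grid is one outer product.
.fit_box_cox <- function(x) {
  n <- length(x)
  lx <- log(x)
  slx <- sum(lx)
  g <- .lambda_grid
  M <- exp(outer(lx, g))
  cm <- colMeans(M)
  v <- colMeans(M * M) - cm^2
  ll <- -n / 2 * log(v / g^2) + (g - 1) * slx
  i0 <- which(abs(g) < 1e-12)
  if (length(i0)) {
    v0 <- sum((lx - mean(lx))^2) / n
    ll[i0] <- -n / 2 * log(v0) + (g[i0] - 1) * slx
  }
  l <- g[which.max(ll)]
  y <- if (abs(l) < 1e-12) lx else (x^l - 1) / l
  list(lambda = l, values = y)
}

.yj_transform <- function(x, l) {
  y <- numeric(length(x))
  pos <- x >= 0
  y[pos] <- if (abs(l) < 1e-12) log1p(x[pos]) else ((x[pos] + 1)^l - 1) / l
  y[!pos] <- if (abs(l - 2) < 1e-12) -log1p(-x[!pos])
  else -((1 - x[!pos])^(2 - l) - 1) / (2 - l)
  y
}

.fit_yeo_johnson <- function(x) {
  n <- length(x)
  g <- .lambda_grid
  # log-Jacobian term: (l - 1) * sum(sign(x) * log(|x| + 1))
  jc <- sum(sign(x) * log1p(abs(x)))
  pos <- x >= 0
  s1 <- s2 <- numeric(length(g))
  if (any(pos)) {
    Yp <- sweep(exp(outer(log1p(x[pos]), g)) - 1, 2, g, "/")
    i0 <- which(abs(g) < 1e-12)
    if (length(i0)) Yp[, i0] <- log1p(x[pos])
    s1 <- s1 + colSums(Yp); s2 <- s2 + colSums(Yp^2)
  }
  if (any(!pos)) {
    Yn <- -sweep(exp(outer(log1p(-x[!pos]), 2 - g)) - 1, 2, 2 - g, "/")
    i2 <- which(abs(g - 2) < 1e-12)
    if (length(i2)) Yn[, i2] <- -log1p(-x[!pos])
    s1 <- s1 + colSums(Yn); s2 <- s2 + colSums(Yn^2)
  }
  v <- s2 / n - (s1 / n)^2
  ll <- -n / 2 * log(v) + (g - 1) * jc
  l <- g[which.max(ll)]
  list(lambda = l, values = .yj_transform(x, l))
}

# normal scores: rank i of n (average ranks for ties) -> qnorm((i - 0.5)/n)
.fit_ordered_quantile <- function(x) {
  n <- length(x)
  list(values = stats::qnorm((rank(x, ties.method = "average") - 0.5) / n))
}

# candidate registry, in tie-break precedence order (prefer simpler).
# Each entry: applicable(x) and fit(x) -> list(values, parameters)
transform_registry <- list(
  identity = list(
    applicable = function(x) TRUE,
    fit = function(x) list(values = x, parameters = list())),
  log = list(
    applicable = function(x) all(x > 0),
    fit = function(x) list(values = log(x), parameters = list())),
  box_cox = list(
    applicable = function(x) all(x > 0),
    fit = function(x) {
      f <- .fit_box_cox(x)
      list(values = f$values, parameters = list(lambda = f$lambda))
    }),
  yeo_johnson = list(
    applicable = function(x) TRUE,
    fit = function(x) {
      f <- .fit_yeo_johnson(x)
      list(values = f$values, parameters = list(lambda = f$lambda))
    }),
  ordered_quantile = list(
    applicable = function(x) TRUE,
    fit = function(x) list(values = .fit_ordered_quantile(x)$values,
                           parameters = list()))
)

.new_transform_report <- function(name, parameters, values) {
  if (is.null(values)) {
    return(structure(list(transform_name = name, parameters = parameters,
                          p_statistic = Inf, dof = NA_integer_, ratio = Inf,
                          transformed_values = NULL),
                     class = "transform_report"))
  }
  pr <- pearson_normality_ratio(values)
  structure(list(transform_name = name, parameters = parameters,
                 p_statistic = pr$p_statistic, dof = pr$dof, ratio = pr$ratio,
                 transformed_values = values),
            class = "transform_report")
}

#' @export
print.transform_report <- function(x, ...) {
  par <- if (length(x$parameters))
    paste0(" (", paste(names(x$parameters), "=",
                       vapply(x$parameters, .fmt, character(1)),
                       collapse = ", "), ")") else ""
  cat(sprintf("Transform '%s'%s: Pearson P/dof = %s\n",
              x$transform_name, par, .fmt(x$ratio)))
  invisible(x)
}

#' Apply one candidate normality transform
#'
#' Fits and applies a single member of the candidate family. Power-transform
#' parameters (`lambda` for Box-Cox and Yeo-Johnson) are fitted by profile
#' maximum likelihood on the grid `lambda in [-5, 5]` with step 0.01. The
#' ordered-quantile transform maps rank i of n to the normal quantile at
#' `(i - 0.5) / n`, averaging ranks over ties. An inapplicable transform
#' (log or Box-Cox on data with non-positive values) returns a sentinel
#' report with `ratio = Inf` rather than raising an error, so that transform
#' selection can skip it.
#'
#' @param values numeric vector (missing values dropped; at least 10 required).
#' @param name one of `"identity"`, `"log"`, `"box_cox"`, `"yeo_johnson"`,
#'   `"ordered_quantile"`.
#' @return a `transform_report`: the transform name, fitted parameters, the
#'   Pearson `p_statistic`, `dof` and `ratio`, and the transformed values
#'   (aligned with the non-missing input).
#' @export
apply_transform <- function(values, name) {
  entry <- transform_registry[[name]]
  if (is.null(entry))
    .stopf("unknown transform '%s'; candidates: %s", name,
           paste(names(transform_registry), collapse = ", "))
  x <- values[!is.na(values)]
  if (length(x) < 10) .stopf("need at least 10 non-missing values, got %d", length(x))
  if (!entry$applicable(x))
    return(.new_transform_report(name, list(), NULL))
  f <- entry$fit(x)
  .new_transform_report(name, f$parameters, f$values)
}

#' Select the best-fit normality transform
#'
#' Evaluates every applicable candidate transform and returns the report with
#' the smallest Pearson P / dof ratio. Ties are broken by a fixed precedence
#' (identity, log, box_cox, yeo_johnson, ordered_quantile), preferring the
#' simpler transform.
#'
#' @param values numeric vector, at least 10 non-missing values.
#' @return the winning `transform_report`; all candidate ratios are attached
#'   as attribute `"candidate_ratios"`.
#' @export
select_transform <- function(values) {
  reports <- lapply(names(transform_registry), function(nm)
    apply_transform(values, nm))
  ratios <- vapply(reports, `[[`, numeric(1), "ratio")
  names(ratios) <- names(transform_registry)
  best <- reports[[which.min(ratios)]]  # which.min takes the first minimum
  attr(best, "candidate_ratios") <- ratios
  best
}
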