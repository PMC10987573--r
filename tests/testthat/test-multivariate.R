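test_that("standardization gives exact z-scores and is idempotent", {
  tab <- community_table(data.frame(region_id = c("A", "B", "C"),
                                    v = c(1, 2, 3), w = c(10, 0, 5)))
  s1 <- standardize(tab, c("v", "w"))
  expect_equal(mean(s1$v), 0)
  expect_equal(sd(s1$v), 1)
  expect_equal(s1$v, c(-1, 0, 1))
  s2 <- standardize(s1, c("v", "w"))
  expect_equal(s2$v, s1$v, tolerance = 1e-12)
  expect_equal(attr(s1, "centers")[["v"]], 2)
  expect_error(standardize(community_table(
    data.frame(region_id = c("A", "B"), v = c(1, 1))), "v"), "zero variance")
})

test_that("OLS equals the explicit normal-equations solution", {
  set.seed(50)
  X <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(0.5, -0.3, 0.2) + rnorm(50)
  fit <- fit_ols(y, X)
  Xd <- cbind(1, X)
  beta_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(unname(fit$intercept), beta_oracle[1], tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), unname(beta_oracle[-1]),
               tolerance = 1e-8)
  # adjusted R^2 by its definition
  res <- y - Xd %*% beta_oracle
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(fit$r2_adjusted, 1 - (1 - r2) * 49 / (50 - 3 - 1))
})

test_that("OLS handles exact fits and rejects collinear designs", {
  x <- rnorm(20)
  fit <- suppressWarnings(fit_ols(x, cbind(x = x)))  # exact fit
  expect_equal(unname(fit$coefficients), 1)
  expect_equal(fit$r2_adjusted, 1)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fit_ols(rnorm(20), X), "collinear.*b")
})

test_that("OLS recovers standardized coefficients within 3 standard errors", {
  set.seed(12)
  n <- 500
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(0.5, -0.3, 0.2)
  y <- X %*% beta + rnorm(n)
  fit <- fit_ols(y, X)
  se <- abs(fit$coefficients / fit$t_values)
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("OLS inference is permutation invariant and matches pearson r", {
  set.seed(77)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, 0.5, -1) + rnorm(40)
  f1 <- fit_ols(y, X)
  f2 <- fit_ols(y, X[, c("c", "a", "b")])
  for (v in c("a", "b", "c")) {
    expect_equal(f1$coefficients[[v]], f2$coefficients[[v]])
    expect_equal(f1$t_values[[v]], f2$t_values[[v]])
    expect_equal(f1$percent_contribution[[v]], f2$percent_contribution[[v]])
  }
  expect_equal(f1$r2_adjusted, f2$r2_adjusted)
  # single standardized feature: beta equals the correlation coefficient
  xs <- scale(rnorm(60))[, 1]; ys <- scale(xs * 0.6 + rnorm(60))[, 1]
  fit <- fit_ols(ys, cbind(x = xs))
  expect_equal(unname(fit$coefficients), cor(xs, ys), tolerance = 1e-12)
})

test_that("logistic regression recovers parameters and detects bad input", {
  set.seed(8)
  n <- 2000
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  eta <- X %*% c(1, -1)
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(y, X)
  se <- abs(fit$coefficients / fit$t_values)
  expect_true(all(abs(fit$coefficients - c(1, -1)) < 3 * se))
  expect_error(fit_logistic(rep(1, 50), matrix(rnorm(50), 50)), "both classes")
  # perfect separation
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  ys <- rep(0:1, each = 20)
  expect_error(fit_logistic(ys, cbind(x = xs)), "separation")
})

test_that("a null logistic feature keeps its nominal type-I error", {
  rejections <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 2000
    X <- cbind(real = rnorm(n), null = rnorm(n))
    y <- rbinom(n, 1, plogis(X[, 1]))
    fit_logistic(y, X)$p_values[["null"]] < 0.05
  }, logical(1))
  expect_lte(sum(rejections), 10)
})

test_that("lasso at lambda = 0 equals OLS and large lambda zeroes everything", {
  set.seed(44)
  n <- 80
  X <- scale(matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c"))))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  y <- drop(X %*% c(0.7, 0, -0.4)) + rnorm(n)
  f0 <- fit_lasso(y, X, lambda = 0)
  fo <- fit_ols(y, X)
  expect_equal(f0$coefficients, fo$coefficients, tolerance = 1e-6)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  fmax <- fit_lasso(y, X, lambda = lambda_max)
  expect_equal(unname(fmax$coefficients), c(0, 0, 0))
  expect_error(fit_lasso(y, X, lambda = -1), "non-negative")
})

test_that("lasso solutions satisfy the KKT subgradient conditions", {
  set.seed(13)
  n <- 40
  X <- scale(matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b"))))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  y <- drop(X %*% c(1, -0.5)) + rnorm(n)
  lambda <- 0.1
  fit <- fit_lasso(y, X, lambda = lambda)
  g <- drop(crossprod(X, y - fit$intercept - X %*% fit$coefficients)) / n
  for (j in seq_along(fit$coefficients)) {
    if (fit$coefficients[j] != 0)
      expect_equal(g[j], lambda * sign(fit$coefficients[j]), tolerance = 1e-5)
    else expect_lte(abs(g[j]), lambda + 1e-8)
  }
})

test_that("lasso agrees with glmnet and soft-thresholding on orthogonal designs", {
  set.seed(21)
  n <- 100
  X <- qr.Q(qr(matrix(rnorm(n * 4), n))) * sqrt(n)  # orthonormal columns * sqrt(n)
  colnames(X) <- paste0("x", 1:4)
  y <- drop(X %*% c(0.8, -0.4, 0.1, 0)) + rnorm(n)
  for (lambda in c(0.05, 0.2, 0.5)) {
    fit <- fit_lasso(y, X, lambda = lambda)
    z <- drop(crossprod(X, y - mean(y))) / n  # since X'X/n = I
    expect_equal(unname(fit$coefficients),
                 unname(sign(z) * pmax(abs(z) - lambda, 0)), tolerance = 1e-6)
  }
  gn <- glmnet::glmnet(X, y, lambda = 0.2, standardize = FALSE,
                       thresh = 1e-12)
  expect_equal(unname(fit_lasso(y, X, lambda = 0.2)$coefficients),
               unname(as.numeric(gn$beta)), tolerance = 2e-3)
})

test_that("cross-validated lambda is deterministic in the seed", {
  set.seed(62)
  n <- 60
  X <- scale(matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4))))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  y <- drop(X %*% c(0.6, -0.6, 0, 0)) + rnorm(n)
  f1 <- fit_lasso(y, X, seed = 5)
  f2 <- fit_lasso(y, X, seed = 5)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("percent contributions reproduce the published report arithmetic", {
  # cervical-cancer example: three standardized coefficients
  t3 <- c(Poverty_rate = 0.112, Neighborhood_safety_rate = -0.450,
          Demographics_Females = 0.257)
  pc3 <- percent_contributions(t3)
  expect_equal(round(pc3[["Demographics_Females"]], 1), 31.4)
  # overall-mortality example: seven coefficients
  t4 <- c(Poverty_rate = 0.432, Teen_birth_rate = 0.398,
          Uninsured_rate = -0.238, Demographics_Hispanic_or_Latino = -0.175,
          Routine_checkup_rate = -0.023, Single_parent_households = 0.031,
          Demographics_Males = -0.007)
  pc4 <- percent_contributions(t4)
  expect_equal(round(pc4[["Teen_birth_rate"]], 1), 30.5)
  expect_equal(round(pc4[["Poverty_rate"]], 1), 33.1)
  expect_equal(round(pc4[["Uninsured_rate"]], 1), 18.3)
  expect_equal(round(pc4[["Demographics_Hispanic_or_Latino"]], 1), 13.4)
  expect_equal(percent_contributions(c(only = -2.5))[["only"]], 100)
  expect_error(percent_contributions(c(a = 0, b = 0)), "all coefficients")
  # contributions always sum to 100
  set.seed(1)
  for (i in 1:10) {
    b <- rnorm(sample(2:8, 1))
    names(b) <- paste0("f", seq_along(b))
    expect_equal(sum(percent_contributions(b)), 100)
  }
})

test_that("factor ranking is descending with stable ties", {
  t4 <- c(Poverty_rate = 0.432, Teen_birth_rate = 0.398,
          Uninsured_rate = -0.238, Demographics_Hispanic_or_Latino = -0.175,
          Routine_checkup_rate = -0.023, Single_parent_households = 0.031,
          Demographics_Males = -0.007)
  fit <- list(model_kind = "ols", coefficients = t4,
              percent_contribution = percent_contributions(t4))
  class(fit) <- "regression_result"
  rk <- rank_factors(fit)
  expect_equal(rk$feature[1:3],
               c("Poverty_rate", "Teen_birth_rate", "Uninsured_rate"))
  expect_true(all(diff(rk$contribution) <= 0))
  # a single dominant coefficient ranks first at 100%
  one <- list(model_kind = "ols", coefficients = c(a = 0, b = 2, c = 0),
              percent_contribution = percent_contributions(c(a = 0, b = 2, c = 0)))
  class(one) <- "regression_result"
  expect_equal(rank_factors(one)$feature[1], "b")
  expect_equal(rank_factors(one)$contribution[1], 100)
  # exact tie keeps input order
  tie <- list(model_kind = "ols", coefficients = c(u = 0.5, v = -0.5),
              percent_contribution = percent_contributions(c(u = 0.5, v = -0.5)))
  class(tie) <- "regression_result"
  expect_equal(rank_factors(tie)$feature, c("u", "v"))
})

test_that("automatic method selection follows the shape rules", {
  n <- 77
  set.seed(2)
  tab <- community_table(data.frame(region_id = sprintf("R%03d", 1:n),
                                    y = rnorm(n), a = rnorm(n), b = rnorm(n),
                                    c = rnorm(n)))
  expect_equal(as.character(auto_select_method(tab, "y", c("a", "b", "c"))), "ols")
  tab$bin <- rbinom(n, 1, 0.5)
  expect_equal(as.character(auto_select_method(tab, "bin", c("a", "b"))), "logistic")
  # wide problem: p >= n/2
  wide <- as.data.frame(matrix(rnorm(40 * 30), 40))
  names(wide) <- paste0("s", 1:30)
  wide$region_id <- sprintf("R%03d", 1:40)
  wide$y <- rnorm(40)
  expect_equal(as.character(auto_select_method(community_table(wide), "y",
                                               paste0("s", 1:30))), "lasso")
  # collinear secondaries
  tab$a2 <- tab$a + rnorm(n, sd = 0.01)
  expect_equal(as.character(auto_select_method(tab, "y", c("a", "a2", "b"))),
               "lasso")
})

test_that("OLS confidence intervals achieve nominal coverage", {
  beta <- c(0.5, -0.3, 0.2)
  per_cov <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 100
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- X %*% beta + rnorm(n)
    fit <- fit_ols(y, X)
    se <- abs(fit$coefficients / fit$t_values)
    crit <- qt(0.975, n - 3 - 1)
    abs(fit$coefficients["a"] - beta[1]) <= crit * se["a"]
  }, logical(1))
  expect_gte(mean(per_cov), 0.90)
  expect_lte(mean(per_cov), 0.99)
})

test_that("the model registry reserves gbm and nn as unimplemented hooks", {
  expect_error(fit_model("gbm", rnorm(10), matrix(rnorm(10))), "not implemented")
  expect_error(fit_model("nn", rnorm(10), matrix(rnorm(10))), "not implemented")
  expect_error(fit_model("svm", rnorm(10), matrix(rnorm(10))), "unknown")
  set.seed(10)
  X <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("a", "b")))
  y <- drop(X %*% c(1, -1)) + rnorm(30)
  expect_s3_class(fit_model("ols", y, X), "regression_result")
})
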