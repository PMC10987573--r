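test_that("candidate screening requires correlation on both arms", {
  # a candidate unrelated to either variable passes the null screen rarely
  excluded <- vapply(1:100, function(s) {
    set.seed(s)
    tab <- community_table(data.frame(region_id = sprintf("R%03d", 1:500),
                                      p = rnorm(500), s = rnorm(500),
                                      c = rnorm(500)))
    length(screen_candidates(tab, "p", "s", "c")) == 0
  }, logical(1))
  expect_gte(sum(excluded), 95)

  set.seed(3)
  tab <- community_table(data.frame(region_id = sprintf("R%02d", 1:50),
                                    p = rnorm(50), s = rnorm(50)))
  tab$copy <- tab$p  # exact copy of the primary: |r| = 1 on one arm
  arm2 <- abs(cor(tab$copy, tab$s))
  got <- screen_candidates(tab, "p", "s", "copy")
  expect_equal(length(got) == 1, arm2 >= 0.3)
  # threshold 0 lets everything through
  expect_equal(as.character(screen_candidates(tab, "p", "s", "copy",
                                              threshold = 0)), "copy")
  # primary/secondary are never candidates
  expect_length(screen_candidates(tab, "p", "s", c("p", "s")), 0)
})

test_that("the 10% change-in-estimate rule is exact arithmetic", {
  expect_equal(coefficient_change(1.0, 0.8),
               list(percent_change = 20, flagged = TRUE))
  expect_equal(coefficient_change(1.0, 1.0),
               list(percent_change = 0, flagged = FALSE))
  expect_true(coefficient_change(0.5, 0.56)$flagged)    # 12%
  expect_false(coefficient_change(0.5, 0.54)$flagged)   # 8%
  expect_true(coefficient_change(0.5, -0.5)$flagged)    # sign flip: 200%
  expect_error(coefficient_change(0, 1), "crude effect is zero")
})

test_that("partial correlation with an empty set is correlation_test exactly", {
  d <- rbvn(40, 0.3, seed = 12)
  a <- correlation_test(d$x, d$y, label = "Confounding Removed")
  b <- partial_correlation(d$x, d$y, NULL)
  expect_identical(a, b)
  expect_identical(partial_correlation(d$x, d$y, data.frame()), a)
})

test_that("partial correlation equals the precision-matrix formula", {
  # exact identity on the sample: residual correlation = -Q12/sqrt(Q11 Q22)
  # with Q the inverse sample covariance of (x, y, z1..zk)
  for (draw in 1:50) {
    set.seed(draw)
    k <- sample(1:3, 1)
    p <- k + 2
    A <- matrix(rnorm(p * p), p)
    S <- crossprod(A) / p + diag(p) * 0.5
    n <- 40
    M <- matrix(rnorm(n * p), n) %*% chol(S)
    colnames(M) <- c("x", "y", paste0("z", seq_len(k)))
    got <- partial_correlation(M[, 1], M[, 2], M[, -(1:2), drop = FALSE])
    Q <- solve(cov(M))
    expect_equal(got$r, -Q[1, 2] / sqrt(Q[1, 1] * Q[2, 2]), tolerance = 1e-10)
  }
})

test_that("sample partial correlation approaches the population value", {
  # trivariate normal with known correlation matrix
  R <- matrix(c(1, 0.5, 0.6,
                0.5, 1, 0.7,
                0.6, 0.7, 1), 3, byrow = TRUE)
  set.seed(99)
  M <- matrix(rnorm(2000 * 3), 2000) %*% chol(R)
  P <- solve(R)
  pop <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  got <- partial_correlation(M[, 1], M[, 2], M[, 3, drop = FALSE])
  expect_lt(abs(got$r - pop), 3 / sqrt(2000))
  expect_equal(got$k_adjusted, 1)
  expect_equal(got$df, 2000 - 3)
})

test_that("partial r is invariant to affine maps of the adjustment set", {
  set.seed(8)
  n <- 60
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- z1 + rnorm(n); y <- z1 - z2 + rnorm(n)
  a <- partial_correlation(x, y, cbind(z1 = z1, z2 = z2))
  b <- partial_correlation(x, y, cbind(z1 = 5 - 2 * z1, z2 = 100 * z2 + 3))
  expect_equal(a$r, b$r, tolerance = 1e-12)
  # collinear adjustment set is detected and named
  expect_error(partial_correlation(x, y, cbind(z1 = z1, z1b = 2 * z1)),
               "collinear")
})

test_that("pure confounding reverses significance after adjustment", {
  hits <- vapply(1:100, function(s) {
    tab <- generate_confounded_table(confounding_scenario(n = 200, seed = s))
    crude <- correlation_test(tab$secondary, tab$primary)
    adj <- partial_correlation(tab$secondary, tab$primary,
                               tab["confounder"])
    abs(adj$r) < abs(crude$r) && adj$p_value > 0.05 && crude$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("assess_confounding recovers a planted confounder", {
  hits <- vapply(1:100, function(s) {
    tab <- generate_confounded_table(confounding_scenario(n = 200, seed = 400 + s))
    rep <- assess_confounding(tab, "primary", "secondary", "confounder")
    rep$flagged && identical(rep$confounder_set, "confounder") &&
      abs(rep$adjusted_result$r) < 0.2
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("assess_confounding stays quiet when there is no confounding path", {
  quiet <- vapply(1:100, function(s) {
    tab <- generate_confounded_table(
      confounding_scenario(n = 200, beta_xc = 0, beta_xy_direct = 0.7,
                           seed = 800 + s))
    rep <- assess_confounding(tab, "primary", "secondary", "confounder")
    !rep$flagged
  }, logical(1))
  expect_gte(sum(quiet), 90)
})

test_that("empty metadata yields the crude correlation as the adjusted result", {
  tab <- generate_confounded_table(confounding_scenario(n = 100, seed = 6))
  rep <- assess_confounding(tab, "primary", "secondary", character(0))
  expect_false(rep$flagged)
  expect_length(rep$confounder_set, 0)
  crude <- correlation_test(tab$primary, tab$secondary,
                            label = "Confounding Removed")
  expect_equal(rep$adjusted_result$r, crude$r)
  # correlation matrix invariants
  cm <- rep$correlation_matrix
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
})
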