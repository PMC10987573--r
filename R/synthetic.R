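#' Specify a synthetic community table
#'
#' The generator emulates the shape of real catchment-area data: a modest
#' number of regions, correlated social-determinant covariates, skewed
#' marginals and occasional gross outliers. Variables are drawn jointly from
#' a latent multivariate normal with the requested correlation matrix, then
#' each marginal is passed through a monotone distortion (a Gaussian copula
#' construction), then a fraction of cells is displaced by a multiple of the
#' column IQR.
#'
#' @param n_regions number of regions (rows).
#' @param latent_correlation symmetric positive semi-definite correlation
#'   matrix with unit diagonal; dimnames give the variable names.
#' @param marginal_map named character vector mapping variables to one of
#'   `"identity"`, `"exponential"` (exp of the latent normal, i.e. log-normal
#'   marginal) or `"logistic"` (logistic squash to (0, 1)). Variables not
#'   named default to identity.
#' @param outlier_rate fraction of cells (0 to 0.2) displaced as outliers.
#' @param outlier_magnitude displacement size as a multiple of the column IQR.
#' @param seed integer seed; the table is fully reproducible from the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions, latent_correlation,
                           marginal_map = character(),
                           outlier_rate = 0, outlier_magnitude = 5, seed = 1) {
  stopifnot(n_regions >= 1)
  R <- as.matrix(latent_correlation)
  if (is.null(rownames(R))) {
    nm <- paste0("v", seq_len(ncol(R)))
    dimnames(R) <- list(nm, nm)
  }
  if (anyDuplicated(rownames(R))) .stopf("variable names must be unique")
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)))
    .stopf("latent_correlation must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-10))
    .stopf("latent_correlation must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    .stopf("latent_correlation is not positive semi-definite (smallest eigenvalue %.3g)",
           min(ev))
  if (outlier_rate < 0 || outlier_rate > 0.2)
    .stopf("outlier_rate must be in [0, 0.2]")
  mm <- as.character(marginal_map)
  names(mm) <- names(marginal_map)
  bad <- setdiff(mm, c("identity", "exponential", "logistic"))
  if (length(bad)) .stopf("unknown marginal map: %s", paste(bad, collapse = ", "))
  structure(list(n_regions = as.integer(n_regions), latent_correlation = R,
                 marginal_map = mm, outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.region_ids <- function(n) {
  sprintf(paste0("R%0", max(3L, nchar(as.character(n))), "d"), seq_len(n))
}

#' Generate a synthetic community table
#'
#' @param spec a [synthetic_spec()].
#' @return a [community_table()] with `spec$n_regions` rows; the realized
#'   pre-distortion latent matrix is attached as attribute `"latent"` and the
#'   injected outlier cells as attribute `"outlier_cells"`.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- spec$latent_correlation
  p <- ncol(R)
  n <- spec$n_regions
  .with_seed(spec$seed, {
    e <- eigen(R, symmetric = TRUE)
    rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
    Z <- matrix(stats::rnorm(n * p), n, p) %*% rt
    colnames(Z) <- colnames(R)
    X <- Z
    for (v in colnames(X)) {
      map <- if (v %in% names(spec$marginal_map)) spec$marginal_map[[v]] else "identity"
      X[, v] <- switch(map,
                       identity = X[, v],
                       exponential = exp(X[, v]),
                       logistic = stats::plogis(X[, v]))
    }
    cells <- NULL
    if (spec$outlier_rate > 0) {
      n_out <- floor(spec$outlier_rate * n * p)
      if (n_out > 0) {
        idx <- sample.int(n * p, n_out)
        sgn <- sample(c(-1, 1), n_out, replace = TRUE)
        col <- (idx - 1L) %/% n + 1L
        iqr <- apply(X, 2, stats::IQR, type = 7)
        X[idx] <- X[idx] + sgn * spec$outlier_magnitude * iqr[col]
        cells <- data.frame(row = (idx - 1L) %% n + 1L, col = col)
      }
    }
    tab <- community_table(data.frame(region_id = .region_ids(n), X,
                                      check.names = FALSE))
    attr(tab, "latent") <- Z
    attr(tab, "outlier_cells") <- cells
    tab
  })
}

#' Specify a confounding scenario
#'
#' A three-variable generating model with a known confounding structure:
#' a confounder `C ~ N(0, 1)`, an exposure (secondary variable)
#' `X = beta_xc * C + e1`, and an outcome (primary variable)
#' `Y = beta_yc * C + beta_xy_direct * X + e2`, with independent
#' `N(0, noise_sd^2)` noise. With `beta_xy_direct = 0` the crude X–Y
#' correlation is entirely spurious (driven by C) and the partial correlation
#' given C is zero in the population.
#'
#' @param n number of regions (at least 10).
#' @param beta_xc,beta_yc confounder effect sizes on exposure and outcome.
#' @param beta_xy_direct direct exposure effect (0 for pure confounding).
#' @param noise_sd residual standard deviation (> 0).
#' @param n_nuisance number of additional independent N(0,1) nuisance columns.
#' @param seed integer seed.
#' @return object of class `confounding_scenario`.
#' @export
confounding_scenario <- function(n = 200, beta_xc = 1, beta_yc = 1,
                                 beta_xy_direct = 0, noise_sd = 1,
                                 n_nuisance = 0, seed = 1) {
  if (n < 10) .stopf("n must be at least 10")
  if (noise_sd <= 0) .stopf("noise_sd must be positive")
  structure(list(n = as.integer(n), beta_xc = beta_xc, beta_yc = beta_yc,
                 beta_xy_direct = beta_xy_direct, noise_sd = noise_sd,
                 n_nuisance = as.integer(n_nuisance), seed = as.integer(seed)),
            class = "confounding_scenario")
}

#' Generate data from a confounding scenario
#'
#' @param scenario a [confounding_scenario()].
#' @return a [community_table()] with columns `primary`, `secondary`,
#'   `confounder` (plus `nuisance1..k`); the generating parameters and the
#'   implied population correlations are attached as attribute `"truth"`.
#' @export
generate_confounded_table <- function(scenario) {
  stopifnot(inherits(scenario, "confounding_scenario"))
  s <- scenario
  .with_seed(s$seed, {
    C <- stats::rnorm(s$n)
    X <- s$beta_xc * C + stats::rnorm(s$n, sd = s$noise_sd)
    Y <- s$beta_yc * C + s$beta_xy_direct * X + stats::rnorm(s$n, sd = s$noise_sd)
    df <- data.frame(region_id = .region_ids(s$n), primary = Y, secondary = X,
                     confounder = C)
    if (s$n_nuisance > 0)
      for (k in seq_len(s$n_nuisance))
        df[[paste0("nuisance", k)]] <- stats::rnorm(s$n)
    tab <- community_table(df)
    # population moments of the generating model
    var_x <- s$beta_xc^2 + s$noise_sd^2
    cov_xy <- s$beta_xc * s$beta_yc + s$beta_xy_direct * var_x
    var_y <- s$beta_yc^2 + s$beta_xy_direct^2 * var_x +
      2 * s$beta_xy_direct * s$beta_xc * s$beta_yc + s$noise_sd^2
    attr(tab, "truth") <- list(
      params = unclass(s),
      cor_xy = cov_xy / sqrt(var_x * var_y),
      cor_xc = s$beta_xc / sqrt(var_x),
      cor_yc = (s$beta_yc + s$beta_xy_direct * s$beta_xc) / sqrt(var_y),
      partial_cor_xy_given_c = s$beta_xy_direct * s$noise_sd /
        sqrt(s$noise_sd^2 * (1 + s$beta_xy_direct^2)))
    tab
  })
}

#' Generate toy grid boundaries
#'
#' Lays the first `n` cells of a ceiling(sqrt(n)) x ceiling(sqrt(n)) grid of
#' unit squares, with region ids matching [generate_table()].
#'
#' @param n number of regions.
#' @return a `boundary_set` of `n` unit squares.
#' @export
generate_boundaries <- function(n) {
  stopifnot(n >= 1)
  side <- ceiling(sqrt(n))
  geoms <- list()
  ids <- .region_ids(n)
  for (i in seq_len(n)) {
    row <- (i - 1L) %/% side
    col <- (i - 1L) %% side
    ring <- rbind(c(col, row), c(col + 1, row), c(col + 1, row + 1),
                  c(col, row + 1), c(col, row))
    geoms[[ids[i]]] <- list(list(ring))
  }
  .new_boundary_set(geoms)
}
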