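#' Run a full disparity analysis from a configuration
#'
#' Drives the whole pipeline from file inputs to written artifacts, as the
#' command-line interface does. The configuration can be a list or a path to
#' a JSON file with the same fields.
#'
#' Fields: `table` (CSV path), `id_column` (default `"region_id"`),
#' `boundaries` (optional GeoJSON path), `id_property` (default
#' `"region_id"`), `primary`, `secondary` (one or more names), `method`
#' (default `"auto"`), `metadata` (optional candidate confounders), `outdir`,
#' `seed` (default 1), `map_variable` (defaults to the primary).
#'
#' Artifacts written to `outdir`: `results.json`, `summary.txt` (the report
#' tables), `map.svg` (when boundaries are supplied), and `config.json` (the
#' resolved configuration, for provenance). On error the partial artifacts
#' of this run are removed.
#'
#' @param config list or JSON path.
#' @return invisibly, a list with the `disparity_fit` and the artifact paths.
#' @export
run_analysis <- function(config) {
  cfg <- .resolve_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- file.path(cfg$outdir,
                         c("results.json", "summary.txt", "map.svg", "config.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(artifacts))

  tab <- read_community_csv(cfg$table, cfg$id_column)
  boundaries <- NULL
  if (!is.null(cfg$boundaries))
    boundaries <- read_boundaries(cfg$boundaries, cfg$id_property)

  fml <- stats::reformulate(cfg$secondary, response = cfg$primary)
  fit <- disparity_fit(fml, tab, method = cfg$method,
                       metadata = cfg$metadata, seed = cfg$seed)

  jsonlite::write_json(.fit_to_json(fit), artifacts[1], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  txt <- utils::capture.output(print(summary(fit)))
  writeLines(txt, artifacts[2])
  map_path <- NULL
  if (!is.null(boundaries)) {
    joined <- join_table_boundaries(tab, boundaries)
    mv <- if (is.null(cfg$map_variable)) cfg$primary else cfg$map_variable
    spec <- choropleth_spec(mv, scale = if (is.numeric(tab[[mv]]))
      "gradient" else "categorical")
    render_choropleth(joined, spec, artifacts[3])
    map_path <- artifacts[3]
  }
  jsonlite::write_json(cfg, artifacts[4], auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  ok <- TRUE
  invisible(list(fit = fit,
                 artifacts = c(results = artifacts[1], summary = artifacts[2],
                               map = if (!is.null(map_path)) map_path,
                               config = artifacts[4])))
}

.resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  defaults <- list(id_column = "region_id", id_property = "region_id",
                   method = "auto", metadata = NULL, seed = 1L,
                   boundaries = NULL, map_variable = NULL)
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, logical(1))])
  for (f in c("table", "primary", "secondary", "outdir"))
    if (is.null(cfg[[f]])) .stopf("config field '%s' is required", f)
  if (cfg$primary %in% cfg$secondary)
    .stopf("primary must not appear among the secondaries")
  if (!file.exists(cfg$table)) .stopf("table file not found: %s", cfg$table)
  if (!is.null(cfg$boundaries) && !file.exists(cfg$boundaries))
    .stopf("boundaries file not found: %s", cfg$boundaries)
  cfg
}

.fit_to_json <- function(fit) {
  if (fit$kind == "univariate") {
    res <- list(
      kind = "univariate",
      raw = .corr_to_list(fit$correlation$raw),
      intelligent = .corr_to_list(fit$correlation$intelligent),
      transforms = lapply(fit$transforms, function(t)
        list(name = t$transform_name, parameters = t$parameters,
             ratio = t$ratio)),
      removed_ids = fit$cleaning$removed_ids)
    if (!is.null(fit$confounding)) {
      cf <- fit$confounding
      res$confounding <- list(
        beta_crude = cf$beta_crude, beta_adjusted = cf$beta_adjusted,
        percent_change = cf$percent_change, flagged = cf$flagged,
        confounder_set = as.character(cf$confounder_set),
        adjusted = .corr_to_list(cf$adjusted_result))
    }
    res
  } else {
    m <- fit$model
    list(kind = "multivariate", model_kind = m$model_kind,
         coefficients = as.list(m$coefficients),
         percent_contribution = as.list(m$percent_contribution),
         t_values = if (!is.null(m$t_values)) as.list(m$t_values),
         p_values = if (!is.null(m$p_values)) as.list(m$p_values),
         r2_adjusted = m$r2_adjusted, n = m$n, lambda = m$lambda,
         ranking = fit$ranking$feature)
  }
}

.corr_to_list <- function(x) {
  list(method = x$method, label = x$label, r = x$r, n = x$n_effective,
       t = x$t_statistic, p = x$p_value, ci95 = x$ci95)
}

#' Generate and write synthetic fixtures
#'
#' Writes the CSV table, grid GeoJSON boundaries and a ground-truth JSON for
#' a synthetic specification, so the analysis pipeline can be exercised
#' end-to-end without external data. The spec can be a [synthetic_spec()], a
#' [confounding_scenario()], or a path to a JSON file with a `type` field
#' (`"table"` or `"confounding"`) plus that constructor's arguments
#' (`latent_correlation` as a matrix of rows, names in `variables`).
#'
#' @param spec specification object or JSON path.
#' @param outdir output directory.
#' @return invisibly, the paths of `table.csv`, `boundaries.geojson`,
#'   `truth.json`.
#' @export
run_simulate <- function(spec, outdir) {
  if (is.character(spec) && length(spec) == 1) {
    if (!file.exists(spec)) .stopf("spec file not found: %s", spec)
    js <- jsonlite::fromJSON(spec, simplifyVector = TRUE)
    if (is.null(js$type)) .stopf("spec JSON needs a 'type' field (table|confounding)")
    spec <- if (js$type == "confounding") {
      do.call(confounding_scenario, js[setdiff(names(js), "type")])
    } else if (js$type == "table") {
      R <- as.matrix(js$latent_correlation)
      if (!is.null(js$variables)) dimnames(R) <- list(js$variables, js$variables)
      args <- js[setdiff(names(js), c("type", "latent_correlation", "variables"))]
      args$latent_correlation <- R
      do.call(synthetic_spec, args)
    } else .stopf("unknown spec type '%s'", js$type)
  }
  tab <- if (inherits(spec, "confounding_scenario")) generate_confounded_table(spec)
  else if (inherits(spec, "synthetic_spec")) generate_table(spec)
  else .stopf("spec must be a synthetic_spec, confounding_scenario, or JSON path")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("table.csv", "boundaries.geojson", "truth.json"))
  write_community_csv(tab, paths[1])
  write_boundaries(generate_boundaries(nrow(tab)), paths[2])
  truth <- attr(tab, "truth")
  if (is.null(truth)) truth <- list(spec = unclass(spec))
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(stats::setNames(paths, c("table", "boundaries", "truth")))
}
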