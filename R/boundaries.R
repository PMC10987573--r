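#' Region boundary sets
#'
#' A boundary set holds one polygon or multipolygon per region id, in WGS84
#' longitude/latitude, as read from a GeoJSON FeatureCollection. Internally
#' each geometry is a list of polygons; each polygon is a list of rings; each
#' ring is a closed two-column (lon, lat) matrix.
#'
#' @name boundary_set
NULL

.as_ring <- function(coords, where) {
  m <- do.call(rbind, lapply(coords, function(p) {
    if (length(p) < 2) .stopf("bad coordinate pair in %s", where)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))
  }))
  if (nrow(m) < 4 || any(m[1, ] != m[nrow(m), ]))
    .stopf("ring not closed in %s", where)
  m
}

.new_boundary_set <- function(geoms) {
  structure(geoms, class = "boundary_set")
}

#' Read region boundaries from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon or MultiPolygon features,
#' each carrying the region id in `properties[[id_property]]`. Coordinates
#' are taken as WGS84 lon/lat.
#'
#' @param path path to a GeoJSON file.
#' @param id_property name of the feature property holding the region id.
#' @return a `boundary_set`: a named list (one element per region id) of
#'   geometries, each a list of polygons (lists of closed ring matrices).
#' @export
read_boundaries <- function(path, id_property = "region_id") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    .stopf("not a GeoJSON FeatureCollection: %s", path)
  feats <- gj$features
  geoms <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_property]]
    if (is.null(id) || !nzchar(trimws(as.character(id))))
      .stopf("feature %d missing id property '%s'", i, id_property)
    id <- trimws(as.character(id))
    g <- f$geometry
    if (is.null(g) || is.null(g$type))
      .stopf("feature %d ('%s') has null geometry", i, id)
    where <- sprintf("feature %d ('%s')", i, id)
    polys <- switch(g$type,
      Polygon = list(lapply(g$coordinates, .as_ring, where = where)),
      MultiPolygon = lapply(g$coordinates, function(poly)
        lapply(poly, .as_ring, where = where)),
      .stopf("feature %d ('%s') has non-polygonal geometry '%s'", i, id, g$type))
    if (!length(polys) || !length(polys[[1]]))
      .stopf("feature %d ('%s') has empty geometry", i, id)
    if (id %in% names(geoms)) .stopf("duplicate region id in boundaries: %s", id)
    geoms[[id]] <- polys
  }
  .new_boundary_set(geoms)
}

#' Write a boundary set to GeoJSON
#' @param boundaries a `boundary_set`.
#' @param path output path.
#' @param id_property property name to store the region id under.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path, id_property = "region_id") {
  feats <- lapply(names(boundaries), function(id) {
    polys <- lapply(boundaries[[id]], function(poly)
      lapply(poly, function(ring)
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))))
    geom <- if (length(polys) == 1L)
      list(type = "Polygon", coordinates = polys[[1]])
    else list(type = "MultiPolygon", coordinates = polys)
    props <- list(); props[[id_property]] <- id
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("Boundary set: %d regions (%s%s)\n", length(x),
              paste(utils::head(names(x), 5), collapse = ", "),
              if (length(x) > 5) ", ..." else ""))
  invisible(x)
}

#' Join a community table with a boundary set by region id
#'
#' Inner join on region id. Ids present on only one side are reported, not an
#' error, unless the intersection is empty.
#'
#' @param table a `community_table`.
#' @param boundaries a `boundary_set`.
#' @return a list of class `joined_communities` with elements `table` (rows in
#'   table order, restricted to shared ids), `boundaries` (same ids, table
#'   order) and `mismatch` (list with `table_only`, `boundary_only`).
#' @export
join_table_boundaries <- function(table, boundaries) {
  tids <- table$region_id
  bids <- names(boundaries)
  shared <- intersect(tids, bids)
  if (!length(shared))
    .stopf("no shared region ids between table and boundaries")
  keep <- tids[tids %in% shared]
  out <- list(
    table = table[match(keep, tids), , drop = FALSE],
    boundaries = .new_boundary_set(unclass(boundaries)[keep]),
    mismatch = list(table_only = setdiff(tids, bids),
                    boundary_only = setdiff(bids, tids)))
  rownames(out$table) <- NULL
  class(out$table) <- c("community_table", "data.frame")
  class(out) <- "joined_communities"
  out
}

#' @export
print.joined_communities <- function(x, ...) {
  cat(sprintf("Joined dataset: %d regions", nrow(x$table)))
  m <- x$mismatch
  if (length(m$table_only))
    cat(sprintf("; table-only ids: %s", paste(m$table_only, collapse = ", ")))
  if (length(m$boundary_only))
    cat(sprintf("; boundary-only ids: %s", paste(m$boundary_only, collapse = ", ")))
  cat("\n")
  invisible(x)
}
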