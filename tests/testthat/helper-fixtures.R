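# fixtures built in code, shared across test files

# small community table with a missing cell and a categorical column
make_small_table <- function() {
  community_table(data.frame(
    region_id = c("R001", "R002", "R003", "R004", "R005"),
    poverty = c(10, 20, 15, NA, 30),
    mortality = c(5, 8, 6, 7, 12),
    side = c("north", "south", "north", "west", "south"),
    stringsAsFactors = FALSE))
}

# bivariate normal pairs with a given correlation
rbvn <- function(n, rho, seed) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  list(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
}

# write a minimal GeoJSON FeatureCollection of unit squares, return path
write_square_geojson <- function(ids, path = tempfile(fileext = ".geojson")) {
  feats <- lapply(seq_along(ids), function(i) {
    x0 <- i - 1
    ring <- list(c(x0, 0), c(x0 + 1, 0), c(x0 + 1, 1), c(x0, 1), c(x0, 0))
    list(type = "Feature",
         properties = list(region_id = ids[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# shoelace area of a closed ring matrix
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# relative luminance of a hex color
luminance <- function(hex) {
  v <- grDevices::col2rgb(hex)[, 1] / 255
  sum(c(0.2126, 0.7152, 0.0722) * v)
}
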