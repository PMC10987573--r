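test_that("CSV reading parses numbers, honours missing markers, validates ids", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("region,poverty,mortality",
               "A ,10.5,2",
               "B,NA,3",
               "C,nan,"), path)
  tab <- read_community_csv(path, id_column = "region")
  expect_s3_class(tab, "community_table")
  expect_equal(nrow(tab), 3)
  expect_equal(sort(numeric_vars(tab)), c("mortality", "poverty"))
  expect_equal(tab$region_id, c("A", "B", "C"))  # whitespace stripped
  expect_equal(tab$poverty, c(10.5, NA, NA))     # NA and nan markers
  expect_equal(tab$mortality, c(2, 3, NA))       # empty cell

  writeLines(c("region,v", "A,1", "A,2"), path)
  expect_error(read_community_csv(path, "region"), "duplicate.*A")
  writeLines(c("region,v", "A,1"), path)
  expect_error(read_community_csv(path, "nope"), "id column")
  expect_error(read_community_csv(tempfile(), "region"), "not found")
})

test_that("columns with unparseable non-missing cells stay categorical", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("region_id,grade,rate", "A,high,1", "B,low,2"), path)
  tab <- read_community_csv(path)
  expect_equal(categorical_vars(tab), "grade")
  expect_equal(tab$rate, c(1, 2))
})

test_that("community table CSV round-trip is exact, including missing cells", {
  set.seed(42)
  tab <- community_table(data.frame(
    region_id = sprintf("R%02d", 1:20),
    a = replace(rnorm(20), c(3, 7), NA),
    b = rexp(20) * 1e-6,
    c = round(runif(20) * 1e6, 3),
    label = replace(sample(c("x", "y"), 20, TRUE), 5, NA),
    stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".csv")
  write_community_csv(tab, path)
  back <- read_community_csv(path)
  expect_identical(back$a, tab$a)
  expect_identical(back$b, tab$b)
  expect_identical(back$c, tab$c)
  expect_identical(back$label, tab$label)
})

test_that("community_table enforces its invariants", {
  expect_error(community_table(data.frame(region_id = c("A", ""), v = 1:2)),
               "non-empty")
  expect_error(community_table(data.frame(region_id = c("A", "A"), v = 1:2)),
               "duplicate")
  expect_error(community_table(data.frame(region_id = "A", v = Inf)),
               "non-finite")
})

test_that("GeoJSON boundaries read, validate and round-trip", {
  path <- write_square_geojson(c("A", "B"))
  bs <- read_boundaries(path)
  expect_s3_class(bs, "boundary_set")
  expect_equal(names(bs), c("A", "B"))
  expect_equal(nrow(bs$A[[1]][[1]]), 5)  # closed ring

  # MultiPolygon accepted as one region
  mp <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(region_id = "M"),
    geometry = list(type = "MultiPolygon", coordinates = list(
      list(list(c(0, 0), c(1, 0), c(1, 1), c(0, 0))),
      list(list(c(2, 2), c(3, 2), c(3, 3), c(2, 2))))))))
  p2 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(mp, p2, auto_unbox = TRUE, digits = NA)
  bs2 <- read_boundaries(p2)
  expect_length(bs2$M, 2)

  # round-trip through the writer
  p3 <- tempfile(fileext = ".geojson")
  write_boundaries(bs, p3)
  expect_equal(read_boundaries(p3), bs)

  # error cases: null geometry, missing id, point geometry
  bad <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(region_id = "X"), geometry = NULL)))
  jsonlite::write_json(bad, p2, auto_unbox = TRUE, null = "null")
  expect_error(read_boundaries(p2), "null geometry")
  bad$features[[1]]$geometry <- list(type = "Point", coordinates = c(0, 0))
  bad$features[[1]]$properties <- list(other = "X")
  jsonlite::write_json(bad, p2, auto_unbox = TRUE)
  expect_error(read_boundaries(p2), "feature 1 missing id")
})

test_that("table-boundary join intersects ids and reports mismatches", {
  tab <- community_table(data.frame(region_id = c("A", "B", "C"), v = 1:3))
  bs <- read_boundaries(write_square_geojson(c("B", "C", "D")))
  j <- join_table_boundaries(tab, bs)
  expect_equal(j$table$region_id, c("B", "C"))
  expect_equal(names(j$boundaries), c("B", "C"))
  expect_equal(j$mismatch$table_only, "A")
  expect_equal(j$mismatch$boundary_only, "D")

  # identical id sets: empty mismatch report
  bs2 <- read_boundaries(write_square_geojson(c("A", "B", "C")))
  j2 <- join_table_boundaries(tab, bs2)
  expect_length(j2$mismatch$table_only, 0)
  expect_length(j2$mismatch$boundary_only, 0)

  # disjoint: error
  bs3 <- read_boundaries(write_square_geojson(c("X", "Y")))
  expect_error(join_table_boundaries(tab, bs3), "no shared")

  # permuting input rows only permutes output rows
  perm <- tab[c(3, 1, 2), ]
  class(perm) <- c("community_table", "data.frame")
  jp <- join_table_boundaries(perm, bs)
  expect_setequal(jp$table$region_id, j$table$region_id)
  expect_equal(jp$table$region_id, c("C", "B"))
})
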