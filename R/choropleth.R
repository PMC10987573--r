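#' Choropleth specification
#'
#' @param variable name of the table variable to map.
#' @param scale `"gradient"` for numeric variables (continuous light-to-dark
#'   interpolation) or `"categorical"` (distinct colors per level).
#' @param low,high gradient endpoint colors (hex); defaults are a light
#'   lavender to dark purple ramp so that darker means higher.
#' @param missing_color fill for regions with no value.
#' @param title map title (defaults to the variable name).
#' @return object of class `choropleth_spec`.
#' @export
choropleth_spec <- function(variable, scale = c("gradient", "categorical"),
                            low = "#EFEDF5", high = "#3F007D",
                            missing_color = "#BDBDBD", title = variable) {
  scale <- match.arg(scale)
  if (toupper(low) == toupper(high)) .stopf("gradient endpoints must be distinct")
  structure(list(variable = variable, scale = scale, low = low, high = high,
                 missing_color = missing_color, title = title),
            class = "choropleth_spec")
}

# fixed qualitative palette for categorical scales (cycled)
.categorical_palette <- c("#1B9E77", "#D95F02", "#7570B3", "#E7298A",
                          "#66A61E", "#E6AB02", "#A6761D", "#666666",
                          "#1F78B4", "#B2DF8A", "#FB9A99", "#CAB2D6")

.hex <- function(rgb) sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])

#' Color for a single value under a choropleth spec
#'
#' Gradient scales interpolate linearly in RGB between the light and dark
#' endpoints over the observed `[min, max]` domain; values outside the domain
#' are clamped with a warning. Categorical scales assign a fixed palette in
#' the order of the supplied category set. Missing values map to the spec's
#' `missing_color`.
#'
#' @param value a number (gradient) or category label (categorical), NA for
#'   missing.
#' @param spec a [choropleth_spec()].
#' @param domain for gradient: numeric `c(min, max)` (must be non-degenerate);
#'   for categorical: the vector of category levels.
#' @return a hex RGB color string.
#' @export
color_for_value <- function(value, spec, domain) {
  if (is.na(value)) return(spec$missing_color)
  if (spec$scale == "categorical") {
    i <- match(as.character(value), as.character(domain))
    if (is.na(i)) .stopf("category '%s' not in domain", value)
    return(.categorical_palette[(i - 1L) %% length(.categorical_palette) + 1L])
  }
  lo <- domain[1]; hi <- domain[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    .stopf("degenerate gradient domain [%s, %s]", lo, hi)
  if (value < lo || value > hi) {
    warning(sprintf("value %s outside domain [%s, %s]; clamped", value, lo, hi))
    value <- min(max(value, lo), hi)
  }
  f <- (value - lo) / (hi - lo)
  c1 <- grDevices::col2rgb(spec$low)[, 1]
  c2 <- grDevices::col2rgb(spec$high)[, 1]
  .hex(round(c1 + f * (c2 - c1)))
}

.svg_num <- function(x) formatC(x, digits = 2, format = "f")

# project lon/lat rings to SVG viewport coordinates (equirectangular, y down)
.project <- function(ring, bbox, width, height, pad) {
  sx <- (width - 2 * pad) / (bbox[2] - bbox[1])
  sy <- (height - 2 * pad) / (bbox[4] - bbox[3])
  cbind(pad + (ring[, 1] - bbox[1]) * sx,
        height - pad - (ring[, 2] - bbox[3]) * sy)
}

#' Render a choropleth map to SVG (and optionally HTML)
#'
#' Draws one filled polygon per region, colored by the spec's variable, with
#' a legend (gradient bar with min/max labels at 3 significant digits, or
#' category swatches) and the regions with missing values listed under a
#' neutral fill. Output is deterministic: identical inputs produce
#' byte-identical SVG. If `out` ends in `.html`, a self-contained pannable/
#' zoomable HTML document embedding the same SVG is written instead.
#'
#' A constant variable cannot span a gradient; all regions then take the
#' mid-scale color and a warning `"degenerate range"` is issued.
#'
#' @param joined a `joined_communities` from [join_table_boundaries()].
#' @param spec a [choropleth_spec()].
#' @param out output file path (`.svg` or `.html`).
#' @param width,height viewport size in pixels.
#' @return `out`, invisibly; the SVG text is attached as attribute `"svg"`.
#' @export
render_choropleth <- function(joined, spec, out, width = 800, height = 600) {
  stopifnot(inherits(joined, "joined_communities"), inherits(spec, "choropleth_spec"))
  tab <- joined$table
  if (!nrow(tab)) .stopf("joined dataset is empty")
  if (!spec$variable %in% names(tab)) .stopf("variable '%s' not in table", spec$variable)
  vals <- tab[[spec$variable]]
  if (spec$scale == "categorical" && is.numeric(vals))
    .stopf("categorical scale requires a categorical variable")

  degenerate <- FALSE
  if (spec$scale == "gradient") {
    domain <- range(vals, na.rm = TRUE)
    if (!all(is.finite(domain)) || domain[1] == domain[2]) {
      warning("degenerate range: constant variable; using mid-scale color")
      degenerate <- TRUE
    }
  } else domain <- sort(unique(stats::na.omit(as.character(vals))))

  mid_color <- .hex(round((grDevices::col2rgb(spec$low)[, 1] +
                           grDevices::col2rgb(spec$high)[, 1]) / 2))
  fills <- vapply(vals, function(v) {
    if (is.na(v)) spec$missing_color
    else if (degenerate) mid_color
    else color_for_value(v, spec, domain)
  }, character(1))

  rings <- unlist(lapply(joined$boundaries, function(g)
    lapply(unlist(g, recursive = FALSE), identity)), recursive = FALSE)
  allc <- do.call(rbind, rings)
  bbox <- c(min(allc[, 1]), max(allc[, 1]), min(allc[, 2]), max(allc[, 2]))
  if (bbox[1] == bbox[2]) bbox[1:2] <- bbox[1:2] + c(-0.5, 0.5)
  if (bbox[3] == bbox[4]) bbox[3:4] <- bbox[3:4] + c(-0.5, 0.5)
  pad <- 10

  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    sprintf('<title>%s</title>', spec$title),
    sprintf('<text x="%d" y="20" font-family="sans-serif" font-size="16">%s</text>',
            pad, spec$title))
  for (i in seq_len(nrow(tab))) {
    id <- tab$region_id[i]
    for (poly in joined$boundaries[[id]]) {
      for (ring in poly) {
        pr <- .project(ring, bbox, width, height - 60, pad)
        pts <- paste(paste(.svg_num(pr[, 1]), .svg_num(pr[, 2] + 30), sep = ","),
                     collapse = " ")
        lines <- c(lines, sprintf(
          '<polygon points="%s" fill="%s" stroke="#FFFFFF" stroke-width="0.5"><title>%s</title></polygon>',
          pts, fills[i], id))
      }
    }
  }
  # legend
  ly <- height - 22
  if (spec$scale == "gradient") {
    lines <- c(lines,
      '<defs><linearGradient id="ramp" x1="0" y1="0" x2="1" y2="0">',
      sprintf('<stop offset="0" stop-color="%s"/><stop offset="1" stop-color="%s"/>',
              spec$low, spec$high),
      '</linearGradient></defs>',
      sprintf('<rect x="%d" y="%d" width="200" height="12" fill="url(#ramp)"/>',
              pad, ly))
    lab <- if (degenerate) c("constant", "constant")
    else signif(domain, 3)
    lines <- c(lines, sprintf(
      '<text x="%d" y="%d" font-family="sans-serif" font-size="11">%s</text>',
      c(pad, pad + 170), ly + 24, lab))
  } else {
    x0 <- pad
    for (i in seq_along(domain)) {
      col <- .categorical_palette[(i - 1L) %% length(.categorical_palette) + 1L]
      lines <- c(lines, sprintf(
        '<rect x="%d" y="%d" width="12" height="12" fill="%s"/><text x="%d" y="%d" font-family="sans-serif" font-size="11">%s</text>',
        x0, ly, col, x0 + 16, ly + 10, domain[i]))
      x0 <- x0 + 16 + 9 * nchar(domain[i]) + 12
    }
  }
  if (anyNA(vals))
    lines <- c(lines, sprintf(
      '<rect x="%d" y="%d" width="12" height="12" fill="%s"/><text x="%d" y="%d" font-family="sans-serif" font-size="11">missing (%s)</text>',
      pad + 230, ly, spec$missing_color, pad + 246, ly + 10,
      paste(tab$region_id[is.na(vals)], collapse = ", ")))
  lines <- c(lines, "</svg>")
  svg <- paste(lines, collapse = "\n")

  if (grepl("\\.html?$", out, ignore.case = TRUE)) {
    html <- paste0(
      "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/><title>", spec$title,
      "</title>\n<style>body{margin:0}#map{cursor:grab}</style></head>\n<body>",
      "<div id=\"map\">", svg, "</div>\n",
      "<script>\n",
      "var s=document.querySelector('svg'),vb=s.getAttribute('viewBox').split(' ').map(Number);\n",
      "var drag=null;\n",
      "s.addEventListener('mousedown',function(e){drag=[e.clientX,e.clientY];});\n",
      "window.addEventListener('mouseup',function(){drag=null;});\n",
      "window.addEventListener('mousemove',function(e){if(!drag)return;",
      "vb[0]-=(e.clientX-drag[0])*vb[2]/s.clientWidth;vb[1]-=(e.clientY-drag[1])*vb[3]/s.clientHeight;",
      "drag=[e.clientX,e.clientY];s.setAttribute('viewBox',vb.join(' '));});\n",
      "s.addEventListener('wheel',function(e){e.preventDefault();var f=e.deltaY<0?0.9:1.1;",
      "vb[2]*=f;vb[3]*=f;s.setAttribute('viewBox',vb.join(' '));});\n",
      "</script></body></html>\n")
    writeLines(html, out, sep = "")
  } else {
    writeLines(svg, out, sep = "")
  }
  invisible(structure(out, svg = svg))
}
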