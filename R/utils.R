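# internal helpers shared across modules

# markers accepted as missing on read (case-insensitive): "", "NA", "NaN"
.is_missing_marker <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | toupper(x) %in% c("NA", "NAN")
}

# parse a character vector as numeric if every non-missing cell parses;
# otherwise return it as-is (categorical). Unparseable cells in a column
# that is otherwise numeric become NA.
.parse_column <- function(x) {
  miss <- .is_missing_marker(x)
  if (all(miss)) return(rep(NA_real_, length(x)))
  num <- suppressWarnings(as.numeric(x))
  if (all(!is.na(num[!miss]))) {
    num[miss] <- NA_real_
    return(num)
  }
  out <- trimws(x)
  out[miss] <- NA_character_
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))

# format numbers for deterministic text output
.fmt <- function(x, digits = 4) formatC(x, digits = digits, format = "g")

# run an expression with a locally seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
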