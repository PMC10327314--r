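# Internal helpers shared across modules.

# Blank semantics: NA, empty string and whitespace-only strings all mean
# "blank". Applies to tri-state variables, arm labels and free-text cells.
is_blank <- function(x) {
  if (inherits(x, "Date")) return(is.na(x))
  is.na(x) | !nzchar(trimws(as.character(x)))
}

blank_to_empty <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  trimws(x)
}

# Round half-up at `digits` decimals (base round() rounds half-to-even;
# reported percentages follow the half-up convention).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Parse ISO-8601 dates, erroring with the offending rows rather than
# silently producing NA.
parse_iso_date <- function(x, field = "date") {
  x <- blank_to_empty(x)
  out <- rep(as.Date(NA), length(x))
  has <- nzchar(x)
  if (any(has)) {
    parsed <- as.Date(x[has], format = "%Y-%m-%d")
    bad <- is.na(parsed)
    if (any(bad)) {
      stop(sprintf("unparseable %s at row(s) %s: %s", field,
                   paste(which(has)[bad], collapse = ", "),
                   paste(unique(x[has][bad]), collapse = ", ")),
           call. = FALSE)
    }
    out[has] <- parsed
  }
  out
}

format_iso_date <- function(x) {
  out <- character(length(x))
  out[!is.na(x)] <- format(x[!is.na(x)], "%Y-%m-%d")
  out
}

# Locale-independent weekday abbreviation (Mon..Sun).
weekday_abbrev <- function(date) {
  c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[as.POSIXlt(date)$wday + 1L]
}

# Atomic file write: write to a temporary file in the same directory, then
# rename, so a crash never leaves a truncated file behind.
write_atomic <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot write '%s': directory does not exist", path),
         call. = FALSE)
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop(sprintf("cannot write '%s': rename failed", path), call. = FALSE)
  }
  ok <- TRUE
  invisible(NULL)
}
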