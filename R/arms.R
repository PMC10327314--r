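#' Treatment arm labels
#'
#' The engine's arm vocabulary mirrors the motivating COVID-19 testing SMART:
#' participants are first randomized to peer navigation or an informational
#' brochure, and a week later re-randomized to continue the first-stage
#' intervention or switch - testers to brief counseling, non-testers to a
#' critical-dialogue group.
#'
#' @param stage `1` restricts to the two first-stage arms, `2` (default)
#'   returns all four labels.
#' @return Character vector of arm labels.
#' @examples
#' arm_labels(1)
#' arm_labels()
#' @export
arm_labels <- function(stage = 2) {
  first <- c("NAVIGATION", "BROCHURE")
  if (identical(as.integer(stage), 1L)) return(first)
  c(first, "BRIEF_COUNSELING", "CRITICAL_DIALOGUE")
}

# Canonicalise an arm label (case-insensitive); "" stays blank.
normalize_arm <- function(x, stage = 2, field = "arm") {
  x <- blank_to_empty(x)
  out <- toupper(x)
  valid <- arm_labels(stage)
  bad <- nzchar(out) & !(out %in% valid)
  if (any(bad)) {
    stop(sprintf("unknown %s label at row(s) %s: %s", field,
                 paste(which(bad), collapse = ", "),
                 paste(unique(out[bad]), collapse = ", ")),
         call. = FALSE)
  }
  out
}

# Canonicalise a yes/no tri-state to "yes"/"no"/"".
normalize_yesno <- function(x, field = "value") {
  x <- tolower(blank_to_empty(x))
  bad <- nzchar(x) & !(x %in% c("yes", "no"))
  if (any(bad)) {
    stop(sprintf("invalid %s at row(s) %s (expected yes/no/blank): %s", field,
                 paste(which(bad), collapse = ", "),
                 paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  x
}

# Instrument status: binary complete/incomplete. EDC exports vary
# ("Complete", "2", "Yes"); anything else, including blank, is incomplete.
normalize_complete <- function(x) {
  x <- tolower(blank_to_empty(x))
  ifelse(x %in% c("complete", "2", "yes"), "complete", "incomplete")
}
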