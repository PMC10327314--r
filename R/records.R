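# Participant record model: one row per participant, holding the six
# randomization-relevant variables plus event dates and anomaly fields.

RECORD_DATE_FIELDS <- c("enrollment_date", "entry_date", "randomization1_date",
                        "covid_test_assessed_date", "randomization2_date",
                        "dropout_date")

RECORD_FIELDS <- c("record_id", "enrollment_date", "entry_date",
                   "approve_b", "consent_2",
                   "randomization1", "randomization1_date",
                   "covid_test", "covid_test_complete",
                   "covid_test_assessed_date",
                   "randomization2", "randomization2_date",
                   "delivered_intervention", "dropout_date")

#' Construct a participant record set
#'
#' Builds a validated, canonically typed record set from a data frame (or
#' nothing, for an empty set). Tri-state variables (`approve_b`, `consent_2`,
#' `covid_test`) are canonicalised to `"yes"`/`"no"`/`""`; arm labels to
#' upper case; dates to `Date`; the instrument status to
#' `"complete"`/`"incomplete"`. A missing cell, empty string or
#' whitespace-only string all denote the blank state. Unknown columns are
#' retained untouched and round-trip through file I/O unchanged.
#'
#' `entry_date` is the date the approval/consent variables were entered into
#' the database (the event the weekday gate acts on); it defaults to
#' `enrollment_date` when absent.
#'
#' @param data A data frame with (a subset of) the participant fields;
#'   missing canonical columns are filled with blanks.
#' @return A `participant_records` data frame.
#' @seealso [load_records()], [validate_records()]
#' @export
participant_records <- function(data = NULL) {
  if (is.null(data)) data <- data.frame(record_id = character())
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"record_id" %in% names(data)) {
    stop("records need a 'record_id' column", call. = FALSE)
  }
  n <- nrow(data)
  out <- data.frame(record_id = blank_to_empty(data$record_id),
                    stringsAsFactors = FALSE)
  get_chr <- function(field) {
    if (field %in% names(data)) blank_to_empty(data[[field]])
    else character(n)
  }
  get_date <- function(field) {
    if (!field %in% names(data)) return(rep(as.Date(NA), n))
    x <- data[[field]]
    if (inherits(x, "Date")) x else parse_iso_date(x, field)
  }
  out$enrollment_date <- get_date("enrollment_date")
  out$entry_date <- get_date("entry_date")
  blank_entry <- is.na(out$entry_date)
  out$entry_date[blank_entry] <- out$enrollment_date[blank_entry]
  out$approve_b <- normalize_yesno(get_chr("approve_b"), "approve_b")
  out$consent_2 <- normalize_yesno(get_chr("consent_2"), "consent_2")
  out$randomization1 <- normalize_arm(get_chr("randomization1"), 1,
                                      "randomization1")
  out$randomization1_date <- get_date("randomization1_date")
  out$covid_test <- normalize_yesno(get_chr("covid_test"), "covid_test")
  out$covid_test_complete <- normalize_complete(get_chr("covid_test_complete"))
  out$covid_test_assessed_date <- get_date("covid_test_assessed_date")
  out$randomization2 <- normalize_arm(get_chr("randomization2"), 2,
                                      "randomization2")
  out$randomization2_date <- get_date("randomization2_date")
  out$delivered_intervention <- normalize_arm(get_chr("delivered_intervention"),
                                              2, "delivered_intervention")
  out$dropout_date <- get_date("dropout_date")

  if (anyDuplicated(out$record_id)) {
    dups <- unique(out$record_id[duplicated(out$record_id)])
    stop(sprintf("duplicate record_id: %s", paste(dups, collapse = ", ")),
         call. = FALSE)
  }

  extras <- setdiff(names(data), RECORD_FIELDS)
  for (col in extras) out[[col]] <- data[[col]]
  rownames(out) <- NULL
  class(out) <- c("participant_records", "data.frame")
  out
}

#' Read participant records from CSV or JSON-lines
#'
#' CSV is RFC-4180 with a header row; header names are matched
#' case-insensitively against the canonical field names. JSON-lines holds one
#' object per line with blank fields omitted or `null`.
#'
#' @param source Path to the file.
#' @param format `"csv"` or `"jsonl"`.
#' @return A `participant_records` data frame in file order.
#' @export
load_records <- function(source, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    raw <- utils::read.csv(source, colClasses = "character",
                           check.names = FALSE)
  } else {
    lines <- readLines(source, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    objs <- lapply(lines, function(l) {
      o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      lapply(o, function(v) if (is.null(v)) "" else as.character(v))
    })
    cols <- unique(unlist(lapply(objs, names)))
    raw <- as.data.frame(
      setNames(lapply(cols, function(cn) {
        vapply(objs, function(o) {
          if (is.null(o[[cn]])) "" else o[[cn]]
        }, character(1))
      }), cols),
      stringsAsFactors = FALSE, check.names = FALSE)
    if (length(lines) == 0) raw <- data.frame(record_id = character())
  }
  canon <- match(tolower(names(raw)), tolower(RECORD_FIELDS))
  names(raw)[!is.na(canon)] <- RECORD_FIELDS[canon[!is.na(canon)]]
  participant_records(raw)
}

#' Write participant records to CSV or JSON-lines
#'
#' The output reloads via [load_records()] to a field-for-field identical
#' record set. Blank states serialise as empty CSV cells; JSON-lines objects
#' omit blank fields.
#'
#' @param records A `participant_records` data frame.
#' @param sink Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @export
write_records <- function(records, sink, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- as.data.frame(records)
  for (col in intersect(RECORD_DATE_FIELDS, names(df))) {
    df[[col]] <- format_iso_date(df[[col]])
  }
  if (format == "csv") {
    write_atomic(function(tmp) {
      utils::write.csv(df, tmp, row.names = FALSE, quote = TRUE, na = "")
    }, sink)
  } else {
    write_atomic(function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      for (i in seq_len(nrow(df))) {
        row <- as.list(df[i, , drop = FALSE])
        row <- row[!vapply(row, function(v) is_blank(v), logical(1))]
        writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
      }
    }, sink)
  }
  invisible(NULL)
}

#' Validate a participant record set
#'
#' Checks the per-record invariants: a second-stage assignment presupposes a
#' first-stage one; the second randomization date cannot precede the first;
#' a non-blank tailoring variable carries an assessment date. Violations are
#' data, not errors.
#'
#' @param records A `participant_records` data frame.
#' @return A character vector of violation descriptions (empty when valid),
#'   each naming the record and the broken rule.
#' @export
validate_records <- function(records) {
  v <- character()
  flag <- function(idx, msg) {
    if (any(idx)) {
      v <<- c(v, sprintf("record %s: %s", records$record_id[idx], msg))
    }
    invisible(NULL)
  }
  flag(nzchar(records$randomization2) & !nzchar(records$randomization1),
       "randomization2 set while randomization1 is blank")
  both <- !is.na(records$randomization1_date) &
    !is.na(records$randomization2_date)
  flag(both & records$randomization2_date < records$randomization1_date,
       "randomization2_date earlier than randomization1_date")
  flag(nzchar(records$covid_test) & is.na(records$covid_test_assessed_date),
       "covid_test set without covid_test_assessed_date")
  v
}
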