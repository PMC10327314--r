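# Participant-flow accounting: the SMART flow diagram as numbers, the
# failure taxonomy, a text renderer, and the two-proportion power helper.

FAILURE_CATEGORIES <- c("dropout_before_r2", "missing_tailoring",
                        "manual_override")

#' Participant-flow counts
#'
#' Container for the SMART flow diagram as numbers: first-stage totals per
#' arm, the eight second-stage cells keyed by
#' (first arm, tester status, second arm), and failures by category.
#' `manual_override` (intervention delivered by hand, differing from the
#' engine's assignment) is a failure category regardless of whether the
#' record also holds an engine second assignment; `dropout_before_r2`
#' takes precedence over `missing_tailoring` so those categories partition
#' the records lacking a second assignment. All percentages use the
#' first-randomized total as denominator and round half-up to one decimal.
#'
#' @param per_arm_first Named integer vector, count per first-stage arm.
#' @param per_cell_second Data frame with columns `first_arm`,
#'   `test_status`, `second_arm`, `n`.
#' @param failures Named integer vector over the failure categories.
#' @param n_unassessed Records first-randomized but not yet assessed at the
#'   accounting date (enters the flow-conservation identity).
#' @return A `flow_counts` list with derived totals and percentages.
#' @export
flow_counts <- function(per_arm_first, per_cell_second,
                        failures = c(dropout_before_r2 = 0L,
                                     missing_tailoring = 0L,
                                     manual_override = 0L),
                        n_unassessed = 0L) {
  miss <- setdiff(FAILURE_CATEGORIES, names(failures))
  failures[miss] <- 0L
  failures <- failures[FAILURE_CATEGORIES]
  n_first <- sum(per_arm_first)
  n_second <- sum(per_cell_second$n)
  pct <- function(k) {
    if (n_first == 0) 0 else round_half_up(100 * k / n_first, 1)
  }
  structure(list(
    n_first_randomized = as.integer(n_first),
    per_arm_first = per_arm_first,
    per_arm_first_pct = vapply(per_arm_first, pct, numeric(1)),
    per_cell_second = per_cell_second,
    n_second_randomized = as.integer(n_second),
    failures = failures,
    n_failures = as.integer(sum(failures)),
    failure_rate_pct = pct(sum(failures)),
    n_unassessed = as.integer(n_unassessed)),
    class = "flow_counts")
}

#' @export
print.flow_counts <- function(x, ...) {
  cat(render_flow(x), sep = "\n")
  invisible(x)
}

#' Summarise participant flow from records
#'
#' Counts are computed purely from the record fields as of the accounting
#' date. A record is first-randomized if `randomization1` is set; a
#' second-stage cell is keyed by (`randomization1`, `covid_test`,
#' `randomization2`). Failures: dropouts (dropout date set, no second
#' assignment), missing tailoring data (first-randomized, tailoring
#' variable blank, not a dropout), manual overrides (delivered intervention
#' set and different from the assigned one).
#'
#' @param records A `participant_records` data frame.
#' @param as_of_date Accounting date (default: after all recorded events).
#' @return A [flow_counts()].
#' @export
flow_summary <- function(records, as_of_date = NULL) {
  future_assess <- rep(FALSE, nrow(records))
  if (!is.null(as_of_date)) {
    as_of_date <- as.Date(as_of_date)
    future_assess <- !is.na(records$covid_test_assessed_date) &
      records$covid_test_assessed_date > as_of_date
    masked <- records_as_of(records, as_of_date + 1L)
    drop_r <- !is.na(records$randomization1_date) &
      records$randomization1_date > as_of_date
    masked$randomization1[drop_r] <- ""
    drop_r2 <- !is.na(records$randomization2_date) &
      records$randomization2_date > as_of_date
    masked$randomization2[drop_r2] <- ""
    records <- masked
  }
  r1 <- nzchar(records$randomization1)
  per_arm <- vapply(arm_labels(1),
                    function(a) sum(records$randomization1 == a),
                    integer(1))
  r2 <- r1 & nzchar(records$randomization2)
  cells <- data.frame(first_arm = character(), test_status = character(),
                      second_arm = character(), n = integer(),
                      stringsAsFactors = FALSE)
  if (any(r2)) {
    agg <- stats::aggregate(
      list(n = records$record_id[r2]),
      by = list(first_arm = records$randomization1[r2],
                test_status = records$covid_test[r2],
                second_arm = records$randomization2[r2]),
      FUN = length)
    cells <- agg[order(agg$first_arm, agg$test_status, agg$second_arm), ]
    rownames(cells) <- NULL
  }
  fails <- failure_tally(records, exclude_missing = future_assess)
  unassessed <- sum(r1 & future_assess & !nzchar(records$randomization2))
  flow_counts(per_arm, cells, fails, unassessed)
}

# Shared failure classification; the categories that reduce the
# second-randomized total are mutually exclusive (dropout takes precedence
# over missing tailoring). `exclude_missing` marks records whose assessment
# is merely scheduled after the accounting date, not missing.
failure_tally <- function(records, exclude_missing = NULL) {
  if (is.null(exclude_missing)) {
    exclude_missing <- rep(FALSE, nrow(records))
  }
  r1 <- nzchar(records$randomization1)
  dropout <- r1 & !is.na(records$dropout_date) &
    !nzchar(records$randomization2)
  missing <- r1 & !nzchar(records$covid_test) & !dropout &
    !nzchar(records$randomization2) & !exclude_missing
  override <- nzchar(records$delivered_intervention) &
    records$delivered_intervention != records$randomization2
  c(dropout_before_r2 = sum(dropout), missing_tailoring = sum(missing),
    manual_override = sum(override))
}

#' Failure accounting
#'
#' Tallies the failure taxonomy and the overall error percentage
#' (failures / first-randomized x 100, half-up to one decimal).
#'
#' @inheritParams flow_summary
#' @return `list(failures, n_failures, failure_rate_pct)`.
#' @export
error_accounting <- function(records, as_of_date = NULL) {
  flow <- flow_summary(records, as_of_date)
  list(failures = flow$failures, n_failures = flow$n_failures,
       failure_rate_pct = flow$failure_rate_pct)
}

#' Render a flow-counts object as a text diagram
#'
#' A deterministic monospaced tree: first-stage arms, then tester /
#' non-tester branches, then the second-stage cells, then the failure
#' taxonomy. Inconsistent totals are a hard error.
#'
#' @param flow A [flow_counts()].
#' @return Character vector of lines.
#' @export
render_flow <- function(flow) {
  stopifnot(inherits(flow, "flow_counts"))
  if (flow$n_first_randomized != sum(flow$per_arm_first) ||
      flow$n_second_randomized != sum(flow$per_cell_second$n)) {
    stop("inconsistent flow counts", call. = FALSE)
  }
  fmt_pct <- function(p) sprintf("%.1f%%", p)
  lines <- c(sprintf("First randomization: n = %d",
                     flow$n_first_randomized))
  for (arm in names(flow$per_arm_first)) {
    lines <- c(lines, sprintf("+-- %s: %d (%s)", arm,
                              flow$per_arm_first[[arm]],
                              fmt_pct(flow$per_arm_first_pct[[arm]])))
    for (ts in c("yes", "no")) {
      sub <- flow$per_cell_second[flow$per_cell_second$first_arm == arm &
                                    flow$per_cell_second$test_status == ts, ,
                                  drop = FALSE]
      label <- if (ts == "yes") "tested" else "not tested"
      lines <- c(lines, sprintf("|   +-- %s: %d", label, sum(sub$n)))
      for (j in seq_len(nrow(sub))) {
        lines <- c(lines, sprintf("|   |   +-- %s: %d", sub$second_arm[j],
                                  sub$n[j]))
      }
    }
  }
  lines <- c(lines,
             sprintf("Second randomization: n = %d",
                     flow$n_second_randomized),
             sprintf("Failures: %d (%s)", flow$n_failures,
                     fmt_pct(flow$failure_rate_pct)))
  for (cat in names(flow$failures)) {
    lines <- c(lines, sprintf("+-- %s: %d", cat, flow$failures[[cat]]))
  }
  if (flow$n_unassessed > 0) {
    lines <- c(lines, sprintf("Awaiting assessment: %d", flow$n_unassessed))
  }
  lines
}

#' Build a synthetic record set matching given flow counts
#'
#' Constructs participant records (with consistent synthetic dates) whose
#' [flow_summary()] reproduces the requested first-stage totals,
#' second-stage cells and failure taxonomy - useful for verifying the
#' accounting against published flow diagrams. All three failure types are
#' hosted on records outside the second-stage cells (a manual override here
#' is a participant whose intervention was delivered by hand instead of by
#' the engine), and are distributed across first-stage arms to reconcile
#' `per_arm_first` with the cell sums; irreconcilable counts are a hard
#' error.
#'
#' @param per_arm_first Named counts for the first-stage arms.
#' @param per_cell_second Data frame `first_arm`, `test_status`,
#'   `second_arm`, `n`.
#' @param n_dropout,n_missing,n_override Failure counts.
#' @param start_date Synthetic enrollment date for the fixture.
#' @return A `participant_records` data frame.
#' @export
records_from_flow <- function(per_arm_first, per_cell_second,
                              n_dropout = 0, n_missing = 0, n_override = 0,
                              start_date = as.Date("2022-01-03")) {
  per_cell_second <- as.data.frame(per_cell_second,
                                   stringsAsFactors = FALSE)
  residual <- vapply(names(per_arm_first), function(a) {
    per_arm_first[[a]] -
      sum(per_cell_second$n[per_cell_second$first_arm == a])
  }, numeric(1))
  if (any(residual < 0) ||
      sum(residual) != n_dropout + n_missing + n_override) {
    stop(paste("per-arm totals minus cell sums must equal",
               "n_dropout + n_missing + n_override"), call. = FALSE)
  }
  rows <- list()
  add <- function(n, first, ts = "", second = "", dropout = FALSE,
                  delivered = "") {
    if (n <= 0) return(invisible(NULL))
    rows[[length(rows) + 1]] <<- data.frame(
      first = rep(first, n), ts = ts, second = second, dropout = dropout,
      delivered = delivered, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  for (j in seq_len(nrow(per_cell_second))) {
    add(per_cell_second$n[j], per_cell_second$first_arm[j],
        per_cell_second$test_status[j], per_cell_second$second_arm[j])
  }
  # distribute dropouts, then missing, then overrides over the arms'
  # residuals, greedily; override hosts were assessed (tailoring known) but
  # had their intervention delivered by hand rather than by the engine
  left <- c(drop = n_dropout, miss = n_missing, over = n_override)
  for (a in names(residual)) {
    room <- residual[[a]]
    d <- min(left[["drop"]], room)
    add(d, a, dropout = TRUE)
    left[["drop"]] <- left[["drop"]] - d
    m <- min(left[["miss"]], room - d)
    add(m, a)
    left[["miss"]] <- left[["miss"]] - m
    o <- min(left[["over"]], room - d - m)
    add(o, a, ts = "no", delivered = a)
    left[["over"]] <- left[["over"]] - o
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  df$delivered[nzchar(df$second)] <- df$second[nzchar(df$second)]
  enroll <- rep(start_date, n)
  assessed <- nzchar(df$ts)
  participant_records(data.frame(
    record_id = sprintf("F%04d", seq_len(n)),
    enrollment_date = enroll,
    approve_b = "yes", consent_2 = "yes",
    randomization1 = df$first,
    randomization1_date = enroll + 1L,
    covid_test = df$ts,
    covid_test_complete = ifelse(assessed, "complete", "incomplete"),
    covid_test_assessed_date = as.Date(ifelse(assessed,
                                              format(enroll + 7L), NA)),
    randomization2 = df$second,
    randomization2_date = as.Date(ifelse(nzchar(df$second),
                                         format(enroll + 8L), NA)),
    delivered_intervention = df$delivered,
    dropout_date = as.Date(ifelse(df$dropout, format(enroll + 3L), NA)),
    stringsAsFactors = FALSE))
}

#' Power of the two-sample proportion z-test
#'
#' Two-sided power for detecting a difference between two independent
#' proportions at equal per-arm sample size, for the usual z-test whose
#' statistic pools the variance under the null.
#'
#' `method = "exact"` (the default) enumerates the joint binomial
#' distribution of the two arm counts and sums the probability of the
#' test's actual rejection region - deterministic and accurate to machine
#' precision for the test as practitioners run it. `method = "normal"` is
#' the classic first-order formula (pooled variance under the null,
#' unpooled under the alternative); it is what sample-size textbooks print,
#' but it can be off by 0.01-0.02 in absolute power around n of a few
#' hundred, which is why it is not the default. Above `n_per_arm` = 2000
#' the two methods agree to well under 0.001 and enumeration switches to
#' the formula automatically.
#'
#' @param p1,p2 Outcome proportions in the two arms, in (0, 1).
#' @param n_per_arm Participants per arm (>= 2).
#' @param alpha Two-sided significance level.
#' @param method `"exact"` (binomial enumeration of the rejection region)
#'   or `"normal"` (first-order approximation).
#' @return Power in \[0, 1\].
#' @examples
#' power_two_proportions(0.5, 0.65, n_per_arm = 291)
#' @export
power_two_proportions <- function(p1, p2, n_per_arm, alpha = 0.05,
                                  method = c("exact", "normal")) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, n_per_arm >= 2,
            alpha > 0, alpha < 1)
  method <- match.arg(method)
  n <- as.integer(n_per_arm)
  if (method == "exact" && n <= 2000) {
    x <- 0:n
    zc <- stats::qnorm(1 - alpha / 2)
    w1 <- stats::dbinom(x, n, p1)
    w2 <- stats::dbinom(x, n, p2)
    x1 <- matrix(x, n + 1L, n + 1L)
    x2 <- t(x1)
    pp <- (x1 + x2) / (2 * n)
    se <- sqrt(pmax(2 * pp * (1 - pp) / n, .Machine$double.xmin))
    reject <- abs((x1 - x2) / n / se) > zc
    return(min(max(as.numeric(w1 %*% reject %*% w2), 0), 1))
  }
  z <- stats::qnorm(1 - alpha / 2)
  pbar <- (p1 + p2) / 2
  sd0 <- sqrt(2 * pbar * (1 - pbar) / n)
  sd1 <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  delta <- p1 - p2
  stats::pnorm((delta - z * sd0) / sd1) +
    stats::pnorm((-delta - z * sd0) / sd1)
}
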