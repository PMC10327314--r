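# Allocation tables: ordered treatment lists consumed from the top.
# Stage 1 rotates rows (assign top, move to bottom); stage 2 scans
# sequentially for the first row matching the participant's stratum
# (first arm x tailoring status) and rotates that row.

new_allocation_table <- function(stage, rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("sequence_id", "first_arm", "test_status", "treatment")
  missing <- setdiff(need, names(rows))
  if (length(missing)) {
    stop(sprintf("allocation table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- rows[, need]
  rows$sequence_id <- as.integer(rows$sequence_id)
  if (anyDuplicated(rows$sequence_id)) {
    stop("sequence_id values must be unique", call. = FALSE)
  }
  rows$first_arm <- normalize_arm(rows$first_arm, 1, "first_arm")
  rows$test_status <- normalize_yesno(rows$test_status, "test_status")
  stage_n <- if (identical(as.integer(stage), 1L)) 1 else 2
  rows$treatment <- normalize_arm(rows$treatment, stage_n, "treatment")
  if (any(!nzchar(rows$treatment))) {
    stop(sprintf("blank treatment at row(s) %s",
                 paste(which(!nzchar(rows$treatment)), collapse = ", ")),
         call. = FALSE)
  }
  crit <- nzchar(rows$first_arm) | nzchar(rows$test_status)
  if (stage_n == 1 && any(crit)) {
    stop(sprintf("stage-1 rows must leave criteria blank; row(s) %s",
                 paste(which(crit), collapse = ", ")), call. = FALSE)
  }
  if (stage_n == 2) {
    part <- !(nzchar(rows$first_arm) & nzchar(rows$test_status))
    if (any(part)) {
      stop(sprintf(
        "stage-2 rows must set both criteria (no wildcards); row(s) %s",
        paste(which(part), collapse = ", ")), call. = FALSE)
    }
  }
  rownames(rows) <- NULL
  structure(list(stage = as.integer(stage), rows = rows),
            class = "allocation_table")
}

#' @export
print.allocation_table <- function(x, ...) {
  cat(sprintf("Stage-%d allocation table: %d row(s)\n", x$stage,
              nrow(x$rows)))
  if (x$stage == 2 && nrow(x$rows)) {
    tab <- table(paste(x$rows$first_arm, x$rows$test_status, sep = "/"),
                 x$rows$treatment)
    print(tab)
  } else if (nrow(x$rows)) {
    print(table(treatment = x$rows$treatment))
  }
  invisible(x)
}

# Permuted-block sequence: within every block each option appears equally
# often; the block order is the only randomness.
permuted_blocks <- function(options, n_rows, block_size) {
  k <- length(options)
  if (block_size <= 0 || block_size %% k != 0) {
    stop(sprintf(
      "block_size (%d) must be a positive multiple of the number of options (%d)",
      block_size, k), call. = FALSE)
  }
  if (n_rows <= 0 || n_rows %% block_size != 0) {
    stop(sprintf("n_rows (%d) must be a positive multiple of block_size (%d)",
                 n_rows, block_size), call. = FALSE)
  }
  unlist(lapply(seq_len(n_rows / block_size), function(b) {
    sample(rep(options, block_size / k))
  }), use.names = FALSE)
}

#' Generate a first-stage allocation table
#'
#' Permuted-block randomization: within every consecutive block of
#' `block_size` rows each arm appears equally often, so arm totals stay
#' within one block of 1:1 at any stopping point under rotation. Set
#' `block_size = n_rows` for simple (single-block) randomization.
#'
#' @param arms Character vector of arm labels (default the two first-stage
#'   arms).
#' @param n_rows Number of rows; a positive multiple of `block_size`.
#' @param block_size Block length; a positive multiple of `length(arms)`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An `allocation_table` (stage 1).
#' @export
generate_first_stage_table <- function(arms = arm_labels(1), n_rows,
                                       block_size = 2, seed) {
  arms <- normalize_arm(arms, 1, "arm")
  treatments <- withr_seed(seed, permuted_blocks(arms, n_rows, block_size))
  new_allocation_table(1L, data.frame(
    sequence_id = seq_len(n_rows), first_arm = "", test_status = "",
    treatment = treatments, stringsAsFactors = FALSE))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default second-stage strata
#'
#' The study design's four strata: testers continue their first-stage
#' intervention or switch to brief counseling; non-testers continue or
#' switch to critical dialogue.
#'
#' @return List of strata, each `list(first_arm, test_status, options)`.
#' @export
default_strata <- function() {
  list(
    list(first_arm = "NAVIGATION", test_status = "yes",
         options = c("NAVIGATION", "BRIEF_COUNSELING")),
    list(first_arm = "NAVIGATION", test_status = "no",
         options = c("NAVIGATION", "CRITICAL_DIALOGUE")),
    list(first_arm = "BROCHURE", test_status = "yes",
         options = c("BROCHURE", "BRIEF_COUNSELING")),
    list(first_arm = "BROCHURE", test_status = "no",
         options = c("BROCHURE", "CRITICAL_DIALOGUE")))
}

#' Generate a second-stage allocation table
#'
#' Rows are generated blockwise per stratum (permuted blocks over the
#' stratum's options), then the strata are interleaved by a seeded shuffle
#' that preserves each stratum's internal order - so the sequential-scan
#' consumption still walks each stratum's blocked sequence in order.
#'
#' @param strata List of strata as in [default_strata()].
#' @param n_rows_per_stratum Rows per stratum; multiple of `block_size`.
#' @param block_size Block length per stratum; multiple of the stratum's
#'   option count.
#' @param seed Integer seed.
#' @return An `allocation_table` (stage 2).
#' @export
generate_second_stage_table <- function(strata = default_strata(),
                                        n_rows_per_stratum, block_size = 2,
                                        seed) {
  keys <- vapply(strata, function(s) {
    paste(normalize_arm(s$first_arm, 1), normalize_yesno(s$test_status),
          sep = "/")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate stratum keys: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  }
  rows <- withr_seed(seed, {
    per <- lapply(strata, function(s) {
      if (length(s$options) == 0) {
        stop("stratum with empty option set", call. = FALSE)
      }
      data.frame(first_arm = normalize_arm(s$first_arm, 1),
                 test_status = normalize_yesno(s$test_status),
                 treatment = permuted_blocks(normalize_arm(s$options, 2),
                                             n_rows_per_stratum, block_size),
                 stringsAsFactors = FALSE)
    })
    # interleave: shuffle stratum labels, fill each stratum in order
    lab <- sample(rep(seq_along(per), each = n_rows_per_stratum))
    taken <- integer(length(per))
    out <- vector("list", length(lab))
    for (i in seq_along(lab)) {
      s <- lab[i]
      taken[s] <- taken[s] + 1L
      out[[i]] <- per[[s]][taken[s], , drop = FALSE]
    }
    do.call(rbind, out)
  })
  rows$sequence_id <- seq_len(nrow(rows))
  new_allocation_table(2L, rows)
}

#' First-stage rotation assignment
#'
#' Steps through the eligible IDs in order: each subject receives the
#' treatment at the top of the table, and that row is moved to the bottom so
#' it is not reused until the whole table has been consumed. The table is
#' cyclic, so it never exhausts; the first wrap-around raises a warning
#' (tables should be over-provisioned).
#'
#' @param eligible_ids Character vector of record IDs, duplicate-free, in
#'   processing order.
#' @param table A stage-1 `allocation_table`.
#' @return `list(assignments, table)`: a data frame with `record_id`,
#'   `treatment`, `sequence_id`, and the rotated table.
#' @export
assign_from_table <- function(eligible_ids, table) {
  stopifnot(inherits(table, "allocation_table"))
  if (table$stage != 1L) stop("expected a stage-1 table", call. = FALSE)
  if (anyDuplicated(eligible_ids)) {
    stop("eligible_ids contains duplicates", call. = FALSE)
  }
  n <- nrow(table$rows)
  if (length(eligible_ids) > 0 && n == 0) {
    stop("allocation table is empty", call. = FALSE)
  }
  rows <- table$rows
  assignments <- data.frame(record_id = character(), treatment = character(),
                            sequence_id = integer(),
                            stringsAsFactors = FALSE)
  if (length(eligible_ids)) {
    if (length(eligible_ids) > n) {
      warning(sprintf(
        "allocation table wrapped around (%d eligible > %d rows)",
        length(eligible_ids), n), call. = FALSE)
    }
    # rotation = cyclic slice: i-th subject (1-based) gets row ((i-1) mod n)+1
    idx <- ((seq_along(eligible_ids) - 1L) %% n) + 1L
    assignments <- data.frame(record_id = as.character(eligible_ids),
                              treatment = rows$treatment[idx],
                              sequence_id = rows$sequence_id[idx],
                              stringsAsFactors = FALSE)
    shift <- length(eligible_ids) %% n
    if (shift > 0) {
      rows <- rbind(rows[-seq_len(shift), , drop = FALSE],
                    rows[seq_len(shift), , drop = FALSE])
      rownames(rows) <- NULL
    }
  }
  list(assignments = assignments,
       table = structure(list(stage = 1L, rows = rows),
                         class = "allocation_table"))
}

#' Stratified second-stage assignment by sequential scan
#'
#' For each eligible entry in order, the table is read from the top until a
#' row is found whose criteria match the participant's first-stage arm and
#' tailoring status; that row's treatment is assigned and exactly that row
#' moves to the bottom, all other rows keeping their relative order. All
#' assignments are computed before anything is returned: a stratum with no
#' matching row aborts the whole batch with no partial result.
#'
#' @param eligible Data frame with columns `record_id`, `first_arm`,
#'   `test_status`, in processing order.
#' @param table A stage-2 `allocation_table`.
#' @return `list(assignments, table)`: assignments carry `record_id`,
#'   `treatment`, `sequence_id`, `first_arm`, `test_status`.
#' @export
assign_stratified <- function(eligible, table) {
  stopifnot(inherits(table, "allocation_table"))
  if (table$stage != 2L) stop("expected a stage-2 table", call. = FALSE)
  eligible <- as.data.frame(eligible, stringsAsFactors = FALSE)
  if (nrow(eligible) && anyDuplicated(eligible$record_id)) {
    stop("eligible entries contain duplicate record_id", call. = FALSE)
  }
  if (nrow(eligible) > 0 && nrow(table$rows) == 0) {
    stop("allocation table is empty", call. = FALSE)
  }
  rows <- table$rows
  out <- vector("list", nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    fa <- toupper(blank_to_empty(eligible$first_arm[i]))
    ts <- tolower(blank_to_empty(eligible$test_status[i]))
    hit <- which(rows$first_arm == fa & rows$test_status == ts)
    if (length(hit) == 0) {
      stop(sprintf(
        "no allocation row matches stratum (%s, %s) for record %s",
        fa, ts, eligible$record_id[i]), call. = FALSE)
    }
    j <- hit[1]
    out[[i]] <- data.frame(record_id = as.character(eligible$record_id[i]),
                           treatment = rows$treatment[j],
                           sequence_id = rows$sequence_id[j],
                           first_arm = fa, test_status = ts,
                           stringsAsFactors = FALSE)
    rows <- rbind(rows[-j, , drop = FALSE], rows[j, , drop = FALSE])
  }
  rownames(rows) <- NULL
  assignments <- if (length(out)) do.call(rbind, out) else
    data.frame(record_id = character(), treatment = character(),
               sequence_id = integer(), first_arm = character(),
               test_status = character(), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(assignments = assignments,
       table = structure(list(stage = 2L, rows = rows),
                         class = "allocation_table"))
}

#' Read / write allocation tables as CSV
#'
#' Column layout: `sequence_id,first_arm,test_status,treatment`; stage-1
#' files leave the criteria columns empty. The stage is inferred from the
#' criteria columns (all blank: stage 1; all set: stage 2; mixed rows are a
#' hard error). `write_allocation_table` replaces the file atomically
#' (temporary file + rename), so a crash never leaves a truncated table -
#' the table file is rewritten in full after every batch.
#'
#' @param path CSV file path.
#' @param stage Optional expected stage (1 or 2); a file whose criteria
#'   columns contradict it is a hard error.
#' @return `read_allocation_table` returns an `allocation_table`.
#' @export
read_allocation_table <- function(path, stage = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sequence_id", "first_arm", "test_status", "treatment")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop(sprintf("allocation table CSV missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sid <- suppressWarnings(as.integer(raw$sequence_id))
  if (nrow(raw) && any(is.na(sid))) {
    stop(sprintf("malformed sequence_id at row(s) %s",
                 paste(which(is.na(sid)), collapse = ", ")), call. = FALSE)
  }
  raw$sequence_id <- sid
  crit <- nzchar(blank_to_empty(raw$first_arm)) |
    nzchar(blank_to_empty(raw$test_status))
  inferred <- if (nrow(raw) == 0 || !any(crit)) 1L else 2L
  if (!is.null(stage)) {
    stage <- as.integer(stage)
    if (nrow(raw) > 0 && stage != inferred) {
      stop(sprintf(
        "file '%s' looks like a stage-%d table, expected stage %d",
        path, inferred, stage), call. = FALSE)
    }
    inferred <- stage
  }
  new_allocation_table(inferred, raw)
}

#' @rdname read_allocation_table
#' @param table An `allocation_table`.
#' @export
write_allocation_table <- function(table, path) {
  stopifnot(inherits(table, "allocation_table"))
  write_atomic(function(tmp) {
    utils::write.csv(table$rows, tmp, row.names = FALSE, quote = FALSE,
                     na = "")
  }, path)
  invisible(NULL)
}
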