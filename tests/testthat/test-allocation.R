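# Allocation tables: permuted-block generation, rotation, stratified scan,
# CSV round-trips.

test_that("permuted-block stage-1 tables balance within every block", {
  tab <- generate_first_stage_table(n_rows = 40, block_size = 4, seed = 11)
  trt <- tab$rows$treatment
  for (b in seq_len(10)) {
    blk <- trt[(4 * (b - 1) + 1):(4 * b)]
    expect_identical(sum(blk == "NAVIGATION"), 2L)
    expect_identical(sum(blk == "BROCHURE"), 2L)
  }
  expect_identical(sum(trt == "NAVIGATION"), 20L)
  # determinism
  again <- generate_first_stage_table(n_rows = 40, block_size = 4,
                                      seed = 11)
  expect_identical(tab$rows, again$rows)
  # indivisible sizes are rejected
  expect_error(generate_first_stage_table(n_rows = 10, block_size = 3,
                                          seed = 1), "multiple")
  expect_error(generate_first_stage_table(n_rows = 7, block_size = 2,
                                          seed = 1), "multiple")
})

test_that("stage-2 tables balance options within every stratum", {
  tab <- generate_second_stage_table(n_rows_per_stratum = 100,
                                     block_size = 2, seed = 5)
  expect_identical(nrow(tab$rows), 400L)
  for (s in default_strata()) {
    sub <- tab$rows[tab$rows$first_arm == s$first_arm &
                      tab$rows$test_status == s$test_status, ]
    expect_identical(nrow(sub), 100L)
    counts <- table(sub$treatment)
    expect_true(all(counts == 50L))
    # interleaving preserves the stratum's internal block structure
    for (b in seq_len(50)) {
      blk <- sub$treatment[(2 * b - 1):(2 * b)]
      expect_identical(sort(unique(blk)), sort(s$options))
    }
  }
  again <- generate_second_stage_table(n_rows_per_stratum = 100,
                                       block_size = 2, seed = 5)
  expect_identical(tab$rows, again$rows)
  dup <- c(default_strata(), default_strata()[1])
  expect_error(generate_second_stage_table(dup, 10, 2, seed = 1),
               "duplicate stratum")
})

test_that("rotation assigns from the top and moves rows to the bottom", {
  tab <- fixed_stage1_table(c("NAVIGATION", "BROCHURE", "NAVIGATION",
                              "BROCHURE"))
  res <- assign_from_table(c("r1", "r2", "r3"), tab)
  expect_identical(res$assignments$treatment,
                   c("NAVIGATION", "BROCHURE", "NAVIGATION"))
  expect_identical(res$table$rows$treatment,
                   c("BROCHURE", "NAVIGATION", "BROCHURE", "NAVIGATION"))
  # conservation of the row multiset
  expect_identical(sort(res$table$rows$sequence_id),
                   sort(tab$rows$sequence_id))
  # empty eligible list leaves the table untouched
  noop <- assign_from_table(character(), tab)
  expect_identical(noop$table$rows, tab$rows)
  expect_identical(nrow(noop$assignments), 0L)
})

test_that("rotation wraps cyclically and warns on the first wrap-around", {
  tab <- fixed_stage1_table(c("NAVIGATION", "BROCHURE"))
  expect_warning(res <- assign_from_table(c("r1", "r2", "r3"), tab),
                 "wrapped around")
  expect_identical(res$assignments$treatment,
                   c("NAVIGATION", "BROCHURE", "NAVIGATION"))
  expect_identical(res$table$rows$treatment, c("BROCHURE", "NAVIGATION"))
  expect_error(assign_from_table("r1", fixed_stage1_table(character())),
               "empty")
  expect_error(assign_from_table(c("r1", "r1"), tab), "duplicates")
})

test_that("rotation equals the cyclic-slicing oracle on random inputs", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    k <- sample(0:20, 1)
    tab <- fixed_stage1_table(sample(arm_labels(1), n, replace = TRUE))
    ids <- sprintf("s%02d", seq_len(k))
    res <- suppressWarnings(assign_from_table(ids, tab))
    oracle <- tab$rows$treatment[((seq_len(k) - 1) %% n) + 1]
    expect_identical(res$assignments$treatment, oracle)
  }
})

test_that("stratified scan takes the first matching row, rotates only it", {
  tab <- fixed_stage2_table(
    first_arm = c("NAVIGATION", "NAVIGATION", "NAVIGATION"),
    test_status = c("yes", "yes", "no"),
    treatment = c("NAVIGATION", "BRIEF_COUNSELING", "CRITICAL_DIALOGUE"))
  # matched row is last: rotation is a no-op on the order
  res <- assign_stratified(data.frame(record_id = "r1",
                                      first_arm = "NAVIGATION",
                                      test_status = "no"), tab)
  expect_identical(res$assignments$treatment, "CRITICAL_DIALOGUE")
  expect_identical(res$table$rows$treatment, tab$rows$treatment)
  # two testers consume the two tester rows in order
  res2 <- assign_stratified(
    data.frame(record_id = c("r1", "r2"),
               first_arm = "NAVIGATION", test_status = c("yes", "yes")),
    tab)
  expect_identical(res2$assignments$treatment,
                   c("NAVIGATION", "BRIEF_COUNSELING"))
  expect_identical(res2$table$rows$treatment,
                   c("CRITICAL_DIALOGUE", "NAVIGATION", "BRIEF_COUNSELING"))
})

test_that("a stratum with no rows is a configuration error, no partials", {
  tab <- fixed_stage2_table("NAVIGATION", "yes", "NAVIGATION")
  expect_error(
    assign_stratified(data.frame(record_id = c("a", "b"),
                                 first_arm = c("NAVIGATION", "BROCHURE"),
                                 test_status = c("yes", "no")), tab),
    "no allocation row matches stratum \\(BROCHURE, no\\)")
})

test_that("stratified scan criteria always match and rows are conserved", {
  set.seed(99)
  for (i in 1:20) {
    tab <- generate_second_stage_table(n_rows_per_stratum = 20,
                                       block_size = 2, seed = i)
    strata <- expand.grid(first_arm = arm_labels(1),
                          test_status = c("yes", "no"),
                          stringsAsFactors = FALSE)
    pick <- strata[sample(4, 15, replace = TRUE), ]
    eligible <- data.frame(record_id = sprintf("e%02d", 1:15),
                           first_arm = pick$first_arm,
                           test_status = pick$test_status)
    res <- assign_stratified(eligible, tab)
    # each assignment came from a row of the subject's own stratum
    src <- tab$rows[match(res$assignments$sequence_id,
                          tab$rows$sequence_id), ]
    expect_identical(src$first_arm, eligible$first_arm)
    expect_identical(src$test_status, eligible$test_status)
    expect_identical(res$assignments$treatment, src$treatment)
    expect_identical(sort(res$table$rows$sequence_id),
                     sort(tab$rows$sequence_id))
  }
})

test_that("allocation tables round-trip through CSV and infer their stage", {
  for (gen in list(
    generate_first_stage_table(n_rows = 20, block_size = 2, seed = 2),
    generate_second_stage_table(n_rows_per_stratum = 10, seed = 2))) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_allocation_table(gen, path)
    back <- read_allocation_table(path)
    expect_identical(back$stage, gen$stage)
    expect_identical(back$rows, gen$rows)
  }
})

test_that("malformed table files are hard errors naming the row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence_id,first_arm,test_status,treatment",
               "1,,,NAVIGATION", "2,,,MYSTERY"), path)
  expect_error(read_allocation_table(path), "row\\(s\\) 2")
  writeLines(c("sequence_id,treatment", "1,NAVIGATION"), path)
  expect_error(read_allocation_table(path), "missing column")
  # a criteria-bearing file read as stage 1 is rejected
  write_allocation_table(generate_second_stage_table(
    n_rows_per_stratum = 2, seed = 1), path)
  expect_error(read_allocation_table(path, stage = 1), "expected stage 1")
  # mixed criteria rows violate the stage invariants
  writeLines(c("sequence_id,first_arm,test_status,treatment",
               "1,NAVIGATION,yes,NAVIGATION", "2,,,BROCHURE"), path)
  expect_error(read_allocation_table(path), "criteria")
})
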