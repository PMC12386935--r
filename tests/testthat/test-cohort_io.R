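test_that("read_cohort parses a minimal file and rejects degenerate input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,day,stage,eggs,sex",
               "a,0,EGG,,unknown", "a,1,EGG,,unknown", "a,2,EGG,,unknown"),
             path)
  coh <- read_cohort(path)
  expect_s3_class(coh, "cohort_table")
  expect_identical(coh$n, 1L)
  expect_identical(coh$omega, 3L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,day,stage,eggs,sex", empty)
  expect_error(read_cohort(empty), "format error")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,day,eggs,sex", "a,0,0,unknown"), nocol)
  expect_error(read_cohort(nocol), "missing column")
})

test_that("read_cohort reports the offending individual on bad records", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,day,stage,eggs,sex",
               "a,0,EGG,,unknown", "a,2,EGG,,unknown"), path)  # gap at day 1
  expect_error(read_cohort(path), "\\[a\\].*consecutive")
})

test_that("write/read round trip is the identity on hand and synthetic cohorts", {
  for (coh in list(fx_three(),
                   generate_cohort(synthetic_preset("faw-default", n = 200),
                                   seed = 42))) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(coh, path)
    back <- read_cohort(path)
    expect_equal(back$data, coh$data)
    expect_identical(back$n, coh$n)
    expect_identical(back$omega, coh$omega)
  }
})

test_that("supernumerary L8 individuals survive the round trip", {
  coh <- cohort_table(rbind(
    make_ind("S1", c(EGG = 2, L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 1, L6 = 2,
                     L7 = 3, L8 = 4, PUPA = 8, ADULT_M = 5), sex = "male"),
    make_ind("S2", c(EGG = 2, L1 = 1))))
  expect_identical(nrow(validate_cohort(coh)), 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_true(any(back$data$stage == "L8"))
  expect_equal(back$data, coh$data)
})

test_that("validate_cohort catches each invariant violation and names the id", {
  expect_identical(nrow(validate_cohort(fx_three())), 0L)

  # stage regression L3 -> L2
  bad <- make_ind("R1", c(EGG = 1, L1 = 1, L2 = 1, L3 = 2))
  bad$stage[5] <- "L2"
  v <- validate_cohort(cohort_table(rbind(bad, make_ind("ok", c(EGG = 2)))))
  expect_true(any(v$rule == "stage_order" & v$id == "R1"))

  # male with eggs
  m <- make_ind("M9", c(full_preadult, ADULT_M = 3), sex = "male")
  m$eggs[m$day == 28] <- 4
  v <- validate_cohort(cohort_table(m))
  expect_true(any(v$rule == "eggs_female_only" & v$id == "M9"))

  # skipping a mandatory stage (L2 missing entirely)
  sk <- make_ind("K1", c(EGG = 1, L1 = 1, L3 = 1))
  v <- validate_cohort(cohort_table(rbind(sk, make_ind("ok", c(EGG = 2)))))
  expect_true(any(v$rule == "stage_order" & v$id == "K1"))

  # sex label inconsistent with stage reached (female label, died as larva)
  sx <- make_ind("X1", c(EGG = 1, L1 = 2), sex = "female")
  v <- validate_cohort(cohort_table(rbind(sx, make_ind("ok", c(EGG = 2)))))
  expect_true(any(v$rule == "sex_consistent" & v$id == "X1"))

  # day 0 not EGG
  d0 <- make_ind("D1", c(L1 = 2))
  v <- validate_cohort(cohort_table(rbind(d0, make_ind("ok", c(EGG = 2)))))
  expect_true(any(v$rule == "egg_first" & v$id == "D1"))

  # L6 -> PUPA skipping optional L7/L8 is legal
  ok <- make_ind("O1", c(EGG = 1, L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 1,
                         L6 = 1, PUPA = 2))
  expect_identical(nrow(validate_cohort(cohort_table(ok))), 0L)
})

test_that("pre-adult deaths carry sex unknown and one sex=unknown record in fixture", {
  coh <- fx_three()
  a <- agestage:::cohort_arrays(coh)
  expect_identical(sum(a$sex == "unknown"), 1L)
  expect_identical(sum(a$sex == "female"), 1L)
})
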