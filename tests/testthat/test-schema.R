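test_that("preterm encoding uses the 37-completed-weeks cutoff and propagates NA", {
  expect_identical(encode_preterm(c(36, 36.9, 37, 41, NA)),
                   c(1L, 1L, 0L, 0L, NA))
  expect_error(encode_preterm(c(36, 12)), "plausibility window")
  expect_error(encode_preterm(50), "plausibility window")
  # window is configurable
  expect_identical(encode_preterm(19, window = c(18, 45)), 1L)
})

test_that("co-occurrence coding is the declared bijection on {0,1}^2", {
  # neither = 0, both = 1, death only = 2, preterm only = 3
  grid <- expand.grid(preterm = 0:1, death = 0:1)
  codes <- encode_cooccurrence(grid$preterm, grid$death)
  expect_setequal(codes, 0:3)
  expect_identical(encode_cooccurrence(0, 0), 0L)
  expect_identical(encode_cooccurrence(1, 1), 1L)
  expect_identical(encode_cooccurrence(0, 1), 2L)
  expect_identical(encode_cooccurrence(1, 0), 3L)
  expect_identical(encode_cooccurrence(c(1, NA), c(NA, 1)), c(NA_integer_, NA_integer_))
  expect_error(encode_cooccurrence(2, 0), "0, 1 or NA")
})

test_that("eligibility filters remove records in order and tallies balance", {
  df <- tibble::tibble(
    mother_id = c(NA, NA, sprintf("m%d", 1:8)),
    plurality = c("singleton", "multiple", rep("multiple", 3),
                  rep("singleton", 5))
  )
  res <- apply_eligibility(df)
  # 2 missing ids (one of them also a multiple: id filter wins by order),
  # then 3 multiples, none unknown
  expect_identical(res$exclusions$n_removed, c(2L, 3L, 0L))
  expect_identical(res$n_kept, 5L)
  expect_identical(sum(res$exclusions$n_removed) + res$n_kept, res$n_input)
  expect_identical(res$records$mother_id, sprintf("m%d", 4:8))

  clean <- tibble::tibble(mother_id = c("a", "b"), plurality = "singleton")
  res2 <- apply_eligibility(clean)
  expect_identical(res2$exclusions$n_removed, c(0L, 0L, 0L))
  expect_identical(res2$n_kept, 2L)

  res3 <- apply_eligibility(clean[0, ])
  expect_identical(res3$n_kept, 0L)
  expect_identical(res3$exclusions$n_removed, c(0L, 0L, 0L))
})

test_that("registry CSV round-trips outcome vectors exactly", {
  reg <- small_registry(n_mothers = 40, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_identical(back$preterm, reg$preterm)
  expect_identical(back$perinatal_death, reg$perinatal_death)
  expect_identical(
    encode_cooccurrence(back$preterm, back$perinatal_death),
    encode_cooccurrence(reg$preterm, reg$perinatal_death)
  )
  expect_equal(back$gestational_age_weeks, reg$gestational_age_weeks)
})

test_that("validation rejects undeclared categories and broken birth indices", {
  reg <- small_registry(n_mothers = 20, seed = 4)
  bad <- reg
  bad$anc_visits <- as.character(bad$anc_visits)
  bad$anc_visits[1] <- "sometimes"
  expect_error(validate_registry(bad), "undeclared categories")

  bad2 <- reg
  bad2$birth_index[1] <- 99L
  expect_error(validate_registry(bad2), "birth_index")

  bad3 <- reg
  bad3$gestational_age_weeks[2] <- 10
  expect_error(validate_registry(bad3), "plausibility")

  expect_silent(validate_registry(reg))
})

test_that("both maternal-age partitions are supported by the code book", {
  expect_identical(bin_maternal_age(c(17, 22, 27, 32, 37, 45)),
                   c("15-19", "20-24", "25-29", "30-34", "35-39", "40+"))
  expect_identical(bin_maternal_age(c(27, 32), scheme = "descriptive"),
                   c("25-34", "25-34"))
  cb_m <- covariate_codebook("model")
  cb_d <- covariate_codebook("descriptive")
  expect_true("25-29" %in% cb_m$levels[[match("maternal_age", cb_m$covariate)]])
  expect_true("25-34" %in% cb_d$levels[[match("maternal_age", cb_d$covariate)]])
  df <- tibble::tibble(mother_id = "a", maternal_age = "25-34")
  expect_silent(validate_registry(df, age_scheme = "either"))
  expect_error(validate_registry(df, age_scheme = "model"), "undeclared")
})

test_that("eligibility report serializes the exclusion tally", {
  df <- tibble::tibble(mother_id = c("a", NA), plurality = "singleton")
  res <- apply_eligibility(df)
  path <- withr::local_tempfile(fileext = ".json")
  write_eligibility_report(res, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$n_input, 2)
  expect_equal(rep$n_kept, 1)
  expect_equal(length(rep$exclusions), 3)
})

test_that("summary-count expansion reproduces totals, events and NA remainders", {
  counts <- tibble::tibble(category = c("a", "b"), total = c(10L, 5L),
                           events = c(4L, 1L))
  rec <- expand_summary_counts(counts, "grp", "y",
                               overall_total = 18, overall_events = 6)
  expect_identical(nrow(rec), 18L)
  expect_identical(sum(rec$y), 6L)
  expect_identical(sum(is.na(rec$grp)), 3L)
  expect_identical(sum(rec$y[rec$grp == "a"], na.rm = TRUE), 4L)
})
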