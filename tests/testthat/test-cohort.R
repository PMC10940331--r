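test_that("cohort CSV round-trip is the identity on validated cohorts", {
  g <- generate_cohort(cohort_sim_config(n = 20, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(g$cohort, f)
  back <- read_cohort_csv(f)
  expect_identical(back$patients$patient_id, g$cohort$patients$patient_id)
  expect_identical(back$patients$impaired, g$cohort$patients$impaired)
  expect_identical(back$patients$income, g$cohort$patients$income)
  expect_identical(back$patients$education, g$cohort$patients$education)
  expect_identical(back$responses, g$cohort$responses)
  expect_equal(back$rt$DCCS, g$cohort$rt$DCCS, tolerance = 1e-12)
})

test_that("an empty data section reads as an empty cohort", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(mycog:::cohort_columns(), collapse = ","), f)
  expect_equal(length(read_cohort_csv(f)), 0)
})

test_that("a single all-correct row yields one record without missingness", {
  co <- tiny_cohort(n = 1)
  co$responses <- lapply(co$responses, function(m) {
    m[] <- 1L
    m
  })
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cog_cohort(co$patients, co$responses, co$rt), f)
  back <- read_cohort_csv(f)
  expect_equal(length(back), 1)
  expect_false(anyNA(unlist(back$responses)))
  expect_equal(sum(unlist(back$responses)), 266)
})

test_that("cohort validation rejects malformed input", {
  co <- tiny_cohort()
  bad <- co$responses
  bad$DCCS <- bad$DCCS[, 1:29]
  expect_error(cog_cohort(co$patients, bad, co$rt), "DCCS")
  bad <- co$responses
  bad$ARW[1, 1] <- NA_integer_
  expect_error(cog_cohort(co$patients, bad, co$rt), "missing")
  rt <- co$rt; rt$PSM[2] <- -1
  expect_error(cog_cohort(co$patients, co$responses, rt), "positive")
  bad <- co$responses
  bad$PSM[2, 3] <- 2L
  expect_error(cog_cohort(co$patients, bad, co$rt), "0, 1 or missing")
})

test_that("malformed CSV cells are reported with row and column", {
  co <- tiny_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  d <- read.csv(f, check.names = FALSE, colClasses = "character")
  d$DCCS_3[2] <- "7"
  write.csv(d, f, row.names = FALSE)
  expect_error(read_cohort_csv(f), "row 2.*DCCS_3")
})

test_that("Cronbach's alpha follows its defining formula", {
  # two identical items with nonzero variance: perfect consistency
  x <- cbind(c(0, 1, 1, 0, 1), c(0, 1, 1, 0, 1))
  expect_equal(cronbach_alpha(x), 1)
  # unit variances, covariance 0.5: alpha = 2 * (1 - 2/3) = 2/3
  x <- cbind(c(0, 1, 2), c(0, 2, 1))
  expect_equal(cronbach_alpha(x), 2 / 3)
  # alpha never exceeds 1
  set.seed(42)
  for (k in 1:20) {
    m <- matrix(rbinom(60, 1, runif(1, 0.3, 0.7)), nrow = 10)
    a <- cronbach_alpha(m)
    if (!is.na(a)) expect_lte(a, 1)
  }
})

test_that("cohort summaries report self-correlation 1 and per-instrument alpha", {
  g <- generate_cohort(cohort_sim_config(n = 40, seed = 8))
  s <- summarize_cohort(g$cohort)
  expect_true(all(abs(diag(s$correlations) - 1) < 1e-12))
  expect_named(s$alpha, instrument_names())
  expect_true(all(s$alpha[c("DCCS", "PSM", "ARW")] > 0, na.rm = TRUE))
  expect_true(s$variance_defined)
})

test_that("a single-patient summary flags variance statistics as undefined", {
  s <- summarize_cohort(tiny_cohort(n = 1))
  expect_false(s$variance_defined)
  expect_true(all(is.na(s$alpha)))
  expect_null(s$correlations)
  expect_equal(s$n, 1)
})

test_that("the packaged printed score table loads with its documented shape", {
  fx <- load_printed_fixture()
  expect_equal(nrow(fx), 86)
  expect_equal(sum(fx$impaired), 19)
  expect_equal(sum(fx$impaired == 0), 67)
  for (col in c("pd_composite3_rf", "pd_ssho2d_linear",
                "pd_composite5_linear", "pd_f16"))
    expect_true(all(fx[[col]] %in% 0:1))
  expect_equal(fx$ssho2d[1], 0.229)
  expect_equal(fx$age[1], 77)
})
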