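test_that("write-then-read round-trips a cohort", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_patients = 3, seed = 4))
  write_cohort(sim$cohort, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$admissions), 3)
  expect_equal(back$admissions$patient_id, sim$cohort$admissions$patient_id)
  expect_equal(back$measurements$value, sim$cohort$measurements$value)
  expect_equal(as.numeric(back$measurements$time),
               as.numeric(sim$cohort$measurements$time))
  expect_equal(nrow(back$errors), 0)
  # a second write of the re-read cohort is byte-identical
  dir2 <- withr::local_tempdir()
  write_cohort(back, dir2)
  for (f in c("admissions.csv", "measurements.csv", "exposures.csv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("nonpositive creatinine rows are reported with row numbers, not dropped silently", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_patients = 2, seed = 4))
  sim$cohort$measurements$value[sim$cohort$measurements$analyte == "scr"][2] <- -1
  write_cohort(sim$cohort, dir)
  back <- read_cohort(dir)
  expect_gte(nrow(back$errors), 1)
  expect_true(any(grepl("nonpositive SCr", back$errors$message)))
  expect_false(any(back$measurements$value[back$measurements$analyte == "scr"] <= 0))
})

test_that("header-only files give an empty cohort with zero errors", {
  dir <- withr::local_tempdir()
  writeLines("patient_id,age,sex,admit_time,discharge_time,height,weight",
             file.path(dir, "admissions.csv"))
  writeLines("patient_id,analyte,time,value", file.path(dir, "measurements.csv"))
  writeLines(paste(c("patient_id", "day", wardaki:::EXPOSURE_FLAGS), collapse = ","),
             file.path(dir, "exposures.csv"))
  cohort <- read_cohort(dir)
  expect_equal(nrow(cohort$admissions), 0)
  expect_equal(nrow(cohort$measurements), 0)
  expect_equal(nrow(cohort$errors), 0)
})

test_that("missing mandatory columns raise a schema error", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,age", "X,40"), file.path(dir, "admissions.csv"))
  writeLines("patient_id,analyte,time,value", file.path(dir, "measurements.csv"))
  expect_error(read_cohort(dir), "missing mandatory column")
})

test_that("site column names map through the config", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_patients = 2, seed = 4))
  write_cohort(sim$cohort, dir)
  adm <- utils::read.csv(file.path(dir, "admissions.csv"))
  names(adm)[names(adm) == "patient_id"] <- "MRN"
  utils::write.csv(adm, file.path(dir, "admissions.csv"), row.names = FALSE)
  cohort <- read_cohort(dir, config = list(admissions = c(patient_id = "MRN")))
  expect_equal(cohort$admissions$patient_id, sim$cohort$admissions$patient_id)
})

test_that("eligibility rules fire in order and the report reconciles", {
  d <- demo_cohort()
  # add an 18-year-old and a patient with missing sex
  extra <- d$cohort$admissions[7:8, ]
  extra$patient_id <- c("YOUNG", "NOSEX")
  extra$age <- c(18, 50)
  extra$sex <- c("male", NA)
  d$cohort$admissions <- rbind(d$cohort$admissions, extra)
  mk <- function(pid) {
    m <- d$cohort$measurements[d$cohort$measurements$patient_id == "CTRL", ]
    m$patient_id <- pid
    m
  }
  d$cohort$measurements <- rbind(d$cohort$measurements, mk("YOUNG"), mk("NOSEX"))
  res <- apply_eligibility(d$cohort)
  r <- res$report
  expect_equal(r$age_below_19, 1)
  expect_equal(r$fewer_than_3_scr, 1) # TWOSCR
  expect_equal(r$day1_aki, 1)         # DAY1
  expect_equal(r$unevaluable, 1)      # NOSEX
  expect_equal(r$age_below_19 + r$fewer_than_3_scr + r$low_first_day_egfr +
                 r$day1_aki + r$unevaluable + r$retained, r$input_total)
  expect_false("DAY1" %in% res$cohort$admissions$patient_id)
})

test_that("a patient with two SCr measurements is excluded", {
  d <- demo_cohort()
  res <- apply_eligibility(d$cohort)
  expect_true("TWOSCR" %in% res$report$excluded_patients$patient_id)
  expect_equal(res$report$excluded_patients$reason[
    res$report$excluded_patients$patient_id == "TWOSCR"], "fewer_than_3_scr")
})

test_that("a low first-day eGFR excludes the patient", {
  d <- demo_cohort()
  # make CTRL's first-day SCr high enough that eGFR <= 60 (female, 35 y)
  sel <- d$cohort$measurements$patient_id == "CTRL" &
    d$cohort$measurements$analyte == "scr"
  d$cohort$measurements$value[sel][1] <- 1.6
  res <- apply_eligibility(d$cohort)
  expect_true("CTRL" %in% res$report$excluded_patients$patient_id)
})

test_that("eligibility filtering is idempotent", {
  sim <- simulate_cohort(sim_config(n_patients = 60, seed = 8))
  once <- apply_eligibility(sim$cohort)
  twice <- apply_eligibility(once$cohort)
  expect_equal(twice$report$retained, once$report$retained)
  expect_equal(sort(twice$cohort$admissions$patient_id),
               sort(once$cohort$admissions$patient_id))
})

test_that("day-1 onsets planted in a cohort are excluded under the day-1 rule", {
  sim <- simulate_cohort(sim_config(n_patients = 100, seed = 17,
                                    scr_sample_prob = 1))
  # shift every true-AKI patient's onset to day 1 by trimming the pre-onset
  # days is intrusive; instead verify against a brute-force scan of who has
  # a refined onset on day 1
  ref <- detect_aki_cohort(sim$cohort, "refined")
  expected <- sum(ref$aki & ref$onset_day == 1, na.rm = TRUE)
  res <- apply_eligibility(sim$cohort)
  expect_equal(res$report$day1_aki, expected)
})
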