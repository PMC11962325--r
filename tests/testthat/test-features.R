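day0 <- as.POSIXct("2021-02-01 07:00:00", tz = "UTC")

tiny_cohort <- function() {
  adm <- data.frame(patient_id = "X", age = 60, sex = "male",
                    admit_time = day0,
                    discharge_time = day0 + 11 * 86400 + 8 * 3600,
                    height = 175, weight = 70)
  mea <- rbind(
    data.frame(patient_id = "X", analyte = "heart_rate",
               time = day0 + c(1, 5, 9) * 3600, value = c(60, 80, 100)),
    data.frame(patient_id = "X", analyte = "scr",
               time = day0 + c(2, 26, 50) * 3600, value = c(0.8, 1.0, 1.3)),
    data.frame(patient_id = "X", analyte = "bun",
               time = day0 + 2 * 3600, value = 18))
  expo <- data.frame(patient_id = "X", day = as.Date("2021-02-03"))
  for (f in wardaki:::EXPOSURE_FLAGS) expo[[f]] <- f == "surgery"
  structure(list(admissions = adm, measurements = mea, exposures = expo,
                 errors = data.frame()), class = "ward_cohort")
}

test_that("vitals aggregate per day as mean/max/min/count", {
  ft <- summarize_days(tiny_cohort())
  d1 <- ft[ft$day == 1, ]
  expect_equal(d1$heart_rate_mean, 80)
  expect_equal(d1$heart_rate_max, 100)
  expect_equal(d1$heart_rate_min, 60)
  expect_equal(d1$heart_rate_count, 3)
  d2 <- ft[ft$day == 2, ]
  expect_equal(d2$heart_rate_count, 0)
  expect_true(is.na(d2$heart_rate_mean))
})

test_that("labs carry forward as most recent value and feed derived features", {
  ft <- summarize_days(tiny_cohort())
  expect_equal(ft$scr[1:4], c(0.8, 1.0, 1.3, 1.3))
  prov <- attr(ft, "provenance")
  expect_equal(unname(prov[1:4, "scr"]),
               c("observed", "observed", "observed", "missing"))
  expect_equal(ft$bun_cr_ratio[1], 18 / 0.8)
  expect_equal(ft$egfr[1], compute_egfr(0.8, 60, "male"))
})

test_that("exposure flags persist over the trailing 7 days", {
  ft <- summarize_days(tiny_cohort())
  expect_equal(ft$surgery, c(FALSE, FALSE, rep(TRUE, 7), FALSE, FALSE, FALSE))
})

test_that("negative vital measurements are a validation error", {
  co <- tiny_cohort()
  co$measurements$value[1] <- -10
  expect_error(summarize_days(co), "negative vital")
})

test_that("deltas subtract the median of previous observed values", {
  co <- tiny_cohort()
  co$measurements <- rbind(co$measurements,
                           data.frame(patient_id = "X", analyte = "scr",
                                      time = day0 + 74 * 3600, value = 1.3))
  ft <- compute_deltas(summarize_days(co))
  # day 2: history {0.8}; day 3: history {0.8, 1.0} -> median 0.9
  expect_true(is.na(ft$delta_scr[1]))
  expect_equal(ft$delta_scr[2], 1.0 - 0.8)
  expect_equal(ft$delta_scr[3], 1.3 - 0.9)
  expect_equal(ft$delta_scr[4], 1.3 - 1.0) # history {0.8, 1.0, 1.3}
  # day 5 carries 1.3 forward; its history is the observed days only
  expect_equal(ft$delta_scr[5], 1.3 - median(c(0.8, 1.0, 1.3, 1.3)))
})

test_that("imputation routes features by missingness and records provenance", {
  set.seed(1)
  n <- 40
  tab <- data.frame(patient_id = rep(sprintf("P%02d", 1:10), each = 4),
                    day = rep(1:4, 10),
                    full = rnorm(n), low_miss = rnorm(n), high_miss = rnorm(n),
                    aux = rnorm(n))
  # place NAs on first days / whole patients so carry-forward cannot fill them
  tab$low_miss[tab$day == 1 & tab$patient_id %in% c("P01", "P02")] <- NA  # 5%
  tab$high_miss[tab$patient_id %in% sprintf("P%02d", 1:4)] <- NA          # 40%
  prov <- matrix("observed", n, 3,
                 dimnames = list(NULL, c("full", "low_miss", "high_miss")))
  prov[is.na(tab$low_miss), "low_miss"] <- "missing"
  prov[is.na(tab$high_miss), "high_miss"] <- "missing"
  attr(tab, "provenance") <- prov
  # block LOCF from resolving anything: put NAs on each patient's first day
  out <- impute_features(tab, train_ids = sprintf("P%02d", 1:10),
                         features = c("full", "low_miss", "high_miss"),
                         seed = 2)
  expect_true(is.numeric(out$low_miss))
  expect_false(any(is.na(out$low_miss)))
  expect_true(is.factor(out$high_miss))
  expect_true("missing" %in% levels(out$high_miss))
  expect_equal(attr(out, "categorised"), "high_miss")
  # fully observed feature untouched
  expect_identical(out$full, tab$full)
  p2 <- attr(out, "provenance")
  expect_true(all(p2[, "full"] == "observed"))
  expect_true(all(p2 %in% c("observed", "carried", "imputed", "missing_level", "missing")))
})

test_that("imputation is deterministic under a fixed seed", {
  set.seed(3)
  tab <- data.frame(patient_id = rep(sprintf("P%02d", 1:8), each = 5),
                    day = rep(1:5, 8), a = rnorm(40), b = rnorm(40))
  tab$a[sample(40, 4)] <- NA
  a1 <- impute_features(tab, sprintf("P%02d", 1:8), features = c("a", "b"), seed = 7)
  a2 <- impute_features(tab, sprintf("P%02d", 1:8), features = c("a", "b"), seed = 7)
  expect_identical(a1$a, a2$a)
})

test_that("no evaluation-split statistic influences the transform", {
  set.seed(4)
  tab <- data.frame(patient_id = rep(sprintf("P%02d", 1:10), each = 4),
                    day = rep(1:4, 10), a = rnorm(40), b = rnorm(40))
  tab$a[c(2, 7, 30)] <- NA
  train <- sprintf("P%02d", 1:6)
  out1 <- impute_features(tab, train, features = c("a", "b"), seed = 5)
  # perturb the evaluation rows wildly; train-side results must not move
  tab2 <- tab
  evalrows <- !tab2$patient_id %in% train
  tab2$a[evalrows & !is.na(tab2$a)] <- tab2$a[evalrows & !is.na(tab2$a)] + 100
  tab2$b[evalrows] <- tab2$b[evalrows] - 50
  out2 <- impute_features(tab2, train, features = c("a", "b"), seed = 5)
  trrows <- tab$patient_id %in% train
  expect_identical(out1$a[trrows], out2$a[trrows])
  sc1 <- fit_scaler(out1, train, features = c("a", "b"))
  sc2 <- fit_scaler(out2, train, features = c("a", "b"))
  expect_identical(sc1$center, sc2$center)
  expect_identical(sc1$scale, sc2$scale)
})

test_that("robust scaling centres at the training median and unit-IQR", {
  tab <- data.frame(patient_id = sprintf("P%d", 1:5), day = 1, x = 1:5)
  st <- fit_scaler(tab, tab$patient_id, features = "x")
  expect_equal(unname(st$center["x"]), 3)
  scaled <- apply_scaler(tab, st)
  expect_equal(scaled$x[3], 0)
  expect_equal(apply_scaler(data.frame(patient_id = "Q", day = 1, x = 5), st)$x,
               (5 - 3) / st$scale[["x"]])
})

test_that("constant features are flagged and passed through unscaled", {
  tab <- data.frame(patient_id = sprintf("P%d", 1:4), day = 1, x = rep(2, 4))
  st <- fit_scaler(tab, tab$patient_id, features = "x")
  expect_true(st$constant[["x"]])
  expect_equal(apply_scaler(tab, st)$x, rep(2, 4))
})

test_that("scaler state serialises to JSON and reloads bit-exactly", {
  set.seed(6)
  tab <- data.frame(patient_id = sprintf("P%d", 1:9), day = 1,
                    x = rnorm(9), y = runif(9))
  st <- fit_scaler(tab, tab$patient_id, features = c("x", "y"))
  path <- withr::local_tempfile(fileext = ".json")
  write_scaler(st, path)
  st2 <- read_scaler(path)
  expect_identical(st$center, st2$center)
  expect_identical(st$scale, st2$scale)
  expect_identical(apply_scaler(tab, st), apply_scaler(tab, st2))
})
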