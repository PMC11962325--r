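test_that("the metric panel matches brute-force confusion arithmetic", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 200
    labels <- rbinom(n, 1, 0.3)
    scores <- pmin(pmax(labels * 0.3 + runif(n, 0, 0.7), 0), 1)
    r <- metric_panel(labels, scores)
    b <- brute_metrics(labels, scores)
    expect_equal(r$accuracy, b$accuracy)
    expect_equal(r$precision, b$precision)
    expect_equal(r$recall, b$recall)
    expect_equal(r$specificity, b$specificity)
    expect_equal(unname(r$confusion["tp"]), b$tp)
    expect_equal(r$auroc, brute_auroc(labels, scores), tolerance = 1e-10)
  }
})

test_that("an all-zero predictor on 10% positives scores accuracy 0.9, recall 0", {
  labels <- rep(c(1, 0), c(10, 90))
  r <- metric_panel(labels, rep(0, 100))
  expect_equal(r$accuracy, 0.9)
  expect_equal(r$recall, 0)
  expect_true(is.na(r$precision))
})

test_that("AUROC is invariant to strictly monotone transforms of the scores", {
  set.seed(15)
  labels <- rbinom(300, 1, 0.4)
  scores <- runif(300)
  a0 <- metric_panel(labels, scores)$auroc
  for (f in list(function(x) x^3, function(x) plogis(5 * x - 2),
                 function(x) exp(x))) {
    expect_equal(metric_panel(labels, f(scores))$auroc, a0, tolerance = 1e-12)
  }
})

test_that("AUPRC warns and returns NA with no positive labels", {
  expect_warning(r <- metric_panel(rep(0, 50), runif(50)), "AUPRC")
  expect_true(is.na(r$auprc))
})

test_that("identical predictions and labels flag a degenerate calibration fit", {
  labels <- rep(c(0, 1), 50)
  r <- metric_panel(labels, labels)
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  # many ties: bins can share the same mean prediction only in the flat case
  r2 <- metric_panel(labels, rep(0.5, 100))
  expect_true(r2$calibration$degenerate)
})

test_that("patient-grouped folds never split a patient", {
  set.seed(16)
  ids <- rep(sprintf("P%03d", 1:40), times = sample(1:6, 40, replace = TRUE))
  folds <- wardaki:::grouped_folds(ids, 5, seed = 3)
  expect_true(all(tapply(folds, ids, function(x) length(unique(x))) == 1))
  expect_equal(sort(unique(folds)), 1:5)
})

test_that("perfectly separable features reach AUROC 1 and F1 1 in CV", {
  set.seed(17)
  n <- 400
  df <- data.frame(patient_id = sprintf("P%03d", 1:n),
                   label = rep(0:1, each = n / 2))
  df$x <- df$label * 2 + runif(n, -0.5, 0.5)
  # glm legitimately warns about fitted probabilities of 0/1 under separation
  m <- suppressWarnings(train_models(df, "x", model = "logistic",
                                     n_folds = 5, seed = 4))
  expect_equal(unname(m$cv$mean["auroc"]), 1, tolerance = 1e-9)
  expect_equal(unname(m$cv$mean["f1"]), 1, tolerance = 1e-9)
})

test_that("labels independent of features give AUROC near one half", {
  set.seed(18)
  n <- 3000
  df <- data.frame(patient_id = sprintf("P%04d", 1:n),
                   label = rbinom(n, 1, 0.5), x = rnorm(n))
  m <- train_models(df, "x", model = "logistic", n_folds = 5, seed = 5)
  se <- sqrt(1 / (12 * n / 5)) # coarse SE of AUROC at balanced classes
  expect_lt(abs(m$cv$mean[["auroc"]] - 0.5), 5 * se + 0.03)
})

test_that("logistic training recovers known generating coefficients within 2 SE", {
  set.seed(19)
  n <- 2500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  df <- data.frame(patient_id = sprintf("P%04d", 1:n), label = y, x = x)
  m <- train_models(df, "x", model = "logistic", n_folds = 5, seed = 6)
  co <- summary(m$fit)$coefficients
  expect_lt(abs(co["x", "Estimate"] - 0.8), 2 * co["x", "Std. Error"])
  expect_lt(abs(co["(Intercept)", "Estimate"] + 1),
            2 * co["(Intercept)", "Std. Error"])
})

test_that("a single-class training fold is an explicit error naming the fold", {
  df <- data.frame(patient_id = sprintf("P%02d", 1:10),
                   label = c(1, rep(0, 9)), x = rnorm(10))
  expect_error(train_models(df, "x", model = "logistic", n_folds = 5, seed = 1),
               "fold")
})

test_that("evaluation on overlapping patients is refused", {
  set.seed(20)
  df <- data.frame(patient_id = sprintf("P%03d", 1:100),
                   label = rbinom(100, 1, 0.5), x = rnorm(100))
  m <- train_models(df, "x", model = "logistic", n_folds = 5, seed = 2)
  expect_error(evaluate_model(m, df[1:10, ]), "overlap")
  expect_silent(r <- evaluate_model(m, transform(df, patient_id = paste0("Q", patient_id))))
  expect_s3_class(r, "eval_report")
})

test_that("a well-calibrated synthetic predictor has slope near 1", {
  set.seed(22)
  n <- 4000
  scores <- rbeta(n, 2, 5)
  labels <- rbinom(n, 1, scores)
  r <- metric_panel(labels, scores)
  expect_gt(r$calibration$slope, 0.85)
  expect_lt(r$calibration$slope, 1.15)
})

test_that("the framework simulation counts early predictions per period", {
  # hand-built multi-year labeled table: 30 events/year, 3 pre-onset days each
  day0 <- as.POSIXct("2016-06-01 07:00:00", tz = "UTC")
  mk_year <- function(year, n_ev, n_ctl) {
    ids <- sprintf("E%d_%02d", year, seq_len(n_ev + n_ctl))
    adm <- data.frame(patient_id = ids, admit_time = as.POSIXct(
      sprintf("%d-06-01 07:00:00", year), tz = "UTC"))
    lab <- do.call(rbind, lapply(seq_along(ids), function(k) {
      is_ev <- k <= n_ev
      data.frame(patient_id = ids[k], day = 1:6,
                 label = if (is_ev) c("0", "0", "0", "1", "1", "1") else rep("0", 6))
    }))
    ev <- data.frame(patient_id = ids[seq_len(n_ev)], aki = TRUE, onset_day = 7)
    list(adm = adm, lab = lab, ev = ev)
  }
  years <- lapply(2016:2018, mk_year, n_ev = 30, n_ctl = 20)
  adm <- do.call(rbind, lapply(years, `[[`, "adm"))
  lab <- do.call(rbind, lapply(years, `[[`, "lab"))
  ev <- do.call(rbind, lapply(years, `[[`, "ev"))
  # oracle predictor: flags exactly the labeled days
  oracle <- function(dt) as.numeric(dt$label == "1")
  fs <- run_framework_sim(lab, ev, adm, oracle)
  expect_equal(fs$n_events, rep(30, 3))
  expect_equal(fs$n_predicted_early, rep(30, 3))
  expect_equal(fs$f1, rep(1, 3))
  # random predictor: early-prediction rate approximates 1 - (1 - q)^3
  set.seed(23)
  q <- 0.4
  rand <- function(dt) ifelse(runif(nrow(dt)) < q, 1, 0)
  fs2 <- run_framework_sim(lab, ev, adm, rand)
  rate <- sum(fs2$n_predicted_early) / sum(fs2$n_events)
  expected <- 1 - (1 - q)^3
  se <- sqrt(expected * (1 - expected) / sum(fs2$n_events))
  expect_lt(abs(rate - expected), 4 * se)
  # a period with zero events reports NA f1
  ev3 <- ev[ev$patient_id %in% years[[1]]$ev$patient_id, ]
  lab3 <- lab
  lab3$label[!lab3$patient_id %in% ev3$patient_id] <- "0"
  fs3 <- run_framework_sim(lab3, ev3, adm, oracle)
  expect_equal(fs3$n_events[fs3$period == 2018], 0)
  expect_true(is.na(fs3$f1[fs3$period == 2018]))
})
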