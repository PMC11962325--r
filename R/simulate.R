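#' Configuration for the synthetic ward-cohort generator
#'
#' Defaults emulate the cohort properties of a general-ward population:
#' median stay ~10 days (log-normal), AKI onset median ~day 7, ~8% of
#' patients developing AKI of whom ~15% progress to AKD, plus a
#' transient-fluctuation class (~6%) that the standard KDIGO criteria call
#' AKI but the refined criteria do not. Patient class probabilities are
#' linked to covariates through a logistic model:
#' logit(p_AKI) = logit(`frac_aki`) + `beta_age` x (age - 47) +
#' `beta_nephrotoxic` x I(nephrotoxic exposure in the first week).
#'
#' @param n_patients Number of admissions.
#' @param seed Integer seed; each patient uses a named substream derived from
#'   it, so enlarging the cohort never perturbs earlier patients.
#' @param stay_meanlog,stay_sdlog Log-normal stay-length parameters (days).
#' @param min_stay Minimum stay (days).
#' @param frac_no_aki,frac_transient,frac_aki_recovered,frac_aki_akd Event-mix
#'   fractions (must sum to 1). `frac_transient` splits into a low-baseline
#'   (< 0.6 mg/dL) fluctuation pattern and a dip-then-return pattern in
#'   proportion `transient_dip_share`.
#' @param transient_dip_share Share of transient patients with the
#'   dip-then-return pattern (default 1/3).
#' @param scr_sample_prob Per-day Bernoulli probability of an SCr measurement.
#' @param event_sample_prob Sampling probability on days around a planted
#'   event (ward practice measures sick patients more).
#' @param jitter_sd Gaussian measurement jitter SD for SCr (mg/dL).
#' @param onset_lambda Onset day = 2 + Poisson(`onset_lambda`) (median ~7).
#' @param beta_age,beta_nephrotoxic Logistic covariate coefficients (per year
#'   of age over 47; per nephrotoxic-exposure indicator).
#' @param lab_noise_sd Relative noise SD for non-SCr labs/vitals.
#' @param admit_span_years Admission dates are spread uniformly over this
#'   many years from `start_date` (enables the yearly framework simulation).
#' @param start_date First possible admission date.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000, seed = 1,
                       stay_meanlog = log(10), stay_sdlog = 0.55, min_stay = 4,
                       frac_no_aki = 0.86, frac_transient = 0.06,
                       frac_aki_recovered = 0.068, frac_aki_akd = 0.012,
                       transient_dip_share = 1 / 3,
                       scr_sample_prob = 0.7, event_sample_prob = 0.95,
                       jitter_sd = 0.05, onset_lambda = 5,
                       beta_age = 0.02, beta_nephrotoxic = 0.5,
                       lab_noise_sd = 0.08, admit_span_years = 5,
                       start_date = as.Date("2016-01-01")) {
  fr <- c(frac_no_aki, frac_transient, frac_aki_recovered, frac_aki_akd)
  if (abs(sum(fr) - 1) > 1e-8) stop("event-mix fractions must sum to 1", call. = FALSE)
  if (any(fr < 0)) stop("fractions must be nonnegative", call. = FALSE)
  if (jitter_sd < 0 || lab_noise_sd < 0) stop("noise SDs must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

patient_seed <- function(seed, i) (abs(seed) + i * 7919L) %% 2147483629L

# sample() collapses a length-1 vector to 1:n; pick uniformly from the set
pick <- function(x) x[sample.int(length(x), 1)]

# Days that must carry an SCr measurement for the planted event pattern to
# be observable (the generator also boosts sampling around events).
forced_days <- function(class, stay, onset) {
  if (is.na(onset)) return(integer())
  switch(class,
         aki_recovered = ,
         aki_akd = intersect(seq(onset - 1L, min(stay, onset + 7L)), seq_len(stay)),
         transient_low = intersect(seq(onset - 2L, onset + 1L), seq_len(stay)),
         transient_dip = seq(onset - 1L, onset + 1L),
         integer())
}

# One patient's daily true-SCr curve. Event-day values are planted with
# explicit margins against the detector thresholds so ground truth is
# recoverable by construction under daily sampling; the transient spike is
# planted relative to the minimum of the *sampled* prior-window values, i.e.
# exactly the baseline the detector will see (see the methods vignette for
# the margin arithmetic).
plant_trajectory <- function(class, stay, baseline, onset, recovery_day,
                             jitter_sd, sampled) {
  v <- baseline + stats::rnorm(stay, 0, jitter_sd)
  if (class %in% c("aki_recovered", "aki_akd")) {
    peak <- 1.8 * baseline + 0.2
    plateau <- function(k) pmax(1.5 * baseline + 0.15,
                                peak - 0.05 * k + stats::rnorm(length(k), 0, jitter_sd))
    v[onset] <- peak
    post <- seq(onset + 1L, stay)
    if (class == "aki_recovered") {
      elev <- post[post < onset + recovery_day]
      v[elev] <- plateau(elev - onset)
      rec_idx <- onset + recovery_day
      v[rec_idx] <- pmax(0.3, 0.85 * baseline + stats::rnorm(1, 0, jitter_sd / 2))
      later <- post[post > rec_idx]
      v[later] <- baseline + stats::rnorm(length(later), 0, jitter_sd)
    } else {
      v[post] <- plateau(post - onset)
    }
  } else if (class == "transient_low") {
    # spike clearing 1.5 x the realized sampled prior minimum m (fires the
    # standard relative criterion) while the absolute rise max(0.26, m/2 +
    # 0.01) stays below 0.3 for the low baselines drawn here
    win <- seq(max(1, onset - 6L), onset - 1L)
    m <- min(v[win[sampled[win]]])
    v[onset] <- max(m + 0.26, 1.5 * m + 0.01)
  } else if (class == "transient_dip") {
    v[onset - 1L] <- baseline
    v[onset] <- baseline - 0.45
    v[onset + 1L] <- baseline
  }
  pmax(v, 0.2)
}

#' Simulate a synthetic ward cohort with planted ground truth
#'
#' Generates admissions, irregularly sampled SCr (plus lab/vital) series and
#' daily exposure flags in the exact schema [read_cohort()] consumes, with a
#' per-patient ground-truth table. Trajectories are piecewise processes:
#' stable baseline with Gaussian jitter; AKI patients get a step rise at
#' onset reaching well beyond max(1.5 x baseline, baseline + 0.3 mg/dL),
#' followed by exponential-like decay below 1.5 x baseline at the planted
#' recovery day (recoverers) or a persistent plateau (AKD); transient
#' patients get either a low-baseline (< 0.6 mg/dL) spike crossing 1.5 x
#' with an absolute rise < 0.3, or a dip-then-return pattern. Identical
#' config (including seed) yields identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `cohort` (a `ward_cohort`) and
#'   `truth` (data.frame `patient_id`, `class`, `onset_day`, `recovery_day`,
#'   `baseline`, `sex`, `age`). `class` is one of `no_aki`, `transient_low`,
#'   `transient_dip`, `aki_recovered`, `aki_akd`; under the refined criteria
#'   only the latter two are AKI.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  adm_l <- list(); mea_l <- list(); exp_l <- list(); tr_l <- list()
  p_aki0 <- config$frac_aki_recovered + config$frac_aki_akd
  p_akd_given_aki <- if (p_aki0 > 0) config$frac_aki_akd / p_aki0 else 0
  for (i in seq_len(config$n_patients)) {
    set.seed(patient_seed(config$seed, i))
    pid <- sprintf("P%05d", i)
    sex <- sample(c("female", "male"), 1)
    age <- sample(19:75, 1)
    stay <- max(config$min_stay,
                round(stats::rlnorm(1, config$stay_meanlog, config$stay_sdlog)))
    admit_date <- config$start_date +
      floor(stats::runif(1, 0, config$admit_span_years * 365.25 - stay - 1))
    admit_time <- as.POSIXct(paste(admit_date, "07:00:00"), tz = "UTC")
    discharge_time <- admit_time + (stay - 1) * SECONDS_PER_DAY + 11 * SECONDS_PER_HOUR

    # daily exposure flags; nephrotoxic antibiotics feed the risk link
    expo <- matrix(stats::runif(stay * length(EXPOSURE_FLAGS)) < 0.04,
                   nrow = stay, dimnames = list(NULL, EXPOSURE_FLAGS))
    nephro_week1 <- any(expo[seq_len(min(7, stay)), "nephrotoxic_abx"])

    p_aki <- stats::plogis(stats::qlogis(max(p_aki0, 1e-12)) +
                             config$beta_age * (age - 47) +
                             config$beta_nephrotoxic * nephro_week1)
    if (p_aki0 == 0) p_aki <- 0
    u <- stats::runif(1)
    class <- if (u < p_aki) {
      if (stats::runif(1) < p_akd_given_aki) "aki_akd" else "aki_recovered"
    } else if (u < p_aki + config$frac_transient) {
      if (stats::runif(1) < config$transient_dip_share) "transient_dip" else "transient_low"
    } else "no_aki"

    onset <- NA_integer_; recovery_day <- NA_integer_
    if (class %in% c("aki_recovered", "aki_akd")) {
      onset <- 2L + stats::rpois(1, config$onset_lambda)
      stay <- max(stay, onset + 8L) # AKI prolongs the stay; keeps outcome observable
      discharge_time <- admit_time + (stay - 1) * SECONDS_PER_DAY + 11 * SECONDS_PER_HOUR
      if (class == "aki_recovered") {
        recovery_day <- sample(3:7, 1, prob = c(0.15, 0.2, 0.3, 0.2, 0.15))
      }
      baseline <- round(stats::runif(1, 0.6, if (sex == "female") 1.0 else 1.15), 2)
    } else if (class == "transient_low") {
      onset <- pick(3:max(3, stay - 1))
      baseline <- round(stats::runif(1, 0.40, 0.50), 2)
    } else if (class == "transient_dip") {
      onset <- pick(3:max(3, stay - 1))
      baseline <- 1.1
      sex <- "male" # keeps the day-1 eGFR screen clear of the 60 cut at baseline 1.1
      age <- sample(19:65, 1)
    } else {
      baseline <- round(stats::runif(1, 0.6, if (sex == "female") 1.0 else 1.15), 2)
    }
    if (stay > nrow(expo)) { # stay extended for AKI patients
      extra <- matrix(stats::runif((stay - nrow(expo)) * length(EXPOSURE_FLAGS)) < 0.04,
                      ncol = length(EXPOSURE_FLAGS),
                      dimnames = list(NULL, EXPOSURE_FLAGS))
      expo <- rbind(expo, extra)
    }

    sampled <- stats::runif(stay) < config$scr_sample_prob
    if (!is.na(onset)) {
      boost_days <- intersect(seq(onset - 3L, onset + 7L), seq_len(stay))
      sampled[boost_days] <- sampled[boost_days] |
        (stats::runif(length(boost_days)) < config$event_sample_prob)
    }
    sampled[forced_days(class, stay, onset)] <- TRUE
    sampled[1:2] <- TRUE # admission workup; also guarantees >= 3 SCr on short stays
    vals <- plant_trajectory(class, stay, baseline, onset, recovery_day,
                             config$jitter_sd, sampled)
    minute <- sample(0:59, 1)
    days <- which(sampled)
    times <- admit_time + (days - 1) * SECONDS_PER_DAY + SECONDS_PER_HOUR +
      minute * 60

    scr <- data.frame(patient_id = pid, analyte = "scr", time = times,
                      value = round(vals[days], 3))
    # companion labs/vitals (used by the feature pipeline, not by labeling)
    vit_days <- seq_len(stay)
    vt <- admit_time + (vit_days - 1) * SECONDS_PER_DAY + 2 * SECONDS_PER_HOUR
    sick <- if (!is.na(onset)) as.integer(abs(vit_days - onset) <= 2) else 0
    labs <- rbind(
      data.frame(patient_id = pid, analyte = "heart_rate", time = vt,
                 value = round(stats::rnorm(stay, 78 + 12 * sick, 9), 1)),
      data.frame(patient_id = pid, analyte = "sbp", time = vt,
                 value = round(stats::rnorm(stay, 122, 12), 1)),
      data.frame(patient_id = pid, analyte = "body_temp", time = vt,
                 value = round(stats::rnorm(stay, 36.8 + 0.4 * sick, 0.3), 2)),
      data.frame(patient_id = pid, analyte = "resp_rate", time = vt,
                 value = round(stats::rnorm(stay, 17 + 2 * sick, 2), 1)))
    lab_days <- which(stats::runif(stay) < 0.5 | seq_len(stay) <= 2)
    lt <- admit_time + (lab_days - 1) * SECONDS_PER_DAY + SECONDS_PER_HOUR + minute * 60
    bun_base <- 13 * vals[lab_days]
    labs2 <- rbind(
      data.frame(patient_id = pid, analyte = "bun", time = lt,
                 value = round(bun_base * (1 + stats::rnorm(length(lab_days), 0, config$lab_noise_sd)), 1)),
      data.frame(patient_id = pid, analyte = "hemoglobin", time = lt,
                 value = round(stats::rnorm(length(lab_days), 12.5, 1.4), 1)),
      data.frame(patient_id = pid, analyte = "albumin", time = lt,
                 value = round(stats::rnorm(length(lab_days), 3.8, 0.4), 2)),
      data.frame(patient_id = pid, analyte = "wbc", time = lt,
                 value = round(stats::rnorm(length(lab_days), 8 + 2 * (if (!is.na(onset)) mean(sick) else 0), 2), 2)),
      data.frame(patient_id = pid, analyte = "crp", time = lt,
                 value = round(pmax(0.1, stats::rlnorm(length(lab_days), 0.5, 0.9)), 2)))

    adm_l[[i]] <- data.frame(patient_id = pid, age = age, sex = sex,
                             admit_time = admit_time,
                             discharge_time = discharge_time,
                             height = round(stats::rnorm(1, if (sex == "female") 160 else 172, 6), 1),
                             weight = round(stats::rnorm(1, if (sex == "female") 58 else 70, 9), 1))
    mea_l[[i]] <- rbind(scr, labs, labs2)
    exp_df <- data.frame(patient_id = pid,
                         day = time_day(admit_time) + (seq_len(stay) - 1L))
    for (f in EXPOSURE_FLAGS) exp_df[[f]] <- expo[, f]
    exp_l[[i]] <- exp_df
    tr_l[[i]] <- data.frame(patient_id = pid, class = class, onset_day = onset,
                            recovery_day = recovery_day, baseline = baseline,
                            sex = sex, age = age)
  }
  mea <- do.call(rbind, mea_l)
  mea <- mea[order(mea$patient_id, mea$analyte, mea$time), , drop = FALSE]
  rownames(mea) <- NULL
  cohort <- structure(list(admissions = do.call(rbind, adm_l),
                           measurements = mea,
                           exposures = do.call(rbind, exp_l),
                           errors = data.frame(file = character(),
                                               row = integer(),
                                               message = character())),
                      class = "ward_cohort")
  structure(list(cohort = cohort, truth = do.call(rbind, tr_l),
                 config = config), class = "sim_cohort")
}

#' The three-measurement worked-example series
#'
#' A patient with SCr 0.9, 0.6 and 0.9 mg/dL measured within 48 hours: AKI
#' under the standard KDIGO criteria (0.9 - 0.6 = 0.3 mg/dL within 48 h) but
#' not under the refined criteria, which exclude the transient 0.6 dip from
#' the baseline.
#'
#' @param t0 Time of the first measurement.
#' @return A list with `times` (POSIXct) and `values`.
#' @export
worked_example_series <- function(t0 = as.POSIXct("2020-03-01 08:00:00", tz = "UTC")) {
  list(times = t0 + c(0, 18, 40) * SECONDS_PER_HOUR, values = c(0.9, 0.6, 0.9))
}

#' Hand-built mini-cohort covering every labeling branch
#'
#' Deterministic eight-patient cohort exercising each branch of the pipeline:
#' the worked-example dip patient (standard-only, pre-onset decrease), a
#' low-baseline fluctuation patient (standard-only, baseline < 0.6), a
#' day-1-onset patient (removed by eligibility), an AKI patient who recovers,
#' an AKI patient progressing to AKD, an AKI patient with no post-onset SCr
#' (indeterminate AKD), a patient with only 2 SCr measurements (removed by
#' eligibility) and an unremarkable control.
#'
#' @return A list of class `sim_cohort` (`cohort`, `truth`).
#' @export
demo_cohort <- function() {
  day0 <- as.POSIXct("2020-03-01 07:00:00", tz = "UTC")
  mk_adm <- function(pid, age, sex, stay) {
    data.frame(patient_id = pid, age = age, sex = sex, admit_time = day0,
               discharge_time = day0 + (stay - 1) * SECONDS_PER_DAY +
                 11 * SECONDS_PER_HOUR,
               height = 170, weight = 65)
  }
  mk_scr <- function(pid, day_hours, values) {
    data.frame(patient_id = pid, analyte = "scr",
               time = day0 + day_hours * SECONDS_PER_HOUR, value = values)
  }
  adm <- rbind(
    mk_adm("DIP", 55, "male", 8), mk_adm("LOWB", 40, "female", 8),
    mk_adm("DAY1", 60, "male", 8), mk_adm("RECOV", 50, "male", 14),
    mk_adm("AKD", 65, "male", 16), mk_adm("INDET", 58, "female", 9),
    mk_adm("TWOSCR", 45, "male", 6), mk_adm("CTRL", 35, "female", 7))
  h <- function(day, hour = 1) (day - 1) * 24 + hour
  mea <- rbind(
    mk_scr("DIP", c(h(1), h(1, 9), h(2, 7), h(3), h(4)), c(0.9, 0.9, 0.6, 0.9, 0.9)),
    mk_scr("LOWB", h(1:6), c(0.50, 0.48, 0.50, 0.76, 0.50, 0.49)),
    mk_scr("DAY1", c(h(1, 1), h(1, 6), h(1, 12), h(2), h(3)), c(0.8, 0.9, 1.2, 1.3, 1.1)),
    mk_scr("RECOV", h(1:12), c(0.8, 0.8, 0.8, 0.8, 1.4, 1.4, 1.35, 1.3, 1.25, 0.9, 0.8, 0.8)),
    mk_scr("AKD", h(1:14), c(0.7, 0.7, 0.7, 0.7, 0.7, 1.3, 1.35, 1.3, 1.3, 1.25, 1.3, 1.3, 1.25, 1.2)),
    mk_scr("INDET", h(1:5), c(0.8, 0.8, 0.8, 0.8, 1.3)),
    mk_scr("TWOSCR", c(h(1), h(3)), c(0.9, 0.95)),
    mk_scr("CTRL", h(c(1, 2, 4, 6)), c(0.7, 0.72, 0.7, 0.71)))
  truth <- data.frame(
    patient_id = c("DIP", "LOWB", "DAY1", "RECOV", "AKD", "INDET", "TWOSCR", "CTRL"),
    class = c("transient_dip", "transient_low", "day1_aki", "aki_recovered",
              "aki_akd", "aki_indeterminate", "too_few_scr", "no_aki"),
    onset_day = c(NA, NA, 1, 5, 6, 5, NA, NA),
    recovery_day = c(NA, NA, NA, 5, NA, NA, NA, NA),
    baseline = c(0.9, 0.49, 0.8, 0.8, 0.7, 0.8, 0.9, 0.7),
    sex = adm$sex, age = adm$age)
  expo <- data.frame(patient_id = character(), day = as.Date(character()))
  for (f in EXPOSURE_FLAGS) expo[[f]] <- logical()
  cohort <- structure(list(admissions = adm, measurements = mea,
                           exposures = expo,
                           errors = data.frame(file = character(),
                                               row = integer(),
                                               message = character())),
                      class = "ward_cohort")
  structure(list(cohort = cohort, truth = truth), class = "sim_cohort")
}
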