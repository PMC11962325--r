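# Canonical column sets of the three cohort CSVs.
ADMISSION_COLS <- c("patient_id", "age", "sex", "admit_time", "discharge_time",
                    "height", "weight")
MEASUREMENT_COLS <- c("patient_id", "analyte", "time", "value")
EXPOSURE_FLAGS <- c("nsaid", "nephrotoxic_abx", "chemo", "vascular_imaging",
                    "surgery", "contrast_ct", "icu_transfer")
EXPOSURE_COLS <- c("patient_id", "day", EXPOSURE_FLAGS)

# Known analyte codes (long-format measurement file). Vitals and labs share
# the table; the feature pipeline decides the aggregation per analyte.
ANALYTES <- c("scr", "bun", "hemoglobin", "albumin", "platelet", "wbc", "crp",
              "aptt", "total_bilirubin", "sodium", "chloride", "calcium",
              "glucose", "ph", "total_co2", "urine_sg", "alt", "alp",
              "heart_rate", "sbp", "dbp", "body_temp", "resp_rate")

read_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML configs", call. = FALSE)
      }
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  stopifnot(is.list(config))
  config
}

rename_cols <- function(df, mapping) {
  if (!length(mapping)) return(df)
  for (canonical in names(mapping)) {
    site <- mapping[[canonical]]
    if (site %in% names(df)) names(df)[names(df) == site] <- canonical
  }
  df
}

#' Read a ward cohort from CSV files
#'
#' Reads the three cohort tables (admissions, long-format measurements, daily
#' exposure flags), renames site-specific columns to the canonical schema via
#' the optional config, parses and sorts timestamps, and validates units and
#' invariants. Malformed rows (unparseable timestamp, nonpositive SCr,
#' out-of-span exposure day) are collected with their file and row numbers in
#' the `errors` element, never silently dropped; missing mandatory columns
#' raise a schema error.
#'
#' @param dir Directory containing `admissions.csv`, `measurements.csv`,
#'   `exposures.csv` (or the file names given in `config$files`).
#' @param config Optional list (or path to a YAML/JSON file) with elements
#'   `admissions`, `measurements`, `exposures`: named character vectors
#'   mapping canonical column names to site column names; and `scr_unit`
#'   (`"mg/dL"`, default, or `"umol/L"` — values are converted to mg/dL by
#'   dividing by 88.4).
#' @return A list of class `ward_cohort`: `admissions`, `measurements`
#'   (time-sorted within patient x analyte), `exposures`, `errors`
#'   (data.frame `file`, `row`, `message`).
#' @export
read_cohort <- function(dir, config = NULL) {
  config <- read_config(config)
  files <- config$files %||% list(admissions = "admissions.csv",
                                  measurements = "measurements.csv",
                                  exposures = "exposures.csv")
  path <- function(f) file.path(dir, f)
  errors <- data.frame(file = character(), row = integer(), message = character())
  note <- function(file, row, message) {
    errors <<- rbind(errors, data.frame(file = file, row = row, message = message))
  }

  adm <- utils::read.csv(path(files$admissions), stringsAsFactors = FALSE)
  adm <- rename_cols(adm, config$admissions)
  stopifnot_cols(adm, setdiff(ADMISSION_COLS, c("height", "weight")), files$admissions)
  if (!"height" %in% names(adm)) adm$height <- NA_real_
  if (!"weight" %in% names(adm)) adm$weight <- NA_real_
  if (nrow(adm)) {
    adm$admit_time <- parse_time(adm$admit_time)
    adm$discharge_time <- parse_time(adm$discharge_time)
    bad <- which(is.na(adm$admit_time) | is.na(adm$discharge_time))
    for (r in bad) note(files$admissions, r, "unparseable admit/discharge time")
    bad2 <- which(!is.na(adm$admit_time) & !is.na(adm$discharge_time) &
                    adm$admit_time >= adm$discharge_time)
    for (r in bad2) note(files$admissions, r, "admit_time not before discharge_time")
    bad3 <- which(!is.na(adm$age) & adm$age < 0)
    for (r in bad3) note(files$admissions, r, "negative age")
    adm <- adm[setdiff(seq_len(nrow(adm)), c(bad, bad2, bad3)), , drop = FALSE]
  } else {
    adm$admit_time <- as.POSIXct(character(), tz = "UTC")
    adm$discharge_time <- as.POSIXct(character(), tz = "UTC")
  }

  mea <- utils::read.csv(path(files$measurements), stringsAsFactors = FALSE)
  mea <- rename_cols(mea, config$measurements)
  stopifnot_cols(mea, MEASUREMENT_COLS, files$measurements)
  if (nrow(mea)) {
    mea$time <- parse_time(mea$time)
    mea$value <- suppressWarnings(as.numeric(mea$value))
    bad <- which(is.na(mea$time))
    for (r in bad) note(files$measurements, r, "unparseable timestamp")
    badv <- which(is.na(mea$value))
    for (r in badv) note(files$measurements, r, "non-numeric value")
    if (identical(config$scr_unit %||% "mg/dL", "umol/L")) {
      mea$value[mea$analyte == "scr"] <- mea$value[mea$analyte == "scr"] / 88.4
    }
    bads <- which(mea$analyte == "scr" & !is.na(mea$value) & mea$value <= 0)
    for (r in bads) note(files$measurements, r, sprintf("nonpositive SCr (%s)", mea$value[r]))
    mea <- mea[setdiff(seq_len(nrow(mea)), c(bad, badv, bads)), , drop = FALSE]
    mea <- mea[order(mea$patient_id, mea$analyte, mea$time), , drop = FALSE]
    rownames(mea) <- NULL
  } else {
    mea$time <- as.POSIXct(character(), tz = "UTC")
  }

  exp_path <- path(files$exposures)
  if (file.exists(exp_path)) {
    expo <- utils::read.csv(exp_path, stringsAsFactors = FALSE)
    expo <- rename_cols(expo, config$exposures)
    stopifnot_cols(expo, c("patient_id", "day"), files$exposures)
    for (f in EXPOSURE_FLAGS) if (!f %in% names(expo)) expo[[f]] <- FALSE
    if (nrow(expo)) {
      expo$day <- as.Date(expo$day)
      for (f in EXPOSURE_FLAGS) expo[[f]] <- as.logical(expo[[f]])
      m <- match(expo$patient_id, adm$patient_id)
      bad <- which(!is.na(m) &
                     (expo$day < time_day(adm$admit_time[m]) |
                        expo$day > time_day(adm$discharge_time[m])))
      for (r in bad) note(files$exposures, r, "exposure day outside admission span")
      expo <- expo[setdiff(seq_len(nrow(expo)), bad), , drop = FALSE]
    } else {
      expo$day <- as.Date(character())
    }
  } else {
    expo <- data.frame(patient_id = character(), day = as.Date(character()))
    for (f in EXPOSURE_FLAGS) expo[[f]] <- logical()
  }

  structure(list(admissions = adm, measurements = mea, exposures = expo,
                 errors = errors),
            class = "ward_cohort")
}

#' Write a ward cohort to CSV files
#'
#' Inverse of [read_cohort()]; output is deterministic (fixed timestamp
#' format, row order preserved) so identical cohorts yield identical bytes.
#'
#' @param cohort A `ward_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adm <- cohort$admissions
  adm$admit_time <- format_time(adm$admit_time)
  adm$discharge_time <- format_time(adm$discharge_time)
  utils::write.csv(adm, file.path(dir, "admissions.csv"), row.names = FALSE)
  mea <- cohort$measurements
  mea$time <- format_time(mea$time)
  utils::write.csv(mea, file.path(dir, "measurements.csv"), row.names = FALSE)
  expo <- cohort$exposures
  expo$day <- format(expo$day)
  utils::write.csv(expo, file.path(dir, "exposures.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.ward_cohort <- function(x, ...) {
  cat(sprintf("ward_cohort: %d admissions, %d measurements, %d exposure-days, %d row errors\n",
              nrow(x$admissions), nrow(x$measurements), nrow(x$exposures),
              nrow(x$errors)))
  invisible(x)
}

subset_cohort <- function(cohort, keep_ids) {
  structure(list(
    admissions = cohort$admissions[cohort$admissions$patient_id %in% keep_ids, , drop = FALSE],
    measurements = cohort$measurements[cohort$measurements$patient_id %in% keep_ids, , drop = FALSE],
    exposures = cohort$exposures[cohort$exposures$patient_id %in% keep_ids, , drop = FALSE],
    errors = cohort$errors), class = "ward_cohort")
}

#' Apply cohort eligibility filters
#'
#' Sequentially excludes (attributing each patient to the first rule that
#' fires): age below 19 years; fewer than 3 SCr measurements during the stay;
#' eGFR <= 60 mL/min/1.73 m^2 on the first calendar day with an SCr
#' measurement (first value chronologically that day); and AKI onset (refined
#' definition) on admission day 1, since at least one prior day of data is
#' needed for prediction. Patients whose eGFR cannot be computed (missing
#' age or sex) are routed to an `unevaluable` bucket, not silently kept.
#'
#' @param cohort A `ward_cohort`.
#' @param params A [kdigo_params()] object (for the day-1 AKI scan).
#' @param egfr_cut eGFR exclusion threshold (default 60).
#' @return A list: `cohort` (filtered `ward_cohort`) and `report`, a list of
#'   class `cohort_filter_report` whose counts reconcile:
#'   `age_below_19 + fewer_than_3_scr + low_first_day_egfr + day1_aki +
#'    unevaluable + retained = input_total`.
#' @export
apply_eligibility <- function(cohort, params = kdigo_params(), egfr_cut = 60) {
  adm <- cohort$admissions
  reason <- rep(NA_character_, nrow(adm))
  for (j in seq_len(nrow(adm))) {
    pid <- adm$patient_id[j]
    if (is.na(adm$age[j]) || is.na(adm$sex[j]) ||
        !adm$sex[j] %in% c("female", "male")) {
      reason[j] <- "unevaluable"
      next
    }
    if (adm$age[j] < 19) { reason[j] <- "age_below_19"; next }
    s <- scr_series(cohort, pid)
    if (length(s$values) < 3) { reason[j] <- "fewer_than_3_scr"; next }
    first_day <- time_day(s$times[1])
    first_of_day <- s$values[time_day(s$times) == first_day][1]
    egfr <- compute_egfr(first_of_day, adm$age[j], adm$sex[j])
    if (egfr <= egfr_cut) { reason[j] <- "low_first_day_egfr"; next }
    ev <- detect_aki(s$times, s$values, "refined", params, pid)
    if (!is.null(ev) && day_index(ev$onset_time, adm$admit_time[j]) == 1L) {
      reason[j] <- "day1_aki"
    }
  }
  retained_ids <- adm$patient_id[is.na(reason)]
  report <- structure(list(
    input_total = nrow(adm),
    age_below_19 = sum(reason == "age_below_19", na.rm = TRUE),
    fewer_than_3_scr = sum(reason == "fewer_than_3_scr", na.rm = TRUE),
    low_first_day_egfr = sum(reason == "low_first_day_egfr", na.rm = TRUE),
    day1_aki = sum(reason == "day1_aki", na.rm = TRUE),
    unevaluable = sum(reason == "unevaluable", na.rm = TRUE),
    retained = length(retained_ids),
    excluded_patients = data.frame(patient_id = adm$patient_id[!is.na(reason)],
                                   reason = reason[!is.na(reason)])),
    class = "cohort_filter_report")
  list(cohort = subset_cohort(cohort, retained_ids), report = report)
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat(sprintf(paste0("eligibility: %d in; excluded %d (age) + %d (<3 SCr) + ",
                     "%d (eGFR<=60) + %d (day-1 AKI) + %d (unevaluable); %d retained\n"),
              x$input_total, x$age_below_19, x$fewer_than_3_scr,
              x$low_first_day_egfr, x$day1_aki, x$unevaluable, x$retained))
  invisible(x)
}
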