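#' Adjudicate acute kidney disease (nonrecovery) after an AKI onset
#'
#' Scans the SCr measurements in the 7 calendar days after onset. The first
#' value strictly below 1.5 x the onset baseline marks recovery; if none
#' qualifies and the window contains at least `min_post_scr` measurements with
#' at least one in days 5-7 (so a late recovery could have been observed), the
#' patient is AKD; otherwise the status is `indeterminate` — a value, not an
#' error — and the patient is excluded from the AKD task. The baseline is
#' frozen at its onset-time value.
#'
#' @param times,values The patient's full SCr series (sorted; mg/dL).
#' @param event An AKI event row as returned by [detect_aki_cohort()] (needs
#'   `onset_time` and `baseline_value`) or an `aki_event`.
#' @param recovery_window_days Recovery window in calendar days (default 7).
#' @param min_post_scr Minimum number of post-onset measurements for an AKD
#'   call (default 1).
#' @param params A [kdigo_params()] object (supplies the 1.5 ratio).
#' @return A list of class `akd_outcome`: `status` in
#'   `{"recovered","akd","indeterminate"}`, `recovery_time` (NA unless
#'   recovered), `recovery_day` (days after onset), `post_onset_scr_count`.
#' @export
assess_akd <- function(times, values, event, recovery_window_days = 7,
                       min_post_scr = 1, params = kdigo_params()) {
  onset_time <- parse_time(event$onset_time)
  baseline <- event$baseline_value
  if (is.na(baseline)) stop("event has no valid baseline", call. = FALSE)
  times <- parse_time(times)
  onset_date <- time_day(onset_time)
  offset <- as.integer(time_day(times) - onset_date)
  post <- which(times > onset_time & offset <= recovery_window_days)
  thr <- params$ratio * baseline
  status <- "indeterminate"
  recovery_time <- as.POSIXct(NA, tz = "UTC")
  recovery_day <- NA_integer_
  rec <- post[lt_strict(values[post], thr, params$tol)]
  if (length(rec)) {
    status <- "recovered"
    recovery_time <- times[rec[1]]
    recovery_day <- offset[rec[1]]
  } else if (length(post) >= min_post_scr &&
             any(offset[post] >= recovery_window_days - 2)) {
    status <- "akd"
  }
  structure(list(status = status, recovery_time = recovery_time,
                 recovery_day = recovery_day,
                 post_onset_scr_count = length(post),
                 onset_time = onset_time, baseline_value = baseline),
            class = "akd_outcome")
}

#' AKD outcomes for every AKI patient of a cohort
#'
#' @param cohort A `ward_cohort`.
#' @param events Event table from [detect_aki_cohort()] (refined definition).
#' @inheritParams assess_akd
#' @return A data.frame with one row per AKI patient: `patient_id`, `status`,
#'   `recovery_day`, `post_onset_scr_count`.
#' @export
assess_akd_cohort <- function(cohort, events, recovery_window_days = 7,
                              min_post_scr = 1, params = kdigo_params()) {
  ev <- events[events$aki, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ev)), function(j) {
    s <- scr_series(cohort, ev$patient_id[j])
    out <- assess_akd(s$times, s$values, ev[j, ], recovery_window_days,
                      min_post_scr, params)
    data.frame(patient_id = ev$patient_id[j], status = out$status,
               recovery_day = out$recovery_day,
               post_onset_scr_count = out$post_onset_scr_count)
  })
  if (!length(rows)) {
    return(data.frame(patient_id = character(), status = character(),
                      recovery_day = integer(), post_onset_scr_count = integer()))
  }
  do.call(rbind, rows)
}

#' Day-level labels for the early AKI prediction task
#'
#' Builds one row per in-hospital patient-day with a label in
#' `{0, 1, excluded}`. For AKI patients the 1-3 days before onset are labeled
#' 1 and the onset day and all later days are excluded; all other days are 0.
#' Any day without an SCr measurement in its next 7 calendar days (including
#' the index day) is excluded, since an onset there could not have been
#' observed. Patients with ambiguous labeling — the refined detector skipped
#' candidate evaluations for lack of any baseline (a >7-day SCr gap) and no
#' unambiguous onset was found, or the onset baseline came from the
#' all-excluded median fallback — are dropped entirely.
#'
#' Exclusion precedence (each excluded day carries exactly one reason):
#' on/after onset > missing lookahead SCr.
#'
#' @param cohort A `ward_cohort`.
#' @param events Refined event table from [detect_aki_cohort()].
#' @param horizon_days Positive-label window before onset (default 3).
#' @param lookahead_days Forward SCr-coverage requirement (default 7).
#' @return A data.frame `patient_id`, `day`, `label` (`"0"`, `"1"` or
#'   `"excluded"`), `reason` (NA unless excluded). Dropped patients appear
#'   with a single row, `day = NA`, reason `"ambiguous_labeling"`.
#' @export
build_aki_day_labels <- function(cohort, events, horizon_days = 3,
                                 lookahead_days = 7) {
  adm <- cohort$admissions
  rows <- vector("list", nrow(adm))
  for (j in seq_len(nrow(adm))) {
    pid <- adm$patient_id[j]
    ev <- events[events$patient_id == pid, , drop = FALSE]
    ambiguous <- nrow(ev) == 1 &&
      ((ev$n_skipped_no_baseline > 0 & !ev$aki) |
         (ev$aki & !is.na(ev$baseline_reason) & ev$baseline_reason == "all_excluded"))
    if (isTRUE(ambiguous)) {
      rows[[j]] <- data.frame(patient_id = pid, day = NA_integer_,
                              label = "excluded", reason = "ambiguous_labeling")
      next
    }
    n_days <- day_index(adm$discharge_time[j], adm$admit_time[j])
    s <- scr_series(cohort, pid)
    scr_days <- unique(day_index(s$times, adm$admit_time[j]))
    onset_day <- if (nrow(ev) == 1 && ev$aki) ev$onset_day else NA_integer_
    d <- seq_len(n_days)
    lookahead_ok <- vapply(d, function(dd) {
      any(scr_days >= dd & scr_days <= dd + lookahead_days - 1L)
    }, logical(1))
    label <- rep("0", n_days)
    reason <- rep(NA_character_, n_days)
    if (!is.na(onset_day)) {
      pos <- d >= onset_day - horizon_days & d < onset_day
      label[pos] <- "1"
      label[d >= onset_day] <- "excluded"
      reason[d >= onset_day] <- ifelse(d[d >= onset_day] == onset_day,
                                       "onset_day", "post_onset")
    }
    drop <- !lookahead_ok & label != "excluded"
    label[drop] <- "excluded"
    reason[drop] <- "no_scr_lookahead"
    rows[[j]] <- data.frame(patient_id = pid, day = d, label = label,
                            reason = reason)
  }
  do.call(rbind, rows)
}

#' Onset-day labels for the AKD (nonrecovery) prediction task
#'
#' One record per AKI patient at the onset day: 1 if the patient progressed
#' to AKD, 0 if recovered, excluded if recovery status is indeterminate.
#'
#' @param events Refined event table from [detect_aki_cohort()].
#' @param outcomes Outcome table from [assess_akd_cohort()].
#' @return A data.frame `patient_id`, `day` (onset day), `label`, `reason`.
#' @export
build_akd_labels <- function(events, outcomes) {
  ev <- events[events$aki, , drop = FALSE]
  miss <- setdiff(ev$patient_id, outcomes$patient_id)
  if (length(miss)) {
    stop(sprintf("AKI event without AKD outcome for patient(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  m <- match(ev$patient_id, outcomes$patient_id)
  status <- outcomes$status[m]
  data.frame(patient_id = ev$patient_id, day = ev$onset_day,
             label = ifelse(status == "akd", "1",
                            ifelse(status == "recovered", "0", "excluded")),
             reason = ifelse(status == "indeterminate",
                             "indeterminate_akd", NA_character_))
}
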