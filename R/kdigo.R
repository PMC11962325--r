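#' KDIGO labeling parameters
#'
#' Threshold set used by the baseline estimator and both AKI detectors.
#' Defaults are the creatinine KDIGO thresholds plus the refinements used for
#' ward phenotyping: the baseline-candidate exclusion delta and the minimum
#' absolute increase. All creatinine thresholds are in mg/dL; pass the
#' equivalent values (e.g. 26.5) to run a series recorded in umol/L.
#'
#' @param window_days Baseline lookback window (days; default 7).
#' @param abs_window_hours Window of the absolute-increase criterion (48 h).
#' @param min_increase_mgdl Minimum absolute SCr increase (0.3 mg/dL).
#' @param ratio Relative-increase criterion (1.5 x baseline).
#' @param exclusion_delta_mgdl Gap below median/recent values at which a
#'   baseline candidate is excluded as a transient dip (0.3 mg/dL).
#' @param low_baseline_cut_mgdl Cut used when classifying standard-only AKI
#'   calls as low-baseline artefacts (0.6 mg/dL).
#' @param tol Floating-point tolerance on threshold comparisons.
#' @return A list of class `kdigo_params`.
#' @export
kdigo_params <- function(window_days = 7, abs_window_hours = 48,
                         min_increase_mgdl = 0.3, ratio = 1.5,
                         exclusion_delta_mgdl = 0.3,
                         low_baseline_cut_mgdl = 0.6, tol = SCR_TOL) {
  stopifnot(window_days > 0, abs_window_hours > 0, min_increase_mgdl > 0,
            ratio > 1, exclusion_delta_mgdl > 0)
  structure(list(window_days = window_days, abs_window_hours = abs_window_hours,
                 min_increase_mgdl = min_increase_mgdl, ratio = ratio,
                 exclusion_delta_mgdl = exclusion_delta_mgdl,
                 low_baseline_cut_mgdl = low_baseline_cut_mgdl, tol = tol),
            class = "kdigo_params")
}

#' Refined baseline serum creatinine estimate
#'
#' The baseline at an evaluation time is the lowest SCr measured within the
#' previous 7 days, after excluding transient dips: a candidate is excluded
#' when it sits at least `exclusion_delta_mgdl` below BOTH the median of the
#' other window values and the most recent other window value. Candidates are
#' tested in ascending order; the first surviving minimum is the baseline. If
#' every candidate is excluded the window median is returned with reason
#' `"all_excluded"`.
#'
#' The window is open at both ends: measurements strictly after
#' `eval_time - window_days` and strictly before `eval_time`, so a measurement
#' is never its own baseline.
#'
#' @param times POSIXct measurement times (sorted ascending).
#' @param values SCr values (mg/dL), parallel to `times`.
#' @param eval_time POSIXct evaluation time.
#' @param params A [kdigo_params()] object.
#' @return A list of class `baseline_estimate` with elements `eval_time`,
#'   `baseline_value`, `baseline_time` (NA when the median fallback was used),
#'   `reason` (`"min"`, `"all_excluded"` or `"empty_window"`), `excluded`
#'   (data.frame of excluded candidates with reasons), `window_values`,
#'   `window_times`. When the window is empty `baseline_value` is `NA` — the
#'   caller must skip the evaluation, never substitute a default.
#' @export
estimate_baseline <- function(times, values, eval_time,
                              params = kdigo_params()) {
  eval_time <- parse_time(eval_time)
  win <- which(times > eval_time - params$window_days * SECONDS_PER_DAY &
                 times < eval_time)
  empty_excl <- data.frame(time = as.POSIXct(character(), tz = "UTC"),
                           value = numeric(), reason = character())
  if (!length(win)) {
    return(structure(list(eval_time = eval_time, baseline_value = NA_real_,
                          baseline_time = as.POSIXct(NA, tz = "UTC"),
                          reason = "empty_window", excluded = empty_excl,
                          window_values = numeric(),
                          window_times = as.POSIXct(character(), tz = "UTC")),
                     class = "baseline_estimate"))
  }
  wt <- times[win]
  wv <- values[win]
  ord <- order(wv, wt) # ascending value, earliest first on ties
  excl <- empty_excl
  result <- NULL
  for (k in ord) {
    ov <- wv[-k]
    ot <- wt[-k]
    if (!length(ov)) { # lone value cannot be compared, keep it
      result <- list(value = wv[k], time = wt[k])
      break
    }
    med_gap <- stats::median(ov) - wv[k]
    recent_gap <- ov[which.max(as.numeric(ot))] - wv[k]
    if (geq(med_gap, params$exclusion_delta_mgdl, params$tol) &&
        geq(recent_gap, params$exclusion_delta_mgdl, params$tol)) {
      excl <- rbind(excl, data.frame(
        time = wt[k], value = wv[k],
        reason = sprintf("below_median_and_recent (gaps %.3g/%.3g)",
                         med_gap, recent_gap)))
      next
    }
    result <- list(value = wv[k], time = wt[k])
    break
  }
  if (is.null(result)) {
    return(structure(list(eval_time = eval_time,
                          baseline_value = stats::median(wv),
                          baseline_time = as.POSIXct(NA, tz = "UTC"),
                          reason = "all_excluded", excluded = excl,
                          window_values = wv, window_times = wt),
                     class = "baseline_estimate"))
  }
  structure(list(eval_time = eval_time, baseline_value = result$value,
                 baseline_time = result$time, reason = "min", excluded = excl,
                 window_values = wv, window_times = wt),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("baseline %.3g mg/dL (%s) at eval %s; %d window value(s), %d excluded\n",
              x$baseline_value, x$reason, format_time(x$eval_time),
              length(x$window_values), nrow(x$excluded)))
  invisible(x)
}

new_aki_event <- function(patient_id, i, times, values, baseline_value,
                          baseline_time, criteria, definition,
                          n_skipped_no_baseline = 0L,
                          baseline_reason = NA_character_) {
  structure(list(patient_id = patient_id, onset_time = times[i],
                 onset_index = i, onset_value = values[i],
                 baseline_value = baseline_value, baseline_time = baseline_time,
                 criteria = criteria, definition = definition,
                 n_skipped_no_baseline = n_skipped_no_baseline,
                 baseline_reason = baseline_reason),
            class = "aki_event")
}

#' @export
print.aki_event <- function(x, ...) {
  cat(sprintf("AKI (%s) at %s: SCr %.3g vs baseline %.3g [%s]\n",
              x$definition, format_time(x$onset_time), x$onset_value,
              x$baseline_value,
              paste(names(x$criteria)[unlist(x$criteria)], collapse = "+")))
  invisible(x)
}

#' Detect AKI on one serum-creatinine series
#'
#' Scans a patient's SCr series chronologically and returns the first
#' measurement at which the chosen definition fires (one event per admission),
#' or `NULL` when no event occurs.
#'
#' Under `definition = "standard"` a measurement fires when it exceeds the
#' minimum of the prior 48-hour values by >= 0.3 mg/dL (`abs48h`), or reaches
#' >= 1.5 times the minimum of the prior 7-day values (`rel7d`).
#'
#' Under `definition = "refined"` the baseline is [estimate_baseline()] (the
#' exclusion-filtered 7-day minimum); a measurement fires when it exceeds that
#' baseline by >= 0.3 mg/dL AND (the baseline was measured within the prior
#' 48 hours OR the measurement reaches >= 1.5 x baseline). Measurements with
#' an empty baseline window are skipped and counted in
#' `n_skipped_no_baseline` (used downstream to flag ambiguous patients).
#'
#' @param times POSIXct measurement times, sorted ascending.
#' @param values SCr values (mg/dL, > 0), parallel to `times`.
#' @param definition `"standard"` or `"refined"`.
#' @param params A [kdigo_params()] object.
#' @param patient_id Optional identifier carried into the event.
#' @return An `aki_event` (list) or `NULL`. When `NULL`, the attribute
#'   `n_skipped_no_baseline` on the return of [detect_aki_cohort()] records
#'   skipped evaluations.
#' @examples
#' t0 <- as.POSIXct("2020-01-01 08:00:00", tz = "UTC")
#' times <- t0 + c(0, 18, 40) * 3600
#' vals <- c(0.9, 0.6, 0.9)
#' detect_aki(times, vals, "standard") # fires (abs48h)
#' detect_aki(times, vals, "refined")  # NULL: the 0.6 dip is excluded
#' @export
detect_aki <- function(times, values, definition = c("refined", "standard"),
                       params = kdigo_params(), patient_id = NA_character_) {
  scan_aki(times, values, definition, params, patient_id)$event
}

# Full scan: the event (or NULL) plus the count of measurements that could
# not be evaluated for lack of any baseline (>7-day gaps).
scan_aki <- function(times, values, definition = c("refined", "standard"),
                     params = kdigo_params(), patient_id = NA_character_) {
  definition <- match.arg(definition)
  if (!length(values)) stop("empty SCr series", call. = FALSE)
  if (any(values <= 0)) stop("SCr values must be > 0", call. = FALSE)
  times <- parse_time(times)
  if (is.unsorted(as.numeric(times))) stop("series must be time-sorted", call. = FALSE)
  n <- length(values)
  skipped <- 0L
  for (i in seq_len(n)) {
    ti <- times[i]
    vi <- values[i]
    if (definition == "standard") {
      in48 <- which(times > ti - params$abs_window_hours * SECONDS_PER_HOUR &
                      times < ti)
      in7d <- which(times > ti - params$window_days * SECONDS_PER_DAY &
                      times < ti)
      abs48h <- length(in48) > 0 &&
        geq(vi - min(values[in48]), params$min_increase_mgdl, params$tol)
      rel7d <- length(in7d) > 0 &&
        geq(vi, params$ratio * min(values[in7d]), params$tol)
      if (abs48h || rel7d) {
        bl <- if (length(in7d)) min(values[in7d]) else NA_real_
        blt <- if (length(in7d)) times[in7d][which.min(values[in7d])] else as.POSIXct(NA, tz = "UTC")
        return(list(event = new_aki_event(patient_id, i, times, values, bl, blt,
                                          list(abs48h = abs48h, rel7d = rel7d,
                                               min_increase = geq(vi - bl, params$min_increase_mgdl, params$tol)),
                                          "standard", skipped),
                    n_skipped_no_baseline = skipped))
      }
    } else {
      bl <- estimate_baseline(times, values, ti, params)
      if (bl$reason == "empty_window") {
        if (i > 1L) skipped <- skipped + 1L # a true >7-day gap, not the first row
        next
      }
      min_inc <- geq(vi - bl$baseline_value, params$min_increase_mgdl, params$tol)
      recent_baseline <- !is.na(bl$baseline_time) &&
        bl$baseline_time > ti - params$abs_window_hours * SECONDS_PER_HOUR
      rel <- geq(vi, params$ratio * bl$baseline_value, params$tol)
      if (min_inc && (recent_baseline || rel)) {
        return(list(event = new_aki_event(patient_id, i, times, values,
                                          bl$baseline_value, bl$baseline_time,
                                          list(abs48h = recent_baseline,
                                               rel7d = rel,
                                               min_increase = min_inc),
                                          "refined", skipped, bl$reason),
                    n_skipped_no_baseline = skipped))
      }
    }
  }
  list(event = NULL, n_skipped_no_baseline = skipped)
}

scr_series <- function(cohort, patient_id) {
  m <- cohort$measurements
  sel <- m$patient_id == patient_id & m$analyte == "scr"
  list(times = m$time[sel], values = m$value[sel])
}

#' Detect AKI for every patient of a cohort
#'
#' @param cohort A `ward_cohort` (see [read_cohort()]).
#' @param definition `"standard"` or `"refined"`.
#' @param params A [kdigo_params()] object.
#' @return A data.frame with one row per patient: `patient_id`, `aki`
#'   (logical), `onset_time`, `onset_day` (admission-day index), `onset_scr`,
#'   `baseline_value`, `baseline_time`, criteria flags, `n_skipped_no_baseline`
#'   and `baseline_reason`.
#' @export
detect_aki_cohort <- function(cohort, definition = c("refined", "standard"),
                              params = kdigo_params()) {
  definition <- match.arg(definition)
  adm <- cohort$admissions
  rows <- lapply(seq_len(nrow(adm)), function(j) {
    pid <- adm$patient_id[j]
    s <- scr_series(cohort, pid)
    if (!length(s$values)) {
      return(data.frame(patient_id = pid, aki = FALSE,
                        onset_time = as.POSIXct(NA, tz = "UTC"),
                        onset_day = NA_integer_, onset_scr = NA_real_,
                        baseline_value = NA_real_,
                        baseline_time = as.POSIXct(NA, tz = "UTC"),
                        abs48h = NA, rel7d = NA, min_increase = NA,
                        n_skipped_no_baseline = 0L,
                        baseline_reason = NA_character_))
    }
    ev <- detect_aki(s$times, s$values, definition, params, pid)
    if (is.null(ev)) {
      data.frame(patient_id = pid, aki = FALSE,
                 onset_time = as.POSIXct(NA, tz = "UTC"),
                 onset_day = NA_integer_, onset_scr = NA_real_,
                 baseline_value = NA_real_,
                 baseline_time = as.POSIXct(NA, tz = "UTC"),
                 abs48h = NA, rel7d = NA, min_increase = NA,
                 n_skipped_no_baseline = attr(ev, "n_skipped_no_baseline") %||% 0L,
                 baseline_reason = NA_character_)
    } else {
      data.frame(patient_id = pid, aki = TRUE, onset_time = ev$onset_time,
                 onset_day = day_index(ev$onset_time, adm$admit_time[j]),
                 onset_scr = ev$onset_value, baseline_value = ev$baseline_value,
                 baseline_time = ev$baseline_time,
                 abs48h = ev$criteria$abs48h, rel7d = ev$criteria$rel7d,
                 min_increase = ev$criteria$min_increase,
                 n_skipped_no_baseline = ev$n_skipped_no_baseline,
                 baseline_reason = ev$baseline_reason)
    }
  })
  do.call(rbind, rows)
}

#' Compare standard and refined AKI criteria on a cohort
#'
#' Runs both detectors on identical series and classifies every patient as
#' `refined` (meets the refined criteria), `standard_only` (meets only the
#' standard KDIGO criteria) or `neither`. Standard-only patients are
#' subclassified: `low_baseline` when the standard-onset baseline (raw 7-day
#' minimum) is below `low_baseline_cut_mgdl`; else `pre_onset_decrease` when
#' the refined baseline-exclusion rule fired at the standard onset time; else
#' `other`.
#'
#' @param cohort A `ward_cohort`.
#' @param params A [kdigo_params()] object.
#' @return A list of class `criteria_comparison`: `patients` (per-patient
#'   audit data.frame with `class` and `subclass`) and `summary` (named
#'   counts). The refined calls are a subset of the standard calls by
#'   construction.
#' @export
compare_criteria <- function(cohort, params = kdigo_params()) {
  std <- detect_aki_cohort(cohort, "standard", params)
  ref <- detect_aki_cohort(cohort, "refined", params)
  stopifnot(identical(std$patient_id, ref$patient_id))
  cls <- ifelse(ref$aki, "refined", ifelse(std$aki, "standard_only", "neither"))
  subclass <- rep(NA_character_, nrow(std))
  so <- which(cls == "standard_only")
  for (j in so) {
    if (!is.na(std$baseline_value[j]) &&
        lt_strict(std$baseline_value[j], params$low_baseline_cut_mgdl, params$tol)) {
      subclass[j] <- "low_baseline"
    } else {
      s <- scr_series(cohort, std$patient_id[j])
      bl <- estimate_baseline(s$times, s$values, std$onset_time[j], params)
      subclass[j] <- if (nrow(bl$excluded) > 0) "pre_onset_decrease" else "other"
    }
  }
  patients <- data.frame(patient_id = std$patient_id, class = cls,
                         subclass = subclass,
                         standard_onset_day = std$onset_day,
                         standard_baseline = std$baseline_value,
                         refined_onset_day = ref$onset_day)
  summary <- c(refined = sum(cls == "refined"),
               standard = sum(cls != "neither"),
               standard_only = sum(cls == "standard_only"),
               neither = sum(cls == "neither"),
               low_baseline = sum(subclass == "low_baseline", na.rm = TRUE),
               pre_onset_decrease = sum(subclass == "pre_onset_decrease", na.rm = TRUE),
               other = sum(subclass == "other", na.rm = TRUE))
  structure(list(patients = patients, summary = summary),
            class = "criteria_comparison")
}

#' @export
print.criteria_comparison <- function(x, ...) {
  cat("AKI criteria comparison\n")
  print(x$summary)
  invisible(x)
}
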