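#' Feature-pipeline configuration
#'
#' The per-day feature table is schema-driven: `vitals` are aggregated within
#' each calendar day as mean/max/min/count, `labs` take the most recent value
#' at or before the end of the day, `delta_labs` additionally get a
#' delta-from-median-of-previous-values feature, and exposure flags are ORed
#' over the trailing 7 days (inclusive of the index day). `clip` gives
#' optional physiologic plausibility ranges applied before aggregation.
#'
#' @param vitals,labs,delta_labs Character vectors of analyte codes.
#' @param exposure_window_days Trailing exposure window (default 7).
#' @param clip Named list of `c(lo, hi)` physiologic ranges.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(vitals = c("heart_rate", "sbp", "dbp", "body_temp",
                                      "resp_rate"),
                           labs = c("scr", "bun", "hemoglobin", "albumin",
                                    "platelet", "wbc", "crp", "aptt",
                                    "total_bilirubin", "sodium", "chloride",
                                    "calcium", "glucose", "ph", "total_co2",
                                    "urine_sg", "alt", "alp"),
                           delta_labs = c("scr", "bun", "hemoglobin", "wbc",
                                          "crp", "albumin"),
                           exposure_window_days = 7,
                           clip = list(heart_rate = c(20, 250),
                                       sbp = c(40, 280), dbp = c(20, 200),
                                       body_temp = c(30, 43),
                                       resp_rate = c(4, 80),
                                       scr = c(0.1, 30))) {
  structure(list(vitals = vitals, labs = labs, delta_labs = delta_labs,
                 exposure_window_days = exposure_window_days, clip = clip),
            class = "feature_config")
}

#' Summarise a cohort into one row per patient-day
#'
#' Implements the 24-hour summarisation: vitals are aggregated per calendar
#' day (mean, max, min and number of measurements; negative vital values are
#' a validation error), labs carry the most recent value at or before the end
#' of the day, eGFR (CKD-EPI 2021) and the BUN/Cr ratio are derived, and
#' exposure flags are true when the exposure occurred in the trailing 7 days.
#' A provenance attribute records, for every lab cell, whether it was
#' `observed` that day or is still `missing` (imputation updates it to
#' `carried`/`imputed`/`missing_level`).
#'
#' @param cohort A `ward_cohort`.
#' @param config A [feature_config()].
#' @return A data.frame (one row per patient-day) with attribute
#'   `"provenance"`, a character matrix over the lab columns.
#' @export
summarize_days <- function(cohort, config = feature_config()) {
  adm <- cohort$admissions
  mea <- cohort$measurements
  bad <- mea$analyte %in% config$vitals & mea$value < 0
  if (any(bad)) {
    stop(sprintf("negative vital value(s) in rows: %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  for (a in names(config$clip)) {
    sel <- mea$analyte == a
    mea$value[sel] <- pmin(pmax(mea$value[sel], config$clip[[a]][1]),
                           config$clip[[a]][2])
  }
  rows <- vector("list", nrow(adm))
  prov_rows <- vector("list", nrow(adm))
  for (j in seq_len(nrow(adm))) {
    pid <- adm$patient_id[j]
    n_days <- day_index(adm$discharge_time[j], adm$admit_time[j])
    pm <- mea[mea$patient_id == pid, , drop = FALSE]
    pm$day <- day_index(pm$time, adm$admit_time[j])
    df <- data.frame(patient_id = pid, day = seq_len(n_days))
    df$age <- adm$age[j]
    df$sex <- adm$sex[j]
    df$bmi <- if (!is.na(adm$height[j]) && !is.na(adm$weight[j])) {
      adm$weight[j] / (adm$height[j] / 100)^2
    } else NA_real_
    for (v in config$vitals) {
      vm <- pm[pm$analyte == v, , drop = FALSE]
      agg <- function(f) vapply(seq_len(n_days), function(d) {
        x <- vm$value[vm$day == d]
        if (length(x)) f(x) else NA_real_
      }, numeric(1))
      df[[paste0(v, "_mean")]] <- agg(mean)
      df[[paste0(v, "_max")]] <- agg(max)
      df[[paste0(v, "_min")]] <- agg(min)
      df[[paste0(v, "_count")]] <- vapply(seq_len(n_days), function(d) {
        sum(vm$day == d)
      }, numeric(1))
    }
    prov <- matrix("missing", nrow = n_days, ncol = length(config$labs),
                   dimnames = list(NULL, config$labs))
    for (l in config$labs) {
      lm_ <- pm[pm$analyte == l, , drop = FALSE]
      df[[l]] <- vapply(seq_len(n_days), function(d) {
        x <- lm_$value[lm_$day <= d]
        if (length(x)) x[length(x)] else NA_real_
      }, numeric(1))
      prov[lm_$day[lm_$day <= n_days], l] <- "observed"
    }
    if (all(c("bun", "scr") %in% config$labs)) {
      df$bun_cr_ratio <- df$bun / df$scr
    }
    if ("scr" %in% config$labs) {
      df$egfr <- ifelse(is.na(df$scr) | is.na(df$age) | is.na(df$sex),
                        NA_real_, compute_egfr(pmax(df$scr, 0.1), df$age, df$sex))
    }
    pe <- cohort$exposures[cohort$exposures$patient_id == pid, , drop = FALSE]
    pe_day <- if (nrow(pe)) as.integer(pe$day - time_day(adm$admit_time[j])) + 1L else integer()
    for (f in EXPOSURE_FLAGS) {
      flagged <- pe_day[which(pe[[f]])]
      df[[f]] <- vapply(seq_len(n_days), function(d) {
        any(flagged >= d - config$exposure_window_days + 1L & flagged <= d)
      }, logical(1))
    }
    rows[[j]] <- df
    prov_rows[[j]] <- prov
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- do.call(rbind, prov_rows)
  out
}

#' Delta-from-median features
#'
#' For each configured lab, adds `delta_<lab>` = the day's value minus the
#' median of the patient's *previous observed* values within the admission
#' (carried-forward or imputed values never enter the history). Days with no
#' previous observed value get `NA` (marked missing).
#'
#' @param day_table Output of [summarize_days()] (provenance attribute
#'   required).
#' @param config A [feature_config()].
#' @return `day_table` with `delta_*` columns appended.
#' @export
compute_deltas <- function(day_table, config = feature_config()) {
  prov <- attr(day_table, "provenance")
  stopifnot(!is.null(prov))
  for (l in config$delta_labs) {
    out <- rep(NA_real_, nrow(day_table))
    for (pid in unique(day_table$patient_id)) {
      idx <- which(day_table$patient_id == pid)
      obs_days <- idx[prov[idx, l] == "observed"]
      for (k in idx) {
        prev <- obs_days[day_table$day[obs_days] < day_table$day[k]]
        if (length(prev) && !is.na(day_table[[l]][k])) {
          out[k] <- day_table[[l]][k] - stats::median(day_table[[l]][prev])
        }
      }
    }
    day_table[[paste0("delta_", l)]] <- out
  }
  day_table
}

#' Two-stage missing-value handling
#'
#' Stage 1: last observation carried forward within each admission. Stage 2:
#' features whose residual missingness (computed on the training rows only)
#' is below `miss_threshold` are completed by chained-equation imputation
#' (round-robin linear regressions over the other numeric features, a fixed
#' number of iterations, fitted on training rows only and applied to all
#' rows); features at or above the threshold are converted to
#' quantile-based categories (training-split cut points) with an explicit
#' `"missing"` level. Imputation models are only ever fitted on training
#' rows, so no evaluation-split statistic can leak into the transform.
#'
#' @param day_table Feature table (with provenance attribute).
#' @param train_ids Patient ids of the training split.
#' @param features Numeric feature columns to process (default: all numeric
#'   columns except `day`).
#' @param miss_threshold Missingness rate separating imputation from
#'   missing-indicator categorisation (default 0.2).
#' @param n_iter Chained-equation iterations (default 10).
#' @param n_cats Number of quantile categories for indicator features
#'   (default 3, i.e. tertiles).
#' @param seed Seed for the (deterministic-given-seed) imputation order.
#' @return The table with missing values resolved; provenance updated;
#'   attribute `"categorised"` lists features converted to factors.
#' @export
impute_features <- function(day_table, train_ids, features = NULL,
                            miss_threshold = 0.2, n_iter = 10, n_cats = 3,
                            seed = 1) {
  prov <- attr(day_table, "provenance")
  if (is.null(features)) {
    num <- vapply(day_table, is.numeric, logical(1))
    features <- setdiff(names(day_table)[num], c("day"))
  }
  train <- day_table$patient_id %in% train_ids
  if (!any(train)) stop("no training rows: refusing to fit imputation on the evaluation split",
                        call. = FALSE)
  # stage 1: LOCF within admission
  for (f in features) {
    for (pid in unique(day_table$patient_id)) {
      idx <- which(day_table$patient_id == pid)
      x <- day_table[[f]][idx]
      filled <- x
      last <- NA_real_
      for (k in seq_along(x)) {
        if (is.na(filled[k])) filled[k] <- last else last <- filled[k]
      }
      carried <- is.na(x) & !is.na(filled)
      day_table[[f]][idx] <- filled
      if (!is.null(prov) && f %in% colnames(prov)) {
        prov[idx[carried], f] <- "carried"
      }
    }
  }
  miss_rate <- vapply(features, function(f) mean(is.na(day_table[[f]][train])),
                      numeric(1))
  impute_set <- features[miss_rate > 0 & miss_rate < miss_threshold]
  cat_set <- features[miss_rate >= miss_threshold]
  # stage 2a: chained-equation imputation, train-fitted
  if (length(impute_set)) {
    set.seed(seed)
    predictors <- features[miss_rate < miss_threshold]
    # initialise with training medians
    for (f in impute_set) {
      med <- stats::median(day_table[[f]][train], na.rm = TRUE)
      nas <- is.na(day_table[[f]])
      day_table[[f]][nas] <- med
      if (!is.null(prov) && f %in% colnames(prov)) prov[nas, f] <- "imputed"
      attr(day_table, paste0(".miss_", f)) <- nas
    }
    for (it in seq_len(n_iter)) {
      for (f in sample(impute_set)) {
        nas <- attr(day_table, paste0(".miss_", f))
        rhs <- setdiff(predictors, f)
        X <- as.matrix(day_table[rhs])
        keep <- colSums(is.na(X)) == 0 & apply(X, 2, stats::sd) > 0
        X <- X[, keep, drop = FALSE]
        if (!ncol(X)) next
        fit <- stats::lm.fit(cbind(1, X[train & !nas, , drop = FALSE]),
                             day_table[[f]][train & !nas])
        pred <- cbind(1, X[nas, , drop = FALSE]) %*% fit$coefficients
        pred[is.na(pred)] <- stats::median(day_table[[f]][train])
        day_table[[f]][nas] <- as.numeric(pred)
      }
    }
    for (f in impute_set) attr(day_table, paste0(".miss_", f)) <- NULL
  }
  # stage 2b: missing-indicator categorisation, train quantile cuts
  for (f in cat_set) {
    cuts <- unique(stats::quantile(day_table[[f]][train], na.rm = TRUE,
                                   probs = seq(0, 1, length.out = n_cats + 1)))
    cuts <- cuts[!is.na(cuts)]
    lab <- if (length(cuts) >= 2) {
      as.character(cut(day_table[[f]], breaks = cuts, include.lowest = TRUE))
    } else { # all-missing or constant on the training split
      ifelse(is.na(day_table[[f]]), NA_character_, "constant")
    }
    nas <- is.na(lab)
    lab[nas] <- "missing"
    if (!is.null(prov) && f %in% colnames(prov)) {
      prov[nas & prov[, f] == "missing", f] <- "missing_level"
    }
    day_table[[f]] <- factor(lab)
  }
  attr(day_table, "provenance") <- prov
  attr(day_table, "categorised") <- cat_set
  day_table
}

#' Fit a robust scaler on the training split
#'
#' Per-feature median and IQR learned on the training rows; features with
#' zero IQR are flagged constant and passed through unscaled. The state is a
#' plain list, serialisable to JSON and reloadable bit-exactly.
#'
#' @param day_table Feature table.
#' @param train_ids Training-patient ids.
#' @param features Numeric columns to scale (default: all numeric except
#'   `day`).
#' @return A list of class `scaler_state`: `features`, `center`, `scale`,
#'   `constant` (logical).
#' @export
fit_scaler <- function(day_table, train_ids, features = NULL) {
  if (is.null(features)) {
    num <- vapply(day_table, is.numeric, logical(1))
    features <- setdiff(names(day_table)[num], "day")
  }
  train <- day_table$patient_id %in% train_ids
  center <- vapply(features, function(f) {
    stats::median(day_table[[f]][train], na.rm = TRUE)
  }, numeric(1))
  scale <- vapply(features, function(f) {
    stats::IQR(day_table[[f]][train], na.rm = TRUE)
  }, numeric(1))
  structure(list(features = features, center = center, scale = scale,
                 constant = scale == 0), class = "scaler_state")
}

#' Apply a fitted robust scaler
#'
#' @param day_table Feature table (training, validation or external — the
#'   state is applied unchanged).
#' @param state A `scaler_state` from [fit_scaler()].
#' @return The scaled table.
#' @export
apply_scaler <- function(day_table, state) {
  for (k in seq_along(state$features)) {
    f <- state$features[k]
    if (state$constant[k] || !f %in% names(day_table)) next
    day_table[[f]] <- (day_table[[f]] - state$center[k]) / state$scale[k]
  }
  day_table
}

#' Serialise / restore a scaler state
#' @param state A `scaler_state`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `scaler_state` (read).
#' @export
write_scaler <- function(state, path) {
  jsonlite::write_json(unclass(state), path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = x$features,
                 center = stats::setNames(x$center, x$features),
                 scale = stats::setNames(x$scale, x$features),
                 constant = stats::setNames(as.logical(x$constant), x$features)),
            class = "scaler_state")
}
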