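#' Classification metric panel with binned calibration
#'
#' Computes accuracy, precision, recall, specificity and F1 at the given
#' probability cutoff, AUROC (via pROC), AUPRC (step summation of the
#' precision-recall curve), and a 5-bin calibration summary: predictions are
#' sorted into equal-count bins and the calibration slope is the least-squares
#' slope of observed event rate on mean predicted probability across bins.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted probabilities.
#' @param cutoff Classification cutoff (default 0.5).
#' @param n_bins Calibration bins (default 5).
#' @return A list of class `eval_report`: the metric panel, `confusion`
#'   (tp/fp/tn/fn), `calibration` (`slope`, `intercept`, `table`,
#'   `degenerate`). AUPRC is `NA` with a warning when there are no positives;
#'   the calibration fit is flagged degenerate when the bin means have zero
#'   variance.
#' @export
metric_panel <- function(labels, scores, cutoff = 0.5, n_bins = 5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  auroc <- if (length(unique(labels)) == 2) {
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  } else NA_real_
  auprc <- if (sum(labels) == 0) {
    warning("AUPRC undefined: no positive labels")
    NA_real_
  } else auprc_step(labels, scores)
  cal <- calibration_bins(labels, scores, n_bins)
  structure(list(n = n, accuracy = (tp + tn) / n, precision = prec,
                 recall = rec, specificity = spec, f1 = f1, auroc = auroc,
                 auprc = auprc,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 calibration = cal),
            class = "eval_report")
}

# Area under the precision-recall curve by step summation over distinct
# score thresholds (precision interpolated at each recall step).
auprc_step <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  keep <- c(diff(sc) != 0, TRUE) # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels)
  sum(diff(c(0, rec)) * prec)
}

calibration_bins <- function(labels, scores, n_bins = 5) {
  ord <- order(scores)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  tab <- data.frame(bin = seq_len(n_bins))
  tab$mean_pred <- vapply(seq_len(n_bins), function(b) {
    mean(scores[ord][bin == b])
  }, numeric(1))
  tab$obs_rate <- vapply(seq_len(n_bins), function(b) {
    mean(labels[ord][bin == b])
  }, numeric(1))
  tab$n <- vapply(seq_len(n_bins), function(b) sum(bin == b), integer(1))
  degenerate <- stats::var(tab$mean_pred) == 0 || any(is.na(tab$mean_pred))
  if (degenerate) {
    return(list(slope = NA_real_, intercept = NA_real_, table = tab,
                degenerate = TRUE))
  }
  fit <- stats::lm(obs_rate ~ mean_pred, data = tab)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), table = tab,
       degenerate = FALSE)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n=%d acc=%.4f prec=%.4f rec=%.4f spec=%.4f F1=%.4f AUROC=%.4f AUPRC=%.4f cal.slope=%.3f\n",
              x$n, x$accuracy, x$precision, x$recall, x$specificity, x$f1,
              x$auroc, x$auprc, x$calibration$slope))
  invisible(x)
}

model_matrix_for <- function(df, features) {
  X <- stats::model.matrix(~ . - 1, data = df[features])
  storage.mode(X) <- "double"
  X
}

fit_one <- function(model, X, y, seed) {
  switch(model,
         logistic = {
           d <- as.data.frame(X); d$.y <- y
           stats::glm(.y ~ ., data = d, family = stats::binomial())
         },
         rf = {
           if (!requireNamespace("ranger", quietly = TRUE)) {
             stop("ranger not installed; use model = 'logistic'", call. = FALSE)
           }
           d <- as.data.frame(X); d$.y <- factor(y, levels = c(0, 1))
           ranger::ranger(.y ~ ., data = d, probability = TRUE,
                          num.trees = 300, seed = seed)
         },
         xgboost = {
           if (!requireNamespace("xgboost", quietly = TRUE)) {
             stop("xgboost not installed; use model = 'logistic'", call. = FALSE)
           }
           xgboost::xgboost(data = X, label = y, nrounds = 100, max_depth = 4,
                            eta = 0.1, objective = "binary:logistic",
                            nthread = 1, verbose = 0)
         },
         stop(sprintf("unknown model family '%s'", model), call. = FALSE))
}

predict_one <- function(model, fit, X) {
  switch(model,
         logistic = {
           as.numeric(stats::predict(fit, newdata = as.data.frame(X),
                                     type = "response"))
         },
         rf = ranger::predictions(stats::predict(fit, data = as.data.frame(X)))[, "1"],
         xgboost = as.numeric(stats::predict(fit, X)))
}

# Patient-grouped fold assignment: all rows of a patient share a fold.
grouped_folds <- function(patient_ids, n_folds, seed) {
  set.seed(seed)
  pats <- unique(patient_ids)
  fold_of <- sample(rep_len(seq_len(n_folds), length(pats)))
  names(fold_of) <- pats
  unname(fold_of[patient_ids])
}

#' Train a classifier with patient-grouped cross-validation
#'
#' Fold assignment is by patient, never by row, so no patient's days are
#' split between training and validation. Model families are pluggable
#' behind one adapter: `"logistic"` (stats::glm, the default), `"rf"`
#' (ranger) and `"xgboost"`. Per-fold metric panels are computed at cutoff
#' 0.5 and summarised as means and SDs; a final model is refitted on all
#' rows.
#'
#' @param day_table Labeled feature table: needs `patient_id`, `label`
#'   (0/1; excluded rows removed upstream), and the feature columns.
#' @param features Feature column names.
#' @param model `"logistic"`, `"rf"` or `"xgboost"`.
#' @param n_folds Number of CV folds (default 5).
#' @param seed Seed for fold assignment and stochastic learners.
#' @return A list of class `trained_model`: `fit` (full-data model),
#'   `model`, `features`, `cv` (per-fold reports, `mean`, `sd`), `folds`.
#' @export
train_models <- function(day_table, features, model = "logistic",
                         n_folds = 5, seed = 1) {
  stopifnot(all(day_table$label %in% c(0, 1)))
  y <- as.integer(day_table$label)
  X <- model_matrix_for(day_table, features)
  folds <- grouped_folds(day_table$patient_id, n_folds, seed)
  for (k in seq_len(n_folds)) {
    if (length(unique(y[folds != k])) < 2) {
      stop(sprintf("training split of fold %d contains a single class", k),
           call. = FALSE)
    }
  }
  reports <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit_k <- fit_one(model, X[tr, , drop = FALSE], y[tr], seed + k)
    sc <- predict_one(model, fit_k, X[!tr, , drop = FALSE])
    reports[[k]] <- metric_panel(y[!tr], sc)
  }
  metric_names <- c("accuracy", "precision", "recall", "specificity", "f1",
                    "auroc", "auprc")
  mm <- sapply(reports, function(r) unlist(r[metric_names]))
  fit <- fit_one(model, X, y, seed)
  structure(list(fit = fit, model = model, features = features,
                 cv = list(reports = reports,
                           mean = rowMeans(mm, na.rm = TRUE),
                           sd = apply(mm, 1, stats::sd, na.rm = TRUE)),
                 folds = folds,
                 patients = unique(day_table$patient_id)),
            class = "trained_model")
}

#' Predict probabilities from a trained model
#' @param object A `trained_model`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Numeric probability vector.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  predict_one(object$model, object$fit,
              model_matrix_for(newdata, object$features))
}

#' Evaluate a trained model on a held-out table
#'
#' @param model A `trained_model`.
#' @param day_table Labeled feature table with patients disjoint from
#'   training (checked; overlapping patients raise an error).
#' @param check_disjoint Set `FALSE` to skip the leakage check (e.g. for
#'   apparent performance).
#' @return An `eval_report` (see [metric_panel()]).
#' @export
evaluate_model <- function(model, day_table, check_disjoint = TRUE) {
  if (check_disjoint) {
    overlap <- intersect(model$patients, unique(day_table$patient_id))
    if (length(overlap)) {
      stop(sprintf("evaluation patients overlap training: %s%s",
                   paste(utils::head(overlap, 3), collapse = ", "),
                   if (length(overlap) > 3) ", ..." else ""), call. = FALSE)
    }
  }
  sc <- predict.trained_model(model, day_table)
  metric_panel(as.integer(day_table$label), sc)
}

#' Rolling yearly framework simulation
#'
#' Replays a labeled cohort period by period (calendar year of admission by
#' default): every labelable patient-day gets a prediction; an AKI event
#' counts as predicted early when at least one of its 1-3 pre-onset labeled
#' days is flagged at the cutoff. Reports per period: patients, events,
#' events predicted early, F1 over the period's labeled days, and the alarm
#' count (flagged days).
#'
#' @param day_table Labeled feature table (`patient_id`, `day`, `label`,
#'   features) restricted to non-excluded rows.
#' @param events Refined event table ([detect_aki_cohort()]).
#' @param admissions Admission table (for the admission year).
#' @param model A `trained_model` (or a function `(day_table) -> scores`).
#' @param cutoff Alarm cutoff (default 0.5).
#' @return A data.frame, one row per period: `period`, `n_patients`,
#'   `n_events`, `n_predicted_early`, `f1`, `n_alarms`. Periods with zero
#'   events report `NA` early-prediction rate components and `f1`.
#' @export
run_framework_sim <- function(day_table, events, admissions, model,
                              cutoff = 0.5) {
  scores <- if (is.function(model)) model(day_table) else {
    predict.trained_model(model, day_table)
  }
  year <- as.integer(format(admissions$admit_time, "%Y"))
  names(year) <- admissions$patient_id
  day_table$period <- year[day_table$patient_id]
  day_table$score <- scores
  out <- lapply(sort(unique(day_table$period)), function(p) {
    dt <- day_table[day_table$period == p, , drop = FALSE]
    ev <- events[events$aki & events$patient_id %in% dt$patient_id, , drop = FALSE]
    early <- vapply(seq_len(nrow(ev)), function(j) {
      pre <- dt$patient_id == ev$patient_id[j] & dt$label == 1
      any(dt$score[pre] >= cutoff)
    }, logical(1))
    lab <- as.integer(dt$label)
    f1 <- if (sum(lab) > 0) metric_panel(lab, dt$score, cutoff)$f1 else NA_real_
    data.frame(period = p, n_patients = length(unique(dt$patient_id)),
               n_events = nrow(ev), n_predicted_early = sum(early),
               f1 = f1, n_alarms = sum(dt$score >= cutoff))
  })
  do.call(rbind, out)
}
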