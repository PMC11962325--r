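# Independent oracles and random-case generators for property tests.
# These deliberately re-derive everything from the definitions with plain
# nested loops and never call the package's windowed implementations.

HOUR <- 3600
DAY <- 86400

# Random irregular SCr trajectory: base level with jitter, occasional dips
# and spikes, values on a 0.01 grid so exact-threshold ties are exercised.
random_trajectory <- function() {
  n <- sample(4:14, 1)
  gaps <- sample(4:40, n - 1, replace = TRUE) * HOUR
  times <- as.POSIXct("2019-06-01 08:00:00", tz = "UTC") + cumsum(c(0, gaps))
  base <- round(runif(1, 0.4, 1.4), 2)
  v <- base + rnorm(n, 0, 0.08)
  kind <- runif(n)
  v[kind < 0.12] <- v[kind < 0.12] - runif(sum(kind < 0.12), 0.2, 0.5) # dips
  k2 <- kind > 0.85
  v[k2] <- v[k2] + runif(sum(k2), 0.2, 0.8) # rises
  v <- round(pmax(v, 0.15), 2)
  list(times = times, values = v)
}

# Brute-force standard KDIGO: every (measurement, earlier measurement) pair.
brute_standard_onset <- function(times, values, tol = 1e-9) {
  t <- as.numeric(times)
  for (i in seq_along(values)) {
    for (j in seq_len(i - 1)) {
      if (j < 1) next
      dt <- t[i] - t[j]
      if (dt <= 0 || dt >= 7 * DAY) next
      if (dt < 48 * HOUR && values[i] - values[j] >= 0.3 - tol) return(i)
      if (values[i] - 1.5 * values[j] >= -tol) return(i)
    }
  }
  NA_integer_
}

# Brute-force refined baseline at measurement i: enumerate every candidate
# in ascending order, testing the exclusion rule literally.
brute_refined_baseline <- function(times, values, i, tol = 1e-9) {
  t <- as.numeric(times)
  win <- which(t > t[i] - 7 * DAY & t < t[i])
  if (!length(win)) return(list(value = NA_real_, time = NA_real_, reason = "empty"))
  ord <- win[order(values[win], t[win])]
  for (c in ord) {
    others <- setdiff(win, c)
    if (!length(others)) return(list(value = values[c], time = t[c], reason = "min"))
    med <- median(values[others])
    recent <- values[others[which.max(t[others])]]
    below_med <- med - values[c] >= 0.3 - tol
    below_recent <- recent - values[c] >= 0.3 - tol
    if (!(below_med && below_recent)) {
      return(list(value = values[c], time = t[c], reason = "min"))
    }
  }
  list(value = median(values[win]), time = NA_real_, reason = "all_excluded")
}

brute_refined_onset <- function(times, values, tol = 1e-9) {
  t <- as.numeric(times)
  for (i in seq_along(values)) {
    bl <- brute_refined_baseline(times, values, i, tol)
    if (bl$reason == "empty") next
    if (values[i] - bl$value < 0.3 - tol) next
    within48 <- !is.na(bl$time) && t[i] - bl$time < 48 * HOUR
    ratio_ok <- values[i] - 1.5 * bl$value >= -tol
    if (within48 || ratio_ok) return(i)
  }
  NA_integer_
}

# CKD-EPI 2021 reference: independent log-space evaluation of the published
# equation.
egfr_reference <- function(scr, age, sex) {
  k <- if (sex == "female") 0.7 else 0.9
  a <- if (sex == "female") -0.241 else -0.302
  lr <- log(scr / k)
  lg <- log(142) + a * min(lr, 0) - 1.2 * max(lr, 0) + age * log(0.9938) +
    if (sex == "female") log(1.012) else 0
  exp(lg)
}

# Brute-force confusion metrics and pairwise-concordance AUROC.
brute_metrics <- function(labels, scores, cutoff = 0.5) {
  pred <- ifelse(scores >= cutoff, 1L, 0L)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(labels)) {
    if (pred[i] == 1 && labels[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && labels[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && labels[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && labels[i] == 1) fn <- fn + 1
  }
  list(accuracy = (tp + tn) / length(labels),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

brute_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
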