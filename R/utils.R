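# Internal helpers shared across modules.

SECONDS_PER_HOUR <- 3600
SECONDS_PER_DAY <- 86400

# All timestamps are naive wall-clock; parsed and handled in UTC so that
# calendar-day arithmetic is independent of the host timezone.
parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

format_time <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

# Calendar day of a timestamp (Date, UTC midnight boundary).
time_day <- function(x) as.Date(x, tz = "UTC")

# 1-based admission-day index of a timestamp given the admission start.
day_index <- function(time, admit_time) {
  as.integer(time_day(time) - time_day(admit_time)) + 1L
}

# Comparison tolerance on creatinine thresholds (mg/dL).
SCR_TOL <- 1e-9

# x >= threshold up to tolerance
geq <- function(x, threshold, tol = SCR_TOL) x - threshold >= -tol

# x < threshold (strict) up to tolerance
lt_strict <- function(x, threshold, tol = SCR_TOL) threshold - x > tol

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}
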