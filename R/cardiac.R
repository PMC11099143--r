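#' Convert beat times to a beats-per-minute series
#'
#' Each inter-beat interval (IBI) yields one BPM value (BPM = 60/IBI),
#' timestamped at the interval's second beat, then linearly interpolated to
#' a regular grid for windowed averaging.
#'
#' @param beat_times strictly increasing beat timestamps in seconds.
#' @param grid_hz sampling rate of the interpolation grid (default 10 Hz).
#' @return an object of class `pat_bpm`: a list with `raw_time`, `raw_bpm`
#'   (one value per IBI) and `time`, `bpm` (the interpolated grid; NA
#'   outside the raw coverage).
#' @export
#' @examples
#' tr <- ibi_to_bpm(seq(0, 10, by = 1))  # constant 1 s IBI
#' unique(tr$raw_bpm)                    # 60
ibi_to_bpm <- function(beat_times, grid_hz = 10) {
  if (length(beat_times) < 2L)
    stop("need at least 2 beats", call. = FALSE)
  ibi <- diff(beat_times)
  if (any(ibi <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  raw_time <- beat_times[-1]
  raw_bpm <- 60 / ibi
  grid <- seq(ceiling(raw_time[1] * grid_hz) / grid_hz,
              floor(raw_time[length(raw_time)] * grid_hz) / grid_hz,
              by = 1 / grid_hz)
  bpm <- if (length(raw_time) >= 2)
    stats::approx(raw_time, raw_bpm, xout = grid, rule = 1)$y
  else rep(raw_bpm, length(grid))
  structure(list(raw_time = raw_time, raw_bpm = raw_bpm,
                 time = grid, bpm = bpm),
            class = "pat_bpm")
}

#' Trial-wise bradycardia index from a cardiac trace
#'
#' Computes \eqn{\Delta hr}: the mean baseline-corrected heart rate over a
#' 5-7 s window after the anticipation onset, with the baseline taken as the
#' mean BPM over the 1 s window immediately before onset. Negative values
#' indicate anticipatory deceleration (bradycardia). Quality control flags a
#' trial when either window is not covered by the trace, or when any IBI
#' (equivalently, any gap in the BPM series) within the trial's span falls
#' outside [0.33, 2] s.
#'
#' @param trace a `pat_bpm` object or a numeric vector of beat times.
#' @param onset anticipation onset in the trace's time base (seconds).
#' @param baseline_window,dhr_window windows in seconds relative to onset.
#' @return list with `baseline_bpm`, `dhr`, `quality` ("ok"/"bad").
#' @export
compute_dhr <- function(trace, onset, baseline_window = c(-1, 0),
                        dhr_window = c(5, 7)) {
  if (is.numeric(trace)) trace <- ibi_to_bpm(trace)
  stopifnot(inherits(trace, "pat_bpm"))
  lo <- onset + baseline_window[1]
  hi <- onset + dhr_window[2]
  span <- trace$raw_time >= lo - 2 & trace$raw_time <= hi + 2
  ibi_ok <- all(60 / trace$raw_bpm[span] >= 0.33 &
                  60 / trace$raw_bpm[span] <= 2)
  gap_ok <- length(trace$raw_time) >= 2 &&
    max(diff(trace$raw_time[trace$raw_time >= lo & trace$raw_time <= hi]),
        0) <= 2
  win_mean <- function(w) {
    sel <- trace$time >= onset + w[1] & trace$time <= onset + w[2]
    v <- trace$bpm[sel]
    if (!length(v) || anyNA(v)) NA_real_ else mean(v)
  }
  baseline <- win_mean(baseline_window)
  resp <- win_mean(dhr_window)
  covered <- trace$raw_time[1] <= lo && trace$raw_time[length(trace$raw_time)] >= hi
  ok <- covered && ibi_ok && gap_ok && !is.na(baseline) && !is.na(resp)
  list(baseline_bpm = baseline,
       dhr = if (ok) resp - baseline else NA_real_,
       quality = if (ok) "ok" else "bad")
}

#' Compute the bradycardia index for every long trial of a dataset
#'
#' Convenience wrapper running [ibi_to_bpm()] and [compute_dhr()] over the
#' `beats` list-column produced by [simulate_cardiac()] /
#' [simulate_dataset()].
#'
#' @param trials trial table containing `onset` and `is_long`.
#' @param traces tibble with `subject, run, trial, beats` (long trials).
#' @return `trials` with added `dhr` and `quality` columns (NA / "bad" on
#'   short trials and uncovered traces).
#' @export
compute_dhr_table <- function(trials, traces) {
  key <- function(d) paste(d$subject, d$run, d$trial)
  idx <- match(key(trials), key(traces))
  dhr <- rep(NA_real_, nrow(trials))
  quality <- rep("bad", nrow(trials))
  for (i in which(!is.na(idx))) {
    b <- traces$beats[[idx[i]]]
    if (is.null(b) || length(b) < 2) next
    rec <- compute_dhr(b, onset = trials$onset[i])
    dhr[i] <- rec$dhr
    quality[i] <- rec$quality
  }
  trials$dhr <- dhr
  trials$quality <- quality
  trials
}

#' Apply trial-level exclusion rules
#'
#' Drops, in order: short-AMI trials (the cardiac response is too slow to
#' develop on them), trials flagged for poor heart-rate data, and
#' active-response trials with response times below 200 ms. The report
#' counts exclusions per rule; counts always sum to the difference between
#' input and output rows.
#'
#' @param table trial table with `is_long`, `rt`, `action_context`,
#'   `choice`, and optionally `quality`.
#' @param rt_min minimum RT in seconds for active responses.
#' @return list with `trials` (retained rows) and `report` (tibble of rule,
#'   n_excluded).
#' @export
apply_exclusions <- function(table, rt_min = 0.200) {
  n0 <- nrow(table)
  keep <- table$is_long
  n_short <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  bad <- if ("quality" %in% names(table)) table$quality != "ok" else
    rep(FALSE, nrow(table))
  n_bad <- sum(bad)
  table <- table[!bad, , drop = FALSE]

  fast <- !is.na(table$rt) & table$rt < rt_min
  n_fast <- sum(fast)
  table <- table[!fast, , drop = FALSE]

  report <- tibble::tibble(
    rule = c("short_ami", "poor_heart_rate", "fast_rt", "total"),
    n_excluded = c(n_short, n_bad, n_fast, n0 - nrow(table)))
  list(trials = table, report = report)
}

#' Standardize model predictors across the pooled analysis set
#'
#' Mean-centers and scales the continuous predictors (money, shocks, the
#' money-shock difference, and the bradycardia index) using the pooled
#' mean and population SD over all included trials of all subjects, and
#' sum-codes the action context (-1 active, +1 passive). The money-shock
#' difference is computed on the raw levels first, then standardized. The
#' standardization statistics are frozen as an attribute so the same
#' transform can be re-applied when building regressors.
#'
#' @param table post-exclusion analysis-set table with `money, shocks,
#'   action_context` and a bradycardia column `dhr`.
#' @param stats optional frozen statistics from a previous call (the
#'   `"standardization"` attribute) to re-apply.
#' @return the table with added `z_money, z_shocks, z_dms, z_dhr, ac_code`
#'   columns and a `"standardization"` attribute.
#' @export
standardize_predictors <- function(table, stats = NULL) {
  dms <- table$money - table$shocks
  vars <- list(money = table$money, shocks = table$shocks,
               dms = dms, dhr = table$dhr)
  if (is.null(stats)) {
    stats <- lapply(vars, function(x) {
      m <- mean(x)
      s <- sqrt(mean((x - m)^2))
      if (s == 0)
        stop("zero pooled SD; cannot standardize", call. = FALSE)
      c(mean = m, sd = s)
    })
  }
  z <- function(x, st) (x - st["mean"]) / st["sd"]
  table$z_money <- z(vars$money, stats$money)
  table$z_shocks <- z(vars$shocks, stats$shocks)
  table$z_dms <- z(vars$dms, stats$dms)
  table$z_dhr <- z(vars$dhr, stats$dhr)
  table$ac_code <- ifelse(table$action_context == "active", -1, 1)
  attr(table, "standardization") <- stats
  table
}
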