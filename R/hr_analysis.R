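#' Per-minute heart-rate epochs from a duty-cycled recording
#'
#' One epoch per recorded segment (minute).  Epoch HR is 60000 divided by the
#' mean RR interval (ms) within the segment, which for a contiguous beat
#' sequence equals \code{(n-1)/(t_last - t_first) * 60}.  An epoch is invalid
#' when it holds fewer than \code{min_beats} beats or overlaps artifact
#' intervals by more than \code{max_artifact_frac} of its length.
#'
#' @param beat_times beat times (s), sorted.
#' @param segments data.frame (start, end) of recorded segments (s).
#' @param artifacts optional data.frame (start, end) of artifact intervals.
#' @param t0_clock clock time (h) at t = 0, for day/night assignment.
#' @param day_start,day_end lights-on window (h).
#' @param min_beats minimum beats for a valid epoch.
#' @param max_artifact_frac maximum tolerated artifact overlap fraction.
#' @return data.frame (start, end, clock, is_day, n_beats, hr, valid).
#' @export
hr_epochs <- function(beat_times, segments, artifacts = NULL, t0_clock = 7,
                      day_start = 7, day_end = 19,
                      min_beats = 20, max_artifact_frac = 0.2) {
  if (is.unsorted(beat_times)) stop("beat_times must be sorted")
  ns <- nrow(segments)
  i0 <- findInterval(segments$start - 1e-9, beat_times) + 1L
  i1 <- findInterval(segments$end + 1e-9, beat_times)
  n_beats <- pmax(i1 - i0 + 1L, 0L)
  hr <- rep(NA_real_, ns)
  ok <- n_beats >= 2L
  hr[ok] <- (n_beats[ok] - 1) /
    (beat_times[i1[ok]] - beat_times[i0[ok]]) * 60
  art_frac <- numeric(ns)
  if (!is.null(artifacts) && nrow(artifacts)) {
    for (r in seq_len(nrow(artifacts))) {
      ov <- pmin(segments$end, artifacts$end[r]) -
        pmax(segments$start, artifacts$start[r])
      art_frac <- art_frac + pmax(ov, 0)
    }
    art_frac <- art_frac / (segments$end - segments$start)
  }
  clock <- (t0_clock + segments$start / 3600) %% 24
  data.frame(start = segments$start, end = segments$end,
             clock = clock,
             is_day = clock >= day_start & clock < day_end,
             n_beats = n_beats, hr = hr,
             valid = n_beats >= min_beats & art_frac <= max_artifact_frac &
               !is.na(hr))
}

#' Day/night heart-rate summary over a long-term recording
#'
#' Mean epoch HR partitioned by the lights-on window, plus the naturally
#' occurring minimum and maximum epoch HR, all over valid epochs only.
#'
#' @param epochs data.frame from \code{\link{hr_epochs}}.
#' @return one-row data.frame (mean_day, mean_night, min_hr, max_hr, n_valid,
#'   defined); \code{defined} is FALSE when no valid epoch exists in one of
#'   the partitions.
#' @export
daynight_summary <- function(epochs) {
  v <- epochs[epochs$valid, , drop = FALSE]
  day <- v$hr[v$is_day]
  night <- v$hr[!v$is_day]
  defined <- length(day) > 0 && length(night) > 0
  data.frame(mean_day = if (length(day)) mean(day) else NA_real_,
             mean_night = if (length(night)) mean(night) else NA_real_,
             min_hr = if (nrow(v)) min(v$hr) else NA_real_,
             max_hr = if (nrow(v)) max(v$hr) else NA_real_,
             n_valid = nrow(v), defined = defined)
}

#' Activity class of an activity value
#'
#' Telemetry activity (A.U.) binned into the 8 standard classes: class 0 is
#' exactly zero activity; classes 1-7 are the half-open intervals (0,5],
#' (5,10], (10,15], (15,20], (20,25], (25,30], (30,300].  Values above 300
#' are clipped into class 7 with a warning.
#'
#' @param a numeric activity values (A.U.).
#' @return integer class indices 0-7.
#' @export
activity_class <- function(a) {
  if (any(a < 0, na.rm = TRUE)) stop("activity must be >= 0")
  if (any(a > 300, na.rm = TRUE))
    warning("activity values > 300 A.U. clipped to class 7")
  a <- pmin(a, 300)
  cls <- as.integer(cut(a, c(0, 5, 10, 15, 20, 25, 30, 300),
                        labels = FALSE, right = TRUE))
  cls[a == 0] <- 0L
  cls
}

#' Activity-normalized heart rate
#'
#' Assigns every valid HR epoch the activity class of its concurrent 5-min
#' activity epoch and averages HR per class, separately for day and night.
#'
#' @param epochs data.frame from \code{\link{hr_epochs}}.
#' @param activity data.frame (epoch_start, value) on the 5-min grid.
#' @return data.frame (period, class, hr, n); classes with no epochs are
#'   absent.
#' @export
bin_hr_by_activity <- function(epochs, activity) {
  v <- epochs[epochs$valid, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(period = character(), class = integer(),
                      hr = numeric(), n = integer()))
  idx <- findInterval(v$start + 1e-9, activity$epoch_start)
  if (any(idx < 1L)) stop("epochs start before the activity series")
  cls <- activity_class(activity$value[idx])
  period <- ifelse(v$is_day, "day", "night")
  agg <- stats::aggregate(v$hr, list(period = period, class = cls),
                          function(x) c(mean(x), length(x)))
  data.frame(period = agg$period, class = agg$class,
             hr = agg$x[, 1], n = as.integer(agg$x[, 2]))
}

#' Heart-rate reduction under chronic beta-blockade
#'
#' Difference between the mean day (night) HR under baseline conditions and
#' under metoprolol; positive values mean the drug lowered HR.
#'
#' @param summary_baseline,summary_metoprolol one-row data.frames from
#'   \code{\link{daynight_summary}} for the two phases of the same animal.
#' @return one-row data.frame (delta_day, delta_night).
#' @export
metoprolol_delta <- function(summary_baseline, summary_metoprolol) {
  if (!isTRUE(summary_baseline$defined) || !isTRUE(summary_metoprolol$defined))
    stop("both phase summaries must be defined")
  data.frame(delta_day = summary_baseline$mean_day -
               summary_metoprolol$mean_day,
             delta_night = summary_baseline$mean_night -
               summary_metoprolol$mean_night)
}

#' Acute chronotropic response over the post-injection window
#'
#' HR on short sliding epochs (default 10 s, resolving the isoproterenol
#' peak that 1-min epochs blur) over the 5 h following an injection; returns
#' the maximal and mean epoch HR, excluding artifact-contaminated epochs.
#'
#' @param beat_times beat times (s) of a continuous recording.
#' @param t_inj injection time (s).
#' @param window analysis window length (s).
#' @param epoch_len epoch length (s).
#' @param artifacts optional artifact intervals.
#' @param min_coverage flag the summary when fewer than this fraction of
#'   epochs is valid.
#' @return one-row data.frame (max_hr, mean_hr, n_valid, coverage, flagged).
#' @export
iso_response <- function(beat_times, t_inj, window = 5 * 3600,
                         epoch_len = 10, artifacts = NULL,
                         min_coverage = 0.9) {
  t_end <- min(t_inj + window, max(beat_times))
  starts <- seq(t_inj, t_end - epoch_len, by = epoch_len)
  seg <- data.frame(start = starts, end = starts + epoch_len)
  ep <- hr_epochs(beat_times, seg, artifacts, min_beats = 5)
  v <- ep[ep$valid, , drop = FALSE]
  coverage <- nrow(v) / nrow(ep)
  data.frame(max_hr = if (nrow(v)) max(v$hr) else NA_real_,
             mean_hr = if (nrow(v)) mean(v$hr) else NA_real_,
             n_valid = nrow(v), coverage = coverage,
             flagged = coverage < min_coverage)
}
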