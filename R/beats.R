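#' Generate sinus beat times from an HR trace
#'
#' Beat times are obtained by exact inversion of the integrated instantaneous
#' rate: the k-th beat falls where the cumulative beat count
#' \eqn{\Lambda(t) = \int \mathrm{HR}(s)/60\, ds} crosses \eqn{u_0 + k}, with
#' a random phase \eqn{u_0} and a small multiplicative RR jitter.  This is
#' exact for arbitrary time-varying HR and yields the quasi-periodic RR
#' structure of sinus rhythm (unlike Poisson thinning, whose exponential
#' inter-event intervals do not resemble a heartbeat).
#'
#' @param trace an \code{hr_trace} from \code{\link{simulate_hr_profile}}.
#' @param rr_jitter SD of the multiplicative beat-to-beat RR jitter
#'   (dimensionless; 0 for perfectly regular rhythm).
#' @param t_offset shift added to all beat times (s), e.g. a segment start.
#' @return numeric vector of beat times (s), strictly increasing.
#' @export
sinus_beats <- function(trace, rr_jitter = 0.015, t_offset = 0) {
  stopifnot(inherits(trace, "hr_trace"))
  dt <- trace$dt
  lam <- cumsum(trace$hr / 60 * dt)        # cumulative beats at step ends
  lam <- c(0, lam)
  tgrid <- c(trace$time[1], trace$time + dt)
  total <- lam[length(lam)]
  u0 <- stats::runif(1)
  n <- floor(total - u0)
  if (n < 1) return(numeric(0))
  quanta <- u0 + seq_len(n)
  if (rr_jitter > 0)
    quanta <- quanta + stats::rnorm(n, sd = rr_jitter)
  quanta <- pmin(pmax(cummax(quanta), 1e-9), total - 1e-9)
  t_offset + stats::approx(lam, tgrid, xout = quanta, ties = "ordered")$y
}

#' Inject scheduled arrhythmias into a sinus beat stream
#'
#' Rewrites a sinus beat stream according to an event schedule, producing the
#' ground-truth beat annotation used throughout testing.  For a run of k
#' premature ventricular beats the k sinus slots starting at the event onset
#' are replaced: the first PVB is placed at 0.6 of the local RR after the
#' preceding sinus beat, intra-run coupling is 0.55 RR, and the next sinus
#' beat keeps its original timing so that the pause after the run is fully
#' compensatory (for a single PVB, RR_pre + RR_post = 2 RR).  PVBs carry
#' atypical morphology and no P wave.  VF episodes delete all beats in their
#' interval (no distinguishable QRS complexes).
#'
#' Events whose onset falls too close to the stream edges (fewer than
#' \code{warmup} preceding beats, or insufficient following beats) are
#' dropped from the realised truth.
#'
#' @param beats numeric vector of sinus beat times (s).
#' @param schedule an \code{\link{schedule_arrhythmias}} data.frame.
#' @param warmup minimum number of beats before the first injected event.
#' @param premature_frac,intra_frac coupling intervals of the first and
#'   subsequent PVBs of a run, as fractions of the local RR.
#' @return list with \code{beats}: data.frame (time, label "N"/"PVB",
#'   morph_atypical, p_present, event_id) and \code{events}: realised truth
#'   events (id, class, onset, end, n_beats).
#' @export
inject_events <- function(beats, schedule, warmup = 8,
                          premature_frac = 0.6, intra_frac = 0.55) {
  n <- length(beats)
  times <- beats
  label <- rep("N", n)
  morph <- logical(n)
  p_pres <- rep(TRUE, n)
  evid <- rep(NA_integer_, n)
  if (n == 0L || nrow(schedule) == 0L) {
    df <- data.frame(time = times, label = label, morph_atypical = morph,
                     p_present = p_pres, event_id = evid,
                     stringsAsFactors = FALSE)
    return(list(beats = df, events = empty_truth_events()))
  }
  touched <- logical(n)
  keep <- rep(TRUE, n)
  ev_id <- integer(0); ev_cls <- character(0)
  ev_on <- numeric(0); ev_end <- numeric(0); ev_nb <- integer(0)
  next_id <- 1L
  # slot indices against the original sinus grid (events are well separated
  # and injections move beats by less than one RR, so these stay valid)
  i_onset <- findInterval(schedule$onset, beats) + 1L
  i_vf_end <- findInterval(schedule$onset +
                             ifelse(is.na(schedule$duration), 0,
                                    schedule$duration), beats)
  for (r in seq_len(nrow(schedule))) {
    cls <- schedule$class[r]
    if (cls == "VF") {
      lo <- schedule$onset[r]; hi <- lo + schedule$duration[r]
      sel0 <- i_onset[r]:max(i_onset[r], i_vf_end[r])
      sel0 <- sel0[sel0 >= 1L & sel0 <= n]
      sel <- sel0[times[sel0] >= lo & times[sel0] < hi & !touched[sel0]]
      if (length(sel)) {
        keep[sel] <- FALSE
        touched[sel] <- TRUE
      }
      ev_id <- c(ev_id, next_id); ev_cls <- c(ev_cls, "VF")
      ev_on <- c(ev_on, lo); ev_end <- c(ev_end, hi)
      ev_nb <- c(ev_nb, NA_integer_)
      next_id <- next_id + 1L
      next
    }
    k <- schedule$run_length[r]
    i <- i_onset[r]
    if (i <= warmup || (i + k) > n) next           # too close to an edge
    idx <- i:(i + k - 1L)
    if (any(touched[c(idx, i - 1L, i + k)])) next  # collision safeguard
    rr <- times[i] - times[i - 1L]
    newt <- times[i - 1L] + rr * (premature_frac + intra_frac * (seq_len(k) - 1))
    times[idx] <- newt
    label[idx] <- "PVB"
    morph[idx] <- TRUE
    p_pres[idx] <- FALSE
    evid[idx] <- next_id
    touched[idx] <- TRUE
    ev_id <- c(ev_id, next_id); ev_cls <- c(ev_cls, cls)
    ev_on <- c(ev_on, newt[1]); ev_end <- c(ev_end, newt[k])
    ev_nb <- c(ev_nb, k)
    next_id <- next_id + 1L
  }
  df <- data.frame(time = times[keep], label = label[keep],
                   morph_atypical = morph[keep], p_present = p_pres[keep],
                   event_id = evid[keep], stringsAsFactors = FALSE)
  events <- data.frame(id = ev_id, class = ev_cls, onset = ev_on,
                       end = ev_end, n_beats = ev_nb,
                       stringsAsFactors = FALSE)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  list(beats = df, events = events)
}

empty_truth_events <- function() {
  data.frame(id = integer(), class = character(), onset = numeric(),
             end = numeric(), n_beats = integer(), stringsAsFactors = FALSE)
}

#' Duty-cycle segments of a long-term recording
#'
#' Long-term telemetry stores 1 min of waveform per 5-min block.  Returns the
#' recorded segments (the first minute of each block) covering a duration.
#'
#' @param duration total duration (s).
#' @param block block length (s).
#' @param recorded recorded prefix per block (s).
#' @return data.frame with \code{start}, \code{end} (s).
#' @export
duty_cycle_segments <- function(duration, block = 300, recorded = 60) {
  n_blocks <- ceiling(duration / block - 1e-9)
  starts <- block * (seq_len(n_blocks) - 1)
  data.frame(start = starts, end = pmin(starts + recorded, duration))
}
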