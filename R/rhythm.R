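#' RR-interval series with rolling normal reference
#'
#' Successive RR intervals plus, per beat, the rolling reference RR: the
#' median of the k most recent preceding intervals flanked by normal-labeled
#' beats.  The reference is undefined (NA) until k normal intervals have been
#' seen.
#'
#' @param times beat times (s), strictly increasing.
#' @param labels optional beat labels ("N"/"PVB"); intervals adjacent to a
#'   non-normal beat are excluded from the reference.  NULL treats all beats
#'   as normal (first-pass reference; the rolling median is robust to
#'   isolated ectopy).
#' @param k reference window (intervals).
#' @return data.frame (time, rr_pre, rr_post, ref), durations in ms.
#' @export
compute_rr <- function(times, labels = NULL, k = 5) {
  n <- length(times)
  if (n < 2L)
    return(data.frame(time = times, rr_pre = rep(NA_real_, n),
                      rr_post = rep(NA_real_, n), ref = rep(NA_real_, n)))
  if (any(diff(times) <= 0)) stop("beat times must be strictly increasing")
  rr <- diff(times) * 1000                     # interval ending at beat i+1
  rr_pre <- c(NA_real_, rr)
  rr_post <- c(rr, NA_real_)
  if (is.null(labels)) {
    isn <- rep(TRUE, n - 1L)
  } else {
    stopifnot(length(labels) == n)
    isn <- labels[-n] == "N" & labels[-1L] == "N"
  }
  norm_idx <- which(isn) + 1L                  # terminating beat index
  ref <- rep(NA_real_, n)
  if (length(norm_idx) >= k) {
    rm <- rollmed_right(rr[norm_idx - 1L], k)
    # reference for beat i: median over normal intervals ending at beat <= i-1
    pos <- findInterval(seq_len(n) - 1L, norm_idx)
    ok <- pos >= k
    ref[ok] <- rm[pos[ok]]
  }
  data.frame(time = times, rr_pre = rr_pre, rr_post = rr_post, ref = ref)
}

# right-aligned rolling median of window k (odd); NA before warm-up
rollmed_right <- function(x, k) {
  n <- length(x)
  if (n < k) return(rep(NA_real_, n))
  out <- rep(NA_real_, n)
  half <- (k - 1L) %/% 2L
  rm <- stats::runmed(x, k)                   # centered, C implementation
  out[k:n] <- rm[(k - half):(n - half)]
  out
}

#' Evaluate the premature-ventricular-beat criteria
#'
#' A beat is labeled PVB when it is premature (RR before the beat shorter
#' than \code{premature_frac} of the rolling reference) and at least 2 of the
#' following 3 criteria hold: (1) atypical QRS configuration with alteration
#' of the T wave (morphology), (2) atrioventricular dissociation (no P wave
#' found), (3) compensatory post-extrasystolic pause (RR after the beat
#' longer than \code{pause_frac} of the reference).  Criteria that cannot be
#' evaluated (missing neighbour, no reference yet) count as not met.
#'
#' @param rr data.frame from \code{\link{compute_rr}}.
#' @param morph_atypical logical per beat: atypical QRS/T morphology.
#' @param p_found logical per beat: P wave found before the QRS.
#' @param premature_frac prematurity threshold (fraction of reference RR).
#' @param pause_frac compensatory-pause threshold (fraction of reference RR).
#' @return data.frame (premature, c1_atypical_qrs_t, c2_av_dissociation,
#'   c3_compensatory_pause, n_met, label) with label "PVB" or "N".
#' @export
evaluate_pvb_criteria <- function(rr, morph_atypical, p_found,
                                  premature_frac = 0.8, pause_frac = 1.15) {
  n <- nrow(rr)
  stopifnot(length(morph_atypical) == n, length(p_found) == n)
  ref_ok <- !is.na(rr$ref)
  premature <- ref_ok & !is.na(rr$rr_pre) & rr$rr_pre < premature_frac * rr$ref
  c1 <- !is.na(morph_atypical) & morph_atypical
  c2 <- !is.na(p_found) & !p_found
  c3 <- ref_ok & !is.na(rr$rr_post) & rr$rr_post > pause_frac * rr$ref
  n_met <- c1 + c2 + c3
  label <- rep("N", n)
  label[premature & n_met >= 2L] <- "PVB"
  data.frame(premature = premature,
             c1_atypical_qrs_t = c1,
             c2_av_dissociation = c2,
             c3_compensatory_pause = c3,
             n_met = n_met,
             label = label,
             stringsAsFactors = FALSE)
}

#' Classify a beat stream (iterated RR reference)
#'
#' Alternates \code{\link{compute_rr}} and
#' \code{\link{evaluate_pvb_criteria}} to a fixed point: the first pass uses
#' all intervals for the rolling reference (the median is robust to isolated
#' ectopy), every later pass recomputes the reference excluding intervals
#' adjacent to beats labeled PVB so far.  Long tachycardic runs corrupt a
#' single-pass reference with their own short cycle length; the iteration
#' peels such runs back to the sinus reference and converges in a few passes
#' (bounded by \code{max_iter}).
#'
#' The reference of the first pass is seeded from the morphology channel
#' (\code{init = "morphology"}): intervals adjacent to morphologically
#' atypical beats are excluded up front, which is what a library-first
#' workflow provides and which makes convergence near-immediate; with
#' \code{init = "none"} the first pass uses all intervals.  Both starts
#' converge to the same fixed point on all but pathological streams.
#'
#' @param beats truth-style data.frame (time, morph_atypical, p_present) or
#'   annotation data.frame with the same columns.
#' @param ... thresholds passed to \code{\link{evaluate_pvb_criteria}}.
#' @param k reference window (intervals).
#' @param max_iter pass bound.
#' @param init reference seeding of the first pass.
#' @return the beats data.frame with criteria columns and \code{label} bound.
#' @export
classify_beats <- function(beats, ..., k = 5, max_iter = 30,
                           init = c("morphology", "none")) {
  init <- match.arg(init)
  p_found <- if ("p_found" %in% names(beats)) beats$p_found else beats$p_present
  labels <- NULL
  if (init == "morphology") {
    labels <- rep("N", nrow(beats))
    labels[!is.na(beats$morph_atypical) & beats$morph_atypical] <- "PVB"
  }
  for (it in seq_len(max_iter)) {
    rr <- compute_rr(beats$time, labels = labels, k = k)
    cr <- evaluate_pvb_criteria(rr, beats$morph_atypical, p_found, ...)
    if (identical(cr$label, labels)) break
    labels <- cr$label
  }
  cbind(beats[setdiff(names(beats), names(cr))], cr)
}

#' Group consecutive PVB-labeled beats into arrhythmia events
#'
#' Maximal runs of consecutive PVB labels map onto the event grammar: a run
#' of 1 is an isolated PVB, 2 a couplet, 3 a triplet, and 4 or more beats a
#' ventricular tachycardia (VT).  Each run yields exactly one event.
#'
#' @param labels character vector of beat labels ("PVB" / other).
#' @param times optional beat times (s) to give events an extent.
#' @return data.frame (class, start_beat, end_beat, n_beats, onset, end).
#' @export
group_runs <- function(labels, times = NULL) {
  empty <- data.frame(class = character(), start_beat = integer(),
                      end_beat = integer(), n_beats = integer(),
                      onset = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (length(labels) == 0L) return(empty)
  r <- rle(labels == "PVB")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  if (!any(sel)) return(empty)
  n_beats <- r$lengths[sel]
  cls <- ifelse(n_beats >= 4L, "VT",
                c("PVB", "couplet", "triplet")[n_beats])
  out <- data.frame(class = cls, start_beat = starts[sel],
                    end_beat = ends[sel], n_beats = n_beats,
                    onset = NA_real_, end = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(times)) {
    out$onset <- times[out$start_beat]
    out$end <- times[out$end_beat]
  }
  out
}

#' Detect ventricular fibrillation in a waveform record
#'
#' VF is identified by the absence of distinguishable individual QRS
#' complexes: sliding 1-s windows are flagged when no annotated beat in the
#' window matches a library template at or above the unmatched threshold
#' while the signal retains substantial energy (RMS above
#' \code{rms_mult} times the estimated noise floor).  Adjacent flagged
#' windows are merged; episodes shorter than \code{min_duration} are
#' discarded.
#'
#' @param record an \code{ecg_record}.
#' @param annotations beat annotation data.frame with \code{time} and
#'   \code{match_score} (see \code{\link{match_beat_morphology}}).
#' @param match_threshold template-match score below which a beat does not
#'   count as a distinguishable QRS.
#' @param rms_mult energy gate multiplier over the noise floor.
#' @param min_duration minimum VF episode length (s).
#' @return data.frame (class = "VF", onset, end) per episode.
#' @export
detect_vf <- function(record, annotations, match_threshold = 0.8,
                      rms_mult = 3, min_duration = 1) {
  sig <- record$signal
  fs <- record$fs
  dur <- floor(length(sig) / fs)
  if (dur < 1L)
    return(data.frame(class = character(), onset = numeric(), end = numeric()))
  d <- diff(sig)
  d <- d[!is.na(d)]
  noise_floor <- max(1.48 * stats::median(abs(d)) / sqrt(2), 0.005)
  good_beats <- annotations$time[!is.na(annotations$match_score) &
                                   annotations$match_score >= match_threshold]
  flagged <- logical(dur)
  for (w in seq_len(dur)) {
    lo <- w - 1L; hi <- w
    seg <- sig[(lo * fs + 1L):(hi * fs)]
    seg <- seg[!is.na(seg)]
    if (!length(seg)) next
    rms <- sqrt(mean(seg^2))
    has_qrs <- any(good_beats >= lo & good_beats < hi)
    flagged[w] <- !has_qrs && rms > rms_mult * noise_floor
  }
  r <- rle(flagged)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_duration)
  data.frame(class = rep("VF", length(sel)),
             onset = as.numeric(starts[sel] - 1L),
             end = as.numeric(ends[sel]),
             stringsAsFactors = FALSE)
}

#' Count arrhythmia events in an observation window
#'
#' Counts events per class over a half-open window [start, end): an event is
#' counted when its onset lies in the window and outside every artifact
#' interval.  Couplets and triplets are pooled as coupled beats at summary
#' level; the total is the sum over PVB, coupled, VT and VF events.
#'
#' @param events data.frame with \code{class} and \code{onset}.
#' @param window numeric length-2 (s).
#' @param artifacts optional data.frame (start, end) of excluded intervals.
#' @return one-row data.frame (pvb, coupled, vt, vf, total).
#' @export
count_events <- function(events, window, artifacts = NULL) {
  stopifnot(length(window) == 2L, window[2] >= window[1])
  if (nrow(events)) {
    keep <- events$onset >= window[1] & events$onset < window[2]
    if (!is.null(artifacts) && nrow(artifacts)) {
      for (r in seq_len(nrow(artifacts)))
        keep <- keep & !(events$onset >= artifacts$start[r] &
                           events$onset < artifacts$end[r])
    }
    events <- events[keep, , drop = FALSE]
  }
  data.frame(pvb = sum(events$class == "PVB"),
             coupled = sum(events$class %in% c("couplet", "triplet")),
             vt = sum(events$class == "VT"),
             vf = sum(events$class == "VF"),
             total = sum(events$class %in%
                           c("PVB", "couplet", "triplet", "VT", "VF")))
}

#' Per-group episode summary (Table-2-style)
#'
#' Aggregates per-animal event counts by group: mean +/- SEM per class and
#' the fraction of animals with at least one event of the class.
#'
#' @param counts data.frame with columns \code{group} plus the per-class
#'   count columns of \code{\link{count_events}}.
#' @return data.frame, one row per group x class, columns (group, class,
#'   mean, sem, n_affected, n, fraction).
#' @export
summarize_episodes <- function(counts) {
  classes <- c("pvb", "coupled", "vt", "vf", "total")
  out <- list()
  for (g in unique(counts$group)) {
    sub <- counts[counts$group == g, , drop = FALSE]
    for (cl in classes) {
      v <- sub[[cl]]
      out[[length(out) + 1L]] <- data.frame(
        group = g, class = cl, mean = mean(v),
        sem = stats::sd(v) / sqrt(length(v)),
        n_affected = sum(v > 0), n = length(v),
        fraction = mean(v > 0), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
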