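#' Detect QRS complexes in a murine ECG record
#'
#' Energy-pipeline detector re-parameterized for mouse ECG (QRS ~ 10 ms, HR
#' up to ~800 bpm): band-pass filter (default 10-50 Hz), squaring,
#' moving-window integration (12 ms), block-adaptive threshold (per 10 s,
#' tracking circadian amplitude drift), peak picking with a 50-ms refractory
#' period (well below the 60000/850 ms RR at ceiling HR), and R-peak
#' refinement on the filtered signal.  NA samples (unrecorded duty-cycle
#' gaps) are treated as silence.
#'
#' @param record an \code{ecg_record}.
#' @param band band-pass corner frequencies (Hz).
#' @param integration_ms integration window (ms).
#' @param refractory_ms refractory period (ms).
#' @param threshold_frac threshold as a fraction of the block's upper energy
#'   quantile.
#' @param block_s adaptation block length (s).
#' @return data.frame (time, sample, r_amplitude); empty with a warning for
#'   an all-constant signal.
#' @export
detect_qrs <- function(record, band = c(10, 50), integration_ms = 12,
                       refractory_ms = 50, threshold_frac = 0.25,
                       block_s = 10) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  if (fs < 500) stop("fs must be >= 500 Hz")
  sig <- record$signal
  sig[is.na(sig)] <- 0
  empty <- data.frame(time = numeric(), sample = integer(),
                      r_amplitude = numeric())
  if (length(sig) < 2 * fs) stop("need at least 2 s of signal")
  if (stats::sd(sig) == 0) {
    warning("all-constant signal: no beats detected")
    return(empty)
  }
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, sig)
  energy <- filt^2
  w <- max(3L, round(integration_ms / 1000 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  n <- length(integ)
  refr <- round(refractory_ms / 1000 * fs)
  pick_peaks <- function(thr) {
    cand <- which(integ > thr & c(FALSE, diff(integ) > 0) &
                    c(rev(diff(rev(integ))) > 0, FALSE))
    if (!length(cand)) return(integer(0))
    keep <- integer(0)
    last <- -Inf
    for (i in cand) {
      if (i - last >= refr) {
        keep <- c(keep, i)
        last <- i
      } else if (integ[i] > integ[keep[length(keep)]]) {
        keep[length(keep)] <- i          # better peak inside refractory
        last <- i
      }
    }
    keep
  }
  # stage 1: provisional peaks above a permissive global floor
  floor0 <- 0.05 * stats::quantile(integ, 0.999, names = FALSE)
  prov <- pick_peaks(rep(floor0, n))
  if (!length(prov)) {
    warning("no suprathreshold energy: no beats detected")
    return(empty)
  }
  # stage 2: per-block threshold from the median provisional peak height,
  # robust to the tall-ectopy minority and tracking amplitude drift
  thr <- numeric(n)
  block <- round(block_s * fs)
  starts <- seq(1L, n, by = block)
  med_global <- stats::median(integ[prov])
  for (s in starts) {
    e <- min(s + block - 1L, n)
    pk <- integ[prov[prov >= s & prov <= e]]
    m <- if (length(pk) >= 3L) stats::median(pk) else med_global
    thr[s:e] <- threshold_frac * m
  }
  cand <- which(integ > thr & c(FALSE, diff(integ) > 0) &
                  c(rev(diff(rev(integ))) > 0, FALSE))
  if (!length(cand)) return(empty)
  # refine to the absolute R peak on the band-passed signal, then apply the
  # refractory on R-peak times (amplitude-priority suppression): the energy
  # envelopes of a premature wide-QRS beat and its neighbour can merge even
  # when their R peaks are separated by more than the refractory period
  half <- round(0.010 * fs)
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(abs(filt[lo:hi])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  ord <- order(abs(filt[refined]), decreasing = TRUE)
  accept <- logical(length(refined))
  for (j in ord) {
    near <- accept & abs(refined - refined[j]) < refr
    if (!any(near)) accept[j] <- TRUE
  }
  refined <- refined[accept]
  data.frame(time = (refined - 1L) / fs, sample = refined,
             r_amplitude = sig[refined])
}

beat_window_samples <- function(fs, pre_ms = 20, post_ms = 40) {
  (-round(pre_ms / 1000 * fs)):(round(post_ms / 1000 * fs))
}

extract_beat_windows <- function(record, samples, pre_ms = 20, post_ms = 40) {
  off <- beat_window_samples(record$fs, pre_ms, post_ms)
  n <- length(record$signal)
  ok <- samples + off[1] >= 1L & samples + off[length(off)] <= n
  M <- matrix(NA_real_, length(samples), length(off))
  for (i in which(ok)) M[i, ] <- record$signal[samples[i] + off]
  M[is.na(M)] <- 0
  list(windows = M, in_bounds = ok, offsets = off)
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

#' Build an animal-specific waveform template library
#'
#' Beat windows (default -20 ms ... +40 ms around the R peak, asymmetric so
#' that the T wave contributes to the match score) are clustered greedily:
#' a beat joins the first existing cluster whose running mean it matches at
#' normalized cross-correlation >= \code{merge_threshold}, otherwise it
#' seeds a new cluster; cluster means are then pairwise re-merged.  Cluster
#' means become templates; the most populous cluster is hinted "normal", all
#' others "abnormal".  Clusters smaller than \code{min_cluster_size} are
#' dropped.
#'
#' @param record an \code{ecg_record}.
#' @param beats detection data.frame from \code{\link{detect_qrs}}.
#' Clusters whose mean waveform is not QRS-like — crest factor (peak over
#' RMS) below \code{min_crest}, as for fibrillatory oscillation arcs or
#' noise segments — are rejected: a waveform library describes beat
#' morphologies, and segments without a distinguishable QRS must stay
#' unmatched so that VF detection can recognise them.
#'
#' @param merge_threshold NCC above which two shapes are the same template.
#' @param min_cluster_size minimum occurrences to keep a template.
#' @param min_crest minimum crest factor of a template waveform.
#' @param pre_ms,post_ms window around the R peak (ms).
#' @return object of class \code{template_library}: list(templates: list of
#'   (waveform, count, hint), offsets, fs).
#' @export
build_template_library <- function(record, beats, merge_threshold = 0.95,
                                   min_cluster_size = 3, min_crest = 2.1,
                                   pre_ms = 20, post_ms = 40) {
  if (nrow(beats) < min_cluster_size) {
    warning("fewer beats than min_cluster_size: single provisional template")
    min_cluster_size <- 1L
  }
  ex <- extract_beat_windows(record, beats$sample, pre_ms, post_ms)
  W <- ex$windows[ex$in_bounds, , drop = FALSE]
  sums <- list(); counts <- integer(0)
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    placed <- FALSE
    for (cset in seq_along(sums)) {
      if (ncc(w, sums[[cset]] / counts[cset]) >= merge_threshold) {
        sums[[cset]] <- sums[[cset]] + w
        counts[cset] <- counts[cset] + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      sums[[length(sums) + 1L]] <- w
      counts <- c(counts, 1L)
    }
  }
  # pairwise re-merge of cluster means
  repeat {
    merged <- FALSE
    for (a in seq_along(sums)) {
      for (b in seq_along(sums)) {
        if (b <= a) next
        if (ncc(sums[[a]] / counts[a], sums[[b]] / counts[b]) >=
            merge_threshold) {
          sums[[a]] <- sums[[a]] + sums[[b]]
          counts[a] <- counts[a] + counts[b]
          sums[[b]] <- NULL
          counts <- counts[-b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  crest <- vapply(seq_along(sums), function(i) {
    w <- sums[[i]] / counts[i]
    max(abs(w)) / max(sqrt(mean(w^2)), 1e-12)
  }, numeric(1))
  keep <- counts >= min_cluster_size & crest >= min_crest
  if (!any(keep)) keep[which.max(counts)] <- TRUE
  sums <- sums[keep]; counts <- counts[keep]
  normal <- which.max(counts)
  templates <- lapply(seq_along(sums), function(i)
    list(waveform = sums[[i]] / counts[i], count = counts[i],
         hint = if (i == normal) "normal" else "abnormal"))
  structure(list(templates = templates, offsets = ex$offsets,
                 fs = record$fs, pre_ms = pre_ms, post_ms = post_ms),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat("<template_library>", length(x$templates), "template(s):",
      paste(sprintf("%s (n=%d)",
                    vapply(x$templates, `[[`, character(1), "hint"),
                    vapply(x$templates, `[[`, integer(1), "count")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Match beat morphology against a template library
#'
#' Scores each beat window against every template by normalized
#' cross-correlation and assigns the best template.  Morphology is
#' "normal" when the best match is the normal-hinted template at or above
#' the unmatched threshold, "atypical" when the best match is an
#' abnormal-hinted template, and "unmatched" when the best score falls below
#' the threshold or the window exceeds the record bounds.
#'
#' @param record an \code{ecg_record}.
#' @param beats detection data.frame (\code{sample} column).
#' @param library a \code{template_library}.
#' @param unmatched_threshold minimum NCC to accept a match.
#' @return data.frame (time, sample, template_id, match_score, morphology).
#' @export
match_beat_morphology <- function(record, beats, library,
                                  unmatched_threshold = 0.8) {
  if (!length(library$templates)) stop("empty template library")
  ex <- extract_beat_windows(record, beats$sample,
                             library$pre_ms, library$post_ms)
  nt <- length(library$templates)
  nb <- nrow(beats)
  scores <- matrix(-1, nb, nt)
  for (j in seq_len(nt)) {
    tpl <- library$templates[[j]]$waveform
    for (i in which(ex$in_bounds))
      scores[i, j] <- ncc(ex$windows[i, ], tpl)
  }
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(nb), best)]
  hint <- vapply(library$templates, `[[`, character(1), "hint")
  morph <- ifelse(!ex$in_bounds | best_score < unmatched_threshold,
                  "unmatched",
                  ifelse(hint[best] == "normal", "normal", "atypical"))
  template_id <- ifelse(morph == "unmatched", NA_integer_, best)
  data.frame(time = beats$time, sample = beats$sample,
             template_id = template_id, match_score = best_score,
             morphology = morph, stringsAsFactors = FALSE)
}

#' Search for a P wave before a QRS complex
#'
#' Looks for a low-amplitude atrial deflection in a pre-QRS window (default
#' -50 ms ... -10 ms relative to the R peak).  To avoid mistaking the
#' previous beat's T wave for a P wave, the window is truncated to start
#' after the previous beat's repolarization (\code{t_guard_ms} after the
#' previous R); a window shorter than \code{min_window_ms} is marked
#' low-confidence and reported as no P found.  The deflection must exceed
#' \code{snr_mult} times the local noise SD (robustly estimated) and an
#' absolute floor.
#'
#' @param record an \code{ecg_record}.
#' @param beats detection data.frame (\code{sample}); rows are processed in
#'   order, using the preceding row as the previous beat.
#' @param pre_ms,stop_ms search window: R - pre_ms to R - stop_ms (the stop
#'   margin keeps wide premature QRS onsets out of the window).
#' @param t_guard_ms dead time after the previous R peak (ms).
#' @param min_window_ms minimum usable window (ms).
#' @param snr_mult detection threshold in noise SDs.
#' @param min_amp absolute amplitude floor (mV).
#' @return data.frame (time, p_found, low_confidence).
#' @export
find_p_wave <- function(record, beats, pre_ms = 50, stop_ms = 20,
                        t_guard_ms = 35, min_window_ms = 12,
                        snr_mult = 3, min_amp = 0.05) {
  fs <- record$fs
  sig <- record$signal
  sig[is.na(sig)] <- 0
  d <- diff(sig)
  noise_sd <- max(1.48 * stats::median(abs(d), na.rm = TRUE) / sqrt(2), 1e-4)
  thr <- max(snr_mult * noise_sd, min_amp)
  n <- nrow(beats)
  p_found <- logical(n)
  lowconf <- logical(n)
  for (i in seq_len(n)) {
    s <- beats$sample[i]
    lo <- s - round(pre_ms / 1000 * fs)
    hi <- s - round(stop_ms / 1000 * fs)
    if (i > 1L)
      lo <- max(lo, beats$sample[i - 1L] + round(t_guard_ms / 1000 * fs))
    if (lo < 1L) { lowconf[i] <- TRUE; lo <- 1L }
    if ((hi - lo) < round(min_window_ms / 1000 * fs)) {
      lowconf[i] <- TRUE
      next
    }
    w <- sig[lo:hi]
    w <- w - stats::median(w)
    p_found[i] <- max(abs(w)) > thr
  }
  data.frame(time = beats$time, p_found = p_found,
             low_confidence = lowconf)
}

#' Flag artifact intervals in a record
#'
#' Sliding 1-s windows are flagged when broadband (high-pass) power or
#' amplitude saturation exceeds thresholds; adjacent flagged windows are
#' merged.  Beats inside flagged intervals should be excluded from
#' classification and HR statistics.
#'
#' @param record an \code{ecg_record}.
#' @param activity optional activity series; recorded in the interval reason
#'   when the concurrent activity is high.
#' @param power_mult flag when high-frequency RMS exceeds this multiple of
#'   the record's median window RMS.
#' @param sat_amp saturation amplitude (mV).
#' @return data.frame (start, end, reason), non-overlapping and sorted.
#' @export
flag_artifacts <- function(record, activity = NULL, power_mult = 5,
                           sat_amp = 2.2) {
  sig <- record$signal
  sig[is.na(sig)] <- 0
  fs <- record$fs
  dur <- floor(length(sig) / fs)
  if (dur < 1L)
    return(data.frame(start = numeric(), end = numeric(),
                      reason = character()))
  bf <- signal::butter(3, min(60 / (fs / 2), 0.9), type = "high")
  hf <- signal::filtfilt(bf, sig)
  idx <- rep(seq_len(dur), each = fs)[seq_along(sig)]
  rms <- sqrt(tapply(hf^2, idx, mean))
  peak <- tapply(abs(sig), idx, max)
  ref <- stats::median(rms)
  flagged <- rms > power_mult * max(ref, 1e-3) | peak > sat_amp
  r <- rle(as.vector(flagged))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  out <- data.frame(start = as.numeric(starts[sel] - 1L),
                    end = as.numeric(ends[sel]),
                    reason = rep("broadband_power", length(sel)),
                    stringsAsFactors = FALSE)
  if (!is.null(activity) && nrow(out)) {
    ai <- findInterval(out$start, activity$epoch_start)
    ai[ai < 1L] <- 1L
    out$reason[activity$value[ai] > 100] <- "high_activity_power"
  }
  out
}
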