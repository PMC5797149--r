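#' Murine single-lead beat templates
#'
#' Gaussian-bump P-QRS-T templates at mouse scale (QRS ~ 10 ms, Einthoven-II
#' polarity).  The premature ventricular morphology widens the QRS by 2.5x,
#' raises the R amplitude by 1.4x, inverts the T wave and omits the P wave,
#' so that the atypical-QRS/T criterion is objectively detectable.
#'
#' @param fs sampling rate (Hz).
#' @param type "normal" or "pvb".
#' @return list with \code{offsets} (sample offsets relative to the R peak)
#'   and \code{values} (mV).
#' @export
beat_template <- function(fs, type = c("normal", "pvb")) {
  type <- match.arg(type)
  comp <- if (type == "normal") {
    # centre (ms), sd (ms), amplitude (mV)
    rbind(c(-30, 4, 0.15),   # P
          c(-6, 2, -0.10),   # Q
          c(0, 2.5, 1.00),   # R
          c(6, 2.5, -0.25),  # S
          c(20, 6, 0.25))    # T
  } else {
    rbind(c(-7, 6, -0.15),
          c(0, 6.0, 1.40),   # widened (x2.4), taller R
          c(9, 6, -0.40),
          c(26, 7, -0.30))   # inverted T
  }
  span <- round(c(-50, 60) * fs / 1000)
  off <- span[1]:span[2]
  t_ms <- off / fs * 1000
  v <- numeric(length(off))
  for (i in seq_len(nrow(comp)))
    v <- v + comp[i, 3] * exp(-0.5 * ((t_ms - comp[i, 1]) / comp[i, 2])^2)
  list(offsets = off, values = v)
}

#' Synthesize a single-lead ECG waveform from annotated beats
#'
#' Renders an annotated beat stream (normal and PVB beats as template
#' waveforms, VF intervals as drifting band-limited oscillation) into a
#' sampled voltage trace with optional baseline wander, white noise and
#' artifact bursts.  The returned record carries the ground truth unchanged.
#'
#' @param beats data.frame as produced by \code{\link{inject_events}} (at
#'   minimum a \code{time} column; \code{label} defaults to normal).
#' @param duration record length (s).
#' @param fs sampling rate (Hz), >= 500.
#' @param vf_events optional truth events data.frame; rows with class "VF"
#'   are rendered as fibrillatory waveform.
#' @param noise list: \code{white} (mV SD), \code{wander} (mV amplitude of
#'   slow baseline drift), \code{artifact_rate} (bursts per hour),
#'   \code{artifact_amp} (mV), \code{artifact_len} (s).
#' @param t0_clock clock time (h) at sample 1.
#' @return object of class \code{ecg_record}: list(fs, signal, t0_clock,
#'   segments, meta, artifact_truth).
#' @export
synthesize_ecg <- function(beats, duration, fs = 1000, vf_events = NULL,
                           noise = list(), t0_clock = 7) {
  if (fs < 500) stop("fs must be >= 500 Hz")
  nz <- utils::modifyList(list(white = 0, wander = 0, artifact_rate = 0,
                               artifact_amp = 2.5, artifact_len = 1.5), noise)
  ns <- round(duration * fs)
  sig <- numeric(ns)
  if (!is.null(beats) && nrow(beats)) {
    if (max(beats$time) > duration) stop("beat outside record window")
    lab <- if ("label" %in% names(beats)) beats$label else rep("N", nrow(beats))
    tpl_n <- beat_template(fs, "normal")
    tpl_p <- beat_template(fs, "pvb")
    centre <- round(beats$time * fs) + 1L
    for (b in seq_len(nrow(beats))) {
      tpl <- if (lab[b] == "PVB") tpl_p else tpl_n
      idx <- centre[b] + tpl$offsets
      ok <- idx >= 1L & idx <= ns
      sig[idx[ok]] <- sig[idx[ok]] + tpl$values[ok]
    }
  }
  if (!is.null(vf_events) && nrow(vf_events)) {
    vf <- vf_events[vf_events$class == "VF", , drop = FALSE]
    for (r in seq_len(nrow(vf))) {
      i0 <- max(1L, round(vf$onset[r] * fs))
      i1 <- min(ns, round(vf$end[r] * fs))
      if (i1 <= i0) next
      nsamp <- i1 - i0 + 1L
      w <- numeric(nsamp)
      for (f0 in c(8.5, 11.5, 15.5)) {      # drifting fibrillatory components
        f <- pmin(pmax(f0 + cumsum(stats::rnorm(nsamp, sd = 0.15)), 8), 16)
        ph <- 2 * pi * cumsum(f) / fs + stats::runif(1, 0, 2 * pi)
        # slow random amplitude modulation so no two cycles repeat
        am <- as.numeric(stats::filter(stats::rnorm(nsamp), 0.995,
                                       method = "recursive"))
        am <- am / max(stats::sd(am), 1e-9)
        w <- w + (1 + 0.5 * am^2)^0.5 * sin(ph)
      }
      sig[i0:i1] <- 0.4 * w / max(stats::sd(w), 1e-9)
    }
  }
  art_truth <- data.frame(start = numeric(), end = numeric())
  if (nz$artifact_rate > 0) {
    nb <- stats::rpois(1, nz$artifact_rate * duration / 3600)
    if (nb > 0) {
      st <- sort(stats::runif(nb, 0, max(duration - nz$artifact_len, 0)))
      for (s in st) {
        i0 <- max(1L, round(s * fs)); i1 <- min(ns, round((s + nz$artifact_len) * fs))
        sig[i0:i1] <- sig[i0:i1] + stats::rnorm(i1 - i0 + 1, sd = nz$artifact_amp)
      }
      art_truth <- data.frame(start = st, end = st + nz$artifact_len)
    }
  }
  if (nz$wander > 0) {
    t <- seq_len(ns) / fs
    sig <- sig + nz$wander * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
  }
  if (nz$white > 0) sig <- sig + stats::rnorm(ns, sd = nz$white)
  rec <- list(fs = fs, signal = sig, t0_clock = t0_clock,
              segments = data.frame(start = 0, end = duration),
              meta = list(), artifact_truth = art_truth)
  class(rec) <- "ecg_record"
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %.1f s at %g Hz, %d segment(s)\n",
              length(x$signal) / x$fs, x$fs, nrow(x$segments)))
  invisible(x)
}

#' Apply the telemetry sampling scheme to a continuous record
#'
#' In long-term mode only the first minute of every 5-min block is retained
#' as recorded segments (samples outside are set to NA and the segment table
#' updated); continuous mode returns the record unchanged.
#'
#' @param record an \code{ecg_record} with a single continuous segment.
#' @param mode "longterm" or "continuous".
#' @return the duty-cycled \code{ecg_record}.
#' @export
apply_sampling_scheme <- function(record, mode = c("longterm", "continuous")) {
  mode <- match.arg(mode)
  if (mode == "continuous") return(record)
  duration <- length(record$signal) / record$fs
  seg <- duty_cycle_segments(duration)
  keep <- logical(length(record$signal))
  idx0 <- round(seg$start * record$fs)
  idx1 <- pmin(round(seg$end * record$fs), length(record$signal))
  for (r in seq_len(nrow(seg))) keep[(idx0[r] + 1L):idx1[r]] <- TRUE
  record$signal[!keep] <- NA_real_
  record$segments <- seg
  record
}
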