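# constant-HR latent trace built directly, for noise-free fixtures
flat_trace <- function(hr, duration, dt = 1) {
  time <- seq(0, duration - dt / 2, by = dt)
  tr <- list(time = time, dt = dt, hr = rep(hr, length(time)),
             components = data.frame(circadian = rep(hr, length(time)),
                                     activity = 0, drug = 0, noise = 0),
             t0_clock = 10, phase = "baseline", profile_name = "fixture")
  class(tr) <- "hr_trace"
  tr
}

# regular beat stream at a fixed RR (ms), as a truth-style data.frame
regular_beats <- function(n, rr_ms = 100, t0 = 0) {
  data.frame(time = t0 + (seq_len(n) - 1) * rr_ms / 1000,
             label = rep("N", n), morph_atypical = rep(FALSE, n),
             p_present = rep(TRUE, n), event_id = rep(NA_integer_, n),
             stringsAsFactors = FALSE)
}

# one premature beat at index i carrying a chosen subset of the 3 criteria
criteria_fixture <- function(subset, n = 30, rr_ms = 100, i = 15) {
  b <- regular_beats(n, rr_ms)
  shift <- 0.3 * rr_ms / 1000
  b$time[i] <- b$time[i] - shift            # RR_pre = 0.7 RR: premature
  if (!("pause" %in% subset))
    b$time[i + 1] <- b$time[i + 1] - shift  # RR_post back to 1.0 RR
  if ("morph" %in% subset) b$morph_atypical[i] <- TRUE
  if ("av_diss" %in% subset) b$p_present[i] <- FALSE
  b
}

# waveform fixture: constant-HR sinus with injected events
sinus_fixture <- function(duration = 60, hr = 600, sched = NULL,
                          noise = list(white = 0), seed = 5, fs = 1000) {
  set.seed(seed)
  bt <- sinus_beats(flat_trace(hr, duration), rr_jitter = 0.01)
  inj <- if (is.null(sched)) {
    list(beats = regular_beats(0), events = NULL)
  } else {
    inject_events(bt, sched)
  }
  if (is.null(sched))
    inj <- inject_events(bt, data.frame(class = character(),
                                        onset = numeric(),
                                        run_length = integer(),
                                        duration = numeric()))
  rec <- synthesize_ecg(inj$beats, duration, fs = fs,
                        vf_events = inj$events, noise = noise)
  list(inj = inj, rec = rec)
}

# independent brute-force run-length encoder over a label string
naive_run_encoder <- function(labels) {
  out <- data.frame(class = character(), n_beats = integer(),
                    stringsAsFactors = FALSE)
  i <- 1L
  while (i <= length(labels)) {
    if (labels[i] == "PVB") {
      j <- i
      while (j < length(labels) && labels[j + 1L] == "PVB") j <- j + 1L
      len <- j - i + 1L
      cls <- if (len == 1L) "PVB" else if (len == 2L) "couplet"
      else if (len == 3L) "triplet" else "VT"
      out <- rbind(out, data.frame(class = cls, n_beats = len))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# independent type-7 percentile (sort + linear interpolation)
naive_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# sensitivity / positive predictive value of detections vs truth times
det_quality <- function(det_times, truth_times, tol = 0.005) {
  tp <- sum(vapply(truth_times, function(t) any(abs(det_times - t) <= tol),
                   logical(1)))
  fp <- sum(vapply(det_times, function(t) !any(abs(truth_times - t) <= tol),
                   logical(1)))
  c(sens = tp / length(truth_times), ppv = 1 - fp / length(det_times))
}
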