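#' Schedule ventricular arrhythmia events in a time window
#'
#' Draws, independently per event class, a homogeneous-Poisson number of
#' events with mean \code{rate * window_length / 5 h}, places the onsets
#' uniformly in the window, and attaches the class grammar: isolated PVBs
#' have run length 1, coupled beats are couplets (2) or triplets (3), VT runs
#' draw their length (>= 4 beats) from the profile's run-length law, and VF
#' episodes draw a duration in seconds.  Onsets closer than \code{min_gap}
#' are re-drawn so that injected events never overlap or fuse into longer
#' runs.
#'
#' @param profile a \code{\link{strain_profile}} carrying the per-class rates.
#' @param window numeric length-2, start and end (s).
#' @param triplet_frac fraction of coupled-beat events that are triplets.
#' @param min_gap minimum onset separation (s).
#' @return data.frame of class \code{event_schedule} with columns
#'   \code{class} (PVB | couplet | triplet | VT | VF), \code{onset} (s),
#'   \code{run_length} (beats; NA for VF), \code{duration} (s; VF only),
#'   sorted by onset.
#' @export
schedule_arrhythmias <- function(profile, window, triplet_frac = 0.3,
                                 min_gap = 5) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  len <- window[2] - window[1]
  scale <- len / (5 * 3600)
  n_pvb <- stats::rpois(1, profile$event_rate_pvb * scale)
  n_cpl <- stats::rpois(1, profile$event_rate_coupled * scale)
  n_vt  <- stats::rpois(1, profile$event_rate_vt * scale)
  n_vf  <- stats::rpois(1, profile$event_rate_vf * scale)

  cls <- c(rep("PVB", n_pvb),
           ifelse(stats::runif(n_cpl) < triplet_frac, "triplet", "couplet"),
           rep("VT", n_vt), rep("VF", n_vf))
  n <- length(cls)
  if (n == 0L) {
    out <- data.frame(class = character(), onset = numeric(),
                      run_length = integer(), duration = numeric())
    class(out) <- c("event_schedule", "data.frame")
    return(out)
  }
  run_length <- rep(NA_integer_, n)
  run_length[cls == "PVB"] <- 1L
  run_length[cls == "couplet"] <- 2L
  run_length[cls == "triplet"] <- 3L
  nvt <- sum(cls == "VT")
  if (nvt > 0) {
    rl <- as.integer(profile$vt_runlength_law(nvt))
    if (any(rl < 4L)) stop("vt_runlength_law produced run lengths < 4")
    run_length[cls == "VT"] <- rl
  }
  duration <- rep(NA_real_, n)
  if (n_vf > 0) duration[cls == "VF"] <- pmax(1, profile$vf_duration_law(n_vf))

  onset <- stats::runif(n, window[1], window[2])
  # effective footprint of each event, used for the overlap re-draw
  foot <- ifelse(cls == "VF", duration, run_length * 0.15) + min_gap
  for (iter in 1:200) {
    o <- order(onset)
    gaps_ok <- c(TRUE, diff(onset[o]) >= foot[o][-n])
    if (all(gaps_ok)) break
    bad <- o[!gaps_ok]
    onset[bad] <- stats::runif(length(bad), window[1], window[2])
  }
  o <- order(onset)
  out <- data.frame(class = cls[o], onset = onset[o],
                    run_length = run_length[o], duration = duration[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("event_schedule", "data.frame")
  out
}
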