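# fast per-segment beat generation from trace arrays (1-s grid assumed)
segment_beats <- function(time, hr, dt, segments, rr_jitter = 0.015) {
  out <- vector("list", nrow(segments))
  for (r in seq_len(nrow(segments))) {
    i0 <- findInterval(segments$start[r], time)
    i0 <- max(i0, 1L)
    i1 <- findInterval(segments$end[r] - 1e-9, time)
    if (i1 <= i0) next
    h <- hr[i0:i1]
    lam <- c(0, cumsum(h / 60 * dt))
    tg <- c(time[i0], time[i0:i1] + dt)
    total <- lam[length(lam)]
    u0 <- stats::runif(1)
    n <- floor(total - u0)
    if (n < 1) next
    q <- u0 + seq_len(n)
    if (rr_jitter > 0) q <- cummax(q + stats::rnorm(n, sd = rr_jitter))
    q <- pmin(pmax(q, 1e-9), total - 1e-9)
    out[[r]] <- stats::approx(lam, tg, xout = q, ties = "ordered")$y
  }
  unlist(out)
}

#' Simulate one long-term (duty-cycled) telemetry session
#'
#' Generates the latent HR trace (circadian + activity + drug + fluctuation)
#' over the full session, the 5-min activity log, and ground-truth beat times
#' for the recorded minutes (1 min per 5-min block).  Long-term sessions
#' carry no injected arrhythmias; their purpose is circadian HR analysis.
#'
#' @param profile a \code{\link{strain_profile}}.
#' @param phase "baseline" or "metoprolol".
#' @param hours session length (h).
#' @param animal_effect per-animal HR intercept (bpm).
#' @param t0_clock clock time (h) at session start.
#' @param noise_sd optional override of the HR fluctuation SD.
#' @param keep_trace retain the latent trace in the output (memory!).
#' @return list(beats, segments, activity, phase, t0_clock, hours
#'   [, trace]); \code{beats} is a truth data.frame as in
#'   \code{\link{inject_events}} with all beats normal.
#' @export
simulate_longterm_session <- function(profile, phase = "baseline", hours = 96,
                                      animal_effect = 0, t0_clock = 7,
                                      noise_sd = NULL, keep_trace = FALSE) {
  duration <- hours * 3600
  activity <- simulate_activity(profile, duration, t0_clock)
  trace <- simulate_hr_profile(profile, phase, activity, duration,
                               t0_clock = t0_clock,
                               animal_effect = animal_effect,
                               noise_sd = noise_sd)
  segments <- duty_cycle_segments(duration)
  bt <- segment_beats(trace$time, trace$hr, trace$dt, segments)
  beats <- data.frame(time = bt, label = "N",
                      morph_atypical = FALSE, p_present = TRUE,
                      event_id = NA_integer_, stringsAsFactors = FALSE)
  out <- list(beats = beats, segments = segments, activity = activity,
              phase = phase, t0_clock = t0_clock, hours = hours)
  if (keep_trace) out$trace <- trace
  out
}

#' Simulate one acute (continuous) injection session
#'
#' Emulates the acute cross-over protocol: recording starts 30 min before the
#' first injection; two injections of the same agent follow 30 min apart;
#' the observation window is the 5 h after the first injection.  Under
#' isoproterenol each injection adds a double-exponential HR surge and
#' ventricular arrhythmias are injected at the profile's per-class rates over
#' the observation window; under vehicle (NaCl) only a residual PVB rate
#' applies.
#'
#' @param profile a \code{\link{strain_profile}}.
#' @param agent "iso" or "vehicle".
#' @param minutes session length (min), >= 330.
#' @param animal_effect per-animal HR intercept (bpm).
#' @param t0_clock clock time (h) at session start.
#' @param noise_sd optional override of the HR fluctuation SD.
#' @param vehicle_pvb_rate residual isolated-PVB rate per 5 h under NaCl.
#' @param keep_trace retain the latent trace.
#' @return list(beats, events, schedule, activity, t_inj, window, agent,
#'   phase, t0_clock [, trace]).
#' @export
simulate_acute_session <- function(profile, agent = c("iso", "vehicle"),
                                   minutes = 330, animal_effect = 0,
                                   t0_clock = 10, noise_sd = NULL,
                                   vehicle_pvb_rate = 0.5,
                                   keep_trace = FALSE) {
  agent <- match.arg(agent)
  if (minutes < 330) stop("acute session must cover 30 + 300 min")
  duration <- minutes * 60
  activity <- simulate_activity(profile, duration, t0_clock)
  phase <- paste0("acute_", if (agent == "iso") "iso" else "vehicle")
  trace <- simulate_hr_profile(profile, phase, activity, duration,
                               t0_clock = t0_clock,
                               animal_effect = animal_effect,
                               noise_sd = noise_sd)
  t_inj <- 30 * 60
  if (agent == "iso") {
    trace <- apply_isoproterenol(trace, t_inj, profile)
    trace <- apply_isoproterenol(trace, t_inj + 30 * 60, profile)
  }
  window <- c(t_inj, t_inj + 5 * 3600)
  window[2] <- min(window[2], duration)
  if (agent == "iso") {
    sched <- schedule_arrhythmias(profile, window)
  } else {
    quiet <- profile
    quiet$event_rate_pvb <- vehicle_pvb_rate
    quiet$event_rate_coupled <- 0
    quiet$event_rate_vt <- 0
    quiet$event_rate_vf <- 0
    sched <- schedule_arrhythmias(quiet, window)
  }
  bt <- sinus_beats(trace)
  inj <- inject_events(bt, sched)
  out <- list(beats = inj$beats, events = inj$events, schedule = sched,
              activity = activity, t_inj = t_inj, window = window,
              agent = agent, phase = phase, t0_clock = t0_clock)
  if (keep_trace) out$trace <- trace
  out
}

#' Simulate a complete telemetry study
#'
#' Runs the full protocol for every animal of a \code{\link{study_design}}:
#' a 96-h duty-cycled baseline session, two acute continuous sessions
#' (vehicle and isoproterenol, cross-over order randomised per animal), and a
#' 96-h duty-cycled session under chronic metoprolol.  All ground truth
#' (beat-level truth, realised event schedules, activity logs) is attached.
#' Identical (design, seed) yields identical output.
#'
#' @param design a \code{\link{study_design}}.
#' @return object of class \code{telemetry_study}: list with \code{design}
#'   and \code{animals}, one entry per animal holding \code{strain},
#'   \code{animal_id}, \code{animal_effect}, \code{crossover} and the four
#'   \code{sessions}.
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  animals <- list()
  aid <- 0L
  for (s in seq_along(design$strains)) {
    profile <- design$strains[[s]]
    n <- design$n_per_strain[s]
    if (n == 0L) next
    for (a in seq_len(n)) {
      aid <- aid + 1L
      eff <- stats::rnorm(1, sd = profile$animal_sd)
      first <- if (stats::runif(1) < 0.5) "iso" else "vehicle"
      order2 <- c(first, setdiff(c("iso", "vehicle"), first))
      sessions <- list(
        baseline = simulate_longterm_session(profile, "baseline",
                                             design$longterm_hours, eff),
        acute_1 = simulate_acute_session(profile, order2[1],
                                         design$acute_minutes, eff),
        acute_2 = simulate_acute_session(profile, order2[2],
                                         design$acute_minutes, eff),
        metoprolol = simulate_longterm_session(profile, "metoprolol",
                                               design$longterm_hours, eff))
      animals[[aid]] <- list(animal_id = sprintf("%s-%02d", profile$name, a),
                             strain = profile$name, animal_effect = eff,
                             crossover = order2, sessions = sessions)
    }
  }
  out <- list(design = design, animals = animals)
  class(out) <- "telemetry_study"
  out
}

#' @export
print.telemetry_study <- function(x, ...) {
  cat("<telemetry_study>", length(x$animals), "animals\n")
  invisible(x)
}
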