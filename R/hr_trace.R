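#' Simulate a 5-min cage-activity series
#'
#' Activity units (A.U.) as logged by a telemetry transponder: one value per
#' 5-min epoch, zero while the animal rests, otherwise gamma-distributed with
#' day/night-specific means, truncated at the transponder ceiling of 300 A.U.
#'
#' @param profile a \code{\link{strain_profile}}.
#' @param duration length of the series (s).
#' @param t0_clock clock time (h of day) at the start of the series.
#' @param day_start,day_end lights-on window (h).
#' @param epoch_len activity epoch length (s).
#' @return data.frame with \code{epoch_start} (s) and \code{value} (A.U.).
#' @export
simulate_activity <- function(profile, duration, t0_clock = 7,
                              day_start = 7, day_end = 19, epoch_len = 300) {
  stopifnot(duration > 0)
  starts <- epoch_len * (seq_len(ceiling(duration / epoch_len - 1e-9)) - 1)
  clock <- (t0_clock + starts / 3600) %% 24
  is_day <- clock >= day_start & clock < day_end
  p0 <- ifelse(is_day, profile$activity_day_p0, profile$activity_night_p0)
  mu <- ifelse(is_day, profile$activity_day_mean, profile$activity_night_mean)
  shape <- 1.5
  v <- stats::rgamma(length(starts), shape = shape, scale = mu / shape)
  v[stats::runif(length(starts)) < p0] <- 0
  v <- pmin(v, 300)
  data.frame(epoch_start = starts, value = v)
}

# raised-cosine circadian weight: 1 during night plateau, 0 during day
# plateau, 1-h cosine ramps centred on the day_start/day_end transitions
circadian_night_weight <- function(clock, day_start = 7, day_end = 19,
                                   ramp = 1) {
  w <- numeric(length(clock))
  ramp_half <- ramp / 2
  # distance to nearest point of the day interval, signed
  in_day <- clock >= day_start & clock < day_end
  w[!in_day] <- 1
  # ramp down at day_start (night -> day), centred on day_start
  d1 <- clock - day_start
  sel <- abs(d1) < ramp_half
  w[sel] <- 0.5 * (1 - sin(pi * d1[sel] / ramp))
  # ramp up at day_end (day -> night), centred on day_end
  d2 <- clock - day_end
  sel <- abs(d2) < ramp_half
  w[sel] <- 0.5 * (1 + sin(pi * d2[sel] / ramp))
  w
}

# Ornstein-Uhlenbeck (AR(1)) fluctuation sampled on a regular grid
ou_noise <- function(n, dt, sd, tau) {
  if (sd == 0 || n == 0L) return(numeric(n))
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- stats::rnorm(n, sd = innov_sd)
  x[1] <- stats::rnorm(1, sd = sd)
  as.numeric(stats::filter(x, a, method = "recursive"))
}

#' Simulate a latent instantaneous heart-rate trace
#'
#' Builds the additive latent HR process behind a telemetry recording:
#' a smooth 24-h circadian term (raised-cosine transitions between the
#' calibrated day and night resting levels), a saturating activity-coupled
#' gain evaluated on the concurrent 5-min activity epoch, a phase-specific
#' drug term (chronic metoprolol subtracts the day/night reduction with the
#' same circadian ramps), and a mean-zero Ornstein-Uhlenbeck fluctuation.
#' Components are returned separately and sum exactly to \code{hr} before
#' clipping to the physiological range [150, 850] bpm.
#'
#' @param profile a \code{\link{strain_profile}}.
#' @param phase one of \code{"baseline"}, \code{"metoprolol"},
#'   \code{"acute_vehicle"}, \code{"acute_iso"} (the acute phases share the
#'   baseline model; the isoproterenol surge is added separately with
#'   \code{\link{apply_isoproterenol}}).
#' @param activity activity series from \code{\link{simulate_activity}}, or
#'   NULL for zero activity.
#' @param duration trace length (s).
#' @param t0_clock clock time (h) at t = 0.
#' @param dt grid step (s).
#' @param animal_effect per-animal random intercept (bpm) added to the
#'   circadian term.
#' @param noise_sd override of the profile's fluctuation SD (e.g. 0 for
#'   noiseless fixtures).
#' @param day_start,day_end lights-on window (h).
#' @return object of class \code{hr_trace}: list with \code{time}, \code{hr}
#'   (clipped), and a \code{components} data.frame (circadian, activity,
#'   drug, noise).
#' @export
simulate_hr_profile <- function(profile, phase = "baseline", activity = NULL,
                                duration = 3600, t0_clock = 7, dt = 1,
                                animal_effect = 0, noise_sd = NULL,
                                day_start = 7, day_end = 19) {
  stopifnot(duration > 0)
  phase <- match.arg(phase, c("baseline", "metoprolol",
                              "acute_vehicle", "acute_iso"))
  if (is.null(noise_sd)) noise_sd <- profile$noise_sd
  time <- seq(0, duration - dt / 2, by = dt)
  clock <- (t0_clock + time / 3600) %% 24
  w <- circadian_night_weight(clock, day_start, day_end)
  circ <- profile$level_day + w * (profile$level_night - profile$level_day) +
    animal_effect

  if (is.null(activity)) {
    act_term <- numeric(length(time))
  } else {
    idx <- findInterval(time, activity$epoch_start)
    idx[idx < 1L] <- 1L
    a <- activity$value[idx]
    act_term <- profile$act_gain * act_coupling_unit(a)
  }

  drug <- numeric(length(time))
  if (phase == "metoprolol") {
    drug <- -(profile$metoprolol_delta_day +
                w * (profile$metoprolol_delta_night -
                       profile$metoprolol_delta_day))
  }
  noise <- ou_noise(length(time), dt, noise_sd, profile$noise_tau)
  raw <- circ + act_term + drug + noise
  tr <- list(time = time, dt = dt,
             hr = pmin(pmax(raw, 150), profile$hr_ceiling),
             components = data.frame(circadian = circ, activity = act_term,
                                     drug = drug, noise = noise),
             t0_clock = t0_clock, phase = phase, profile_name = profile$name)
  class(tr) <- "hr_trace"
  tr
}

#' Add an isoproterenol surge to an HR trace
#'
#' Adds a double-exponential chronotropic response
#' \eqn{A (e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}})} starting at the
#' injection time, scaled so its maximum equals the profile's
#' \code{iso_peak_delta}.  With the default time constants the added term has
#' declined below 1 bpm 300 min after the injection, matching the observation
#' window of the acute protocol.  The result is re-clipped to the profile's
#' physiological ceiling.
#'
#' @param trace an \code{hr_trace}.
#' @param t_inj injection time (s) within the trace.
#' @param profile the \code{\link{strain_profile}} providing the surge
#'   parameters.
#' @return the modified \code{hr_trace}; the surge is accumulated into the
#'   \code{drug} component.
#' @export
apply_isoproterenol <- function(trace, t_inj, profile) {
  stopifnot(inherits(trace, "hr_trace"))
  if (t_inj < trace$time[1] || t_inj > trace$time[length(trace$time)])
    stop("t_inj outside trace")
  surge <- iso_surge(trace$time - t_inj, profile$iso_peak_delta,
                     profile$iso_rise_tau * 60, profile$iso_decay_tau * 60)
  trace$components$drug <- trace$components$drug + surge
  raw <- with(trace$components, circadian + activity + drug + noise)
  trace$hr <- pmin(pmax(raw, 150), profile$hr_ceiling)
  trace
}

# double-exponential surge, peak-normalised to `peak`; t in s, taus in s
iso_surge <- function(t, peak, tau_rise, tau_decay) {
  if (peak == 0) return(numeric(length(t)))
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  tmax <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  fmax <- exp(-tmax / tau_decay) - exp(-tmax / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- peak / fmax * (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise))
  out
}

#' @export
print.hr_trace <- function(x, ...) {
  cat(sprintf("<hr_trace> %s/%s: %g s at dt=%g s, HR %.0f-%.0f bpm\n",
              x$profile_name, x$phase, length(x$time) * x$dt, x$dt,
              min(x$hr), max(x$hr)))
  invisible(x)
}
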