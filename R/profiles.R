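#' Strain profile: generator parameters for one genetic background
#'
#' A \code{strain_profile} bundles everything the synthetic-data generator
#' needs to emulate one mouse strain: circadian heart-rate levels, the
#' naturally occurring HR extremes used to calibrate the circadian trough,
#' cage-activity levels, beta-adrenergic pharmacodynamics (chronic metoprolol
#' reduction, acute isoproterenol surge), and per-class ventricular-arrhythmia
#' rates expressed as events per 5-hour observation window.
#'
#' The circadian resting levels are not free parameters: they are calibrated
#' at construction time so that (a) the expected minimum valid-epoch HR over a
#' 96-h duty-cycled recording equals \code{hr_min} and (b) the expected day and
#' night epoch means equal \code{hr_day_mean} / \code{hr_night_mean} once the
#' activity-coupled HR gain is added.  See \code{\link{calibrate_profile}}.
#'
#' @param name strain label, e.g. "Balb/c".
#' @param hr_day_mean,hr_night_mean target mean epoch HR (bpm) during the
#'   lights-on (07:00-19:00) and lights-off windows.
#' @param hr_min,hr_max naturally occurring minimal / maximal epoch HR (bpm)
#'   over a 96-h baseline recording; \code{hr_min} drives trough calibration.
#' @param activity_day_mean,activity_night_mean mean of the non-zero part of
#'   the 5-min cage-activity distribution (A.U.).
#' @param activity_day_p0,activity_night_p0 probability that a 5-min activity
#'   epoch is exactly zero (animal at rest).
#' @param metoprolol_delta_day,metoprolol_delta_night chronic metoprolol HR
#'   reduction (bpm) during day / night.
#' @param iso_peak_delta peak HR increase after isoproterenol bolus (bpm).
#' @param iso_rise_tau,iso_decay_tau time constants (min) of the
#'   double-exponential isoproterenol response.
#' @param event_rate_pvb,event_rate_coupled,event_rate_vt,event_rate_vf mean
#'   number of isolated PVBs, coupled beats (couplets/triplets), VT runs and
#'   VF episodes per 5 h under beta-adrenergic stimulation.
#' @param vt_runlength_law function(n) drawing n integer VT run lengths >= 4.
#' @param vf_duration_law function(n) drawing n VF durations in seconds.
#' @param noise_sd standard deviation (bpm) of the Ornstein-Uhlenbeck HR
#'   fluctuation process.
#' @param noise_tau correlation time (s) of the HR fluctuation process.
#' @param animal_sd between-animal standard deviation (bpm) of the circadian
#'   HR level (random intercept shared across phases of one animal).
#' @param hr_ceiling physiological HR ceiling (bpm); the clip bound for
#'   baseline + drug surges.
#' @return object of class \code{strain_profile}.
#' @export
strain_profile <- function(name,
                           hr_day_mean, hr_night_mean, hr_min, hr_max,
                           activity_day_mean = 8, activity_night_mean = 18,
                           activity_day_p0 = 0.5, activity_night_p0 = 0.15,
                           metoprolol_delta_day = 50, metoprolol_delta_night = 70,
                           iso_peak_delta = 200,
                           iso_rise_tau = 3, iso_decay_tau = 50,
                           event_rate_pvb = 0, event_rate_coupled = 0,
                           event_rate_vt = 0, event_rate_vf = 0,
                           vt_runlength_law = function(n) 4L + stats::rgeom(n, 0.5),
                           vf_duration_law = function(n) stats::rlnorm(n, log(3), 0.4),
                           noise_sd = 70, noise_tau = 30,
                           animal_sd = 20,
                           hr_ceiling = 850) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(hr_min < hr_day_mean && hr_day_mean <= hr_night_mean &&
        hr_night_mean < hr_max))
    stop("require hr_min < hr_day_mean <= hr_night_mean < hr_max for '",
         name, "'")
  rates <- c(event_rate_pvb, event_rate_coupled, event_rate_vt, event_rate_vf)
  if (any(rates < 0)) stop("event rates must be >= 0")
  if (hr_max + iso_peak_delta > 2 * hr_ceiling)
    stop("iso_peak_delta implausibly large relative to hr_ceiling")
  p <- list(
    name = name,
    hr_day_mean = hr_day_mean, hr_night_mean = hr_night_mean,
    hr_min = hr_min, hr_max = hr_max,
    activity_day_mean = activity_day_mean,
    activity_night_mean = activity_night_mean,
    activity_day_p0 = activity_day_p0,
    activity_night_p0 = activity_night_p0,
    metoprolol_delta_day = metoprolol_delta_day,
    metoprolol_delta_night = metoprolol_delta_night,
    iso_peak_delta = iso_peak_delta,
    iso_rise_tau = iso_rise_tau, iso_decay_tau = iso_decay_tau,
    event_rate_pvb = event_rate_pvb,
    event_rate_coupled = event_rate_coupled,
    event_rate_vt = event_rate_vt,
    event_rate_vf = event_rate_vf,
    vt_runlength_law = vt_runlength_law,
    vf_duration_law = vf_duration_law,
    noise_sd = noise_sd, noise_tau = noise_tau,
    animal_sd = animal_sd,
    hr_ceiling = hr_ceiling)
  class(p) <- "strain_profile"
  calibrate_profile(p)
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("<strain_profile>", x$name, "\n")
  cat(sprintf("  HR day/night mean: %.0f / %.0f bpm; min/max: %.0f / %.0f bpm\n",
              x$hr_day_mean, x$hr_night_mean, x$hr_min, x$hr_max))
  cat(sprintf("  circadian resting levels (calibrated): day %.1f, night %.1f bpm\n",
              x$level_day, x$level_night))
  cat(sprintf("  metoprolol delta day/night: %.0f / %.0f bpm; iso peak +%.0f bpm\n",
              x$metoprolol_delta_day, x$metoprolol_delta_night, x$iso_peak_delta))
  cat(sprintf("  event rates /5h: PVB %.1f, coupled %.1f, VT %.1f, VF %.1f\n",
              x$event_rate_pvb, x$event_rate_coupled, x$event_rate_vt,
              x$event_rate_vf))
  invisible(x)
}

# Hill-type activity->HR coupling, unit gain at saturation.
act_coupling_unit <- function(a, K = 10) a / (a + K)

# E[g(A)] under the zero-inflated gamma activity law (gamma shape fixed at
# 1.5, scale chosen to give the requested non-zero mean, truncated at 300).
expected_coupling <- function(mean_nonzero, p0, K = 10, shape = 1.5) {
  scale <- mean_nonzero / shape
  f <- function(a) act_coupling_unit(pmin(a, 300), K) *
    stats::dgamma(a, shape = shape, scale = scale)
  (1 - p0) * stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

# Expected minimum of a collection of independent gaussians with common sd 1
# and given mean offsets (each offset repeated `counts` times), by numerical
# integration of the survival function of the minimum.
expected_min_gauss <- function(offsets, counts) {
  stopifnot(length(offsets) == length(counts))
  surv <- function(x) {
    s <- rep(1, length(x))
    for (i in seq_along(offsets))
      s <- s * stats::pnorm(x - offsets[i], lower.tail = FALSE)^counts[i]
    s
  }
  lo <- min(offsets) - 8
  hi <- max(offsets) + 8
  # E[min] = lo + integral of survival of (min - lo)
  lo + stats::integrate(function(x) surv(x), lo, hi, rel.tol = 1e-8,
                        subdivisions = 400L)$value
}

# Variance bookkeeping for the OU fluctuation process at the 1-min epoch
# scale: fraction of the stationary variance retained by the epoch mean, and
# the within-epoch remainder (drives the harmonic-mean bias of epoch HR).
ou_epoch_var_split <- function(sd, tau, epoch_len = 60) {
  r <- tau / epoch_len
  f_mean <- 2 * (r - r^2 * (1 - exp(-1 / r)))
  c(mean = sd^2 * f_mean, within = sd^2 * (1 - f_mean))
}

# mean of the circadian night-weight over the day and night windows: the
# 1-h raised-cosine ramps put a small fraction of the night elevation into
# the day window and vice versa
circadian_weight_means <- function(ramp = 1, day_hours = 12) {
  inside <- 2 * (0.25 - 0.5 / pi) * ramp      # integral of w over the day (h)
  c(day = inside / day_hours,
    night = (day_hours - inside) / day_hours)
}

#' Calibrate the latent circadian levels of a strain profile
#'
#' Solves for the latent day/night resting HR levels and the
#' activity-coupling gain such that, under the generator's noise and
#' activity models, (i) the expected minimum valid-epoch HR of a 96-h
#' duty-cycled baseline recording equals \code{hr_min} and (ii) the expected
#' day and night epoch-mean HRs equal \code{hr_day_mean} /
#' \code{hr_night_mean}.  The expected minimum is evaluated by exact order
#' statistics of the epoch-mean fluctuation at rest (epochs lie 5 min apart,
#' far beyond the fluctuation correlation time, so they are treated as
#' independent), pooling the day and night rest epochs at their calibrated
#' level gap; the means use the exact circadian ramp weights and the
#' analytic expectation of the activity-coupled gain.  The three unknowns
#' (day level, day-night gap, coupling gain) are solved by a short fixed
#' point; an infeasible negative gap or gain is clamped to zero with a
#' least-squares compromise on the two mean targets.
#'
#' Called automatically by \code{\link{strain_profile}}.
#'
#' @param p a \code{strain_profile} (possibly with stale calibration fields).
#' @param hours reference recording length used for the trough calibration.
#' @return the profile with fields \code{level_day}, \code{level_night},
#'   \code{act_gain}, \code{epoch_noise_sd} filled in.
#' @export
calibrate_profile <- function(p, hours = 96) {
  vs <- ou_epoch_var_split(p$noise_sd, p$noise_tau)
  sd_e <- sqrt(vs[["mean"]])
  n_epochs <- hours / 24 * 12 * 12   # 1-min epochs per 12-h partition
  n0_day <- p$activity_day_p0 * n_epochs
  n0_night <- p$activity_night_p0 * n_epochs

  eg_day <- expected_coupling(p$activity_day_mean, p$activity_day_p0)
  eg_night <- expected_coupling(p$activity_night_mean, p$activity_night_p0)
  wm <- circadian_weight_means()

  gap <- p$hr_night_mean - p$hr_day_mean
  gain <- 0
  level_day <- p$hr_min
  for (i in 1:6) {
    dmin <- if (sd_e > 0)
      expected_min_gauss(c(0, gap / sd_e), c(n0_day, n0_night)) * sd_e
    else 0
    level_day <- p$hr_min - dmin
    rhs <- c(p$hr_day_mean, p$hr_night_mean) - level_day
    A <- rbind(c(wm[["day"]], eg_day), c(wm[["night"]], eg_night))
    sol <- solve(A, rhs)
    gap <- sol[1]; gain <- sol[2]
    if (gap < 0 || gain < 0) {            # clamp and least-squares the rest
      if (gap < 0) {
        gap <- 0
        gain <- sum(rhs * c(eg_day, eg_night)) / sum(c(eg_day, eg_night)^2)
        gain <- max(gain, 0)
      } else {
        gain <- 0
        gap <- sum(rhs * unlist(wm)) / sum(unlist(wm)^2)
        gap <- max(gap, 0)
      }
    }
  }
  p$level_day <- as.numeric(level_day)
  p$level_night <- as.numeric(level_day + gap)
  p$act_gain <- as.numeric(gain)
  p$epoch_noise_sd <- as.numeric(sd_e)
  p
}

#' Default strain panel
#'
#' Profiles for the four genetic backgrounds of the study design this package
#' emulates (Balb/c, C57Bl/6, BS = Black Swiss, FVB), with naturally occurring
#' HR extremes and per-class arrhythmia rates set to the published group means
#' and the remaining parameters set to realistic murine telemetry values.
#'
#' @return named list of \code{\link{strain_profile}} objects.
#' @export
default_strains <- function() {
  list(
    "Balb/c" = strain_profile("Balb/c",
      hr_day_mean = 500, hr_night_mean = 560, hr_min = 317, hr_max = 747,
      activity_night_mean = 18, iso_peak_delta = 230,
      event_rate_pvb = 158.2, event_rate_coupled = 46.7,
      event_rate_vt = 14.0, event_rate_vf = 4.7),
    "C57Bl/6" = strain_profile("C57Bl/6",
      hr_day_mean = 520, hr_night_mean = 575, hr_min = 327, hr_max = 768,
      activity_night_mean = 20, iso_peak_delta = 220,
      event_rate_pvb = 72.8, event_rate_coupled = 18.2,
      event_rate_vt = 1.2, event_rate_vf = 0),
    "BS" = strain_profile("BS",
      hr_day_mean = 555, hr_night_mean = 620, hr_min = 392, hr_max = 763,
      activity_night_mean = 30, iso_peak_delta = 190,
      event_rate_pvb = 40.2, event_rate_coupled = 11.2,
      event_rate_vt = 0.5, event_rate_vf = 0),
    "FVB" = strain_profile("FVB",
      hr_day_mean = 560, hr_night_mean = 615, hr_min = 372, hr_max = 774,
      activity_night_mean = 14, iso_peak_delta = 230,
      event_rate_pvb = 89.8, event_rate_coupled = 25.2,
      event_rate_vt = 4.0, event_rate_vf = 0))
}

#' Study design
#'
#' Describes a complete telemetry study: the strain panel, group sizes, the
#' phase sequence (96-h baseline, acute cross-over injections, 96-h recording
#' under chronic metoprolol), the lights-on window, the sampling rate, and the
#' long-term duty cycle (1 min recorded per 5 min).
#'
#' @param strains list of \code{\link{strain_profile}}s.
#' @param n_per_strain integer vector of animals per strain (recycled).
#' @param longterm_hours duration of each long-term phase (h).
#' @param acute_minutes duration of each acute session (min); must cover the
#'   30-min pre-injection baseline plus the 300-min observation window.
#' @param day_start,day_end lights-on window (hours of day).
#' @param fs ECG sampling rate (Hz).
#' @param seed integer seed controlling every random draw of the study.
#' @return object of class \code{study_design}.
#' @export
study_design <- function(strains = default_strains(),
                         n_per_strain = c(6, 6, 6, 5),
                         longterm_hours = 96,
                         acute_minutes = 330,
                         day_start = 7, day_end = 19,
                         fs = 1000,
                         seed = 1L) {
  if (length(strains) == 0L) stop("at least one strain profile required")
  if (!all(vapply(strains, inherits, logical(1), "strain_profile")))
    stop("strains must be strain_profile objects")
  n_per_strain <- rep_len(as.integer(n_per_strain), length(strains))
  if (any(n_per_strain < 0)) stop("n_per_strain must be >= 0")
  if (acute_minutes < 300) stop("acute_minutes must be >= 300")
  if (fs <= 0) stop("fs must be > 0")
  stopifnot(day_start >= 0, day_end <= 24, day_start < day_end)
  d <- list(strains = strains, n_per_strain = n_per_strain,
            longterm_hours = longterm_hours, acute_minutes = acute_minutes,
            day_start = day_start, day_end = day_end,
            fs = fs, seed = as.integer(seed))
  class(d) <- "study_design"
  d
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>", sum(x$n_per_strain), "animals,",
      length(x$strains), "strains\n")
  cat("  n per strain:", paste(names(x$strains), x$n_per_strain,
                               sep = "=", collapse = ", "), "\n")
  cat(sprintf("  long-term %g h (1 min / 5 min), acute %g min, fs %g Hz, seed %d\n",
              x$longterm_hours, x$acute_minutes, x$fs, x$seed))
  invisible(x)
}
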