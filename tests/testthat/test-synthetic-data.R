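test_that("study simulation honours the design and is deterministic", {
  strains <- default_strains()[c("Balb/c", "BS")]
  d <- study_design(strains, n_per_strain = c(2, 1), longterm_hours = 1,
                    acute_minutes = 330, seed = 7)
  s1 <- simulate_study(d)
  expect_length(s1$animals, 3L)
  expect_setequal(unique(vapply(s1$animals, `[[`, character(1), "strain")),
                  c("Balb/c", "BS"))
  s2 <- simulate_study(d)
  expect_identical(s1, s2)
  s3 <- simulate_study(study_design(strains, c(2, 1), longterm_hours = 1,
                                    seed = 8))
  expect_false(identical(s1$animals[[1]]$sessions$baseline$beats,
                         s3$animals[[1]]$sessions$baseline$beats))
  # zero animals everywhere: empty collection, no error
  s0 <- simulate_study(study_design(strains, c(0, 0), longterm_hours = 1))
  expect_length(s0$animals, 0L)
  expect_error(study_design(strains, c(-1, 2)), "n_per_strain")
})

test_that("full default design enumerates 23 animals", {
  d <- study_design()
  expect_identical(sum(d$n_per_strain), 23L)
})

test_that("HR trace components sum to the instantaneous HR before clipping", {
  p <- default_strains()[["BS"]]
  set.seed(1)
  act <- simulate_activity(p, 7200, 10)
  tr <- simulate_hr_profile(p, "baseline", act, 7200, t0_clock = 10)
  raw <- rowSums(tr$components)
  inside <- raw > 150 & raw < p$hr_ceiling
  expect_true(all(abs(raw[inside] - tr$hr[inside]) < 1e-9))
  expect_true(all(tr$hr >= 150 & tr$hr <= p$hr_ceiling))
})

test_that("zero activity and zero noise give the pure circadian term", {
  p <- default_strains()[["Balb/c"]]
  tr <- simulate_hr_profile(p, "baseline", activity = NULL,
                            duration = 24 * 3600, noise_sd = 0)
  expect_equal(tr$hr, tr$components$circadian, tolerance = 1e-12)
  # smooth 24-h periodicity between the two calibrated plateaus
  expect_equal(sort(unique(round(range(tr$components$circadian), 6))),
               round(c(p$level_day, p$level_night), 6))
})

test_that("metoprolol phase lowers the day-time mean by the programmed delta", {
  p <- default_strains()[["C57Bl/6"]]
  base <- simulate_hr_profile(p, "baseline", NULL, 12 * 3600,
                              t0_clock = 7, noise_sd = 0)
  met <- simulate_hr_profile(p, "metoprolol", NULL, 12 * 3600,
                             t0_clock = 7, noise_sd = 0)
  day <- base$time > 3600 & base$time < 11 * 3600   # inside the plateau
  expect_equal(mean(base$hr[day]) - mean(met$hr[day]),
               p$metoprolol_delta_day, tolerance = 1e-6)
})

test_that("isoproterenol surge has analytic peak and declines below 1 bpm", {
  p <- default_strains()[["FVB"]]
  tr <- flat_trace(500, 6 * 3600)
  out <- apply_isoproterenol(tr, 600, p)
  surge <- out$components$drug
  tau_r <- p$iso_rise_tau * 60; tau_d <- p$iso_decay_tau * 60
  tmax <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
  expect_equal(max(surge), p$iso_peak_delta, tolerance = 1e-3)
  expect_equal(out$time[which.max(surge)] - 600, tmax, tolerance = 1)
  # declined below 1 bpm 300 min after injection, for every default strain
  for (q in default_strains()) {
    v <- telemarr:::iso_surge(300 * 60, q$iso_peak_delta,
                              q$iso_rise_tau * 60, q$iso_decay_tau * 60)
    expect_lt(v, 1)
  }
  # zero peak delta leaves the trace unchanged
  p0 <- p; p0$iso_peak_delta <- 0
  expect_equal(apply_isoproterenol(tr, 600, p0)$hr, tr$hr)
  expect_error(apply_isoproterenol(tr, -5, p), "t_inj")
})

test_that("arrhythmia scheduling is Poisson-calibrated per class", {
  p <- default_strains()[["BS"]]   # PVB rate 40.2 per 5 h
  set.seed(31)
  counts <- replicate(400, {
    s <- schedule_arrhythmias(p, c(0, 5 * 3600))
    sum(s$class == "PVB")
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 40.2), 3 * se)
  # Poisson: variance close to the mean
  expect_gt(var(counts) / mean(counts), 0.75)
  expect_lt(var(counts) / mean(counts), 1.3)
  # empty when all rates are zero
  p0 <- p
  p0$event_rate_pvb <- p0$event_rate_coupled <- 0
  p0$event_rate_vt <- p0$event_rate_vf <- 0
  expect_identical(nrow(schedule_arrhythmias(p0, c(0, 1000))), 0L)
  # grammar of the schedule itself
  set.seed(32)
  s <- schedule_arrhythmias(default_strains()[["Balb/c"]], c(0, 5 * 3600))
  expect_true(all(diff(s$onset) > 0))
  expect_true(all(s$run_length[s$class == "PVB"] == 1L, na.rm = TRUE))
  expect_true(all(s$run_length[s$class == "VT"] >= 4L, na.rm = TRUE))
  expect_true(all(s$duration[s$class == "VF"] > 0, na.rm = TRUE))
})

test_that("injected runs carry prematurity and a fully compensatory pause", {
  set.seed(9)
  bt <- sinus_beats(flat_trace(600, 120), rr_jitter = 0)
  sched <- data.frame(class = c("PVB", "couplet", "VT"),
                      onset = c(30, 60, 90),
                      run_length = c(1L, 2L, 5L), duration = NA_real_)
  inj <- inject_events(bt, sched)
  expect_identical(nrow(inj$events), 3L)
  expect_identical(sum(inj$beats$label == "PVB"), 8L)
  rr <- diff(inj$beats$time) * 1000
  i <- which(!is.na(inj$beats$event_id) & inj$beats$event_id == 1L)
  # single PVB: RR_pre + RR_post = 2 x local RR (fully compensatory)
  expect_equal(rr[i - 1] + rr[i], 2 * 100, tolerance = 1e-6)
  expect_lt(rr[i - 1], 0.8 * 100)
  expect_gt(rr[i], 1.15 * 100)
  # PVBs lack P waves and carry atypical morphology
  pvb <- inj$beats$label == "PVB"
  expect_true(all(inj$beats$morph_atypical[pvb]))
  expect_true(all(!inj$beats$p_present[pvb]))
  expect_true(all(!inj$beats$morph_atypical[!pvb]))
})

test_that("long-term duty cycle keeps the first minute of each 5-min block", {
  seg <- duty_cycle_segments(96 * 3600)
  expect_identical(nrow(seg), 1152L)
  expect_equal(sum(seg$end - seg$start), 96 * 3600 / 5)
  # waveform-level: longterm blanks unrecorded samples, continuous is identity
  fx <- sinus_fixture(duration = 25 * 60, hr = 600)
  expect_identical(apply_sampling_scheme(fx$rec, "continuous"), fx$rec)
  duty <- apply_sampling_scheme(fx$rec, "longterm")
  expect_identical(nrow(duty$segments), 5L)
  expect_equal(mean(!is.na(duty$signal)), 1 / 5, tolerance = 0.01)
  expect_true(all(is.na(duty$signal[(61 * 1000):(290 * 1000)])))
})

test_that("waveform synthesis places template beats at the commanded rate", {
  fx <- sinus_fixture(duration = 30, hr = 600, noise = list(white = 0))
  # beat count ~ HR x duration
  expect_equal(nrow(fx$inj$beats), 600 / 60 * 30, tolerance = 0.01)
  # every noiseless beat window matches the normal template exactly
  tpl <- beat_template(1000, "normal")
  sel <- tpl$offsets >= -20 & tpl$offsets <= 40
  ctr <- round(fx$inj$beats$time[10:20] * 1000) + 1L
  for (s in ctr) {
    w <- fx$rec$signal[s + tpl$offsets[sel]]
    expect_gt(cor(w, tpl$values[sel]), 0.9999)
  }
  expect_error(synthesize_ecg(regular_beats(3), duration = 0.1, fs = 400),
               "fs")
})

test_that("profile invariants are enforced", {
  expect_error(strain_profile("x", hr_day_mean = 500, hr_night_mean = 490,
                              hr_min = 300, hr_max = 700), "hr_min")
  expect_error(strain_profile("x", hr_day_mean = 500, hr_night_mean = 550,
                              hr_min = 300, hr_max = 700,
                              event_rate_pvb = -1), "rates")
})
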