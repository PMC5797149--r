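test_that("clean sinus at 600 bpm is detected beat for beat", {
  fx <- sinus_fixture(duration = 60, hr = 600, noise = list(white = 0.02))
  det <- detect_qrs(fx$rec)
  expect_equal(nrow(det), nrow(fx$inj$beats), tolerance = 1 / 600)
  q <- det_quality(det$time, fx$inj$beats$time)
  expect_identical(unname(q["sens"]), 1)
  expect_identical(unname(q["ppv"]), 1)
  # every detection within 5 ms of a true beat
  dt <- vapply(fx$inj$beats$time,
               function(t) min(abs(det$time - t)), numeric(1))
  expect_lt(max(dt), 0.005)
})

test_that("no beats are clipped at the highest naturally occurring HR", {
  fx <- sinus_fixture(duration = 30, hr = 774, noise = list(white = 0.02),
                      seed = 11)
  det <- detect_qrs(fx$rec)
  q <- det_quality(det$time, fx$inj$beats$time)
  expect_identical(unname(q["sens"]), 1)
  expect_identical(unname(q["ppv"]), 1)
})

test_that("degenerate signals yield empty detection with a warning", {
  rec <- synthesize_ecg(regular_beats(0), duration = 5, fs = 1000)
  expect_warning(det <- detect_qrs(rec), "no beats")
  expect_identical(nrow(det), 0L)
  short <- synthesize_ecg(regular_beats(0), duration = 1, fs = 1000)
  expect_error(detect_qrs(short), "2 s")
})

test_that("detection holds sensitivity and PPV >= 0.98 at 10 dB SNR", {
  clean <- sinus_fixture(duration = 60, hr = 600, noise = list(white = 0),
                         seed = 21)
  rms <- sqrt(mean(clean$rec$signal^2))
  noisy_sd <- rms / 10^(10 / 20)
  set.seed(22)
  rec <- synthesize_ecg(clean$inj$beats, 60, fs = 1000,
                        noise = list(white = noisy_sd))
  det <- detect_qrs(rec)
  q <- det_quality(det$time, clean$inj$beats$time)
  expect_gte(q["sens"], 0.98)
  expect_gte(q["ppv"], 0.98)
})

test_that("template library reflects the injected morphologies", {
  # only normal beats, noiseless: exactly one template
  fx <- sinus_fixture(duration = 30, hr = 600, noise = list(white = 0))
  det <- detect_qrs(fx$rec)
  lib <- build_template_library(fx$rec, det)
  expect_length(lib$templates, 1L)
  expect_identical(lib$templates[[1]]$hint, "normal")
  # normal + PVB morphology: >= 2 templates, minority hinted abnormal
  sched <- data.frame(class = "PVB", onset = c(5, 10, 15, 20, 25),
                      run_length = 1L, duration = NA_real_)
  fx2 <- sinus_fixture(duration = 30, hr = 600, sched = sched,
                       noise = list(white = 0))
  det2 <- detect_qrs(fx2$rec)
  lib2 <- build_template_library(fx2$rec, det2)
  expect_gte(length(lib2$templates), 2L)
  hints <- vapply(lib2$templates, `[[`, character(1), "hint")
  expect_identical(sum(hints == "normal"), 1L)
  # template count bounded by distinct morphologies + 1
  expect_lte(length(lib2$templates), 3L)
  # idempotent: rebuilding from the same inputs is identical
  expect_identical(lib2, build_template_library(fx2$rec, det2))
})

test_that("morphology matching separates normal, atypical and unmatched", {
  sched <- data.frame(class = "PVB", onset = c(5, 10, 15, 20, 25),
                      run_length = 1L, duration = NA_real_)
  fx <- sinus_fixture(duration = 30, hr = 600, sched = sched,
                      noise = list(white = 0))
  det <- detect_qrs(fx$rec)
  lib <- build_template_library(fx$rec, det)
  ann <- match_beat_morphology(fx$rec, det, lib)
  truth_pvb <- fx$inj$beats$time[fx$inj$beats$label == "PVB"]
  is_pvb <- vapply(ann$time, function(t) any(abs(truth_pvb - t) < 0.005),
                   logical(1))
  expect_true(all(ann$morphology[is_pvb] == "atypical"))
  expect_true(all(ann$morphology[!is_pvb] == "normal"))
  # a beat identical to the template scores 1
  expect_gt(max(ann$match_score), 0.9999)
  # sign inversion anticorrelates with the normal template
  inv <- fx$rec
  inv$signal <- -inv$signal
  ann_inv <- match_beat_morphology(inv, det, lib)
  expect_true(all(ann_inv$match_score < 0.95))
})

test_that("P-wave search finds sinus P and rejects PVB and flat windows", {
  sched <- data.frame(class = "PVB", onset = c(10, 20), run_length = 1L,
                      duration = NA_real_)
  fx <- sinus_fixture(duration = 30, hr = 500, sched = sched,
                      noise = list(white = 0.01))
  det <- detect_qrs(fx$rec)
  pw <- find_p_wave(fx$rec, det)
  truth_pvb <- fx$inj$beats$time[fx$inj$beats$label == "PVB"]
  is_pvb <- vapply(pw$time, function(t) any(abs(truth_pvb - t) < 0.005),
                   logical(1))
  expect_true(all(!pw$p_found[is_pvb]))
  normal_ok <- pw$p_found[!is_pvb][-1]      # first beat lacks context
  expect_gt(mean(normal_ok), 0.98)
  # flat signal: nothing found
  flat <- synthesize_ecg(regular_beats(0), duration = 5, fs = 1000)
  fake <- data.frame(time = c(1, 2), sample = c(1000L, 2000L))
  expect_true(all(!find_p_wave(flat, fake)$p_found))
})

test_that("artifact bursts are flagged and intervals never overlap", {
  fx <- sinus_fixture(duration = 30, hr = 600, noise = list(white = 0.02))
  expect_identical(nrow(flag_artifacts(fx$rec)), 0L)
  set.seed(8)
  rec <- synthesize_ecg(fx$inj$beats, 30, fs = 1000,
                        noise = list(white = 0.02, artifact_rate = 250,
                                     artifact_amp = 3))
  art <- flag_artifacts(rec)
  expect_gt(nrow(art), 0L)
  # each true burst is covered at >= 90%
  for (r in seq_len(nrow(rec$artifact_truth))) {
    tr <- rec$artifact_truth[r, ]
    cov <- sum(pmax(0, pmin(art$end, tr$end) - pmax(art$start, tr$start)))
    expect_gte(cov / (tr$end - tr$start), 0.9)
  }
  if (nrow(art) > 1L) expect_true(all(art$start[-1] >= art$end[-nrow(art)]))
})
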