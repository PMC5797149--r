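test_that("RR series matches brute-force differencing and warms up correctly", {
  b <- c(0, 0.1, 0.2)
  rr <- compute_rr(b)
  expect_equal(rr$rr_pre, c(NA, 100, 100))
  expect_equal(rr$rr_post, c(100, 100, NA))
  # constant RR: reference is 100 ms once 5 preceding intervals exist
  rr2 <- compute_rr(regular_beats(20)$time)
  expect_true(all(is.na(rr2$ref[1:6])))
  expect_equal(rr2$ref[7:20], rep(100, 14))
  # random beat list: successive differences equal the naive oracle
  set.seed(4)
  t <- cumsum(runif(50, 0.05, 0.2))
  rr3 <- compute_rr(t)
  expect_equal(rr3$rr_pre[-1], diff(t) * 1000)
  expect_equal(rr3$rr_post[-50], diff(t) * 1000)
  expect_identical(nrow(compute_rr(numeric(1))), 1L)
  expect_error(compute_rr(c(1, 1)), "increasing")
})

test_that("a beat is PVB iff premature with at least 2 of 3 criteria", {
  subsets <- list(character(0), "morph", "av_diss", "pause",
                  c("morph", "av_diss"), c("morph", "pause"),
                  c("av_diss", "pause"), c("morph", "av_diss", "pause"))
  got <- vapply(subsets, function(ss) {
    b <- criteria_fixture(ss)
    cl <- classify_beats(b)
    cl$label[15] == "PVB"
  }, logical(1))
  expect_identical(got, lengths(subsets) >= 2L)
  # a non-premature beat is never PVB, even with all three criteria
  b <- regular_beats(30)
  b$morph_atypical[15] <- TRUE
  b$p_present[15] <- FALSE
  expect_true(all(classify_beats(b)$label == "N"))
})

test_that("run grouping maps 1/2/3/4+ runs onto the event grammar", {
  expect_identical(group_runs(c("N", "PVB", "PVB", "N"))$class, "couplet")
  expect_identical(group_runs(rep("PVB", 4))$class, "VT")
  expect_identical(nrow(group_runs(rep("N", 10))), 0L)
  expect_identical(nrow(group_runs(character(0))), 0L)
  # random label strings agree with the brute-force encoder
  set.seed(12)
  for (i in 1:25) {
    lab <- sample(c("N", "PVB"), 40, replace = TRUE, prob = c(0.7, 0.3))
    got <- group_runs(lab)
    ref <- naive_run_encoder(lab)
    expect_identical(got$class, ref$class)
    expect_identical(got$n_beats, ref$n_beats)
  }
  # grammar bijection: expanding events reproduces the label string
  set.seed(13)
  lab <- sample(c("N", "PVB"), 60, replace = TRUE)
  ev <- group_runs(lab)
  rebuilt <- rep("N", 60)
  for (r in seq_len(nrow(ev)))
    rebuilt[ev$start_beat[r]:ev$end_beat[r]] <- "PVB"
  expect_identical(rebuilt, lab)
})

test_that("adding one isolated PVB raises the PVB and total counts by one", {
  set.seed(20)
  bt <- sinus_beats(flat_trace(600, 300), rr_jitter = 0.01)
  sched <- data.frame(class = "PVB", onset = c(60, 120),
                      run_length = 1L, duration = NA_real_)
  sched2 <- rbind(sched, data.frame(class = "PVB", onset = 240,
                                    run_length = 1L, duration = NA_real_))
  c1 <- {
    inj <- inject_events(bt, sched)
    count_events(classify_truth(inj$beats, inj$events)$events, c(0, 300))
  }
  c2 <- {
    inj <- inject_events(bt, sched2)
    count_events(classify_truth(inj$beats, inj$events)$events, c(0, 300))
  }
  expect_identical(c2$pvb, c1$pvb + 1L)
  expect_identical(c2$total, c1$total + 1L)
})

test_that("event counting is window-additive and conserves the total", {
  ev <- data.frame(class = c("PVB", "couplet", "VT", "VF", "PVB", "triplet"),
                   onset = c(10, 50, 110, 160, 210, 260))
  w_all <- count_events(ev, c(0, 300))
  w1 <- count_events(ev, c(0, 150))
  w2 <- count_events(ev, c(150, 300))
  for (cl in c("pvb", "coupled", "vt", "vf", "total"))
    expect_identical(w_all[[cl]], w1[[cl]] + w2[[cl]])
  expect_identical(w_all$total,
                   w_all$pvb + w_all$coupled + w_all$vt + w_all$vf)
  # events inside artifact intervals are not counted
  art <- data.frame(start = 100, end = 200)
  expect_identical(count_events(ev, c(0, 300), art)$total, 4L)
  # empty event list: all-zero summary
  expect_identical(unlist(count_events(ev[0, ], c(0, 300))),
                   c(pvb = 0L, coupled = 0L, vt = 0L, vf = 0L, total = 0L))
})

test_that("truth-bypass classification reproduces the schedule exactly", {
  p <- default_strains()[["Balb/c"]]
  for (seed in c(3, 41)) {
    set.seed(seed)
    a <- simulate_acute_session(p, "iso")
    cl <- classify_truth(a$beats, a$events)
    got <- count_events(cl$events, a$window)
    want <- count_events(data.frame(class = a$events$class,
                                    onset = a$events$onset), a$window)
    expect_identical(got, want)
    # zero beat-level confusion against truth labels
    expect_identical(sum(a$beats$label != cl$beats$label), 0L)
  }
})

test_that("VF is found by absent QRS matching, gated on signal energy", {
  sched <- data.frame(class = "VF", onset = 20, run_length = NA_integer_,
                      duration = 4)
  fx <- sinus_fixture(duration = 40, hr = 600, sched = sched,
                      noise = list(white = 0.02), seed = 17)
  res <- analyze_record(fx$rec)
  vf <- res$events[res$events$class == "VF", ]
  expect_identical(nrow(vf), 1L)
  cov <- max(0, min(vf$end, 24) - max(vf$onset, 20))
  expect_gte(cov / 4, 0.9)
  # clean sinus: no VF
  fx2 <- sinus_fixture(duration = 30, hr = 600, noise = list(white = 0.02))
  det <- detect_qrs(fx2$rec)
  lib <- build_template_library(fx2$rec, det)
  ann <- match_beat_morphology(fx2$rec, det, lib)
  expect_identical(nrow(detect_vf(fx2$rec, ann)), 0L)
  # flat signal fails the RMS gate
  flat <- synthesize_ecg(regular_beats(0), duration = 10, fs = 1000)
  expect_identical(nrow(detect_vf(flat, ann[0, ])), 0L)
})

test_that("episode summary reports zero-rate groups as 0.0 (0/n)", {
  counts <- data.frame(group = rep(c("A", "B"), each = 3),
                       pvb = c(3, 1, 2, 0, 4, 1),
                       coupled = 0L, vt = 0L,
                       vf = c(1, 0, 2, 0, 0, 0))
  counts$total <- counts$pvb + counts$coupled + counts$vt + counts$vf
  es <- summarize_episodes(counts)
  vfB <- es[es$group == "B" & es$class == "vf", ]
  expect_identical(vfB$mean, 0)
  expect_identical(vfB$n_affected, 0L)
  expect_identical(vfB$fraction, 0)
  vfA <- es[es$group == "A" & es$class == "vf", ]
  expect_identical(vfA$n_affected, 2L)
  expect_equal(vfA$fraction, 2 / 3)
})
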