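make_stack <- function(mean_rr = 0.4, jitter = 0, noise = 0, duration = 30,
                       frame_rate = 152, gaps = list(), seed = 1) {
  spec <- recording_spec(mean_rr = mean_rr, rr_jitter_sd = jitter,
                         gap_events = gaps, duration = duration,
                         frame_rate = frame_rate, noise_sd = noise, seed = seed)
  sch <- simulate_beat_times(spec)
  list(spec = spec, sch = sch, st = render_frame_stack(sch, spec))
}

test_that("template selection finds an extreme cardiac phase", {
  fx <- make_stack(noise = 0)
  ti <- select_template(fx$st)
  t_time <- (ti - 1) * fx$st$frame_interval
  # distance to the nearest beat, as a phase fraction of the RR interval
  phase <- min(abs(t_time - fx$sch$beat_times)) / 0.4
  mid_dist <- abs(phase - 0.5)
  expect_true(phase <= 0.1 || mid_dist <= 0.1)

  # forced pair of 2 frames returns the earlier
  two <- fx$st
  two$frames <- two$frames[1:2, , , drop = FALSE]
  expect_equal(select_template(two, window = 2), 1)
})

test_that("constant recordings are rejected as degenerate", {
  st <- structure(list(frames = array(0.5, dim = c(50, 16, 16)),
                       frame_interval = 1 / 100), class = "frame_stack")
  expect_error(select_template(st), "degenerate")
})

test_that("correlation trace self-correlates at 1 and is shift-invariant", {
  fx <- make_stack(duration = 4)
  ti <- select_template(fx$st)
  tr <- correlation_trace(fx$st, ti)
  expect_equal(length(tr$values), dim(fx$st$frames)[1])
  expect_equal(tr$values[ti], 1, tolerance = 1e-12)
  expect_true(all(tr$values >= -1 - 1e-9 & tr$values <= 1 + 1e-9))

  shifted <- fx$st
  shifted$frames <- shifted$frames + 5
  tr2 <- correlation_trace(shifted, ti)
  expect_equal(tr$values, tr2$values, tolerance = 1e-9)
})

test_that("the trace is periodic at the schedule's RR interval", {
  fx <- make_stack(mean_rr = 0.4, duration = 8, frame_rate = 150, noise = 0)
  tr <- correlation_trace(fx$st, select_template(fx$st))
  x <- tr$values - mean(tr$values)
  ac <- stats::acf(x, lag.max = 90, plot = FALSE)$acf[-1]
  # autocorrelation peaks at the 60-frame period
  expect_equal(which.max(ac[40:80]) + 39, 60, tolerance = 1)
})

test_that("peak detection recovers the beat count and timing", {
  fx <- make_stack(noise = 0)
  tr <- correlation_trace(fx$st, select_template(fx$st))
  pk <- detect_peaks(tr)
  expect_lte(abs(length(pk) - 75), 1)

  # timing match within 2 frame intervals at 10% amplitude noise
  fxn <- make_stack(jitter = 0.02, noise = 0.09, seed = 5)
  trn <- correlation_trace(fxn$st, select_template(fxn$st))
  pkn <- detect_peaks(trn)
  err <- vapply(pkn, function(p) min(abs(fxn$sch$beat_times - p)), numeric(1))
  expect_lt(max(err), 2 * fxn$st$frame_interval)
})

test_that("a constant trace yields zero peaks", {
  tr <- structure(list(values = rep(0.5, 100), template_index = 1,
                       frame_interval = 0.01), class = "correlation_trace")
  expect_length(detect_peaks(tr), 0)
})

test_that("gap classification separates pauses from arrests at the stated thresholds", {
  mk <- function(gap) cumsum(c(0, rep(0.4, 20), gap, rep(0.4, 20)))
  arrest <- classify_gaps(mk(2.5), 1 / 152)
  expect_equal(arrest$gap_events$class, "arrest")
  expect_equal(arrest$gap_events$length, 2.5)

  pause <- classify_gaps(mk(1.3), 1 / 152)
  expect_equal(pause$gap_events$class, "pause")

  none <- classify_gaps(mk(1.19), 1 / 152)
  expect_equal(nrow(none$gap_events), 0)

  # arrest precedence: a gap satisfying both definitions is one arrest
  slow <- cumsum(c(0, rep(0.7, 15), 2.05, rep(0.7, 15)))
  both <- classify_gaps(slow, 1 / 152)
  expect_equal(both$gap_events$class, "arrest")
  expect_equal(nrow(both$gap_events), 1)

  # flagged intervals are excluded from the NN set
  expect_equal(length(arrest$nn_intervals), 40)
  expect_false(any(arrest$nn_intervals > 2))
})

test_that("phenotype metrics match hand computation", {
  const <- classify_gaps(cumsum(c(0, rep(0.4, 30))), 1 / 152)
  ph <- compute_phenotype(const)
  expect_equal(ph$heart_rate, 150)
  expect_equal(ph$sdnn, 0)
  expect_equal(ph$rmssd, 0)
  expect_equal(ph$hrv, 0)

  # NN = [0.40, 0.42, 0.38, 0.40] s
  wk <- classify_gaps(cumsum(c(0.4, 0.40, 0.42, 0.38, 0.40)), 1 / 152)
  phw <- compute_phenotype(wk)
  expect_equal(phw$sdnn, 1000 * pop_sd(c(0.40, 0.42, 0.38, 0.40)), tolerance = 1e-9)
  expect_equal(phw$sdnn, 14.142, tolerance = 1e-3)
  expect_equal(phw$rmssd, 1000 * sqrt(mean(c(0.02, -0.04, 0.02)^2)), tolerance = 1e-9)
  expect_equal(phw$rmssd, 28.284, tolerance = 1e-3)
  expect_equal(phw$hrv, (phw$sdnn + phw$rmssd) / 2)
})

test_that("hrv is always the mean of sdnn and rmssd", {
  set.seed(31)
  for (i in 1:10) {
    nn <- 0.4 + rnorm(50, 0, 0.03)
    ph <- compute_phenotype(classify_gaps(cumsum(c(0.4, abs(nn))), 1 / 152))
    expect_equal(ph$hrv, (ph$sdnn + ph$rmssd) / 2)
  }
})

test_that("insufficient beats set the too_few_beats flag instead of erroring", {
  calls <- classify_gaps(c(0, 0.4), 1 / 152)
  ph <- compute_phenotype(calls)
  expect_equal(ph$qc_flag, "too_few_beats")
  expect_true(is.na(ph$sdnn))
})

test_that("RMSSD/SDNN approaches sqrt(2) for i.i.d. RR jitter", {
  set.seed(8)
  nn <- 0.4 + rnorm(300, 0, 0.02)
  ph <- compute_phenotype(classify_gaps(cumsum(c(0.4, nn)), 1 / 152))
  expect_lt(abs(ph$rmssd / ph$sdnn - sqrt(2)) / sqrt(2), 0.15)
})

test_that("SDNN recovers the generated jitter from rendered recordings", {
  fx <- make_stack(jitter = 0.02, noise = 0.05, seed = 13)
  ph <- quantify_stack(fx$st)
  truth <- 1000 * pop_sd(fx$sch$rr_intervals)
  expect_lt(abs(ph$sdnn - truth), 0.25 * truth)
})

test_that("heart rate is recovered within 1% across the physiological range", {
  for (rr in c(0.25, 0.45, 0.6)) {
    fx <- make_stack(mean_rr = rr, noise = 0, seed = 21)
    ph <- quantify_stack(fx$st)
    truth <- 60 / mean(fx$sch$rr_intervals)
    expect_lt(abs(ph$heart_rate - truth) / truth, 0.01)
  }
})

test_that("missed-beat QC flags dropout but tolerates clean data and true pauses", {
  clean <- classify_gaps(cumsum(c(0, rep(0.4, 60))), 1 / 152)
  expect_equal(qc_missed_beats(clean), "ok")

  # delete every 10th beat: doubled intervals appear in (1.7x, 3x] median
  beats <- cumsum(c(0, rep(0.4, 60)))
  dropped <- beats[-seq(10, length(beats), by = 10)]
  expect_equal(qc_missed_beats(classify_gaps(dropped, 1 / 152)),
               "suspect_missed_beat")

  # a true pause is excluded from the NN set before QC
  paused <- classify_gaps(cumsum(c(0, rep(0.4, 30), 1.3, rep(0.4, 30))), 1 / 152)
  expect_equal(qc_missed_beats(paused), "ok")
})

test_that("pauses and arrests are detected end to end from rendered stacks", {
  fx <- make_stack(gaps = list(c(20, 2.5), c(50, 1.3)), noise = 0.03, seed = 3)
  ph <- quantify_stack(fx$st)
  ev <- attr(ph, "calls")$gap_events
  expect_true(ph$has_arrest)
  expect_true(ph$has_pause)
  expect_equal(sort(ev$class), c("arrest", "pause"))
  expect_equal(ph$qc_flag, "ok")
})

test_that("the quantification pipeline is deterministic", {
  fx <- make_stack(jitter = 0.02, noise = 0.05, duration = 6, seed = 17)
  p1 <- quantify_stack(fx$st)
  p2 <- quantify_stack(fx$st)
  expect_identical(unclass(p1)[names(unclass(p1))],
                   unclass(p2)[names(unclass(p2))])
})
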