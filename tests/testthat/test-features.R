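test_that("beat detection finds constructed beats and ignores flat traces", {
  expect_equal(nrow(detect_beats(make_flat_trace())), 0)

  tr <- make_ap_train(n_beats = 5, period_ms = 1000)
  bt <- detect_beats(tr)
  expect_equal(nrow(bt), 5)
  expect_true(all(diff(bt$upstroke_ms) > 0))
  expect_equal(diff(bt$upstroke_ms), rep(1000, 4), tolerance = tr$dt_out_ms)
})

test_that("square and triangle fixtures give their analytic APDs", {
  ## square pulse of width 200 ms: APD90 = 200 ms (up to edge widths)
  sq <- make_ap_train(n_beats = 1, period_ms = 2000, apd_ms = 200, dt = 0.1)
  bt <- detect_beats(sq)
  expect_equal(bt$apd90, 200, tolerance = 3)

  ## linear decay at 1 mV/ms, amplitude 100: 90% repolarization happens
  ## 90 ms after the peak, plus the 1 ms upstroke offset
  tri <- make_triangle_ap(amplitude = 100, decay = 1, rise_ms = 1)
  bt2 <- detect_beats(tri)
  expect_equal(nrow(bt2), 1)
  expect_equal(bt2$apd90, 91, tolerance = 1)
  expect_equal(bt2$apd50, 51, tolerance = 1)
})

test_that("APD50 never exceeds APD90 on model beats", {
  bt <- detect_beats(cached_baseline_trace())
  expect_gt(nrow(bt), 3)
  ok <- !is.na(bt$apd50) & !is.na(bt$apd90)
  expect_true(all(bt$apd50[ok] <= bt$apd90[ok]))
})

test_that("amplitudes are peak minus diastole and offset-invariant", {
  tr <- make_ap_train(amplitude = 100, diastolic = -75)
  a <- beat_amplitudes(tr)
  expect_equal(a$ap_amplitude, rep(100, 5), tolerance = 1e-6)

  shifted <- tr; shifted$V <- tr$V + 33
  expect_equal(beat_amplitudes(shifted)$ap_amplitude, a$ap_amplitude)

  norm <- normalize_traces(tr)
  expect_equal(max(beat_amplitudes(norm)$ap_amplitude), 1, tolerance = 1e-6)
})

test_that("duration metrics are unchanged by normalization", {
  tr <- cached_baseline_trace()
  bt_raw <- detect_beats(tr)
  bt_norm <- detect_beats(normalize_traces(tr))
  expect_equal(nrow(bt_raw), nrow(bt_norm))
  expect_equal(bt_norm$apd90, bt_raw$apd90, tolerance = 0.5)
  expect_equal(bt_norm$upstroke_ms, bt_raw$upstroke_ms, tolerance = 1)
})

test_that("spontaneous rate follows the beats-over-duration convention", {
  expect_true(is.na(spontaneous_rate(make_flat_trace())))

  tr <- make_ap_train(n_beats = 4, period_ms = 1500, lead_ms = 0)
  ## 4 beats in 6 s of analyzed trace
  expect_equal(spontaneous_rate(tr), 4 / 6, tolerance = 0.01)
})

test_that("the classifier applies its rules in priority order", {
  cfg <- arrhythmia_config()
  expect_equal(classify_arrhythmia(make_flat_trace(), cfg = cfg), "cessation")

  reg <- make_ap_train(n_beats = 6, period_ms = 1000)
  expect_equal(classify_arrhythmia(reg, baseline_rate = 1, cfg = cfg), "none")

  ## alternans: APD90 alternating +/-10% over 6 beats
  alt <- make_ap_train(n_beats = 6, period_ms = 1000,
                       apd_scale = rep(c(1.1, 0.9), 3))
  expect_equal(classify_arrhythmia(alt, baseline_rate = 1, cfg = cfg),
               "alternans")

  ## tachycardia: regular beating far above the baseline rate
  tach <- make_ap_train(n_beats = 12, period_ms = 240, apd_ms = 120)
  expect_equal(classify_arrhythmia(tach, baseline_rate = 1, cfg = cfg),
               "tachycardia")

  ## cessation by amplitude collapse relative to baseline
  tiny <- make_ap_train(n_beats = 5, amplitude = 5)
  expect_equal(classify_arrhythmia(tiny, baseline_amplitude = 100, cfg = cfg),
               "cessation")

  ## determinism
  expect_identical(classify_arrhythmia(alt, baseline_rate = 1, cfg = cfg),
                   classify_arrhythmia(alt, baseline_rate = 1, cfg = cfg))
})

test_that("a phase-3 re-depolarization bump is an afterdepolarization", {
  ## 3-beat train; each beat carries a 10% re-depolarization bump during
  ## late repolarization that decays again before the next upstroke
  tr <- make_ap_train(n_beats = 3, period_ms = 1500, apd_ms = 250, dt = 0.5)
  for (b in 0:2) {
    t0 <- 100 + b * 1500 + 600            # well after the beat's peak
    sel <- tr$time_ms > t0 & tr$time_ms < t0 + 120
    bump <- 10 * exp(-((tr$time_ms[sel] - t0 - 60)^2) / 400)
    tr$V[sel] <- tr$V[sel] + bump
  }
  expect_equal(classify_arrhythmia(tr, baseline_rate = 1,
                                   cfg = arrhythmia_config()),
               "afterdepolarization")
})

test_that("irregular rhythm is flagged by inter-beat variability", {
  tt <- seq(0, 8000, by = 0.5)
  v <- rep(-80, length(tt))
  onsets <- c(100, 900, 2100, 2700, 4100, 5600, 6100, 7400)
  for (t0 in onsets) {
    up <- tt >= t0 & tt < t0 + 1
    v[up] <- -80 + 100 * (tt[up] - t0)
    pl <- tt >= t0 + 1 & tt < t0 + 150
    v[pl] <- 20
    dn <- tt >= t0 + 150 & tt < t0 + 151
    v[dn] <- 20 - 100 * (tt[dn] - t0 - 150)
  }
  tr <- cmcal:::new_cm_trace(tt, v, (v + 80) / 1e5, 0.5, NULL, FALSE)
  expect_equal(classify_arrhythmia(tr, baseline_rate = 1), "irregular")
})
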