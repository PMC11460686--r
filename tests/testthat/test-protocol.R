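test_that("window extraction returns the re-zeroed trailing window", {
  tr <- make_ap_train(n_beats = 5, period_ms = 1000, dt = 1)
  w <- extract_window(tr, 2000)
  expect_equal(w$time_ms[1], 0)
  expect_equal(w$time_ms[length(w$time_ms)], 2000)
  expect_equal(w$V, tr$V[tr$time_ms >= max(tr$time_ms) - 2000 - 1e-9])

  full <- extract_window(tr, max(tr$time_ms))
  expect_equal(full$V, tr$V)

  expect_error(extract_window(tr, 1e6), "shorter than")
})

test_that("a 5 s window at 0.1 ms carries 50,001 samples", {
  x0 <- cached_x0()
  tr <- simulate_cell(duration_ms = 8000, x0 = x0, dt_out_ms = 0.1,
                      record_from_ms = 3000)
  expect_length(extract_window(tr, 5000)$time_ms, 50001)
})

test_that("uniform resampling is exact on linear signals and identity on own grid", {
  tt <- seq(0, 100, by = 1)
  tr <- cmcal:::new_cm_trace(tt, V = 2 * tt, Cai = 0.5 * tt, dt_out_ms = 1,
                             final_state = NULL, failed = FALSE)
  r <- resample_uniform(tr, 0.25)
  expect_equal(r$V, 2 * r$time_ms, tolerance = 1e-12)

  same <- resample_uniform(tr, 1)
  expect_equal(same$V, tr$V)
  expect_equal(same$time_ms, tr$time_ms)

  bad <- tr; bad$time_ms <- rev(bad$time_ms)
  expect_error(resample_uniform(bad, 1), "strictly increasing")
})

test_that("linear interpolation error respects the curvature bound", {
  f_hz <- 50
  dt1 <- 1            # 1 kHz sampling, ms units
  tt <- seq(0, 200, by = dt1)
  omega <- 2 * pi * f_hz / 1000   # rad per ms
  tr <- cmcal:::new_cm_trace(tt, V = sin(omega * tt), Cai = sin(omega * tt),
                             dt_out_ms = dt1, final_state = NULL,
                             failed = FALSE)
  r <- resample_uniform(tr, 0.1)  # 10 kHz grid
  truth <- sin(omega * r$time_ms)
  bound <- dt1^2 * omega^2 / 8    # dt^2 * max|v''| / 8
  expect_lt(max(abs(r$V - truth)), bound + 1e-12)
})

test_that("min-max normalization has the stated algebraic properties", {
  tr <- make_ap_train()
  n <- normalize_traces(tr)
  expect_equal(min(n$V), 0)
  expect_equal(max(n$V), 1)
  expect_true(n$normalized)

  ## explicit mapping for min -75, max +25
  tr2 <- tr; tr2$V <- seq(-75, 25, length.out = length(tr$V))
  expect_equal(normalize_traces(tr2)$V, (tr2$V + 75) / 100)

  ## affine invariance: normalize(a*V + b) == normalize(V), a > 0
  tr3 <- tr; tr3$V <- 3.7 * tr$V + 42
  expect_equal(normalize_traces(tr3)$V, normalize_traces(tr)$V,
               tolerance = 1e-12)

  ## idempotence
  expect_equal(normalize_traces(n)$V, n$V, tolerance = 1e-12)

  expect_error(normalize_traces(make_flat_trace()), "constant")
})

test_that("per-segment normalization makes every segment attain 0 and 1", {
  ts <- make_fixture_trace_set()
  ts$segments[[2]]$V <- ts$segments[[2]]$V * 0.5 - 10
  n <- normalize_traces(ts)
  for (seg in n$segments) {
    expect_equal(range(seg$V), c(0, 1))
    expect_equal(range(seg$Cai), c(0, 1))
  }
  ## global mode: extremes attained somewhere, every value in [0, 1]
  g <- normalize_traces(ts, mode = "global")
  allV <- unlist(lapply(g$segments, `[[`, "V"))
  expect_equal(range(allV), c(0, 1))
})

test_that("a 1-condition protocol reproduces simulate-then-extract", {
  x0 <- cached_x0()
  prot <- protocol(condition("baseline", duration_ms = 10000),
                   window_ms = 3000, dt_out_ms = 1)
  ts <- run_protocol(conductance_set(), prot, x0 = x0)
  expect_length(ts$segments, 1)

  tr <- simulate_cell(duration_ms = 10000, x0 = x0, dt_out_ms = 1,
                      record_from_ms = 7000)
  tr <- cmcal:::rezero_trace(tr)
  expect_equal(ts$segments[[1]]$V, tr$V)
  expect_equal(ts$segments[[1]]$Cai, tr$Cai)
  expect_equal(ts$final_state, tr$final_state)
})

test_that("multi-condition protocols carry state over and keep counts", {
  x0 <- cached_x0()
  prot <- protocol(list(
    condition("a", ca_o = 1.0, duration_ms = 6000),
    condition("b", duration_ms = 6000),
    condition("c", pacing_hz = 1.25, blocks = block_map(I_CaL = 0.25),
              duration_ms = 6000)
  ), window_ms = 2000, dt_out_ms = 1)
  ts <- run_protocol(conductance_set(), prot, x0 = x0)
  expect_false(ts$failed)
  expect_length(ts$segments, 3)
  expect_true(all(vapply(ts$segments, function(s) length(s$V) > 0, TRUE)))

  ## carry-over: the protocol engine reproduces a manual chain of
  ## simulations exactly (each condition starts from the previous final
  ## state)
  prot2 <- protocol(list(condition("b1", duration_ms = 5000),
                         condition("b2", duration_ms = 5000)),
                    window_ms = 2000, dt_out_ms = 1)
  ts2 <- run_protocol(conductance_set(), prot2, x0 = x0)
  leg1 <- simulate_cell(duration_ms = 5000, x0 = x0, dt_out_ms = 1,
                        record_from_ms = 3000)
  leg2 <- simulate_cell(duration_ms = 5000, x0 = leg1$final_state,
                        dt_out_ms = 1, record_from_ms = 3000)
  expect_identical(ts2$final_state, leg2$final_state)
  expect_equal(ts2$segments[[2]]$V, leg2$V)
})

test_that("consecutive identical steady-state conditions superimpose", {
  x0 <- cached_x0()
  prot <- protocol(list(condition("b1", duration_ms = 20000),
                        condition("b2", duration_ms = 20000)),
                   window_ms = 5000, dt_out_ms = 1)
  ts <- run_protocol(conductance_set(), prot, x0 = x0)
  s1 <- ts$segments[[1]]; s2 <- ts$segments[[2]]
  i1 <- cmcal:::.first_upstroke_idx(s1$V, 1)
  i2 <- cmcal:::.first_upstroke_idx(s2$V, 1)
  n <- min(2000, length(s1$V) - max(i1, i2))
  ## RMS bound: steep upstrokes make a pointwise bound ill-conditioned
  expect_lt(sqrt(mean((s1$V[i1:(i1 + n)] - s2$V[i2:(i2 + n)])^2)), 3)
})

test_that("the condition library matches the documented roster", {
  lib <- condition_library()
  expect_length(lib, 19)
  expect_equal(lib$c19$label, "baseline_spont")
  expect_null(lib$c19$pacing_hz)
  expect_equal(lib$c19$mil$ca_o, 1.8)
  cas <- vapply(lib, function(x) x$mil$ca_o, 0)
  expect_setequal(unique(cas), c(1.0, 1.8, 2.5))

  p <- optimized_protocol()
  expect_length(p$conditions, 3)
  expect_equal(p$conditions[[1]]$mil$ca_o, 1.0)
  expect_equal(p$conditions[[3]]$pacing_hz, 1.25)
  expect_equal(unclass(p$conditions[[3]]$blocks)[["I_CaL"]], 0.25)
})

test_that("protocols round-trip through YAML declarations", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "window_s: 2",
    "dt_out_ms: 1",
    "protocol:",
    "  - label: low_ca",
    "    ca_o: 1.0",
    "    duration_s: 10",
    "  - label: paced",
    "    pacing_hz: 1.25",
    "    blocks:",
    "      I_CaL: 0.25",
    "    duration_s: 10"
  ), f)
  p <- protocol_from_yaml(f)
  expect_length(p$conditions, 2)
  expect_equal(p$window_ms, 2000)
  expect_equal(p$conditions[[1]]$mil$ca_o, 1.0)
  expect_equal(p$conditions[[2]]$pacing_hz, 1.25)
  expect_equal(unclass(p$conditions[[2]]$blocks)[["I_CaL"]], 0.25)
})
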