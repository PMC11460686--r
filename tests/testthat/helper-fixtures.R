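## Shared fixtures and memoised expensive objects for the suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

cached_x0 <- function() memo("x0", initial_state())

## 60 s baseline spontaneous run, last 30 s recorded at 1 ms
cached_baseline_trace <- function() memo("baseline_trace", {
  simulate_cell(conductance_set(), duration_ms = 60000, x0 = cached_x0(),
                dt_out_ms = 1, record_from_ms = 30000)
})

## Piecewise-linear AP train: rise over `rise_ms`, plateau of `apd_ms`,
## fall over `fall_ms`, rest at `diastolic`. Returns a cm_trace whose V and
## Cai both carry the waveform.
make_ap_train <- function(n_beats = 5, period_ms = 1000, apd_ms = 200,
                          rise_ms = 1, fall_ms = 1, amplitude = 100,
                          diastolic = -80, dt = 0.5, lead_ms = 100,
                          apd_scale = rep(1, n_beats)) {
  total <- lead_ms + n_beats * period_ms
  tt <- seq(0, total, by = dt)
  v <- rep(diastolic, length(tt))
  for (b in seq_len(n_beats)) {
    t0 <- lead_ms + (b - 1) * period_ms
    a <- apd_ms * apd_scale[b]
    seg <- tt - t0
    up <- seg >= 0 & seg < rise_ms
    v[up] <- diastolic + amplitude * seg[up] / rise_ms
    plateau <- seg >= rise_ms & seg < rise_ms + a
    v[plateau] <- diastolic + amplitude
    fall <- seg >= rise_ms + a & seg < rise_ms + a + fall_ms
    v[fall] <- diastolic + amplitude * (1 - (seg[fall] - rise_ms - a) / fall_ms)
  }
  cmcal:::new_cm_trace(time_ms = tt, V = v, Cai = (v - diastolic) / 1e5,
                       dt_out_ms = dt, final_state = NULL, failed = FALSE)
}

## Triangle AP: instantaneous-ish rise then linear decay at `decay` mV/ms.
make_triangle_ap <- function(amplitude = 100, decay = 1, rise_ms = 1,
                             diastolic = -80, dt = 0.1, lead_ms = 50,
                             tail_ms = 50) {
  dur <- amplitude / decay
  tt <- seq(0, lead_ms + rise_ms + dur + tail_ms, by = dt)
  v <- rep(diastolic, length(tt))
  seg <- tt - lead_ms
  up <- seg >= 0 & seg < rise_ms
  v[up] <- diastolic + amplitude * seg[up] / rise_ms
  down <- seg >= rise_ms & seg < rise_ms + dur
  v[down] <- diastolic + amplitude - decay * (seg[down] - rise_ms)
  cmcal:::new_cm_trace(time_ms = tt, V = v, Cai = (v - diastolic) / 1e5,
                       dt_out_ms = dt, final_state = NULL, failed = FALSE)
}

## flat trace at a constant level
make_flat_trace <- function(level = -70, dur_ms = 5000, dt = 1) {
  tt <- seq(0, dur_ms, by = dt)
  cmcal:::new_cm_trace(time_ms = tt, V = rep(level, length(tt)),
                       Cai = rep(1e-4, length(tt)), dt_out_ms = dt,
                       final_state = NULL, failed = FALSE)
}

## hand-built two-segment trace set for fitness tests
make_fixture_trace_set <- function(offset_V = 0, offset_Ca = 0,
                                   normalized = FALSE) {
  seg <- function() {
    tr <- make_ap_train(n_beats = 3, period_ms = 800, apd_ms = 150, dt = 1)
    tr$V <- tr$V + offset_V
    tr$Cai <- tr$Cai + offset_Ca
    tr$normalized <- normalized
    tr
  }
  cmcal:::new_trace_set(segments = list(seg(), seg()),
                        normalized = normalized)
}
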