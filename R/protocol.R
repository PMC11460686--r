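#' Experimental condition
#'
#' One segment of a protocol: an extracellular milieu, optional pacing,
#' optional channel block, and a duration. The default duration of 5
#' minutes is sufficient to reach an operational steady state under
#' physiological, unperturbed conditions.
#'
#' @param label short condition label.
#' @param ca_o,na_o,k_o bath concentrations (mM).
#' @param pacing_hz pacing frequency in Hz, or `NULL` for spontaneous.
#' @param blocks optional [block_map()] (or named fractions).
#' @param duration_ms condition duration (ms).
#' @param stim_amplitude,stim_width stimulus pulse settings (pA/pF, ms).
#' @return an object of class `cm_condition`.
#' @export
condition <- function(label = "", ca_o = 1.8, na_o = 151, k_o = 5.4,
                      pacing_hz = NULL, blocks = NULL, duration_ms = 300000,
                      stim_amplitude = 60, stim_width = 1) {
  stopifnot(duration_ms > 0)
  if (!is.null(blocks) && !inherits(blocks, "block_map")) {
    blocks <- do.call(block_map, as.list(blocks))
  }
  stim <- if (is.null(pacing_hz)) NULL else {
    stopifnot(pacing_hz > 0)
    stimulus(period_ms = 1000 / pacing_hz, amplitude_pApF = stim_amplitude,
             width_ms = stim_width)
  }
  structure(list(label = label, mil = milieu(na_o, ca_o, k_o),
                 pacing_hz = pacing_hz, stim = stim, blocks = blocks,
                 duration_ms = duration_ms), class = "cm_condition")
}

#' Protocol: an ordered list of conditions with state carry-over
#'
#' @param conditions list of [condition()] objects (at least one).
#' @param window_ms length of the recorded steady-state window taken from
#'   the end of each condition (ms).
#' @param dt_out_ms output sampling step of the recorded windows (ms).
#' @return an object of class `cm_protocol`.
#' @export
protocol <- function(conditions, window_ms = 5000, dt_out_ms = 0.1) {
  if (inherits(conditions, "cm_condition")) conditions <- list(conditions)
  stopifnot(length(conditions) >= 1,
            all(vapply(conditions, inherits, TRUE, "cm_condition")))
  for (cnd in conditions) {
    if (cnd$duration_ms < window_ms) {
      stop("condition '", cnd$label, "' is shorter than the recorded window")
    }
  }
  structure(list(conditions = conditions, window_ms = window_ms,
                 dt_out_ms = dt_out_ms), class = "cm_protocol")
}

#' @export
print.cm_protocol <- function(x, ...) {
  cat(sprintf("<cm_protocol> %d condition(s), window %g s, dt %g ms\n",
              length(x$conditions), x$window_ms / 1000, x$dt_out_ms))
  for (cnd in x$conditions) {
    cat(sprintf("  - %-28s Ca_o %.2g mM, %s%s, %.0f s\n", cnd$label,
                cnd$mil$ca_o,
                if (is.null(cnd$pacing_hz)) "spontaneous"
                else sprintf("%g Hz", cnd$pacing_hz),
                if (length(cnd$blocks))
                  paste0(", block ", paste(names(cnd$blocks),
                         sprintf("%.0f%%", 100 * unclass(cnd$blocks)),
                         collapse = " ")) else "",
                cnd$duration_ms / 1000))
  }
  invisible(x)
}

#' Run a protocol with state carry-over
#'
#' Simulates the conditions sequentially; each condition starts from the
#' final state of the previous one (all state variables carried over, only
#' the external parameters switch). The recorded segment of each condition
#' is its trailing steady-state window, re-zeroed and sampled at the
#' protocol's output step. If any condition fails to integrate the whole
#' trace set is flagged failed.
#'
#' @param mult a [conductance_set()].
#' @param prot a [protocol()].
#' @param x0 starting state (typically [initial_state()]).
#' @param condition_duration_ms optional override of every condition's
#'   duration (used for reduced-cost calibration runs).
#' @return an object of class `cm_trace_set`.
#' @export
run_protocol <- function(mult, prot, x0 = initial_state(),
                         condition_duration_ms = NULL) {
  stopifnot(inherits(prot, "cm_protocol"))
  mult <- as_conductance_set(mult)
  segs <- vector("list", length(prot$conditions))
  state <- x0
  failed <- FALSE
  for (i in seq_along(prot$conditions)) {
    cnd <- prot$conditions[[i]]
    dur <- if (is.null(condition_duration_ms)) cnd$duration_ms else
      max(condition_duration_ms, prot$window_ms)
    tr <- simulate_cell(mult, mil = cnd$mil, blocks = cnd$blocks,
                        stim = cnd$stim, duration_ms = dur, x0 = state,
                        dt_out_ms = prot$dt_out_ms,
                        record_from_ms = dur - prot$window_ms)
    if (tr$failed) { failed <- TRUE; segs[[i]] <- tr; break }
    state <- tr$final_state
    tr <- rezero_trace(tr)
    tr$label <- cnd$label
    segs[[i]] <- tr
  }
  new_trace_set(segments = segs[!vapply(segs, is.null, TRUE)],
                normalized = FALSE, truth = mult, prot = prot,
                failed = failed, final_state = if (failed) NULL else state)
}

new_trace_set <- function(segments, normalized, truth = NULL, prot = NULL,
                          failed = FALSE, final_state = NULL) {
  structure(list(segments = segments, normalized = normalized,
                 truth = truth, protocol = prot, failed = failed,
                 final_state = final_state), class = "cm_trace_set")
}

#' @export
print.cm_trace_set <- function(x, ...) {
  cat(sprintf("<cm_trace_set> %d segment(s)%s%s\n", length(x$segments),
              if (isTRUE(x$normalized)) ", normalized" else "",
              if (isTRUE(x$failed)) ", FAILED" else ""))
  invisible(x)
}

rezero_trace <- function(trace) {
  if (length(trace$time_ms)) trace$time_ms <- trace$time_ms - trace$time_ms[1]
  trace
}

#' Extract the trailing window of a trace
#'
#' @param trace a `cm_trace`.
#' @param window_ms window length (ms); must not exceed the trace span.
#' @return a `cm_trace` covering the final window, time re-zeroed.
#' @export
extract_window <- function(trace, window_ms) {
  stopifnot(inherits(trace, "cm_trace"), !trace$failed)
  span <- trace$time_ms[length(trace$time_ms)] - trace$time_ms[1]
  if (window_ms > span + 1e-9) {
    stop("trace (", span, " ms) is shorter than the requested window")
  }
  t_end <- trace$time_ms[length(trace$time_ms)]
  keep <- trace$time_ms >= t_end - window_ms - 1e-9
  out <- trace
  out$time_ms <- trace$time_ms[keep] - (t_end - window_ms)
  out$V <- trace$V[keep]
  out$Cai <- trace$Cai[keep]
  if (!is.null(trace$currents)) out$currents <- trace$currents[keep, , drop = FALSE]
  out
}

#' Resample a trace onto a uniform grid
#'
#' Linear interpolation onto a uniform grid with step `dt_ms` covering the
#' original span.
#'
#' @param trace a `cm_trace`.
#' @param dt_ms new sampling step (ms).
#' @return a `cm_trace` on the new grid.
#' @export
resample_uniform <- function(trace, dt_ms) {
  stopifnot(inherits(trace, "cm_trace"), !trace$failed, dt_ms > 0)
  tt <- trace$time_ms
  if (is.unsorted(tt, strictly = TRUE)) stop("trace time grid must be strictly increasing")
  grid <- seq(tt[1], tt[length(tt)], by = dt_ms)
  out <- trace
  out$time_ms <- grid
  out$V <- approx(tt, trace$V, xout = grid)$y
  out$Cai <- approx(tt, trace$Cai, xout = grid)$y
  out$dt_out_ms <- dt_ms
  out$currents <- NULL
  out
}

.normalize01 <- function(x, lo = min(x), hi = max(x)) {
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < .Machine$double.eps * 100) {
    stop("cannot normalize a constant segment (non-beating recording?)")
  }
  (x - lo) / (hi - lo)
}

#' Min-max normalize traces (fluorescence surrogate)
#'
#' Scales each signal to span \[0, 1\], emulating relative fluorescence
#' recordings that carry no absolute voltage/calcium scale. `per-segment`
#' normalizes each condition's V and Ca independently (each recording
#' treated as an independent acquisition); `global` uses one min/max per
#' signal across all segments.
#'
#' @param ts a `cm_trace_set` (or a single `cm_trace`).
#' @param mode `"per-segment"` or `"global"`.
#' @return the normalized object with its normalization flag set.
#' @export
normalize_traces <- function(ts, mode = c("per-segment", "global")) {
  mode <- match.arg(mode)
  if (inherits(ts, "cm_trace")) {
    ts$V <- .normalize01(ts$V)
    ts$Cai <- .normalize01(ts$Cai)
    ts$normalized <- TRUE
    return(ts)
  }
  stopifnot(inherits(ts, "cm_trace_set"))
  if (ts$failed) stop("cannot normalize a failed trace set")
  if (mode == "per-segment") {
    ts$segments <- lapply(ts$segments, function(tr) {
      tr$V <- .normalize01(tr$V)
      tr$Cai <- .normalize01(tr$Cai)
      tr$normalized <- TRUE
      tr
    })
  } else {
    loV <- min(vapply(ts$segments, function(tr) min(tr$V), 0))
    hiV <- max(vapply(ts$segments, function(tr) max(tr$V), 0))
    loC <- min(vapply(ts$segments, function(tr) min(tr$Cai), 0))
    hiC <- max(vapply(ts$segments, function(tr) max(tr$Cai), 0))
    ts$segments <- lapply(ts$segments, function(tr) {
      tr$V <- .normalize01(tr$V, loV, hiV)
      tr$Cai <- .normalize01(tr$Cai, loC, hiC)
      tr$normalized <- TRUE
      tr
    })
  }
  ts$normalized <- TRUE
  ts
}

#' Canonical condition library
#'
#' A reconstruction of the in-silico dataset's 19 experimental conditions:
#' hypo- to hyper-calcemic buffer (1.0 / 1.8 / 2.5 mM Ca), pacing from 1
#' to 2 Hz, 25% and 50% L-type calcium channel block, and mixtures.
#' Condition 19 is the physiological, unperturbed baseline (1.8 mM Ca,
#' spontaneous) used for steady-state derivation and population filtering.
#'
#' @param duration_ms per-condition duration (ms).
#' @return a named list of 19 [condition()] objects.
#' @export
condition_library <- function(duration_ms = 300000) {
  cnd <- function(label, ...) condition(label, ..., duration_ms = duration_ms)
  list(
    c01 = cnd("hypoCa_spont",        ca_o = 1.0),
    c02 = cnd("hyperCa_spont",       ca_o = 2.5),
    c03 = cnd("pace1.0",             pacing_hz = 1.0),
    c04 = cnd("pace1.25",            pacing_hz = 1.25),
    c05 = cnd("pace1.5",             pacing_hz = 1.5),
    c06 = cnd("pace2.0",             pacing_hz = 2.0),
    c07 = cnd("ical25_spont",        blocks = block_map(I_CaL = 0.25)),
    c08 = cnd("ical50_spont",        blocks = block_map(I_CaL = 0.50)),
    c09 = cnd("hypoCa_pace1.0",      ca_o = 1.0, pacing_hz = 1.0),
    c10 = cnd("hypoCa_pace2.0",      ca_o = 1.0, pacing_hz = 2.0),
    c11 = cnd("hyperCa_pace1.0",     ca_o = 2.5, pacing_hz = 1.0),
    c12 = cnd("hyperCa_pace1.25",    ca_o = 2.5, pacing_hz = 1.25),
    c13 = cnd("pace1.25_ical25",     pacing_hz = 1.25, blocks = block_map(I_CaL = 0.25)),
    c14 = cnd("pace1.0_ical25",      pacing_hz = 1.0, blocks = block_map(I_CaL = 0.25)),
    c15 = cnd("pace1.5_ical50",      pacing_hz = 1.5, blocks = block_map(I_CaL = 0.50)),
    c16 = cnd("hypoCa_ical25_spont", ca_o = 1.0, blocks = block_map(I_CaL = 0.25)),
    c17 = cnd("hyperCa_ical25_spont", ca_o = 2.5, blocks = block_map(I_CaL = 0.25)),
    c18 = cnd("hypoCa_pace1.25",     ca_o = 1.0, pacing_hz = 1.25),
    c19 = cnd("baseline_spont")
  )
}

#' The optimized 3-condition calibration protocol
#'
#' (1) hypo-calcemic buffer (1.0 mM Ca), spontaneous; (2) physiological
#' buffer (1.8 mM Ca), spontaneous; (3) physiological buffer with 1.25 Hz
#' pacing and 25% I_CaL block. State is carried over between conditions.
#'
#' @param duration_ms per-condition duration (ms).
#' @param window_ms recorded window (ms).
#' @param dt_out_ms output step (ms).
#' @return a `cm_protocol`.
#' @export
optimized_protocol <- function(duration_ms = 300000, window_ms = 5000,
                               dt_out_ms = 0.1) {
  protocol(list(
    condition("hypoCa_spont", ca_o = 1.0, duration_ms = duration_ms),
    condition("baseline_spont", duration_ms = duration_ms),
    condition("pace1.25_ical25", pacing_hz = 1.25,
              blocks = block_map(I_CaL = 0.25), duration_ms = duration_ms)
  ), window_ms = window_ms, dt_out_ms = dt_out_ms)
}

#' Baseline single-condition protocol
#'
#' Physiological, unperturbed conditions (1.8 mM Ca, spontaneous).
#' @inheritParams optimized_protocol
#' @return a `cm_protocol`.
#' @export
baseline_protocol <- function(duration_ms = 300000, window_ms = 5000,
                              dt_out_ms = 0.1) {
  protocol(list(condition("baseline_spont", duration_ms = duration_ms)),
           window_ms = window_ms, dt_out_ms = dt_out_ms)
}

#' Read a protocol from a YAML declaration
#'
#' Expected layout: a top-level `protocol:` list of conditions with keys
#' `label`, `ca_o`, `na_o`, `k_o`, `pacing_hz` (null for spontaneous),
#' `blocks` (map current -> fraction), `duration_s`; optional top-level
#' `window_s` and `dt_out_ms`.
#'
#' @param path YAML file path.
#' @return a `cm_protocol`.
#' @export
protocol_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$protocol))
  conds <- lapply(y$protocol, function(p) {
    condition(
      label = p$label %||% "",
      ca_o = p$ca_o %||% 1.8, na_o = p$na_o %||% 151, k_o = p$k_o %||% 5.4,
      pacing_hz = p$pacing_hz,
      blocks = if (length(p$blocks)) do.call(block_map, p$blocks),
      duration_ms = 1000 * (p$duration_s %||% 300)
    )
  })
  protocol(conds, window_ms = 1000 * (y$window_s %||% 5),
           dt_out_ms = y$dt_out_ms %||% 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
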