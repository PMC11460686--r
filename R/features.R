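#' Arrhythmia classifier thresholds
#'
#' Detection rules for the arrhythmia-dynamics labels. The label set
#' follows the arrhythmia dynamics considered for the block-tolerance
#' threshold (afterdepolarizations, alternans, beating cessation,
#' tachycardia, and an irregular-rhythm surrogate); the numeric detection
#' thresholds are package choices, kept in one place so their influence
#' can be reported.
#'
#' @param upstroke_frac beat detection: fraction of the window-maximum
#'   smoothed dV/dt that defines an upstroke.
#' @param lockout_ms refractory lockout between detected upstrokes (ms).
#' @param min_beats_cessation fewer detected beats than this is cessation.
#' @param cessation_amp_frac cessation also when all beat amplitudes fall
#'   below this fraction of the baseline amplitude (when known).
#' @param ead_frac afterdepolarization: re-depolarization of at least this
#'   fraction of the beat amplitude between peak and next upstroke.
#' @param alternans_frac alternans: >= `alternans_beats` consecutive beats
#'   with alternating-sign APD90 differences, each larger than this
#'   fraction of the mean APD90.
#' @param alternans_beats minimum consecutive beats for alternans.
#' @param tachy_hz absolute tachycardia bound (Hz); the effective rule is
#'   rate > max(`tachy_hz`, `tachy_rel` x baseline rate).
#' @param tachy_rel relative tachycardia factor.
#' @param irregular_cv irregular rhythm: coefficient of variation of
#'   inter-beat intervals above this value.
#' @return a list of thresholds.
#' @export
arrhythmia_config <- function(upstroke_frac = 0.10, lockout_ms = 200,
                              min_beats_cessation = 2,
                              cessation_amp_frac = 0.10,
                              ead_frac = 0.05, alternans_frac = 0.05,
                              alternans_beats = 4, tachy_hz = 2,
                              tachy_rel = 2, irregular_cv = 0.2) {
  as.list(environment())
}

ARRHYTHMIA_LABELS <- c("none", "afterdepolarization", "alternans",
                       "cessation", "tachycardia", "irregular")

#' Detect beats in a trace
#'
#' Upstrokes are located where the smoothed first derivative exceeds a
#' fraction of its window maximum, with a refractory lockout. The same
#' rule applies to raw (mV) and normalized traces. For each beat the peak,
#' the preceding diastolic level (minimum since the previous upstroke),
#' amplitude, and (optionally) APD50/APD90 are tabulated.
#'
#' @param trace a `cm_trace`.
#' @param signal `"V"` or `"Cai"`.
#' @param cfg an [arrhythmia_config()] (supplies the upstroke fraction and
#'   lockout).
#' @param apd if `TRUE`, add `apd50` / `apd90` columns.
#' @param smooth_ms derivative smoothing window (ms).
#' @param min_range traces whose total excursion is below this value are
#'   treated as quiescent (no beats).
#' @return a data.frame (class `beat_table`) with one row per beat:
#'   `upstroke_ms`, `peak_ms`, `peak`, `diastolic`, `amplitude`, and APD
#'   columns when requested. Zero rows when no beats are found.
#' @export
detect_beats <- function(trace, signal = c("V", "Cai"),
                         cfg = arrhythmia_config(), apd = TRUE,
                         smooth_ms = 1, min_range = 1e-3) {
  signal <- match.arg(signal)
  empty <- data.frame(upstroke_ms = numeric(0), peak_ms = numeric(0),
                      peak = numeric(0), diastolic = numeric(0),
                      amplitude = numeric(0))
  if (apd) { empty$apd50 <- numeric(0); empty$apd90 <- numeric(0) }
  class(empty) <- c("beat_table", "data.frame")
  if (trace$failed || length(trace$time_ms) < 5) return(empty)

  x <- trace[[signal]]
  tt <- trace$time_ms
  dt <- trace$dt_out_ms
  if (!is.finite(dt) || dt <= 0) dt <- median(diff(tt))
  if (diff(range(x)) < min_range) return(empty)

  dv <- c(diff(x) / dt, 0)
  k <- max(1L, round(smooth_ms / dt))
  if (k > 1) {
    dv <- as.numeric(stats::filter(dv, rep(1 / k, k), sides = 2))
    dv[is.na(dv)] <- 0
  }
  thr <- cfg$upstroke_frac * max(dv)
  if (thr <= 0) return(empty)
  above <- dv >= thr
  cand <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(cand)) return(empty)
  lock <- cfg$lockout_ms
  ups <- cand[1]
  for (i in cand[-1]) {
    if (tt[i] - tt[ups[length(ups)]] >= lock) ups <- c(ups, i)
  }

  n <- length(ups)
  res <- vector("list", n)
  for (b in seq_len(n)) {
    i0 <- ups[b]
    i1 <- if (b < n) ups[b + 1] - 1L else length(x)
    ipk <- which.max(x[i0:i1]) + i0 - 1L
    idia0 <- if (b > 1) ups[b - 1] else 1L
    dia <- min(x[idia0:i0])
    res[[b]] <- data.frame(upstroke_ms = tt[i0], peak_ms = tt[ipk],
                           peak = x[ipk], diastolic = dia,
                           amplitude = x[ipk] - dia,
                           i_up = i0, i_peak = ipk, i_end = i1)
  }
  bt <- do.call(rbind, res)
  ## drop sub-threshold "beats" (noise): amplitude under 30% of the global
  ## excursion never corresponds to a full AP/CaT
  bt <- bt[bt$amplitude >= 0.3 * diff(range(x)), , drop = FALSE]
  if (apd && nrow(bt)) {
    bt$apd50 <- apd_from_table(trace, bt, 0.50, signal)
    bt$apd90 <- apd_from_table(trace, bt, 0.90, signal)
  }
  rownames(bt) <- NULL
  class(bt) <- c("beat_table", "data.frame")
  bt
}

## duration from upstroke to f-fraction repolarization, linear interpolation
apd_from_table <- function(trace, bt, fraction, signal = "V") {
  stopifnot(fraction > 0, fraction < 1)
  x <- trace[[signal]]
  tt <- trace$time_ms
  out <- rep(NA_real_, nrow(bt))
  for (b in seq_len(nrow(bt))) {
    ipk <- bt$i_peak[b]; iend <- bt$i_end[b]
    level <- bt$peak[b] - fraction * bt$amplitude[b]
    seg <- x[ipk:iend]
    idx <- which(seg <= level)[1]
    if (is.na(idx)) next                       # non-repolarizing beat
    i <- ipk + idx - 1L
    t_cross <- if (idx == 1) tt[i] else {
      ## interpolate between the sample above and the first at/below level
      t0 <- tt[i - 1]; t1 <- tt[i]
      v0 <- x[i - 1]; v1 <- x[i]
      t0 + (v0 - level) / (v0 - v1) * (t1 - t0)
    }
    out[b] <- t_cross - bt$upstroke_ms[b]
  }
  out
}

#' Action-potential duration at a repolarization fraction
#'
#' Time from the upstroke to the point where the signal has repolarized
#' `fraction` of the beat amplitude (APD90: `fraction = 0.90`), with
#' linear interpolation between samples. Beats that never repolarize to
#' the level report `NA`.
#'
#' @param trace a `cm_trace`.
#' @param beats a [detect_beats()] table (computed if missing).
#' @param fraction repolarization fraction in (0, 1).
#' @param signal `"V"` or `"Cai"`.
#' @return numeric vector, one duration (ms) per beat.
#' @export
apd <- function(trace, fraction, beats = NULL, signal = "V") {
  if (is.null(beats)) beats <- detect_beats(trace, signal, apd = FALSE)
  if (!nrow(beats)) return(numeric(0))
  apd_from_table(trace, beats, fraction, signal)
}

#' Beat amplitudes of the voltage and calcium signals
#'
#' Peak minus preceding diastolic level, per beat and per signal. Beats
#' are detected on the voltage trace; calcium amplitudes are measured
#' between consecutive voltage upstrokes.
#'
#' @param trace a `cm_trace`.
#' @param cfg an [arrhythmia_config()].
#' @return data.frame with `ap_amplitude` and `cat_amplitude` per beat.
#' @export
beat_amplitudes <- function(trace, cfg = arrhythmia_config()) {
  bt <- detect_beats(trace, "V", cfg, apd = FALSE)
  if (!nrow(bt)) {
    return(data.frame(ap_amplitude = numeric(0), cat_amplitude = numeric(0)))
  }
  ca <- trace$Cai
  cat_amp <- vapply(seq_len(nrow(bt)), function(b) {
    i0 <- bt$i_up[b]; i1 <- bt$i_end[b]
    idia0 <- if (b > 1) bt$i_up[b - 1] else 1L
    max(ca[i0:i1]) - min(ca[idia0:i0])
  }, 0)
  data.frame(ap_amplitude = bt$amplitude, cat_amplitude = cat_amp)
}

#' Spontaneous beating rate
#'
#' Beat count divided by the analyzed duration; `NA` for fewer than two
#' detected beats (quiescent or single-event traces).
#'
#' @param trace an un-paced `cm_trace`.
#' @param cfg an [arrhythmia_config()].
#' @return rate in Hz, or `NA_real_`.
#' @export
spontaneous_rate <- function(trace, cfg = arrhythmia_config()) {
  bt <- detect_beats(trace, "V", cfg, apd = FALSE)
  if (nrow(bt) < 2) return(NA_real_)
  dur_s <- (trace$time_ms[length(trace$time_ms)] - trace$time_ms[1]) / 1000
  nrow(bt) / dur_s
}

#' Classify arrhythmia dynamics of a steady-state window
#'
#' Applies the detection rules of [arrhythmia_config()] in the fixed
#' priority order cessation > afterdepolarization > alternans >
#' tachycardia > irregular > none. The classifier is deterministic given
#' the trace and thresholds.
#'
#' An afterdepolarization is a transient secondary depolarization between
#' a beat's peak and the next upstroke: the signal rises at least
#' `ead_frac` of the beat amplitude above the running post-peak minimum
#' and falls again by at least half of that rise, which separates genuine
#' early/delayed afterdepolarizations from the smooth diastolic
#' depolarization of a spontaneous cell.
#'
#' @param trace a `cm_trace` (steady-state window, e.g. the last 5-30 s).
#' @param baseline_rate optional reference spontaneous rate (Hz) for the
#'   tachycardia rule.
#' @param baseline_amplitude optional reference AP amplitude for the
#'   cessation amplitude rule.
#' @param cfg an [arrhythmia_config()].
#' @return a single label (see `ARRHYTHMIA_LABELS`).
#' @export
classify_arrhythmia <- function(trace, baseline_rate = NULL,
                                baseline_amplitude = NULL,
                                cfg = arrhythmia_config()) {
  if (trace$failed) return("cessation")
  bt <- detect_beats(trace, "V", cfg, apd = TRUE)

  ## cessation
  if (nrow(bt) < cfg$min_beats_cessation) return("cessation")
  if (!is.null(baseline_amplitude) &&
      all(bt$amplitude < cfg$cessation_amp_frac * baseline_amplitude)) {
    return("cessation")
  }

  ## afterdepolarization (EAD/DAD combined)
  if (.has_afterdepolarization(trace, bt, cfg)) return("afterdepolarization")

  ## alternans on APD90
  if (.has_alternans(bt$apd90, cfg)) return("alternans")

  ## tachycardia
  dur_s <- (trace$time_ms[length(trace$time_ms)] - trace$time_ms[1]) / 1000
  rate <- nrow(bt) / dur_s
  tachy_bound <- max(cfg$tachy_hz,
                     if (is.null(baseline_rate) || is.na(baseline_rate)) 0
                     else cfg$tachy_rel * baseline_rate)
  if (rate > tachy_bound) return("tachycardia")

  ## irregular rhythm (single-cell surrogate for torsadogenic dynamics)
  if (nrow(bt) >= 3) {
    ibi <- diff(bt$upstroke_ms)
    if (sd(ibi) / mean(ibi) > cfg$irregular_cv) return("irregular")
  }
  "none"
}

.has_afterdepolarization <- function(trace, bt, cfg) {
  x <- trace[[ "V" ]]
  for (b in seq_len(nrow(bt))) {
    i0 <- bt$i_peak[b]; i1 <- bt$i_end[b]
    if (i1 - i0 < 3) next
    seg <- x[i0:i1]
    runmin <- cummin(seg)
    rise <- seg - runmin
    need <- cfg$ead_frac * bt$amplitude[b]
    cand <- which(rise >= need)
    if (!length(cand)) next
    ## require the bump to come back down by half its rise before the
    ## segment ends (otherwise it is the next upstroke / DD foot)
    for (i in cand) {
      peak_rise <- rise[i]
      later <- seg[i:length(seg)]
      if (any(later <= seg[i] - peak_rise / 2)) return(TRUE)
    }
  }
  FALSE
}

.has_alternans <- function(apd90, cfg) {
  a <- apd90[!is.na(apd90)]
  if (length(a) < cfg$alternans_beats) return(FALSE)
  d <- diff(a)
  lim <- cfg$alternans_frac * mean(a)
  big <- abs(d) > lim
  altern <- c(TRUE, diff(sign(d)) != 0)   # sign alternates vs previous diff
  run <- 0
  for (i in seq_along(d)) {
    run <- if (big[i] && (run == 0 || altern[i])) run + 1 else if (big[i]) 1 else 0
    if (run >= cfg$alternans_beats - 1) return(TRUE)
  }
  FALSE
}
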