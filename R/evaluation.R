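#' Per-parameter calibration error
#'
#' `|log2(fitted / true)|` per parameter, plus the mean over all fitted
#' parameters.
#'
#' @param fitted,truth [conductance_set()]s (or named positive vectors).
#' @param free optional subset of parameter names to score.
#' @return list with `per_parameter` (named vector) and `mean`.
#' @export
calibration_error <- function(fitted, truth, free = NULL) {
  fitted <- unclass(as_conductance_set(fitted))
  truth <- unclass(as_conductance_set(truth))
  if (any(fitted <= 0) || any(truth <= 0)) {
    stop("calibration error requires strictly positive multipliers")
  }
  err <- abs(log2(fitted / truth))
  if (!is.null(free)) err <- err[free]
  list(per_parameter = err, mean = mean(err))
}

#' Per-parameter calibration spread
#'
#' Sample standard deviation (n - 1) across GA runs of
#' `log2(fitted / true)`, per parameter; undefined (error) for fewer than
#' two runs. The spread is invariant to the truth value, which only
#' shifts every run's log-ratio equally.
#'
#' @param ens a `calibration_ensemble` (or runs x parameters multiplier
#'   matrix).
#' @param truth the ground-truth [conductance_set()].
#' @param free optional subset of parameter names.
#' @return list with `per_parameter` (named vector) and `mean`.
#' @export
calibration_spread <- function(ens, truth, free = NULL) {
  M <- if (inherits(ens, "calibration_ensemble")) ensemble_multipliers(ens) else as.matrix(ens)
  if (nrow(M) < 2) stop("calibration spread is undefined for fewer than 2 runs")
  truth <- unclass(as_conductance_set(truth))
  L <- sweep(log2(M), 2, log2(truth))
  spr <- apply(L, 2, sd)
  names(spr) <- colnames(M)
  if (!is.null(free)) spr <- spr[free]
  list(per_parameter = spr, mean = mean(spr))
}

#' Simulate a fitted model's response to an unseen perturbation
#'
#' Runs the fitted multipliers under a perturbation protocol - by default
#' 30% block of the rapid delayed rectifier current under the baseline
#' spontaneous condition - to evaluate predictions on conditions that were
#' not part of calibration.
#'
#' @param fitted a [conductance_set()].
#' @param perturbation a [block_map()] (default `I_Kr` 30%).
#' @param prot protocol to run under the perturbation (default baseline
#'   single condition).
#' @param x0 starting state.
#' @param condition_duration_ms optional duration override.
#' @return a `cm_trace_set` (failed flag propagated).
#' @export
predict_response <- function(fitted, perturbation = block_map(I_Kr = 0.30),
                             prot = baseline_protocol(), x0 = initial_state(),
                             condition_duration_ms = NULL) {
  blocked <- apply_block(as_conductance_set(fitted), perturbation)
  run_protocol(blocked, prot, x0 = x0,
               condition_duration_ms = condition_duration_ms)
}

#' Scores of predicted versus true responses
#'
#' Computes (i) the summed trace MSE (same definition as the calibration
#' fitness), (ii) the percent error of the amplitude-normalized APD90
#' under the perturbation, and (iii) when baseline trace sets are given,
#' the percent error of the amplitude-normalized change in APD90
#' (perturbed minus baseline). APD90 values are normalized to the
#' corresponding AP amplitudes before percent errors are computed.
#' Missing beats yield `NA` scores rather than errors.
#'
#' @param predicted,truth `cm_trace_set`s under the perturbation.
#' @param baseline_predicted,baseline_truth optional `cm_trace_set`s under
#'   the unperturbed condition (for the delta-APD90 score).
#' @param alignment alignment used for the MSE component.
#' @return list with `mse`, `apd90_pct_error`, `delta_apd90_pct_error`.
#' @export
prediction_scores <- function(predicted, truth, baseline_predicted = NULL,
                              baseline_truth = NULL,
                              alignment = "first-upstroke") {
  mse <- trace_fitness(predicted, truth, alignment = alignment)

  apd_over_amp <- function(ts) {
    vals <- vapply(ts$segments, function(tr) {
      bt <- detect_beats(tr, "V")
      if (!nrow(bt) || all(is.na(bt$apd90))) return(NA_real_)
      mean(bt$apd90 / bt$amplitude, na.rm = TRUE)
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  p <- apd_over_amp(predicted)
  t <- apd_over_amp(truth)
  apd_err <- if (is.na(p) || is.na(t) || t == 0) NA_real_ else 100 * (p - t) / t

  d_err <- NA_real_
  if (!is.null(baseline_predicted) && !is.null(baseline_truth)) {
    pb <- apd_over_amp(baseline_predicted)
    tb <- apd_over_amp(baseline_truth)
    dp <- p - pb; dt_ <- t - tb
    d_err <- if (anyNA(c(dp, dt_)) || dt_ == 0) NA_real_ else 100 * (dp - dt_) / dt_
  }
  list(mse = mse, apd90_pct_error = apd_err, delta_apd90_pct_error = d_err)
}

#' Classify arrhythmia under one I_Kr block level
#'
#' @keywords internal
.block_level_label <- function(mult, level_pct, pre_ms, observe_ms, x0,
                               mil, cfg, baseline_rate, baseline_amplitude,
                               dt_out_ms = 1) {
  tr <- simulate_cell(mult, mil = mil,
                      blocks = block_map(I_Kr = level_pct / 100),
                      duration_ms = pre_ms + observe_ms, x0 = x0,
                      dt_out_ms = dt_out_ms, record_from_ms = pre_ms)
  classify_arrhythmia(tr, baseline_rate = baseline_rate,
                      baseline_amplitude = baseline_amplitude, cfg = cfg)
}

#' I_Kr block tolerance threshold
#'
#' Scans increasing I_Kr block levels under the baseline spontaneous
#' condition (each level pre-equilibrated from the same starting state,
#' not carried over between levels) and returns the lowest level whose
#' steady-state window shows any arrhythmia dynamics. Cells arrhythmia-free
#' up to 100% block are reported as tolerant (threshold `Inf`).
#'
#' @param mult a [conductance_set()].
#' @param step_pct scan granularity in percent (default 1).
#' @param pre_ms per-level pre-equilibration (default 5 min).
#' @param observe_ms classified window at the end of each level (default
#'   30 s).
#' @param x0 starting state (the cell's baseline steady state).
#' @param mil extracellular milieu.
#' @param cfg an [arrhythmia_config()].
#' @param exhaustive if `TRUE`, evaluate every level instead of stopping
#'   at the first arrhythmic one (brute-force reference scan).
#' @return list with `threshold_pct` (first arrhythmic level, or `Inf` if
#'   tolerant), `label`, `step_pct`, and (if exhaustive) `labels` for all
#'   levels.
#' @export
ikr_block_threshold <- function(mult, step_pct = 1, pre_ms = 300000,
                                observe_ms = 30000, x0 = initial_state(),
                                mil = milieu(), cfg = arrhythmia_config(),
                                exhaustive = FALSE) {
  stopifnot(step_pct > 0, step_pct <= 100)
  levels <- seq(step_pct, 100, by = step_pct)

  ## reference run (no block) for the tachycardia/cessation baselines
  tr0 <- simulate_cell(mult, mil = mil, duration_ms = pre_ms + observe_ms,
                       x0 = x0, dt_out_ms = 1, record_from_ms = pre_ms)
  base_rate <- if (tr0$failed) NA_real_ else spontaneous_rate(tr0, cfg)
  base_amp <- if (tr0$failed) NULL else {
    ba <- beat_amplitudes(tr0, cfg)
    if (nrow(ba)) mean(ba$ap_amplitude) else NULL
  }

  labels <- character(0)
  thr <- Inf; thr_label <- "tolerant"
  for (lv in levels) {
    lab <- .block_level_label(mult, lv, pre_ms, observe_ms, x0, mil, cfg,
                              base_rate, base_amp)
    labels <- c(labels, lab)
    if (lab != "none" && !is.finite(thr)) {
      thr <- lv; thr_label <- lab
      if (!exhaustive) break
    }
  }
  out <- list(threshold_pct = thr, label = thr_label, step_pct = step_pct,
              baseline_rate = base_rate)
  if (exhaustive) {
    out$labels <- setNames(labels, levels)
    first <- which(labels != "none")[1]
    out$threshold_pct <- if (is.na(first)) Inf else levels[first]
    out$label <- if (is.na(first)) "tolerant" else labels[first]
  }
  out
}

#' Phenotype outputs of a population
#'
#' Simulates each cell under the baseline milieu and extracts mean APD90,
#' mean AP and CaT amplitudes, and spontaneous rate from the trailing
#' window - the phenotype table used for sensitivity regression.
#'
#' Duration-type phenotypes of spontaneously beating cells confound a
#' parameter's direct effect on repolarization with its effect on beating
#' rate; phenotyping under overdrive pacing (e.g. `pacing_hz = 1.5`,
#' above the population's spontaneous rates) removes the rate confound
#' and is the recommended setting for sensitivity analysis.
#'
#' @param cells list of conductance sets.
#' @param x0 shared starting state.
#' @param pre_ms pre-equilibration duration (ms).
#' @param window_ms analyzed window (ms).
#' @param dt_out_ms sampling step (ms).
#' @param pacing_hz optional pacing frequency (Hz); `NULL` for
#'   spontaneous activity.
#' @return data.frame with one row per cell (`NA`s for failed or
#'   non-beating cells): `apd90`, `ap_amplitude`, `cat_amplitude`,
#'   `rate_hz`.
#' @export
population_phenotypes <- function(cells, x0 = initial_state(),
                                  pre_ms = 60000, window_ms = 10000,
                                  dt_out_ms = 0.5, pacing_hz = NULL) {
  stim <- if (is.null(pacing_hz)) NULL else stimulus(1000 / pacing_hz)
  rows <- lapply(cells, function(m) {
    tr <- simulate_cell(m, stim = stim, duration_ms = pre_ms + window_ms,
                        x0 = x0, dt_out_ms = dt_out_ms,
                        record_from_ms = pre_ms)
    if (tr$failed) {
      return(data.frame(apd90 = NA_real_, ap_amplitude = NA_real_,
                        cat_amplitude = NA_real_, rate_hz = NA_real_))
    }
    bt <- detect_beats(tr, "V")
    amps <- beat_amplitudes(tr)
    data.frame(
      apd90 = if (nrow(bt)) mean(bt$apd90, na.rm = TRUE) else NA_real_,
      ap_amplitude = if (nrow(amps)) mean(amps$ap_amplitude) else NA_real_,
      cat_amplitude = if (nrow(amps)) mean(amps$cat_amplitude) else NA_real_,
      rate_hz = spontaneous_rate(tr)
    )
  })
  do.call(rbind, rows)
}

#' Multivariable regression sensitivity analysis
#'
#' Ordinary least squares of z-scored outputs on z-scored log2
#' multipliers: one coefficient per parameter per output, representing the
#' magnitude and direction of that parameter's effect on the phenotype.
#' Outputs that are strictly positive are log-transformed before
#' z-scoring. Rows with missing outputs are dropped; a rank-deficient
#' design is an error.
#'
#' @param cells list of conductance sets (the population).
#' @param outputs data.frame of phenotype outputs, one row per cell.
#' @param top_n size of the top/bottom coefficient-magnitude groups.
#' @return an object of class `sensitivity_result`: `coefficients`
#'   (parameters x outputs matrix), `top` and `bottom` (per-output
#'   parameter names ranked by |coefficient|), `n_used`.
#' @export
sensitivity_regression <- function(cells, outputs, top_n = 4) {
  X <- log2(do.call(rbind, lapply(cells, unclass)))
  stopifnot(nrow(X) == nrow(outputs))
  keep <- stats::complete.cases(outputs)
  X <- X[keep, , drop = FALSE]
  Y <- outputs[keep, , drop = FALSE]
  if (nrow(X) <= ncol(X) + 1) stop("population too small for regression")
  Xz <- scale(X)
  if (any(!is.finite(Xz))) stop("degenerate parameter design (zero variance)")
  if (qr(Xz)$rank < ncol(Xz)) stop("rank-deficient parameter design")
  coefs <- sapply(names(Y), function(nm) {
    y <- Y[[nm]]
    if (all(y > 0)) y <- log(y)
    yz <- as.numeric(scale(y))
    stats::lm.fit(cbind(1, Xz), yz)$coefficients[-1]
  })
  rownames(coefs) <- colnames(X)
  ranked <- apply(abs(coefs), 2, function(a) rownames(coefs)[order(-a)])
  structure(list(
    coefficients = coefs,
    top = apply(ranked, 2, function(p) p[seq_len(top_n)], simplify = FALSE),
    bottom = apply(ranked, 2, function(p) rev(p)[seq_len(top_n)], simplify = FALSE),
    n_used = nrow(X)
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d parameters x %d outputs (n = %d)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$n_used))
  print(round(x$coefficients, 3))
  invisible(x)
}
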