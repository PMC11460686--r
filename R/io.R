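#' Read a raw fluorescence recording
#'
#' Delimited text with a time column and an intensity column; the schema
#' maps column names. Non-uniform timestamps are tolerated (traces are
#' resampled during preprocessing). Plate-imager recordings are typically
#' sampled at 125 points per second.
#'
#' @param path file path (CSV or other delimiter).
#' @param schema list with `time` and `value` column names.
#' @param time_unit `"s"` or `"ms"`.
#' @param channel `"voltage-dye"` or `"calcium-dye"`.
#' @param label condition label.
#' @param sep field separator.
#' @return an object of class `raw_recording`: `time_s`, `value`,
#'   `rate_hz` (median sampling rate), `channel`, `label`.
#' @export
read_recording <- function(path, schema = list(time = "time", value = "value"),
                           time_unit = c("s", "ms"),
                           channel = c("voltage-dye", "calcium-dye"),
                           label = "", sep = ",") {
  time_unit <- match.arg(time_unit)
  channel <- match.arg(channel)
  d <- tryCatch(read.csv(path, sep = sep, check.names = FALSE),
                error = function(e) stop("cannot parse '", path, "': ",
                                         conditionMessage(e)))
  for (col in c(schema$time, schema$value)) {
    if (!col %in% names(d)) stop("missing column '", col, "' in ", path)
  }
  tt <- d[[schema$time]]; vv <- d[[schema$value]]
  bad <- which(!is.finite(suppressWarnings(as.numeric(tt))) |
               !is.finite(suppressWarnings(as.numeric(vv))))
  if (length(bad)) {
    stop("non-numeric rows in ", path, " at line(s): ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  }
  if (!length(tt)) stop("no samples in ", path)
  tt <- as.numeric(tt); vv <- as.numeric(vv)
  if (time_unit == "ms") tt <- tt / 1000
  if (is.unsorted(tt, strictly = TRUE)) stop("time stamps must be strictly increasing")
  structure(list(time_s = tt, value = vv,
                 rate_hz = 1 / median(diff(tt)),
                 channel = channel, label = label), class = "raw_recording")
}

#' Write a recording back to CSV (full precision)
#' @param rec a `raw_recording`.
#' @param path file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  d <- data.frame(time = rec$time_s, value = rec$value)
  utils::write.table(d, path, sep = ",", row.names = FALSE, qmethod = "double",
                     col.names = TRUE)
  invisible(path)
}

#' Preprocessing settings for fluorescence recordings
#'
#' @param erosion_window_s baseline-erosion structuring window (s); `NULL`
#'   chooses 1.5 x the median beat interval estimated from the recording,
#'   so the baseline tracks drift but not the AP itself.
#' @param median_window median-filter width in samples (odd).
#' @param dt_out_ms output grid step after resampling (ms).
#' @param normalize min-max normalize to \[0, 1\] at the end.
#' @return a list of settings.
#' @export
preprocess_config <- function(erosion_window_s = NULL, median_window = 5,
                              dt_out_ms = 0.1, normalize = TRUE) {
  stopifnot(median_window %% 2 == 1)
  as.list(environment())
}

## grayscale erosion with a flat structuring element = moving minimum
.moving_min <- function(x, k) {
  n <- length(x)
  k <- min(k, n)
  out <- numeric(n)
  half <- k %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- min(x[lo:hi])
  }
  out
}

## crude beat-interval estimate used only to size the erosion window
.estimate_beat_interval_s <- function(time_s, value) {
  v <- runmed(value, 5)
  thr <- min(v) + 0.5 * diff(range(v))
  above <- v > thr
  ups <- which(above & !c(FALSE, above[-length(above)]))
  if (length(ups) < 3) return(1.0)
  median(diff(time_s[ups]))
}

#' Preprocess a fluorescence recording into a trace signal
#'
#' Deterministic, order-fixed pipeline: (1) baseline-drift estimation by
#' grayscale erosion (moving minimum over a structuring window wider than
#' one beat) and subtraction; (2) median filtering to remove noise;
#' (3) linear resampling onto the pipeline grid; (4) min-max
#' normalization. Requires at least 2 s of data; a signal that is
#' constant after preprocessing is an error (non-beating sample).
#'
#' @param rec a `raw_recording` from [read_recording()].
#' @param cfg a [preprocess_config()].
#' @return a `cm_trace` whose `V` (voltage dye) or `Cai` (calcium dye)
#'   slot holds the processed signal; the other slot mirrors it so that
#'   single-channel traces remain well-formed. The `channel` is kept in
#'   the metadata.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  span_s <- rec$time_s[length(rec$time_s)] - rec$time_s[1]
  if (span_s < 2) stop("recording shorter than 2 s")

  x <- rec$value
  win_s <- cfg$erosion_window_s %||%
    (1.5 * .estimate_beat_interval_s(rec$time_s, x))
  k <- max(3L, round(win_s * rec$rate_hz))
  baseline <- .moving_min(x, k)
  x <- x - baseline

  x <- runmed(x, cfg$median_window)

  tt_ms <- (rec$time_s - rec$time_s[1]) * 1000
  grid <- seq(0, tt_ms[length(tt_ms)], by = cfg$dt_out_ms)
  x <- approx(tt_ms, x, xout = grid)$y

  if (cfg$normalize) x <- .normalize01(x)

  tr <- new_cm_trace(time_ms = grid, V = x, Cai = x,
                     dt_out_ms = cfg$dt_out_ms, final_state = NULL,
                     failed = FALSE, normalized = cfg$normalize,
                     label = rec$label)
  tr$channel <- rec$channel
  tr
}

#' Calibrate the model to in-vitro recordings with a hold-out condition
#'
#' Builds a normalized calibration target from preprocessed voltage- and
#' calcium-dye recordings grouped by condition, calibrates the
#' conductances with repeated GA runs, then predicts the hold-out
#' condition and reports prediction scores. The hold-out condition must
#' not appear in the calibration set.
#'
#' @param recordings named list: for each condition label, a list with
#'   elements `V` and `Cai`, each a preprocessed `cm_trace` (from
#'   [preprocess_recording()]).
#' @param condition_map named list mapping each condition label to a
#'   [condition()] describing how to simulate it.
#' @param holdout label of the hold-out condition.
#' @param cfg a [ga_config()].
#' @param n_runs GA repetitions.
#' @param window_ms,dt_out_ms compared window and grid.
#' @param x0 starting state.
#' @return list with `ensemble` (a `calibration_ensemble`), `holdout`
#'   (label), `prediction` (`cm_trace_set` of the best run under the
#'   hold-out condition), `holdout_target`, and `scores`.
#' @export
run_invitro_calibration <- function(recordings, condition_map, holdout,
                                    cfg = ga_config(), n_runs = 10,
                                    window_ms = 5000, dt_out_ms = 0.1,
                                    x0 = initial_state()) {
  stopifnot(holdout %in% names(condition_map))
  fit_labels <- setdiff(names(condition_map), holdout)
  if (!length(fit_labels)) stop("no calibration conditions besides the hold-out")
  if (holdout %in% fit_labels) stop("hold-out condition present in the calibration set")
  for (lab in names(condition_map)) {
    if (is.null(recordings[[lab]]$V) || is.null(recordings[[lab]]$Cai)) {
      stop("condition '", lab, "' lacks a V or Cai recording")
    }
  }

  make_segment <- function(lab) {
    v <- recordings[[lab]]$V; ca <- recordings[[lab]]$Cai
    grid <- seq(0, window_ms, by = dt_out_ms)
    crop <- function(tr) {
      tr <- extract_window(tr, min(window_ms,
                                   tr$time_ms[length(tr$time_ms)]))
      approx(tr$time_ms, tr$V, xout = grid, rule = 2)$y
    }
    new_cm_trace(time_ms = grid, V = crop(v), Cai = crop(ca),
                 dt_out_ms = dt_out_ms, final_state = NULL, failed = FALSE,
                 normalized = TRUE, label = lab)
  }

  prot_fit <- protocol(lapply(fit_labels, function(l) condition_map[[l]]),
                       window_ms = window_ms, dt_out_ms = dt_out_ms)
  target <- new_trace_set(segments = lapply(fit_labels, make_segment),
                          normalized = TRUE, prot = prot_fit)

  ens <- calibrate_ensemble(target, prot_fit, cfg, n_runs = n_runs, x0 = x0)
  best <- ens$runs[[which.min(vapply(ens$runs, `[[`, 0, "best_fitness"))]]

  prot_holdout <- protocol(list(condition_map[[holdout]]),
                           window_ms = window_ms, dt_out_ms = dt_out_ms)
  pred <- run_protocol(best$best, prot_holdout, x0 = x0,
                       condition_duration_ms = cfg$condition_duration_ms)
  pred_n <- if (pred$failed) pred else normalize_traces(pred)
  holdout_target <- new_trace_set(segments = list(make_segment(holdout)),
                                  normalized = TRUE, prot = prot_holdout)
  scores <- list(
    holdout = holdout,
    mse = if (pred$failed) NA_real_ else
      trace_fitness(pred_n, holdout_target, alignment = cfg$alignment)
  )
  list(ensemble = ens, holdout = holdout, prediction = pred_n,
       holdout_target = holdout_target, scores = scores)
}
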