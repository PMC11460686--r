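#' Draw a population of conductance multiplier sets
#'
#' Each of the 16 multipliers is drawn independently as `exp(z)` (or
#' `2^z`) with `z ~ Normal(0, spread)`, the population-of-models
#' convention: the median multiplier is exactly 1 and `spread` is the
#' standard deviation on the log scale. The dataset default spread is 0.2.
#'
#' @param n number of cells (>= 1).
#' @param spread log-scale standard deviation (>= 0); 0 gives all-ones.
#' @param seed RNG seed for reproducibility.
#' @param log_base `"natural"` (multiplier = exp(z)) or `"log2"`
#'   (multiplier = 2^z).
#' @return a list of `n` [conductance_set()] objects.
#' @export
draw_multipliers <- function(n, spread = 0.2, seed = NULL,
                             log_base = c("natural", "log2")) {
  stopifnot(n >= 1, spread >= 0)
  log_base <- match.arg(log_base)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    z <- rnorm(length(KERNIK_PARAMS), 0, spread)
    m <- if (log_base == "natural") exp(z) else 2^z
    conductance_set(values = setNames(m, KERNIK_PARAMS))
  })
}

#' Spontaneous rates of a population under baseline conditions
#'
#' Simulates each cell under the physiological, unperturbed baseline
#' condition and measures its spontaneous beating rate over the trailing
#' window.
#'
#' @param cells list of conductance sets.
#' @param x0 starting state ([initial_state()] by default).
#' @param pre_ms pre-equilibration duration (ms).
#' @param window_ms rate-measurement window (ms).
#' @param dt_out_ms sampling step for rate measurement (ms).
#' @return numeric vector of rates (Hz), `NA` for quiescent or failed cells.
#' @export
population_rates <- function(cells, x0 = initial_state(), pre_ms = 300000,
                             window_ms = 30000, dt_out_ms = 1) {
  vapply(cells, function(m) {
    tr <- simulate_cell(m, duration_ms = pre_ms, x0 = x0,
                        dt_out_ms = dt_out_ms,
                        record_from_ms = pre_ms - window_ms)
    if (tr$failed) return(NA_real_)
    spontaneous_rate(tr)
  }, 0)
}

#' Filter a population on spontaneous rate
#'
#' Keeps cells whose baseline spontaneous beating rate lies in the closed
#' interval `[f_min, f_max]`; quiescent (NA-rate) cells are excluded.
#'
#' @param cells list of conductance sets.
#' @param rates per-cell rates (Hz) as from [population_rates()].
#' @param f_min,f_max band edges in Hz (default the 0.3-1.0 Hz automaticity
#'   band used to select dataset cells).
#' @return the kept subset of `cells` (with a `rates` attribute).
#' @export
filter_population <- function(cells, rates, f_min = 0.3, f_max = 1.0) {
  stopifnot(length(cells) == length(rates))
  keep <- !is.na(rates) & rates >= f_min & rates <= f_max
  out <- cells[keep]
  attr(out, "rates") <- rates[keep]
  out
}

#' Build the in-silico dataset
#'
#' Simulates every cell under every condition (5 minutes each, from the
#' shared baseline steady state) and stores the trailing 5-second V and Ca
#' windows on the 0.1 ms grid, together with the ground-truth multipliers.
#' Normalized copies (min-max per segment) are derived from the identical
#' simulations. Failed simulations are recorded as failed entries, never
#' dropped silently.
#'
#' @param cells list of conductance sets (e.g. 4 filtered cells).
#' @param conditions named list of [condition()]s (default the 19-condition
#'   library).
#' @param normalized also store normalized copies.
#' @param x0 shared starting state.
#' @param window_ms,dt_out_ms recorded window and step.
#' @return an object of class `insilico_dataset`: `cells` (ground truth),
#'   `traces[[cell]][[condition]]` raw `cm_trace`s, `normalized_traces`
#'   likewise (if requested), `conditions`, and per-entry `failed` flags.
#' @export
build_dataset <- function(cells, conditions = condition_library(),
                          normalized = TRUE, x0 = initial_state(),
                          window_ms = 5000, dt_out_ms = 0.1) {
  stopifnot(length(cells) >= 1, length(conditions) >= 1)
  if (is.null(names(conditions))) {
    names(conditions) <- sprintf("c%02d", seq_along(conditions))
  }
  traces <- list(); ntraces <- list()
  failed <- matrix(FALSE, length(cells), length(conditions),
                   dimnames = list(NULL, names(conditions)))
  for (i in seq_along(cells)) {
    row <- list(); nrow_ <- list()
    for (j in seq_along(conditions)) {
      cnd <- conditions[[j]]
      tr <- simulate_cell(cells[[i]], mil = cnd$mil, blocks = cnd$blocks,
                          stim = cnd$stim, duration_ms = cnd$duration_ms,
                          x0 = x0, dt_out_ms = dt_out_ms,
                          record_from_ms = cnd$duration_ms - window_ms)
      if (!tr$failed) tr <- rezero_trace(tr)
      tr$label <- cnd$label
      failed[i, j] <- tr$failed
      row[[names(conditions)[j]]] <- tr
      if (normalized) {
        nrow_[[names(conditions)[j]]] <- if (tr$failed) tr else
          tryCatch(normalize_traces(tr), error = function(e) {
            tr$failed <- TRUE; tr
          })
      }
    }
    traces[[i]] <- row
    if (normalized) ntraces[[i]] <- nrow_
  }
  structure(list(cells = cells, conditions = conditions, traces = traces,
                 normalized_traces = if (normalized) ntraces,
                 window_ms = window_ms, dt_out_ms = dt_out_ms,
                 failed = failed), class = "insilico_dataset")
}

#' @export
print.insilico_dataset <- function(x, ...) {
  cat(sprintf("<insilico_dataset> %d cell(s) x %d condition(s), %d failed entries\n",
              length(x$cells), length(x$conditions), sum(x$failed)))
  invisible(x)
}

#' Save / load an in-silico dataset
#'
#' Plain-text container: a directory with a JSON manifest (ground-truth
#' multipliers, condition descriptions, grid) and one CSV per stored
#' trace.
#'
#' @param ds an `insilico_dataset`.
#' @param dir directory path (created if needed).
#' @return `load_dataset` returns the `insilico_dataset`.
#' @export
save_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "insilico_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    cells = lapply(ds$cells, function(m) as.list(unclass(m))),
    conditions = lapply(ds$conditions, function(cnd) list(
      label = cnd$label, ca_o = cnd$mil$ca_o, na_o = cnd$mil$na_o,
      k_o = cnd$mil$k_o, pacing_hz = cnd$pacing_hz,
      blocks = if (length(cnd$blocks)) as.list(unclass(cnd$blocks)),
      duration_ms = cnd$duration_ms
    )),
    window_ms = ds$window_ms, dt_out_ms = ds$dt_out_ms,
    failed = apply(ds$failed, 1, as.list),
    has_normalized = !is.null(ds$normalized_traces)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(ds$traces)) {
    for (nm in names(ds$traces[[i]])) {
      tr <- ds$traces[[i]][[nm]]
      if (!tr$failed) {
        write_trace_csv(tr, file.path(dir, sprintf("cell%02d_%s.csv", i, nm)))
      }
    }
  }
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  cells <- lapply(man$cells, function(m) conductance_set(values = unlist(m)))
  conditions <- lapply(man$conditions, function(p) {
    condition(label = p$label, ca_o = p$ca_o, na_o = p$na_o, k_o = p$k_o,
              pacing_hz = p$pacing_hz,
              blocks = if (length(p$blocks)) do.call(block_map, p$blocks),
              duration_ms = p$duration_ms)
  })
  names(conditions) <- names(man$conditions) %||%
    sprintf("c%02d", seq_along(conditions))
  failed <- do.call(rbind, lapply(man$failed, function(r) unlist(r)))
  traces <- list(); ntraces <- list()
  for (i in seq_along(cells)) {
    row <- list(); nrow_ <- list()
    for (j in seq_along(conditions)) {
      nm <- names(conditions)[j]
      f <- file.path(dir, sprintf("cell%02d_%s.csv", i, nm))
      if (file.exists(f)) {
        tr <- read_trace_csv(f)
        tr$label <- conditions[[j]]$label
        row[[nm]] <- tr
        if (isTRUE(man$has_normalized)) nrow_[[nm]] <- normalize_traces(tr)
      } else {
        tr <- new_cm_trace(numeric(0), numeric(0), numeric(0),
                           man$dt_out_ms, NULL, failed = TRUE)
        row[[nm]] <- tr
        if (isTRUE(man$has_normalized)) nrow_[[nm]] <- tr
      }
    }
    traces[[i]] <- row
    if (isTRUE(man$has_normalized)) ntraces[[i]] <- nrow_
  }
  structure(list(cells = cells, conditions = conditions, traces = traces,
                 normalized_traces = if (isTRUE(man$has_normalized)) ntraces,
                 window_ms = man$window_ms, dt_out_ms = man$dt_out_ms,
                 failed = failed), class = "insilico_dataset")
}

#' Assemble a calibration target from a dataset
#'
#' Builds the `cm_trace_set` for one cell over the conditions of a
#' protocol, matched by condition label.
#'
#' @param ds an `insilico_dataset`.
#' @param cell cell index.
#' @param prot a `cm_protocol` whose condition labels exist in the dataset.
#' @param normalized use the normalized copies.
#' @return a `cm_trace_set` with the cell's ground truth attached.
#' @export
dataset_target <- function(ds, cell, prot, normalized = FALSE) {
  src <- if (normalized) ds$normalized_traces else ds$traces
  stopifnot(!is.null(src), cell >= 1, cell <= length(src))
  labels <- vapply(ds$conditions, function(x) x$label, "")
  segs <- lapply(prot$conditions, function(cnd) {
    j <- match(cnd$label, labels)
    if (is.na(j)) stop("condition '", cnd$label, "' not present in dataset")
    src[[cell]][[j]]
  })
  new_trace_set(segments = segs, normalized = normalized,
                truth = ds$cells[[cell]], prot = prot,
                failed = any(vapply(segs, function(s) s$failed, TRUE)))
}
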