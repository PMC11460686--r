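#' @useDynLib cmcal
#' @importFrom stats approx median rnorm runif sd setNames runmed
#' @importFrom utils read.csv write.csv
"_PACKAGE"

## Names of the 16 scaled maximal conductances / fluxes, in the order the
## compiled right-hand side expects them.
KERNIK_PARAMS <- c(
  "g_Na", "g_f", "g_CaL", "g_CaT", "g_to", "g_Kr", "g_Ks", "g_K1",
  "g_NaK", "g_NaCa", "g_PCa", "g_bNa", "g_bCa", "g_up", "g_leak", "g_rel"
)

## Fixed registry mapping current/flux names to the multiplier they scale.
CURRENT_REGISTRY <- c(
  I_Na = "g_Na", I_f = "g_f", I_CaL = "g_CaL", I_CaT = "g_CaT",
  I_to = "g_to", I_Kr = "g_Kr", I_Ks = "g_Ks", I_K1 = "g_K1",
  I_NaK = "g_NaK", I_NaCa = "g_NaCa", I_PCa = "g_PCa", I_bNa = "g_bNa",
  I_bCa = "g_bCa", J_up = "g_up", J_leak = "g_leak", J_rel = "g_rel"
)

STATE_NAMES <- c(
  "V", "Ca_SR", "Cai", "Nai", "Ki",
  "d", "f", "fCa", "Xr1", "Xr2", "Xs", "h", "j", "m", "Xf", "s", "r",
  "dCaT", "fCaT", "R_ryr", "O_ryr", "I_ryr"
)

## A plausible beating-cell state used only to start the 10-minute
## steady-state derivation in initial_state(); never used directly.
.kernik_seed_state <- c(
  V = -75.6, Ca_SR = 0.33, Cai = 2.2e-4, Nai = 7.17, Ki = 104.75,
  d = 4e-4, f = 0.17, fCa = 0.88, Xr1 = 0.0031, Xr2 = 0.45, Xs = 0.154,
  h = 0.74, j = 0.125, m = 0.03, Xf = 0.0064, s = 0.747, r = 2.7e-4,
  dCaT = 2.7e-4, fCaT = 0.756, R_ryr = 0.0113, O_ryr = 1.65e-4,
  I_ryr = 0.0142
)

.cmcal_cache <- new.env(parent = emptyenv())

#' Conductance multiplier set
#'
#' A named vector of 16 strictly positive dimensionless multipliers applied
#' to the model's maximal conductances and fluxes. An all-ones set
#' reproduces the baseline model exactly.
#'
#' @param ... named multipliers to override (e.g. `g_Kr = 1.6`); unnamed
#'   defaults are 1.
#' @param values optional full named vector (all 16 entries).
#' @return an object of class `conductance_set`.
#' @export
#' @examples
#' conductance_set(g_Kr = 0.5)
conductance_set <- function(..., values = NULL) {
  x <- setNames(rep(1, length(KERNIK_PARAMS)), KERNIK_PARAMS)
  if (!is.null(values)) {
    values <- unclass(values)
    if (!all(names(values) %in% KERNIK_PARAMS)) {
      stop("unknown conductance name(s): ",
           paste(setdiff(names(values), KERNIK_PARAMS), collapse = ", "))
    }
    x[names(values)] <- values
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("multipliers must be passed by name")
    }
    bad <- setdiff(names(dots), KERNIK_PARAMS)
    if (length(bad)) stop("unknown conductance name(s): ", paste(bad, collapse = ", "))
    x[names(dots)] <- unlist(dots)
  }
  validate_conductance_set(x)
  structure(x, class = "conductance_set")
}

validate_conductance_set <- function(x) {
  if (length(x) != length(KERNIK_PARAMS) ||
      !identical(names(x), KERNIK_PARAMS)) {
    stop("a conductance set must have exactly the 16 named multipliers")
  }
  if (!all(is.finite(x)) || any(x < 0)) {
    stop("conductance multipliers must be finite and non-negative")
  }
  invisible(x)
}

#' @export
print.conductance_set <- function(x, ...) {
  cat("<conductance_set> 16 multipliers\n")
  print(round(unclass(x), 4))
  invisible(x)
}

as_conductance_set <- function(x) {
  if (inherits(x, "conductance_set")) return(x)
  conductance_set(values = x)
}

#' Extracellular milieu
#'
#' Bath ion concentrations. Defaults are the physiological Tyrode used to
#' derive the model's steady state: 151 mM Na+, 1.8 mM Ca2+, 5.4 mM K+.
#'
#' @param na_o,ca_o,k_o concentrations in mM (all > 0).
#' @return an object of class `milieu`.
#' @export
milieu <- function(na_o = 151, ca_o = 1.8, k_o = 5.4) {
  stopifnot(na_o > 0, ca_o > 0, k_o > 0)
  structure(list(na_o = na_o, ca_o = ca_o, k_o = k_o), class = "milieu")
}

#' Channel block map
#'
#' Named blocked fractions in \[0, 1\] for currents in the fixed registry
#' (`I_Na`, `I_f`, `I_CaL`, `I_CaT`, `I_to`, `I_Kr`, `I_Ks`, `I_K1`,
#' `I_NaK`, `I_NaCa`, `I_PCa`, `I_bNa`, `I_bCa`, `J_up`, `J_leak`,
#' `J_rel`). Unlisted currents are unblocked.
#'
#' @param ... named fractions, e.g. `I_Kr = 0.30`.
#' @return an object of class `block_map`.
#' @export
block_map <- function(...) {
  b <- unlist(list(...))
  if (length(b)) {
    bad <- setdiff(names(b), names(CURRENT_REGISTRY))
    if (length(bad) || is.null(names(b)) || any(names(b) == "")) {
      stop("unknown current name(s) in block map: ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    }
    if (any(b < 0 | b > 1)) stop("block fractions must lie in [0, 1]")
  } else {
    b <- numeric(0)
  }
  structure(b, class = "block_map")
}

#' Apply channel block to a conductance set
#'
#' Scales each targeted multiplier by `(1 - b)`; all other multipliers are
#' unchanged.
#'
#' @param x a [conductance_set()].
#' @param blocks a [block_map()] (or named numeric of fractions).
#' @return a new `conductance_set`.
#' @export
#' @examples
#' apply_block(conductance_set(), block_map(I_Kr = 0.30))
apply_block <- function(x, blocks) {
  x <- as_conductance_set(x)
  if (is.null(blocks) || length(blocks) == 0) return(x)
  if (!inherits(blocks, "block_map")) blocks <- do.call(block_map, as.list(blocks))
  out <- unclass(x)
  for (cur in names(blocks)) {
    par <- CURRENT_REGISTRY[[cur]]
    out[par] <- out[par] * (1 - blocks[[cur]])
  }
  structure(out, class = "conductance_set")
}

#' Stimulus specification
#'
#' Square inward current pulses. The default amplitude (60 pA/pF) and
#' width (1 ms) match the pacing stimulus applied throughout; the first
#' pulse is delivered at `t = period`.
#'
#' @param period_ms pulse period in ms (e.g. 1000 for 1 Hz). `NULL` means
#'   spontaneous (no stimulus).
#' @param amplitude_pApF pulse amplitude in pA/pF (inward).
#' @param width_ms pulse width in ms; must be below `period_ms`.
#' @return an object of class `stimulus` or `NULL`.
#' @export
stimulus <- function(period_ms, amplitude_pApF = 60, width_ms = 1) {
  if (is.null(period_ms)) return(NULL)
  stopifnot(period_ms > width_ms, amplitude_pApF > 0, width_ms > 0)
  structure(list(period_ms = period_ms, amplitude_pApF = amplitude_pApF,
                 width_ms = width_ms), class = "stimulus")
}

## per-state absolute tolerances: V 1e-4, concentrations 1e-8, gates 1e-6
.kernik_atol <- function() {
  a <- setNames(rep(1e-6, length(STATE_NAMES)), STATE_NAMES)
  a["V"] <- 1e-4
  a[c("Ca_SR", "Cai", "Nai", "Ki")] <- 1e-8
  a
}

## One lsoda leg with fixed stimulus level. `times` must be strictly
## increasing and start at the current state time. Returns the matrix or
## NULL on solver failure.
.kernik_leg <- function(x0, times, mult, mil, stim_level, rtol, nout) {
  p <- c(unclass(mult), mil$na_o, mil$ca_o, mil$k_o, stim_level)
  out <- try(suppressWarnings(
    deSolve::lsoda(
      y = x0, times = times, func = "kernik_derivs", parms = p,
      dllname = "cmcal", initfunc = "kernik_init",
      nout = nout, outnames = if (nout) names(CURRENT_REGISTRY),
      rtol = rtol, atol = .kernik_atol(), maxsteps = 1e6
    )
  ), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  if (nrow(out) < length(times) || !all(is.finite(out[nrow(out), ]))) return(NULL)
  if (any(abs(out[, "V"]) > 200)) return(NULL)
  out
}

#' Simulate a model cell
#'
#' Integrates the conductance-scaled iPSC-CM model over `[0, duration_ms]`
#' with a stiff adaptive solver (LSODA, rtol 1e-6, per-state atol), and
#' samples membrane potential and intracellular calcium on a uniform output
#' grid. Stimulus pulses are handled by piecewise integration so that no
#' pulse can be stepped over. On integrator failure a flagged failed trace
#' is returned (never an error), which downstream fitness evaluation maps
#' to a sentinel penalty.
#'
#' @param mult a [conductance_set()] (or named vector of multipliers).
#' @param mil a [milieu()].
#' @param blocks optional [block_map()]; applied on top of `mult`.
#' @param stim optional [stimulus()]; `NULL` for spontaneous activity.
#' @param duration_ms total simulated time (ms).
#' @param x0 initial state vector; defaults to the cached baseline steady
#'   state from [initial_state()].
#' @param dt_out_ms output sampling step (ms).
#' @param record_from_ms sample the output grid only from this time onward
#'   (state is still carried through the unrecorded interval). Use it to
#'   keep only a trailing steady-state window.
#' @param currents if `TRUE`, also record the 16 scaled currents/fluxes.
#' @param rtol relative solver tolerance.
#' @return an object of class `cm_trace` with elements `time_ms`, `V`,
#'   `Cai`, `final_state`, `failed`, and metadata. Time stamps are absolute
#'   (simulation clock).
#' @export
simulate_cell <- function(mult = conductance_set(), mil = milieu(),
                          blocks = NULL, stim = NULL, duration_ms,
                          x0 = initial_state(), dt_out_ms = 0.1,
                          record_from_ms = 0, currents = FALSE,
                          rtol = 1e-6) {
  stopifnot(duration_ms > 0, dt_out_ms > 0,
            record_from_ms >= 0, record_from_ms < duration_ms)
  mult <- apply_block(as_conductance_set(mult), blocks)
  if (!is.null(stim) && !inherits(stim, "stimulus")) {
    stop("`stim` must be a stimulus() or NULL")
  }
  x0 <- .check_state(x0)
  nout <- if (currents) length(CURRENT_REGISTRY) else 0

  grid <- seq(record_from_ms, duration_ms, by = dt_out_ms)

  ## piecewise integration plan: [start, end, stim_level]
  legs <- .stim_legs(duration_ms, stim)

  rows <- vector("list", nrow(legs))
  state <- x0
  failed <- FALSE
  for (i in seq_len(nrow(legs))) {
    t0 <- legs[i, 1]; t1 <- legs[i, 2]; lvl <- legs[i, 3]
    gt <- grid[grid > t0 + 1e-9 & grid < t1 - 1e-9]
    times <- c(t0, gt, t1)
    out <- .kernik_leg(state, times, mult, mil, lvl, rtol, nout)
    if (is.null(out)) { failed <- TRUE; break }
    state <- setNames(out[nrow(out), STATE_NAMES], STATE_NAMES)
    rows[[i]] <- out
  }

  if (failed) {
    return(new_cm_trace(time_ms = numeric(0), V = numeric(0), Cai = numeric(0),
                        dt_out_ms = dt_out_ms, final_state = NULL,
                        failed = TRUE, mult = mult, mil = mil, stim = stim))
  }
  res <- do.call(rbind, rows)
  ## snap assembled samples onto the exact requested grid, dropping leg
  ## boundaries that are not grid points and duplicated boundary samples
  tt <- res[, "time"]
  idx <- round((tt - record_from_ms) / dt_out_ms) + 1
  snap <- record_from_ms + (idx - 1) * dt_out_ms
  ok <- idx >= 1 & idx <= length(grid) & abs(tt - snap) < dt_out_ms / 4
  res <- res[ok, , drop = FALSE]
  res <- res[!duplicated(idx[ok]), , drop = FALSE]
  cur <- NULL
  if (currents) cur <- res[, names(CURRENT_REGISTRY), drop = FALSE]
  new_cm_trace(
    time_ms = res[, "time"], V = res[, "V"], Cai = res[, "Cai"],
    dt_out_ms = dt_out_ms, final_state = state, failed = FALSE,
    mult = mult, mil = mil, stim = stim, currents = cur
  )
}

## Integration legs honouring 1 ms stimulus pulses; first pulse at
## t = period (condition clock).
.stim_legs <- function(duration_ms, stim) {
  if (is.null(stim)) {
    return(matrix(c(0, duration_ms, 0), nrow = 1))
  }
  p <- stim$period_ms; w <- stim$width_ms; a <- stim$amplitude_pApF
  onsets <- seq(p, duration_ms - 1e-9, by = p)
  if (!length(onsets)) return(matrix(c(0, duration_ms, 0), nrow = 1))
  legs <- list(c(0, onsets[1], 0))
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    off <- min(on + w, duration_ms)
    legs[[length(legs) + 1]] <- c(on, off, a)
    nxt <- if (k < length(onsets)) onsets[k + 1] else duration_ms
    if (nxt > off + 1e-9) legs[[length(legs) + 1]] <- c(off, nxt, 0)
  }
  do.call(rbind, legs)
}

.check_state <- function(x0) {
  if (length(x0) != length(STATE_NAMES)) {
    stop("state vector must have exactly ", length(STATE_NAMES), " entries")
  }
  if (is.null(names(x0))) {
    names(x0) <- STATE_NAMES
  }
  if (!identical(names(x0), STATE_NAMES)) {
    if (!all(STATE_NAMES %in% names(x0))) stop("state vector names are incomplete")
    x0 <- x0[STATE_NAMES]
  }
  if (!all(is.finite(x0))) stop("initial state contains non-finite values")
  if (x0[["V"]] < -150 || x0[["V"]] > 100) {
    stop("initial membrane potential outside [-150, 100] mV")
  }
  x0
}

new_cm_trace <- function(time_ms, V, Cai, dt_out_ms, final_state, failed,
                         mult = NULL, mil = NULL, stim = NULL,
                         currents = NULL, normalized = FALSE, label = NULL) {
  structure(list(
    time_ms = as.numeric(time_ms), V = as.numeric(V), Cai = as.numeric(Cai),
    dt_out_ms = dt_out_ms, final_state = final_state, failed = failed,
    mult = mult, mil = mil, stim = stim, currents = currents,
    normalized = normalized, label = label
  ), class = "cm_trace")
}

#' @export
print.cm_trace <- function(x, ...) {
  if (x$failed) {
    cat("<cm_trace> FAILED integration\n")
    return(invisible(x))
  }
  cat(sprintf("<cm_trace> %d samples, %.1f-%.1f ms (dt %.3g ms)%s\n",
              length(x$time_ms), min(x$time_ms), max(x$time_ms),
              x$dt_out_ms, if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Derive the baseline initial state
#'
#' Runs the all-ones (baseline) model for 10 minutes without stimulus in
#' the default milieu (151/1.8/5.4 mM Na/Ca/K) and returns the final state
#' vector, the model's operational steady state. The result is cached in
#' memory for the session and optionally to a JSON file.
#'
#' @param cache_file optional path to a JSON snapshot; if the file exists
#'   it is loaded instead of re-deriving, otherwise it is written.
#' @param force re-derive even if a cached value exists.
#' @return a named state vector.
#' @export
initial_state <- function(cache_file = NULL, force = FALSE) {
  if (!force && !is.null(.cmcal_cache$x0)) return(.cmcal_cache$x0)
  if (!force && !is.null(cache_file) && file.exists(cache_file)) {
    x0 <- load_state(cache_file)
    .cmcal_cache$x0 <- x0
    return(x0)
  }
  ## 10-minute unpaced baseline run; the snapshot is taken at the maximum
  ## diastolic potential of the final seconds so that the canonical state
  ## is a diastolic point on the limit cycle.
  mult <- conductance_set()
  mil <- milieu()
  leg1 <- .kernik_leg(.kernik_seed_state, c(0, 597000), mult, mil, 0, 1e-6, 0)
  if (is.null(leg1)) stop("baseline steady-state derivation failed (0-597 s)")
  s1 <- setNames(leg1[nrow(leg1), STATE_NAMES], STATE_NAMES)
  leg2 <- .kernik_leg(s1, seq(597000, 600000, by = 1), mult, mil, 0, 1e-6, 0)
  if (is.null(leg2)) stop("baseline steady-state derivation failed (597-600 s)")
  i_mdp <- which.min(leg2[, "V"])
  x0 <- setNames(leg2[i_mdp, STATE_NAMES], STATE_NAMES)
  .cmcal_cache$x0 <- x0
  if (!is.null(cache_file) && !file.exists(cache_file)) save_state(x0, cache_file)
  x0
}

#' Save / load a state snapshot as JSON
#'
#' Full double precision, named fields.
#' @param state a named state vector.
#' @param path file path.
#' @return `load_state` returns the named state vector.
#' @export
save_state <- function(state, path) {
  jsonlite::write_json(as.list(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  x <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  .check_state(x)
}

#' Write / read a trace as CSV
#'
#' Columns `time_ms`, `V`, `Cai`.
#' @param trace a `cm_trace`.
#' @param path file path.
#' @return `read_trace_csv` returns a `cm_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cm_trace"), !trace$failed)
  write.csv(data.frame(time_ms = trace$time_ms, V = trace$V,
                       Cai = trace$Cai), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_ms", "V", "Cai") %in% names(d)))
  dt <- if (nrow(d) > 1) median(diff(d$time_ms)) else NA_real_
  new_cm_trace(d$time_ms, d$V, d$Cai, dt, final_state = NULL, failed = FALSE)
}
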