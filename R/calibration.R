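#' Genetic-algorithm configuration
#'
#' Search settings for conductance calibration. Genes are log2
#' multipliers of the free parameters; the default bounds span 0.1x-10x
#' and always contain the baseline value 1. The defaults (population 200,
#' 20 generations, size-2 tournament selection, uniform crossover,
#' Gaussian log2 mutation, 5% elitism) are package choices documented in
#' the methods vignette.
#'
#' @param population population size.
#' @param generations number of generations (>= 1).
#' @param init initial-population distribution over log2 genomes:
#'   `"normal"` (centred on baseline, SD `init_sigma`, clamped to the
#'   bounds — a biologically plausible population-of-models prior) or
#'   `"uniform"` over the full bounds box.
#' @param init_sigma SD (log2) of the normal initializer.
#' @param free character vector of free parameter names (default all 16).
#' @param fixed named multipliers for the non-free parameters (default 1).
#' @param bounds_log2 length-2 log2 search bounds; must contain 0.
#' @param tournament tournament size for selection.
#' @param crossover_p per-gene uniform crossover probability.
#' @param mut_sigma mutation standard deviation in log2 space at the
#'   first generation.
#' @param mut_sigma_final mutation standard deviation at the last
#'   generation; the schedule anneals geometrically between the two so
#'   early generations explore and late generations refine. Set equal to
#'   `mut_sigma` for a constant schedule.
#' @param mut_rate per-gene mutation probability.
#' @param elitism_frac fraction of top individuals copied unchanged.
#' @param sentinel fitness assigned to failed/non-beating candidates.
#' @param seed RNG seed for the run.
#' @param condition_duration_ms optional per-condition duration override
#'   (pre-equilibration time) applied to candidate simulations; `NULL`
#'   uses the protocol's full durations.
#' @param alignment beat alignment before the point-wise error:
#'   `"first-upstroke"` (circular shift to the first upstroke),
#'   `"xcorr"` (best circular shift by cross-correlation), or `"none"`.
#' @param ca_weight weight of the calcium MSE relative to the voltage
#'   MSE in the combined fitness. `NULL` (auto) weights each raw calcium
#'   segment by the squared ratio of the target's voltage range to its
#'   calcium range, so both signals constrain the fit equally despite
#'   their disparate physical units (mV versus mM); normalized data
#'   already share the [0, 1] scale and get weight 1.
#' @param seed_individuals optional matrix/list of log2 genomes injected
#'   into the initial population.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population = 200, generations = 20,
                      init = c("normal", "uniform"), init_sigma = 1,
                      free = KERNIK_PARAMS, fixed = NULL,
                      bounds_log2 = c(-3.32, 3.32), tournament = 2,
                      crossover_p = 0.5, mut_sigma = 0.2,
                      mut_sigma_final = 0.05, mut_rate = 0.3,
                      elitism_frac = 0.05, sentinel = 1e6, seed = 1,
                      condition_duration_ms = NULL,
                      alignment = c("first-upstroke", "xcorr", "none"),
                      ca_weight = NULL, seed_individuals = NULL) {
  alignment <- match.arg(alignment)
  init <- match.arg(init)
  stopifnot(population >= 2, generations >= 1, init_sigma > 0,
            length(bounds_log2) == 2, bounds_log2[1] < 0, bounds_log2[2] > 0,
            all(free %in% KERNIK_PARAMS), length(free) >= 1)
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% KERNIK_PARAMS))
  }
  if (!is.null(seed_individuals)) {
    if (is.list(seed_individuals)) {
      seed_individuals <- do.call(rbind, seed_individuals)
    }
    stopifnot(ncol(seed_individuals) == length(free))
  }
  structure(as.list(environment()), class = "ga_config")
}

## full 16-multiplier set from a log2 genome under a config
genome_to_mult <- function(genome, cfg) {
  m <- setNames(rep(1, length(KERNIK_PARAMS)), KERNIK_PARAMS)
  if (!is.null(cfg$fixed)) m[names(cfg$fixed)] <- unlist(cfg$fixed)
  m[cfg$free] <- 2^genome
  conductance_set(values = m)
}

## index of the first upstroke (max-slope threshold rule); NA if none
.first_upstroke_idx <- function(x, dt) {
  if (length(x) < 5 || diff(range(x)) < 1e-12) return(NA_integer_)
  dv <- diff(x) / dt
  thr <- 0.1 * max(dv)
  if (thr <= 0) return(NA_integer_)
  idx <- which(dv >= thr)[1]
  if (is.na(idx)) NA_integer_ else idx
}

.circshift <- function(x, k) {
  n <- length(x)
  if (n == 0) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(k + 1):n], x[1:k])
}

## align candidate signal to target signal by circular shift
.align_signal <- function(cand, targ, dt, alignment) {
  if (alignment == "none") return(cand)
  if (alignment == "first-upstroke") {
    ic <- .first_upstroke_idx(cand, dt)
    it <- .first_upstroke_idx(targ, dt)
    if (is.na(ic) || is.na(it)) return(cand)
    return(.circshift(cand, ic - it))
  }
  ## cross-correlation over circular shifts via FFT
  n <- length(cand)
  cc <- Re(stats::fft(stats::fft(targ) * Conj(stats::fft(cand)), inverse = TRUE))
  k <- which.max(cc) - 1
  .circshift(cand, -k)
}

#' Trace-set fitness (summed point-wise mean squared error)
#'
#' For each segment the candidate's V and Ca signals are beat-aligned to
#' the target (configurable) and the point-wise mean squared errors are
#' summed over both signals and all segments. Failed or non-beating
#' candidates (when the target beats) receive the sentinel value; grid or
#' normalization mismatches are errors.
#'
#' @param candidate,target `cm_trace_set`s from the same protocol, on the
#'   same grid and with the same normalization flag.
#' @param alignment see [ga_config()].
#' @param sentinel penalty for failed candidates.
#' @param ca_weight weight of the calcium MSE; `NULL` (auto) equalizes
#'   the two signals' scales on raw data (see [ga_config()]), `1` sums
#'   the plain MSEs.
#' @return a single non-negative error value.
#' @export
trace_fitness <- function(candidate, target,
                          alignment = c("first-upstroke", "xcorr", "none"),
                          sentinel = 1e6, ca_weight = 1) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(target, "cm_trace_set"))
  if (!inherits(candidate, "cm_trace_set") || isTRUE(candidate$failed)) {
    return(sentinel)
  }
  if (isTRUE(candidate$normalized) != isTRUE(target$normalized)) {
    stop("candidate and target normalization flags differ")
  }
  if (length(candidate$segments) != length(target$segments)) {
    stop("candidate and target segment counts differ")
  }
  total <- 0
  for (i in seq_along(target$segments)) {
    ct <- candidate$segments[[i]]; tt <- target$segments[[i]]
    if (ct$failed) return(sentinel)
    if (length(ct$time_ms) != length(tt$time_ms) ||
        abs(ct$dt_out_ms - tt$dt_out_ms) > 1e-9) {
      stop("candidate/target grid mismatch in segment ", i)
    }
    targ_beats <- !is.na(.first_upstroke_idx(tt$V, tt$dt_out_ms))
    cand_beats <- !is.na(.first_upstroke_idx(ct$V, ct$dt_out_ms)) &&
      diff(range(ct$V)) > 0.3 * diff(range(tt$V))
    if (targ_beats && !cand_beats) return(sentinel)
    v <- .align_signal(ct$V, tt$V, tt$dt_out_ms, alignment)
    ca <- .align_signal(ct$Cai, tt$Cai, tt$dt_out_ms, alignment)
    w <- if (is.null(ca_weight)) {
      if (isTRUE(target$normalized)) 1 else
        (diff(range(tt$V)) / diff(range(tt$Cai)))^2
    } else ca_weight
    total <- total + mean((v - tt$V)^2) + w * mean((ca - tt$Cai)^2)
  }
  total
}

## simulate a candidate genome under the target's protocol and score it
.eval_genome <- function(genome, target, prot, cfg, x0) {
  mult <- genome_to_mult(genome, cfg)
  ts <- run_protocol(mult, prot, x0 = x0,
                     condition_duration_ms = cfg$condition_duration_ms)
  if (ts$failed) return(cfg$sentinel)
  if (isTRUE(target$normalized)) {
    ts <- tryCatch(normalize_traces(ts), error = function(e) NULL)
    if (is.null(ts)) return(cfg$sentinel)
  }
  trace_fitness(ts, target, alignment = cfg$alignment,
                sentinel = cfg$sentinel, ca_weight = cfg$ca_weight)
}

#' Run one genetic-algorithm calibration
#'
#' Evolves a population of log2-multiplier genomes for
#' `cfg$generations` generations. Every individual is evaluated by
#' simulating the protocol and scoring the summed trace MSE against the
#' target; elitism guarantees a non-increasing best fitness. Identical
#' genomes are cached within a run so elites are not re-simulated.
#'
#' @param target a `cm_trace_set` (raw or normalized) from a declared
#'   protocol.
#' @param prot the `cm_protocol` that produced the target.
#' @param cfg a [ga_config()].
#' @param x0 starting state for candidate simulations.
#' @return an object of class `calibration_run`: `best` (full
#'   [conductance_set()]), `best_fitness`, `history` (per-generation best
#'   and mean fitness, generation 0 = initial population), `seed`,
#'   `free`, and `elapsed_s`.
#' @export
ga_run <- function(target, prot, cfg = ga_config(), x0 = initial_state()) {
  stopifnot(inherits(target, "cm_trace_set"), inherits(prot, "cm_protocol"),
            inherits(cfg, "ga_config"))
  t_start <- Sys.time()
  set.seed(cfg$seed)
  k <- length(cfg$free)
  n <- cfg$population
  lo <- cfg$bounds_log2[1]; hi <- cfg$bounds_log2[2]

  pop <- if (cfg$init == "uniform") {
    matrix(runif(n * k, lo, hi), nrow = n)
  } else {
    matrix(pmin(pmax(rnorm(n * k, 0, cfg$init_sigma), lo), hi), nrow = n)
  }
  if (!is.null(cfg$seed_individuals)) {
    m <- min(nrow(cfg$seed_individuals), n)
    pop[seq_len(m), ] <- pmin(pmax(cfg$seed_individuals[seq_len(m), ,
                                                        drop = FALSE], lo), hi)
  }

  cache <- new.env(parent = emptyenv())
  eval_pop <- function(P) {
    vapply(seq_len(nrow(P)), function(i) {
      key <- paste(sprintf("%.12g", P[i, ]), collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      f <- .eval_genome(P[i, ], target, prot, cfg, x0)
      cache[[key]] <- f
      f
    }, 0)
  }

  fit <- eval_pop(pop)
  n_elite <- max(1L, ceiling(cfg$elitism_frac * n))
  hist_best <- min(fit); hist_mean <- mean(fit)

  sig0 <- cfg$mut_sigma
  sig1 <- if (is.null(cfg$mut_sigma_final)) sig0 else cfg$mut_sigma_final
  for (gen in seq_len(cfg$generations)) {
    ## geometric annealing of the mutation step: explore early, refine late
    sig <- sig0 * (sig1 / sig0)^((gen - 1) / max(1, cfg$generations - 1))
    ord <- order(fit)
    elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    children <- matrix(0, n - n_elite, k)
    for (c_i in seq_len(nrow(children))) {
      p1 <- pop[.tournament(fit, cfg$tournament), ]
      p2 <- pop[.tournament(fit, cfg$tournament), ]
      take2 <- runif(k) < cfg$crossover_p
      child <- ifelse(take2, p2, p1)
      mut <- runif(k) < cfg$mut_rate
      child[mut] <- child[mut] + rnorm(sum(mut), 0, sig)
      children[c_i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- rbind(elites, children)
    fit <- eval_pop(pop)
    hist_best <- c(hist_best, min(fit))
    hist_mean <- c(hist_mean, mean(fit))
  }

  ib <- which.min(fit)
  structure(list(
    best = genome_to_mult(pop[ib, ], cfg),
    best_genome = pop[ib, ],
    best_fitness = fit[ib],
    history = data.frame(generation = 0:cfg$generations,
                         best = hist_best, mean = hist_mean),
    seed = cfg$seed, free = cfg$free,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "calibration_run")
}

.tournament <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = FALSE)
  cand[which.min(fit[cand])]
}

#' @export
print.calibration_run <- function(x, ...) {
  cat(sprintf("<calibration_run> best fitness %.4g after %d generations (%.1f s)\n",
              x$best_fitness, max(x$history$generation), x$elapsed_s))
  invisible(x)
}

#' Repeated GA calibrations against one target
#'
#' Runs the GA `n_runs` times with independent seeds (and therefore
#' independent initial populations); the collection quantifies how
#' consistently the target constrains each parameter.
#'
#' @param target,prot,cfg,x0 as in [ga_run()].
#' @param n_runs number of runs (>= 2 for a defined spread; default 10).
#' @return an object of class `calibration_ensemble` (list of runs).
#' @export
calibrate_ensemble <- function(target, prot, cfg = ga_config(), n_runs = 10,
                               x0 = initial_state()) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i * 1000L
    ga_run(target, prot, cfg_i, x0 = x0)
  })
  structure(list(runs = runs, target_truth = target$truth),
            class = "calibration_ensemble")
}

#' @export
print.calibration_ensemble <- function(x, ...) {
  cat(sprintf("<calibration_ensemble> %d run(s); best fitnesses: %s\n",
              length(x$runs),
              paste(sprintf("%.3g", vapply(x$runs, `[[`, 0, "best_fitness")),
                    collapse = ", ")))
  invisible(x)
}

#' Fitted multipliers of an ensemble as a matrix
#'
#' @param ens a `calibration_ensemble`.
#' @return runs x 16 matrix of fitted multipliers.
#' @export
ensemble_multipliers <- function(ens) {
  do.call(rbind, lapply(ens$runs, function(r) unclass(r$best)))
}
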