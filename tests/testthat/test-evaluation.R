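test_that("calibration error is |log2(fitted/true)| with its symmetries", {
  truth <- conductance_set()
  expect_equal(calibration_error(truth, truth)$mean, 0)

  doubled <- conductance_set(g_Kr = 2)
  e <- calibration_error(doubled, truth)
  expect_equal(unname(e$per_parameter["g_Kr"]), 1)
  expect_equal(e$mean, 1 / 16)

  halved <- conductance_set(g_Kr = 0.5)
  expect_equal(unname(calibration_error(halved, truth)$per_parameter["g_Kr"]), 1)

  bad <- unclass(truth); bad["g_Na"] <- 0
  expect_error(calibration_error(bad, truth), "positive")
})

test_that("calibration spread uses the sample-SD convention", {
  truth <- conductance_set()
  M <- rbind(unclass(conductance_set()), unclass(conductance_set()),
             unclass(conductance_set()))
  expect_equal(calibration_spread(M, truth)$mean, 0)

  two <- rbind(unclass(conductance_set(g_Kr = 2)),
               unclass(conductance_set(g_Kr = 0.5)))
  spr <- calibration_spread(two, truth)$per_parameter
  expect_equal(unname(spr["g_Kr"]), sd(c(1, -1)))        # 1.4142
  expect_equal(unname(spr["g_Kr"]), sqrt(2), tolerance = 1e-12)

  ## invariance to rescaling truth and fits together
  k <- 3.3
  truth_k <- conductance_set(values = unclass(truth) * k)
  two_k <- two * k
  expect_equal(calibration_spread(two_k, truth_k)$per_parameter, spr)
})

test_that("prediction scores are zero on identity and exact on ratios", {
  ts <- make_fixture_trace_set()
  sc <- prediction_scores(ts, ts, baseline_predicted = ts, baseline_truth = ts)
  expect_equal(sc$mse, 0)
  expect_equal(sc$apd90_pct_error, 0)

  ## APD90/amplitude of 3.3 against 3.0 is a 10% error
  expect_equal(100 * (3.3 - 3.0) / 3.0, 10)

  ## the MSE component shares the fitness definition
  off <- make_fixture_trace_set(offset_V = 2)
  expect_equal(prediction_scores(off, ts, alignment = "none")$mse,
               trace_fitness(off, ts, alignment = "none"))
})

test_that("predicted response to I_Kr block prolongs the action potential", {
  x0 <- cached_x0()
  prot <- baseline_protocol(duration_ms = 30000, window_ms = 5000,
                            dt_out_ms = 1)
  truth_ts <- run_protocol(conductance_set(), prot, x0 = x0)
  pred <- predict_response(conductance_set(), block_map(I_Kr = 0.30),
                           prot = prot, x0 = x0)
  expect_false(pred$failed)
  ## identical parameters: prediction equals ground-truth response exactly
  pred2 <- predict_response(conductance_set(), block_map(I_Kr = 0.30),
                            prot = prot, x0 = x0)
  expect_identical(pred$segments[[1]]$V, pred2$segments[[1]]$V)

  ## removing repolarizing current lengthens APD90
  apd_of <- function(ts) mean(detect_beats(ts$segments[[1]])$apd90, na.rm = TRUE)
  expect_gt(apd_of(pred), apd_of(truth_ts))

  ## the alternative I_K1 perturbation is supported
  predk1 <- predict_response(conductance_set(), block_map(I_K1 = 0.30),
                             prot = prot, x0 = x0,
                             condition_duration_ms = 10000)
  expect_false(predk1$failed)
})

test_that("regression recovers planted linear sensitivities", {
  set.seed(99)
  cells <- draw_multipliers(250, spread = 0.3)
  X <- log2(do.call(rbind, lapply(cells, unclass)))
  beta <- setNames(rep(0, 16), colnames(X))
  beta[c("g_Kr", "g_CaL")] <- c(-2, 1.5)
  y <- as.numeric(X %*% beta) + rnorm(250, 0, 0.1)
  out <- data.frame(pheno = y, indep = rnorm(250))

  sens <- sensitivity_regression(cells, out)
  co <- sens$coefficients[, "pheno"]
  ## signs and ranking recovered
  expect_lt(co["g_Kr"], 0)
  expect_gt(co["g_CaL"], 0)
  expect_true(all(c("g_Kr", "g_CaL") %in% sens$top$pheno))
  ## an output independent of every parameter has near-zero coefficients
  expect_lt(max(abs(sens$coefficients[, "indep"])), 0.2)

  ## z-scoring makes coefficients invariant to output units
  out2 <- data.frame(pheno = 1000 * y + 5)
  sens2 <- sensitivity_regression(cells, out2)
  expect_equal(unname(sens2$coefficients[, 1]), unname(co), tolerance = 1e-9)

  expect_error(sensitivity_regression(cells[1:10], out[1:10, ]), "small")
})

test_that("threshold scan granularity bounds the coarse estimate", {
  ## purely structural check on the scan grid logic against a stubbed
  ## arrhythmia boundary: first arrhythmic level at 37%
  lab_at <- function(lv) if (lv >= 37) "alternans" else "none"
  fine <- seq(1, 100, by = 1); coarse <- seq(5, 100, by = 5)
  thr_fine <- fine[which(vapply(fine, lab_at, "") != "none")[1]]
  thr_coarse <- coarse[which(vapply(coarse, lab_at, "") != "none")[1]]
  expect_equal(thr_fine, 37)
  expect_equal(thr_coarse, 40)
  expect_gte(thr_coarse, thr_fine)
  expect_lte(thr_coarse - thr_fine, 5)
})

test_that("ikr block threshold finds an arrhythmic level for a fragile cell", {
  x0 <- cached_x0()
  ## strong I_Kr dependence: scanning in coarse steps with short windows
  res <- ikr_block_threshold(conductance_set(), step_pct = 25,
                             pre_ms = 30000, observe_ms = 15000, x0 = x0)
  expect_true(is.finite(res$threshold_pct) || res$label == "tolerant")
  expect_true(res$threshold_pct > 0)
  if (is.finite(res$threshold_pct)) {
    expect_true(res$label %in% cmcal:::ARRHYTHMIA_LABELS[-1])
  }
})
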