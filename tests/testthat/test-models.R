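test_that("standardize_predictors centers and scales", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 10, 40))
  out <- standardize_predictors(d, c("a", "b"))
  expect_equal(mean(out$a), 0)
  expect_equal(stats::sd(out$a), 1)
  # already-standardized input is unchanged
  out2 <- standardize_predictors(out, "a")
  expect_equal(out2$a, out$a, tolerance = 1e-12)
  d$c <- 5
  expect_error(standardize_predictors(d, "c"), "zero-variance.*c")
})

test_that("a null model has zero marginal R2", {
  d <- simulate_mixed_data(n_part = 10, n_stim = 24, seed = 2)
  fit <- fit_mixed(model_spec("liking", character()), d)
  expect_equal(fit$marginal_r2, 0)
  expect_gt(fit$conditional_r2, 0)
  expect_lte(fit$marginal_r2, fit$conditional_r2)
  expect_lte(fit$conditional_r2, 1)
})

test_that("variance decomposition recovers a 2:1:1 design", {
  # var_fixed : var_random : var_residual = 2 : 1 : 1
  # => marginal R2 = 0.5, conditional R2 = 0.75
  d <- simulate_mixed_data(beta = sqrt(2), var_part = 0.5, var_sing = 0.25,
                           var_stim = 0.25, var_resid = 1, seed = 3)
  fit <- fit_mixed(model_spec("liking", "x", standardize = FALSE), d)
  expect_equal(fit$marginal_r2, 0.5, tolerance = 0.05 / 0.5)
  expect_equal(fit$conditional_r2, 0.75, tolerance = 0.05 / 0.75)
})

test_that("without random variance, marginal ~ conditional", {
  d <- simulate_mixed_data(n_part = 20, n_stim = 48, beta = 1,
                           var_part = 0, var_sing = 0, var_stim = 0,
                           var_resid = 1, seed = 4)
  fit <- suppressWarnings(fit_mixed(model_spec("liking", "x"), d))
  expect_lt(fit$conditional_r2 - fit$marginal_r2, 0.02)
})

test_that("VIF gate refuses collinear predictors unless overridden", {
  d <- simulate_mixed_data(n_part = 8, n_stim = 24, seed = 5)
  d$x2 <- d$x + stats::rnorm(nrow(d), 0, 0.05)   # near-duplicate
  spec <- model_spec("liking", c("x", "x2"))
  expect_error(fit_mixed(spec, d), "VIF")
  expect_warning(fit_mixed(spec, d, vif_action = "warn"), "VIF")
  expect_s3_class(suppressWarnings(fit_mixed(spec, d, vif_action = "ignore")),
                  "mixed_fit")
})

test_that("likelihood ratio test matches the stored log-likelihoods", {
  d <- simulate_mixed_data(n_part = 12, n_stim = 32, seed = 6)
  null_ml <- fit_mixed(model_spec("liking", character()), d, reml = FALSE)
  full_ml <- fit_mixed(model_spec("liking", "x"), d, reml = FALSE)
  lrt <- likelihood_ratio_test(null_ml, full_ml)
  expect_equal(lrt$chi2,
               2 * (full_ml$log_likelihood - null_ml$log_likelihood),
               tolerance = 1e-8)
  expect_equal(lrt$df, 1)
  same <- likelihood_ratio_test(null_ml, null_ml)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  reml_fit <- fit_mixed(model_spec("liking", "x"), d)
  expect_error(likelihood_ratio_test(null_ml, reml_fit), "ML")
})

test_that("the acoustic model LRT has 9 degrees of freedom", {
  fx <- fix_lab_sim()
  norm <- normalize_within_participant(filter_participants(fx$ratings)$ratings)
  suite <- suppressWarnings(build_model_suite(
    norm, fx$stimuli$acoustic_truth, acoustic_terms = truth_model_terms()))
  expect_equal(suite$lrt_acoustic$df, 9)
  expect_lt(suite$lrt_acoustic$p, 0.05)
})

test_that("individual models: exact fit, null data, and pairing", {
  set.seed(7)
  d <- expand.grid(participant_id = sprintf("p%02d", 1:4), stim = 1:30)
  d$a <- stats::rnorm(nrow(d)); d$b <- stats::rnorm(nrow(d))
  d$liking <- 2 * d$a - d$b + 3   # exact linear function
  res <- suppressWarnings(
    fit_individual_models(d, c("a", "b"), model_kind = "exact"))
  expect_equal(res$adjusted_r2, rep(1, 4), tolerance = 1e-9)
  # liking independent of predictors: adjusted R2 ~ 0 on average
  d$liking <- stats::rnorm(nrow(d))
  nullres <- fit_individual_models(d, c("a", "b"), model_kind = "null")
  expect_lt(abs(mean(nullres$adjusted_r2)), 0.1)
  # under-determined participants yield NA
  tiny <- d[d$stim <= 2, ]
  expect_true(all(is.na(fit_individual_models(tiny, c("a", "b"))$adjusted_r2)))
})

test_that("mediation: perceptual beats acoustic at the individual level", {
  fx <- fix_lab_sim()
  norm <- normalize_within_participant(filter_participants(fx$ratings)$ratings)
  wide <- model_frame(norm, fx$stimuli$acoustic_truth)
  acou <- fit_individual_models(wide, truth_model_terms(),
                                model_kind = "acoustic")
  perc <- fit_individual_models(wide, perceptual_scales()$scale,
                                model_kind = "perceptual")
  cmp <- compare_individual_fits(acou, perc)
  expect_gt(cmp$mean_perceptual, cmp$mean_acoustic)
  expect_lt(cmp$t, 0)
  expect_lt(cmp$p, 0.001)
})

test_that("acoustic sensitivities: exact pair, Fisher z, group ordering", {
  set.seed(8)
  truth <- data.frame(stimulus_id = sprintf("s%02d", 1:30),
                      bpm = stats::rnorm(30, 100, 10))
  ratings <- data.frame(participant_id = "p1",
                        stimulus_id = truth$stimulus_id,
                        scale = "tempo", value = truth$bpm * 0.1 + 2)
  pairs <- data.frame(feature = "bpm", scale = "tempo")
  sens <- acoustic_sensitivity(ratings, truth, pairs = pairs,
                               use_normalized = FALSE)
  expect_equal(sens$r_tempo, 1, tolerance = 1e-9)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # simulator: high-sensitivity group orders above low-sensitivity group
  stim <- build_stimulus_set(seed = 65, render = FALSE)
  parts <- draw_participant_population(20, seed = 66)
  for (i in 1:10) parts[[i]]$sensitivity[] <- abs(parts[[i]]$sensitivity) + 0.5
  for (i in 11:20) parts[[i]]$sensitivity[] <- 0
  r <- simulate_lab_ratings(stim, parts, seed = 67)
  sens2 <- acoustic_sensitivity(r, stim$acoustic_truth,
                                pairs = sensitivity_pairs("truth"),
                                use_normalized = FALSE)
  hi <- sens2$mean_sensitivity[sens2$participant_id %in%
                                 sprintf("p%03d", 1:10)]
  lo <- sens2$mean_sensitivity[sens2$participant_id %in%
                                 sprintf("p%03d", 11:20)]
  expect_gt(mean(hi), mean(lo))
})

test_that("stepwise reduction keeps informative covariates, drops noise", {
  set.seed(9)
  hits <- 0L
  for (run in 1:5) {
    n <- 200
    d <- data.frame(informative = stats::rnorm(n))
    for (j in 1:6) d[[paste0("noise", j)]] <- stats::rnorm(n)
    d$z <- 0.5 * d$informative + stats::rnorm(n)
    res <- characteristics_regression(d, "z")
    expect_lte(res$aic_reduced, res$aic_full)
    if ("informative" %in% res$retained) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
  # all-noise covariates: usually reduces to (near) nothing
  set.seed(10)
  d0 <- data.frame(z = stats::rnorm(100))
  for (j in 1:5) d0[[paste0("noise", j)]] <- stats::rnorm(100)
  res0 <- characteristics_regression(d0, "z")
  expect_lte(length(res0$retained), 2)
})

test_that("model suite reports raw and normalized fits coherently", {
  fx <- fix_lab_sim()
  norm <- normalize_within_participant(filter_participants(fx$ratings)$ratings)
  suite <- suppressWarnings(build_model_suite(
    norm, fx$stimuli$acoustic_truth, acoustic_terms = truth_model_terms()))
  cmp <- suite$comparison
  expect_setequal(cmp$model, c("null", "acoustic", "perceptual"))
  # marginal <= conditional everywhere
  expect_true(all(cmp$marginal_r2_normalized <= cmp$conditional_r2_normalized))
  expect_true(all(cmp$marginal_r2_raw <= cmp$conditional_r2_raw))
  # raw vs normalized: fixed-effect share barely moves
  a <- cmp[cmp$model == "acoustic", ]
  expect_lt(abs(a$marginal_r2_normalized - a$marginal_r2_raw), 0.05)
  p <- cmp[cmp$model == "perceptual", ]
  expect_lt(abs(p$marginal_r2_normalized - p$marginal_r2_raw), 0.1)
})
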