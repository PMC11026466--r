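test_that("lab simulation has the full design shape and integer ranges", {
  fx <- fix_lab_sim()
  r <- fx$ratings
  expect_equal(nrow(r), 42 * 96 * 11)
  expect_setequal(unique(r$scale), c("liking", perceptual_scales()$scale))
  lik <- r$value[r$scale == "liking"]
  perc <- r$value[r$scale != "liking"]
  expect_true(all(lik == round(lik) & lik >= 1 & lik <= 9))
  expect_true(all(perc == round(perc) & perc >= 1 & perc <= 7))
  expect_false(any(r$is_repeat))
})

test_that("rating simulation is deterministic in the seed", {
  stim <- build_stimulus_set(n_singers = 3, n_takes = 1, seed = 5,
                             render = FALSE)
  parts <- draw_participant_population(4, seed = 6)
  a <- simulate_lab_ratings(stim, parts, seed = 7)
  b <- simulate_lab_ratings(stim, parts, seed = 7)
  expect_identical(a, b)
  cc <- simulate_lab_ratings(stim, parts, seed = 8)
  expect_false(identical(a, cc))
  expect_error(simulate_lab_ratings(stim, list(), seed = 1), "empty")
})

test_that("noise-free identical raters agree perfectly", {
  stim <- build_stimulus_set(n_singers = 4, n_takes = 1, seed = 15,
                             render = FALSE)
  parts <- draw_participant_population(6, seed = 16)
  template <- parts[[1]]
  template$perception_noise_sd <- 0
  template$idio_sd <- 0
  template$scale_use_min <- 1; template$scale_use_max <- 7
  parts <- lapply(seq_along(parts), function(i) {
    p <- template
    p$participant_id <- sprintf("p%03d", i)
    p
  })
  ratings <- simulate_lab_ratings(stim, parts, seed = 17)
  for (s in c("pitch_accuracy", "vibrato")) {
    m <- rating_matrix(ratings[ratings$scale == s, ])
    expect_equal(krippendorff_alpha(m), 1)
  }
})

test_that("zero liking weights erase the perceptual fixed effects", {
  stim <- build_stimulus_set(seed = 25, render = FALSE)
  parts <- draw_participant_population(15, seed = 26)
  zero_w <- lapply(default_liking_weights(), function(w) w * 0)
  ratings <- simulate_lab_ratings(stim, parts, seed = 27, weights = zero_w)
  ratings <- normalize_within_participant(ratings)
  wide <- model_frame(ratings)
  spec <- model_spec("liking", perceptual_scales()$scale)
  fit <- suppressWarnings(fit_mixed(spec, wide, vif_action = "ignore"))
  expect_lt(fit$marginal_r2, 0.03)
})

test_that("online design yields 32 scored + 16 repeat trials per participant", {
  stim <- build_stimulus_set(seed = 35, render = FALSE)
  parts <- draw_participant_population(3, seed = 36)
  r <- simulate_online_ratings(stim, parts, seed = 37)
  counts <- table(r$participant_id, r$is_repeat)
  expect_true(all(counts[, "FALSE"] == 32))
  expect_true(all(counts[, "TRUE"] == 16))
  # one distinct singer per scored trial within each block
  one <- r[r$participant_id == r$participant_id[1] & !r$is_repeat, ]
  for (b in unique(one$block)) {
    expect_equal(anyDuplicated(one$singer_id[one$block == b]), 0L)
  }
  expect_true(all(r$value >= 1 & r$value <= 9))
  # every repeat refers to a stimulus the participant scored
  reps <- r[r$is_repeat, ]
  scored <- r[!r$is_repeat, ]
  expect_true(all(paste(reps$participant_id, reps$stimulus_id) %in%
                    paste(scored$participant_id, scored$stimulus_id)))
})

test_that("a large online sample covers every stimulus", {
  stim <- build_stimulus_set(seed = 45, render = FALSE)
  parts <- draw_participant_population(326, seed = 46)
  r <- simulate_online_ratings(stim, parts, seed = 47)
  rated <- unique(r$stimulus_id[!r$is_repeat])
  expect_setequal(rated, stim$acoustic_truth$stimulus_id)
  expect_error(simulate_online_ratings(
    build_stimulus_set(n_singers = 4, n_takes = 1, seed = 1, render = FALSE),
    parts, block_size = 16), "fewer singers")
})

test_that("participant population respects its declared invariants", {
  parts <- draw_participant_population(30, seed = 55)
  for (p in parts) {
    expect_lt(p$scale_use_min, p$scale_use_max)
    expect_gte(p$scale_use_min, 1); expect_lte(p$scale_use_max, 7)
    expect_gte(p$consistency, 0); expect_lte(p$consistency, 1)
    expect_true(all(is.finite(unlist(p$covariates))))
  }
  # STOMP dimensions are averages of 1-7 genre ratings
  stomp <- vapply(parts, function(p) p$covariates$stomp_mellow, numeric(1))
  expect_true(all(stomp >= 1 & stomp <= 7))
})
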