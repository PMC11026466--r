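make_long <- function(m, scale = "liking") {
  data.frame(
    participant_id = rep(rownames(m), ncol(m)),
    stimulus_id = rep(colnames(m), each = nrow(m)),
    scale = scale,
    value = as.vector(m))
}

test_that("within-participant normalization maps the used range to [0, 1]", {
  r <- data.frame(participant_id = "p1", stimulus_id = paste0("s", 1:3),
                  scale = "liking", value = c(2, 4, 6))
  out <- normalize_within_participant(r)
  expect_equal(out$normalized_value, c(0, 0.5, 1))
  full <- data.frame(participant_id = "p2", stimulus_id = paste0("s", 1:9),
                     scale = "liking", value = 1:9)
  out2 <- normalize_within_participant(full)
  expect_equal(out2$normalized_value[c(1, 9)], c(0, 1))
  # affine map: correlation with raw is exactly 1, rank order unchanged
  expect_equal(stats::cor(out2$value, out2$normalized_value), 1)
  # constant rater flagged by NA
  cst <- data.frame(participant_id = "p3", stimulus_id = paste0("s", 1:3),
                    scale = "liking", value = c(5, 5, 5))
  expect_true(all(is.na(normalize_within_participant(cst)$normalized_value)))
})

test_that("degenerate raters are filtered out", {
  m <- rbind(p_all1 = rep(1, 10),
             p_89 = rep(c(8, 9), 5),
             p_full = c(1:9, 5))
  colnames(m) <- paste0("s", 1:10)
  res <- filter_participants(make_long(m))
  expect_setequal(res$excluded, c("p_all1", "p_89"))
  expect_true("p_full" %in% res$ratings$participant_id)
})

test_that("test-retest correlation behaves at the extremes", {
  base <- data.frame(participant_id = "p1",
                     stimulus_id = paste0("s", 1:8),
                     scale = "liking", value = c(1, 3, 5, 7, 9, 2, 4, 6),
                     is_repeat = FALSE)
  identical_rep <- base
  identical_rep$is_repeat <- TRUE
  tr <- test_retest(rbind(base, identical_rep))
  expect_equal(tr$r, 1)
  expect_true(tr$consistent)
  flipped <- base
  flipped$is_repeat <- TRUE
  flipped$value <- 10 - base$value
  tr2 <- test_retest(rbind(base, flipped))
  expect_equal(tr2$r, -1)
  expect_error(test_retest(base), "repeat")
})

test_that("simulated raters reproduce their consistency parameter", {
  stim <- build_stimulus_set(seed = 71, render = FALSE)
  parts <- draw_participant_population(200, seed = 72)
  for (p in seq_along(parts)) parts[[p]]$consistency <- 0.8
  ratings <- simulate_online_ratings(stim, parts, seed = 73)
  tr <- test_retest(ratings)
  expect_equal(mean(tr$r, na.rm = TRUE), 0.8, tolerance = 0.15 / 0.8)
})

test_that("Krippendorff alpha: perfect agreement and chance level", {
  m <- matrix(rep(c(1, 3, 5, 7, 2, 4, 6, 8, 9, 5) * 1, each = 10), nrow = 10)
  expect_equal(krippendorff_alpha(m), 1)
  set.seed(9)
  rnd <- matrix(sample(1:9, 50 * 96, replace = TRUE), nrow = 50)
  expect_equal(krippendorff_alpha(rnd), 0, tolerance = 0.05)
  expect_error(krippendorff_alpha(matrix(1:4, 1)), "2 raters")
  # no pairable values
  m2 <- matrix(NA_real_, 3, 3)
  m2[1, 1] <- 1; m2[2, 2] <- 2; m2[3, 3] <- 3
  expect_error(krippendorff_alpha(m2), "pairable")
})

test_that("Krippendorff alpha matches brute-force pairwise enumeration", {
  set.seed(31)
  for (i in 1:6) {
    m <- matrix(sample(1:7, 3 * 4, replace = TRUE), nrow = 3)
    expect_equal(krippendorff_alpha(m), alpha_bruteforce(m), tolerance = 1e-12)
  }
  # with missing entries
  for (i in 1:4) {
    m <- matrix(sample(1:9, 5 * 20, replace = TRUE), nrow = 5)
    m[sample(length(m), 15)] <- NA
    expect_equal(krippendorff_alpha(m), alpha_bruteforce(m), tolerance = 1e-12)
  }
})

test_that("alpha is affine-invariant and decreases with added noise", {
  set.seed(13)
  base <- matrix(rep(stats::runif(30, 1, 9), each = 6), nrow = 6) +
    matrix(stats::rnorm(180, 0, 0.5), nrow = 6)
  a0 <- krippendorff_alpha(base)
  expect_equal(krippendorff_alpha(base * 3.7 - 12), a0, tolerance = 1e-12)
  alphas <- vapply(c(0, 1, 3), function(sd) {
    krippendorff_alpha(base + matrix(stats::rnorm(180, 0, sd), nrow = 6))
  }, numeric(1))
  expect_true(all(diff(alphas) < 0))
})

test_that("ICC(2,1) recovers known variance structure", {
  items <- rep(c(2, 4, 6, 8, 1, 3, 5, 7, 9, 5), 2)
  m <- rbind(items, items, items)
  expect_equal(icc2_1(m), 1, tolerance = 1e-9)
  # raters = items + independent noise: ICC ~ var_item/(var_item+var_noise)
  set.seed(17)
  item_vals <- stats::rnorm(200, 0, 2)   # var 4
  noisy <- t(vapply(1:10, function(i) item_vals + stats::rnorm(200, 0, 1),
                    numeric(200)))        # noise var 1 -> ICC ~ 0.8
  expect_equal(icc2_1(noisy), 4 / 5, tolerance = 0.05 / 0.8)
  expect_error(icc2_1(matrix(5, 4, 6)), "undefined")
  expect_error(icc2_1(matrix(1:6, 1)), "2 raters")
})

test_that("MM1 matches leave-one-out recomputation", {
  set.seed(23)
  m <- matrix(stats::rnorm(8 * 20), nrow = 8,
              dimnames = list(paste0("p", 1:8), NULL))
  res <- mm1(m)
  for (i in 1:8) {
    expected_r <- stats::cor(m[i, ], colMeans(m[-i, ]))
    expect_equal(res$individual$r[i], expected_r, tolerance = 1e-12)
  }
  expect_equal(res$overall, tanh(mean(atanh(res$individual$r))),
               tolerance = 1e-12)
})

test_that("MM1 extremes: identical raters and an anti-correlated rater", {
  v <- c(1, 5, 3, 9, 7, 2, 8, 4, 6, 5)
  ident <- matrix(rep(v, each = 10), nrow = 10)
  expect_equal(mm1(ident)$overall, 1, tolerance = 1e-9)
  contrarian <- rbind(matrix(rep(v, each = 10), nrow = 10), 10 - v)
  res <- mm1(contrarian)
  expect_equal(res$individual$r[11], -1, tolerance = 1e-9)
  expect_true(all(res$individual$r[1:10] > 0.9))
  # constant participant gets NA, not a silent zero
  with_const <- rbind(matrix(rep(v, each = 3), nrow = 3), rep(4, 10))
  expect_true(is.na(mm1(with_const)$individual$r[4]))
})

test_that("agreement_report composes the statistics for one scale", {
  set.seed(3)
  stim <- build_stimulus_set(n_singers = 4, n_takes = 1, seed = 81,
                             render = FALSE)
  parts <- draw_participant_population(8, seed = 82)
  ratings <- simulate_lab_ratings(stim, parts, seed = 83)
  ratings <- normalize_within_participant(ratings)
  rep_ <- agreement_report(ratings, "liking")
  expect_lte(rep_$alpha_k, 1)
  expect_lte(rep_$icc2_1, 1)
  expect_true(abs(rep_$mm1_overall) <= 1)
  expect_equal(rep_$n_raters, 8)
  expect_equal(rep_$n_items, 8)
})
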