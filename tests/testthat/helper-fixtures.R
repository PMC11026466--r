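# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a clean (noise-free, vibrato-free) rendered performance
fix_clean_performance <- function() {
  fixture("clean_perf", function() {
    score <- default_melody_scores()$over_the_rainbow
    singer <- singer_params(pitch_sd_cents = 0, jitter_pct = 0,
                            shimmer_pct = 0, breath_noise_db = -80,
                            vibrato_extent_cents = 0, gap_frac = 0.05)
    list(score = score,
         perf = synthesize_performance(score, singer, take_seed = 101))
  })
}

# a typical rendered performance with every perturbation on
fix_typical_performance <- function() {
  fixture("typical_perf", function() {
    score <- default_melody_scores()$over_the_rainbow
    singer <- singer_params(pitch_sd_cents = 12, jitter_pct = 1,
                            shimmer_pct = 3, breath_noise_db = -28,
                            vibrato_rate_hz = 5.5, vibrato_extent_cents = 50)
    list(score = score, singer = singer,
         perf = synthesize_performance(score, singer, take_seed = 202))
  })
}

# a small design-only stimulus set + simulated lab ratings
fix_lab_sim <- function() {
  fixture("lab_sim", function() {
    stim <- build_stimulus_set(seed = 11, render = FALSE)
    parts <- draw_participant_population(42, seed = 12)
    ratings <- simulate_lab_ratings(stim, parts, seed = 13)
    list(stimuli = stim, participants = parts, ratings = ratings)
  })
}

truth_model_terms <- function() {
  c("pitch_dev_cents", "bpm", "formant_band_gain_db", "breath_noise_db",
    "spectral_slope_db_oct", "gap_frac", "vibrato_extent_cents",
    "vibrato_rate_hz", "jitter_pct")
}

# simulate data straight from the mixed model's own family with known
# variance components (used for the decomposition recovery checks); each
# realized component is rescaled to its exact target SD, so the
# generative variance ratios hold in-sample, not just in expectation
simulate_mixed_data <- function(n_part = 42, n_stim = 96, beta = 1,
                                var_part = 0.5, var_sing = 0.25,
                                var_stim = 0.25, var_resid = 1, seed = 1) {
  set.seed(seed)
  exact_sd <- function(n, s) {
    if (s == 0) return(numeric(n))
    v <- stats::rnorm(n)
    (v - mean(v)) / stats::sd(v) * sqrt(s)
  }
  singer <- rep(sprintf("g%02d", 1:16), length.out = n_stim)
  x <- exact_sd(n_stim, 1)
  u_p <- exact_sd(n_part, var_part)
  u_s <- exact_sd(16, var_sing)
  u_i <- exact_sd(n_stim, var_stim)
  d <- expand.grid(participant_id = sprintf("p%03d", 1:n_part),
                   stim = seq_len(n_stim))
  d$stimulus_id <- sprintf("s%03d", d$stim)
  d$singer_id <- singer[d$stim]
  d$x <- x[d$stim]
  d$liking <- beta * d$x + u_p[as.integer(d$participant_id)] +
    u_s[match(d$singer_id, sprintf("g%02d", 1:16))] + u_i[d$stim] +
    exact_sd(nrow(d), var_resid)
  d
}

# brute-force Krippendorff alpha: explicit loops over every ordered pair
# of pairable values (independent oracle for the vectorized version)
alpha_bruteforce <- function(m) {
  vals <- list()
  for (u in seq_len(ncol(m))) {
    x <- m[!is.na(m[, u]), u]
    if (length(x) >= 2) vals[[length(vals) + 1]] <- x
  }
  n <- sum(lengths(vals))
  do_sum <- 0
  for (x in vals) {
    mu <- length(x)
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i != j) do_sum <- do_sum + (x[i] - x[j])^2 / (mu - 1)
    }
  }
  d_o <- do_sum / n
  pooled <- unlist(vals)
  de_sum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) de_sum <- de_sum + (pooled[i] - pooled[j])^2
  }
  d_e <- de_sum / (n * (n - 1))
  1 - d_o / d_e
}

# segment stub for extractors that only need samples + sample_rate
raw_segment <- function(samples, sample_rate, mean_f0 = NA_real_) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 mean_f0 = mean_f0,
                 f0_track = NULL),
            class = "note_segment")
}
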