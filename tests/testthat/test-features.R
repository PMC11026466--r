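test_that("f0 tracking locates known tones", {
  fs <- 22050
  tt <- (0:(fs - 1)) / fs
  sine <- sin(2 * pi * 220 * tt)
  trk <- track_f0(sine, fs, fmin = 100, fmax = 900)
  expect_equal(stats::median(trk$f0, na.rm = TRUE), 220, tolerance = 0.5 / 220)
  # harmonic complex at 329.63 Hz
  harm <- rowSums(sapply(1:10, function(h)
    10^(-h / 10) * sin(2 * pi * h * 329.63 * tt)))
  trk2 <- track_f0(harm, fs)
  expect_equal(stats::median(trk2$f0, na.rm = TRUE), 329.63, tolerance = 1 / 330)
  expect_error(track_f0(sine[1:100], fs), "window")
})

test_that("white noise is overwhelmingly unvoiced", {
  set.seed(42)
  fs <- 22050
  trk <- track_f0(stats::rnorm(fs), fs)
  expect_gte(mean(is.na(trk$f0)), 0.9)
})

test_that("segment_notes validates labels and recovers note pitches", {
  fx <- fix_clean_performance()
  p <- fx$perf
  segs <- segment_notes(p)
  expect_length(segs, length(fx$score$notes))
  meas <- vapply(segs, function(s) s$mean_f0, numeric(1))
  # generator target f0 recovered within 2 cents on every note
  expect_lt(max(abs(1200 * log2(meas / p$note_f0_hz))), 2)

  bad <- p$labels
  bad$end_s[nrow(bad)] <- bad$end_s[nrow(bad)] + 100  # beyond audio
  expect_error(segment_notes(p, bad), "beyond")
  bad2 <- p$labels
  bad2$start_s[2] <- bad2$start_s[2] - 0.5  # overlap
  expect_error(segment_notes(p, bad2), "overlap")
})

test_that("pitch interval deviation implements the cents-error definition", {
  two <- melody_score("maj2", list(note_spec(0), note_spec(200)))
  # singing 250 cents against an expected major second: error is 50 cents
  expect_equal(pitch_interval_deviation(c(261.626, 302.270), two), 50,
               tolerance = 1e-3)
  # 150 cents (quarter-tone flat) scores the same 50
  expect_equal(pitch_interval_deviation(
    c(261.626, 261.626 * 2^(150 / 1200)), two), 50, tolerance = 1e-9)
  # a perfectly in-tune performance scores 0
  three <- melody_score("x", list(note_spec(0), note_spec(200), note_spec(500)))
  perfect <- cents_to_hz(c(0, 200, 500))
  expect_equal(pitch_interval_deviation(perfect, three), 0)
  # deviations +10 and -10 average to 10
  sung <- cents_to_hz(c(0, 210, 500))  # intervals 210, 290 vs 200, 300
  expect_equal(pitch_interval_deviation(sung, three), 10, tolerance = 1e-9)
  # excluded notes drop both adjacent intervals
  excl <- melody_score("e", list(note_spec(0),
                                 note_spec(200, exclude_from_pitch = TRUE),
                                 note_spec(500)))
  expect_error(pitch_interval_deviation(perfect, excl), "excluded")
  expect_error(pitch_interval_deviation(c(261, 300), three), "count")
})

test_that("vibrato analysis recovers rate and extent", {
  score <- default_melody_scores()$over_the_rainbow
  for (case in list(c(5.5, 50), c(6.2, 120))) {
    s <- singer_params(pitch_sd_cents = 0, jitter_pct = 0.3, shimmer_pct = 1,
                       breath_noise_db = -35, vibrato_rate_hz = case[1],
                       vibrato_extent_cents = case[2])
    p <- synthesize_performance(score, s, take_seed = 31)
    segs <- segment_notes(p)
    v <- vibrato_analyze(segs[[vibrato_note_index(score)]])
    expect_equal(unname(v["rate"]), case[1], tolerance = 0.2 / case[1])
    expect_equal(unname(v["extent"]), case[2], tolerance = 0.1)
  }
  # unmodulated tone reports (0, 0)
  fx <- fix_clean_performance()
  v0 <- vibrato_analyze(segment_notes(fx$perf)[[1]])
  expect_equal(unname(v0), c(0, 0))
})

test_that("energy ratio reflects band energy", {
  fs <- 22050
  set.seed(7)
  n <- fs
  white <- stats::rnorm(n)
  spec_shape <- function(x, lo, hi) {
    X <- stats::fft(x)
    freqs <- (seq_along(X) - 1) * fs / n
    mirror <- pmin(freqs, fs - freqs)
    X[mirror < lo | mirror > hi] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  }
  # noise confined to 3-5 kHz: everything in the numerator band
  banded <- spec_shape(white, 3000, 5000)
  expect_equal(energy_ratio(raw_segment(banded, fs)), 1, tolerance = 0.02)
  # 1 kHz sinusoid: nothing in the numerator band
  sine <- sin(2 * pi * 1000 * (0:(n - 1)) / fs)
  expect_lt(energy_ratio(raw_segment(sine, fs)), 0.01)
  # flat noise over 0-10 kHz: ratio equals the bandwidth ratio 3/10
  flat <- spec_shape(white, 0, 10000)
  expect_equal(energy_ratio(raw_segment(flat, fs)), 0.3, tolerance = 0.02 / 0.3)
  expect_error(energy_ratio(raw_segment(sine, 16000)), "sample_rate")
  # always in [0, 1]
  expect_true(energy_ratio(raw_segment(white, fs)) >= 0)
  expect_true(energy_ratio(raw_segment(white, fs)) <= 1)
})

test_that("jitter and shimmer implement the local perturbation formula", {
  expect_equal(jitter_local(rep(0.01, 50)), 0)
  expect_equal(shimmer_local(rep(1, 50)), 0)
  alt <- rep(c(0.0100, 0.0102), 25)
  expect_equal(jitter_local(alt), 100 * 0.0002 / 0.0101, tolerance = 1e-3)
  expect_equal(shimmer_local(rep(c(1.00, 1.02), 25)), 100 * 0.02 / 1.01,
               tolerance = 1e-3)
  expect_error(jitter_local(0.01), "at least 2")
  expect_error(shimmer_local(1), "at least 2")
})

test_that("generator jitter and shimmer are recovered from audio", {
  score <- default_melody_scores()$over_the_rainbow
  s <- singer_params(pitch_sd_cents = 5, jitter_pct = 1, shimmer_pct = 2,
                     breath_noise_db = -30, vibrato_extent_cents = 40)
  prof <- extract_profile(synthesize_performance(score, s, take_seed = 77),
                          score)
  expect_equal(prof$jitter_local, 1, tolerance = 0.2)
  expect_equal(prof$shimmer_local, 2, tolerance = 0.2)
})

test_that("HNR is high for clean tones and falls with added noise", {
  fx <- fix_clean_performance()
  segs <- segment_notes(fx$perf)
  expect_gte(hnr35(segs[[1]]), 30)
  score <- fx$score
  hnrs <- vapply(c(-35, -20, -10), function(db) {
    s <- singer_params(pitch_sd_cents = 0, jitter_pct = 0, shimmer_pct = 0,
                       breath_noise_db = db, vibrato_extent_cents = 0)
    p <- synthesize_performance(score, s, take_seed = 41)
    hnr35(segment_notes(p)[[1]])
  }, numeric(1))
  expect_true(all(diff(hnrs) < 0))
})

test_that("CPP separates periodic from noisy signals and tracks breathiness", {
  fs <- 22050
  fx <- fix_clean_performance()
  seg_periodic <- segment_notes(fx$perf)[[1]]
  set.seed(5)
  seg_noise <- raw_segment(stats::rnorm(fs), fs)
  cpp_p <- cpp(seg_periodic)
  cpp_n <- cpp(seg_noise)
  expect_gt(cpp_p, cpp_n + 5)
  expect_lte(cpp_n, 5)
  # monotone decrease over three breath-noise levels
  score <- fx$score
  cpps <- vapply(c(-35, -20, -10), function(db) {
    s <- singer_params(pitch_sd_cents = 0, jitter_pct = 0, shimmer_pct = 0,
                       breath_noise_db = db, vibrato_extent_cents = 0)
    p <- synthesize_performance(score, s, take_seed = 43)
    cpp(segment_notes(p)[[1]])
  }, numeric(1))
  expect_true(all(diff(cpps) < 0))
  expect_error(cpp(raw_segment(stats::rnorm(100), fs)), "40 ms")
})

test_that("spectral tilt tracks the source slope", {
  score <- default_melody_scores()$over_the_rainbow
  h1h2_for_slope <- function(slope) {
    s <- singer_params(pitch_sd_cents = 0, jitter_pct = 0, shimmer_pct = 0,
                       breath_noise_db = -60, vibrato_extent_cents = 0,
                       spectral_slope_db_oct = slope,
                       formant_band_gain_db = 0)
    p <- synthesize_performance(score, s, take_seed = 51)
    spectral_tilt(segment_notes(p)[[1]])
  }
  t6 <- h1h2_for_slope(-6)
  expect_equal(unname(t6["h1_h2"]), 6, tolerance = 1 / 6)
  t0 <- h1h2_for_slope(0)
  expect_equal(unname(t0["h1_h2"]), 0, tolerance = 1)
  # steeper slope => larger H1-A3 (monotone over three slopes)
  h1a3 <- vapply(c(-6, -12, -18),
                 function(sl) unname(h1h2_for_slope(sl)["h1_a3"]), numeric(1))
  expect_true(all(diff(h1a3) > 0))
})

test_that("tempo is span over beats", {
  perf <- list(labels = data.frame(start_s = c(0, 4), end_s = c(4, 8),
                                   note_index = 0:1))
  s <- melody_score("t", list(note_spec(0, 8), note_spec(100, 8)))
  expect_equal(tempo(perf, s), 0.5)
  expect_equal(60 / tempo(perf, s), 120)
  fx <- fix_typical_performance()
  expect_equal(tempo(fx$perf, fx$score), fx$singer$tempo_s_per_beat,
               tolerance = 0.01)
})

test_that("outlier trimming is one-sided at mean + k SD", {
  # 20 ones and one aberrant value: mean + 2 SD ~ 48.9, so 100 is trimmed
  r <- trim_outliers(c(rep(1, 20), 100))
  expect_equal(r$kept, rep(1, 20))
  expect_equal(r$excluded_fraction, 1 / 21)
  # a single outlier among few values can never exceed mean + 2 SD
  # (max z in n = 5 is 1.79): trimming correctly keeps it
  expect_equal(trim_outliers(c(1, 1, 1, 1, 100))$excluded_fraction, 0)
  same <- trim_outliers(rep(3, 10))
  expect_equal(same$excluded_fraction, 0)
  # low outliers are never removed
  low <- trim_outliers(c(100, 100, 100, 100, 1))
  expect_equal(low$excluded_fraction, 0)
  expect_error(trim_outliers(c(1, 2)), "at least 3")
})

test_that("feature extraction is gain-invariant except loudness", {
  fx <- fix_typical_performance()
  p <- fx$perf
  p2 <- p
  p2$samples <- p$samples * 10^(6 / 20)
  a <- extract_profile(p, fx$score)
  b <- extract_profile(p2, fx$score)
  gain_free <- c("pitch_interval_deviation", "vibrato_rate", "vibrato_extent",
                 "energy_ratio", "jitter_local", "shimmer_local", "hnr35",
                 "cpp", "h1_h2", "tempo_s_per_beat", "mean_f0")
  for (f in gain_free) expect_equal(b[[f]], a[[f]], tolerance = 1e-6, label = f)
  expect_equal(b$loudness_lufs - a$loudness_lufs, 6, tolerance = 0.05)
})

test_that("profiles recover generator parameters across a seeded sweep", {
  # 8-performance sweep here; the full 20-performance sweep runs in the
  # acceptance suite
  stim <- build_stimulus_set(n_singers = 4, n_takes = 1, seed = 61)
  prof <- extract_profiles(stim)
  truth <- stim$acoustic_truth
  expect_equal(nrow(prof), 8)
  expect_true(all(!is.na(prof$pitch_interval_deviation)))
  expect_lt(max(abs(prof$vibrato_rate - truth$vibrato_rate_hz)), 0.2)
  expect_lt(max(abs(prof$vibrato_extent / truth$vibrato_extent_cents - 1)), 0.1)
  expect_lt(max(abs(prof$jitter_local - truth$jitter_pct)), 0.3)
  expect_equal(prof$tempo_s_per_beat, truth$tempo_s_per_beat,
               tolerance = 0.01)
  # realized pitch deviation recovered within a few cents
  expect_lt(max(abs(prof$pitch_interval_deviation - truth$pitch_dev_cents)), 4)
})
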