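# Synthetic singing-performance generator. Harmonic additive synthesis with
# cycle-accurate control of every measured feature: per-note pitch error
# (cents), sinusoidal FM vibrato on the designated sustained note,
# cycle-level period perturbation (jitter) and amplitude perturbation
# (shimmer), additive breath noise, a dB/octave spectral rolloff plus a
# singer's-formant band gain (2.4-5.4 kHz), note articulation gaps, and a
# per-singer tempo. Not a physical voice model: it is a controllable test
# bench whose parameters are exactly the quantities the extractors measure.

#' Singer parameter set
#'
#' Generative parameters for one singer (optionally realized at take level).
#'
#' @param singer_id Identifier.
#' @param pitch_sd_cents SD of the per-interval pitch error in cents
#'   (successive sung intervals deviate from notation with this SD).
#' @param vibrato_rate_hz Vibrato rate in Hz, in [0, 12].
#' @param vibrato_extent_cents Vibrato excursion (+/- cents around the note
#'   center; half the peak-to-peak excursion).
#' @param jitter_pct Local jitter in % (cycle-to-cycle period perturbation).
#' @param shimmer_pct Local shimmer in % (cycle-to-cycle amplitude
#'   perturbation).
#' @param breath_noise_db Broadband noise level in dB relative to the
#'   harmonic part (negative = quieter than the voice).
#' @param spectral_slope_db_oct Harmonic rolloff in dB/octave (negative).
#' @param formant_band_gain_db Gain applied to harmonics falling in the
#'   2.4-5.4 kHz singer's-formant band.
#' @param tempo_s_per_beat Tempo in seconds per beat.
#' @param gap_frac Fraction of each note left silent at its end
#'   (articulation: 0 = fully legato, larger = more staccato).
#' @param quality_offset Latent singer likability (dimensionless), used by
#'   the rating simulators as a singer-level intercept on liking.
#' @return A `singer_params` list.
#' @export
singer_params <- function(singer_id = "s1",
                          pitch_sd_cents = 20,
                          vibrato_rate_hz = 5.5,
                          vibrato_extent_cents = 50,
                          jitter_pct = 0.8,
                          shimmer_pct = 3,
                          breath_noise_db = -28,
                          spectral_slope_db_oct = -12,
                          formant_band_gain_db = 3,
                          tempo_s_per_beat = 0.56,
                          gap_frac = 0.08,
                          quality_offset = 0) {
  stopifnot(pitch_sd_cents >= 0,
            vibrato_rate_hz >= 0, vibrato_rate_hz <= 12,
            jitter_pct >= 0, shimmer_pct >= 0,
            tempo_s_per_beat > 0,
            gap_frac >= 0, gap_frac < 1)
  structure(as.list(environment()), class = "singer_params")
}

#' Draw a population of singers
#'
#' Draws `n` singer parameter sets from the generator's population
#' distributions. Defaults emulate the acoustic ranges of highly trained
#' singers performing short a cappella excerpts: per-interval pitch error
#' lognormal with median ~20 cents realized deviation, vibrato around
#' 5.5 Hz and ~50 cents extent, tempi giving 6-9 s excerpts.
#'
#' @param n Number of singers.
#' @param seed Integer seed.
#' @param spec Optional named list overriding population hyperparameters;
#'   see source for names.
#' @return List of [singer_params()] objects.
#' @export
draw_singer_population <- function(n, seed = 1, spec = list()) {
  pop <- utils::modifyList(list(
    pitch_sd_meanlog = log(25), pitch_sd_sdlog = 0.5,
    vib_rate_mean = 5.5, vib_rate_sd = 0.6,
    vib_extent_meanlog = log(45), vib_extent_sdlog = 0.45,
    jitter_meanlog = log(0.8), jitter_sdlog = 0.35,
    shimmer_meanlog = log(3), shimmer_sdlog = 0.35,
    breath_mean = -28, breath_sd = 4,
    slope_mean = -12, slope_sd = 1.5,
    formant_gain_mean = 3, formant_gain_sd = 3,
    tempo_mean = 0.56, tempo_sd = 0.045,
    gap_min = 0.02, gap_max = 0.25,
    quality_sd = 0.2
  ), spec)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      singer_params(
        singer_id = sprintf("singer%02d", i),
        pitch_sd_cents = stats::rlnorm(1, pop$pitch_sd_meanlog, pop$pitch_sd_sdlog),
        vibrato_rate_hz = clip(stats::rnorm(1, pop$vib_rate_mean, pop$vib_rate_sd), 3.5, 8.5),
        vibrato_extent_cents = clip(stats::rlnorm(1, pop$vib_extent_meanlog, pop$vib_extent_sdlog), 5, 150),
        jitter_pct = clip(stats::rlnorm(1, pop$jitter_meanlog, pop$jitter_sdlog), 0.1, 3),
        shimmer_pct = clip(stats::rlnorm(1, pop$shimmer_meanlog, pop$shimmer_sdlog), 0.5, 10),
        breath_noise_db = stats::rnorm(1, pop$breath_mean, pop$breath_sd),
        spectral_slope_db_oct = stats::rnorm(1, pop$slope_mean, pop$slope_sd),
        formant_band_gain_db = stats::rnorm(1, pop$formant_gain_mean, pop$formant_gain_sd),
        tempo_s_per_beat = clip(stats::rnorm(1, pop$tempo_mean, pop$tempo_sd), 0.48, 0.65),
        gap_frac = stats::runif(1, pop$gap_min, pop$gap_max),
        quality_offset = stats::rnorm(1, 0, pop$quality_sd)
      )
    })
  })
}

# Render one note: returns list(samples, f0_target)
render_note <- function(f0_target, duration_s, singer, is_vibrato,
                        sample_rate, formant_band = c(2400, 5400)) {
  n <- round(duration_s * sample_rate)
  voiced_dur <- duration_s * (1 - singer$gap_frac)
  n_voiced <- max(round(voiced_dur * sample_rate), round(0.05 * sample_rate))
  ts <- (seq_len(n_voiced) - 1) / sample_rate

  # cycle start times with jitter; vibrato FM on the designated note
  sigma_j <- (singer$jitter_pct / 100) * sqrt(pi) / 2
  sigma_s <- (singer$shimmer_pct / 100) * sqrt(pi) / 2
  n_cycles_max <- ceiling(voiced_dur * f0_target * 1.6) + 4L
  jit <- stats::rnorm(n_cycles_max, 0, sigma_j)
  t_cyc <- numeric(n_cycles_max + 1L)
  k <- 1L
  while (t_cyc[k] < voiced_dur + 2 / f0_target && k <= n_cycles_max) {
    f_inst <- f0_target
    if (is_vibrato && singer$vibrato_extent_cents > 0 && singer$vibrato_rate_hz > 0) {
      f_inst <- f0_target *
        2^(singer$vibrato_extent_cents *
             sin(2 * pi * singer$vibrato_rate_hz * t_cyc[k]) / 1200)
    }
    t_cyc[k + 1L] <- t_cyc[k] + (1 + jit[k]) / f_inst
    k <- k + 1L
  }
  t_cyc <- t_cyc[seq_len(k)]
  n_cyc <- k - 1L

  # piecewise-linear phase (cycle index as a function of time)
  phase <- stats::approx(t_cyc, seq_along(t_cyc) - 1, xout = ts, rule = 2)$y
  # per-cycle amplitude (shimmer), stepwise
  amp_cyc <- 1 + stats::rnorm(n_cyc, 0, sigma_s)
  amp <- stats::approx(t_cyc[-length(t_cyc)], amp_cyc, xout = ts,
                       method = "constant", rule = 2)$y

  # harmonic amplitudes: spectral slope + formant-band gain
  h_max <- floor(0.95 * (sample_rate / 2) / (f0_target * 2^(160 / 1200)))
  h_max <- max(h_max, 1L)
  h <- seq_len(h_max)
  gain_db <- singer$spectral_slope_db_oct * log2(h) +
    ifelse(h * f0_target >= formant_band[1] & h * f0_target <= formant_band[2],
           singer$formant_band_gain_db, 0)
  a_h <- 10^(gain_db / 20)

  y <- numeric(n_voiced)
  two_pi_phase <- 2 * pi * phase
  for (i in seq_along(h)) {
    y <- y + a_h[i] * sin(h[i] * two_pi_phase)
  }
  y <- y * amp

  # breath noise at breath_noise_db relative to the harmonic RMS
  rms_h <- sqrt(mean(y^2))
  noise <- stats::rnorm(n_voiced, 0, 1)
  noise <- noise * (rms_h * 10^(singer$breath_noise_db / 20)) / sqrt(mean(noise^2))
  y <- y + noise

  # onset/offset ramps (15 ms raised cosine) to avoid clicks
  ramp_n <- min(round(0.015 * sample_rate), floor(n_voiced / 4))
  if (ramp_n > 1) {
    w <- 0.5 * (1 - cos(pi * (seq_len(ramp_n) - 1) / (ramp_n - 1)))
    y[seq_len(ramp_n)] <- y[seq_len(ramp_n)] * w
    y[(n_voiced - ramp_n + 1):n_voiced] <- y[(n_voiced - ramp_n + 1):n_voiced] * rev(w)
  }

  out <- numeric(n)
  out[seq_len(min(n_voiced, n))] <- y[seq_len(min(n_voiced, n))]
  out
}

#' Synthesize one singing performance
#'
#' Renders a melody score with one singer's parameters into mono audio plus
#' ground-truth note-boundary annotations. Per note, a harmonic source at
#' f0 = reference * 2^((expected_cents + pitch error)/1200) with >= 20
#' harmonics (up to Nyquist), sinusoidal FM vibrato on the score's
#' designated vibrato note, cycle-level jitter/shimmer perturbations,
#' additive breath noise, spectral rolloff and singer's-formant band gain.
#' Audio is loudness-normalized to `lufs_target`. Identical seeds give
#' bit-identical audio.
#'
#' @param score A [melody_score()].
#' @param singer A [singer_params()].
#' @param take_seed Integer seed for all within-performance randomness.
#' @param sample_rate Sample rate in Hz (>= 16000; >= 20000 needed for the
#'   energy-ratio feature). Default 22050.
#' @param lufs_target Integrated loudness target in LUFS (default -14).
#' @return A `performance` object: list with `samples`, `sample_rate`,
#'   `labels` (data frame `start_s`, `end_s`, `note_index` with half-open
#'   `[start, end)` intervals, 0-based indices), `note_errors_cents`,
#'   `note_f0_hz`, `singer_id`, `params`.
#' @export
synthesize_performance <- function(score, singer, take_seed = 1,
                                   sample_rate = 22050, lufs_target = -14) {
  stopifnot(inherits(score, "melody_score"), inherits(singer, "singer_params"))
  if (sample_rate < 16000) stop("sample_rate must be >= 16000")
  if (length(score$notes) < 2L) stop("degenerate score: need >= 2 notes")
  with_seed(take_seed, {
    cents <- score_cents(score)
    durs <- score_durations(score) * singer$tempo_s_per_beat
    vib_idx <- vibrato_note_index(score)
    # per-note pitch error with per-interval SD = pitch_sd_cents
    errors <- stats::rnorm(length(cents), 0, singer$pitch_sd_cents / sqrt(2))
    f0s <- cents_to_hz(cents + errors, score$reference_hz)
    notes <- lapply(seq_along(cents), function(i) {
      render_note(f0s[i], durs[i], singer,
                  is_vibrato = identical(i, as.integer(vib_idx)),
                  sample_rate = sample_rate)
    })
    samples <- unlist(notes, use.names = FALSE)
    ends <- cumsum(vapply(notes, length, integer(1))) / sample_rate
    starts <- c(0, ends[-length(ends)])
    samples <- normalize_lufs(samples, sample_rate, lufs_target)
    structure(
      list(samples = samples, sample_rate = sample_rate,
           labels = data.frame(start_s = starts, end_s = ends,
                               note_index = seq_along(cents) - 1L),
           note_errors_cents = errors, note_f0_hz = f0s,
           melody = score$name, singer_id = singer$singer_id,
           params = singer),
      class = "performance")
  })
}

#' @export
print.performance <- function(x, ...) {
  cat(sprintf("<performance> %s / %s: %.2f s @ %d Hz, %d notes\n",
              x$singer_id, x$melody, length(x$samples) / x$sample_rate,
              x$sample_rate, nrow(x$labels)))
  invisible(x)
}

# realized mean absolute interval deviation given note errors and score
realized_pitch_deviation <- function(errors, score) {
  sung <- score_cents(score) + errors
  dev <- abs(diff(sung) - expected_intervals(score))
  excl <- score_excluded(score)
  keep <- !(excl[-length(excl)] | excl[-1])
  if (!any(keep)) return(NA_real_)
  mean(dev[keep])
}

#' Build a synthetic stimulus set
#'
#' Draws a singer population, realizes take-level parameter variation, and
#' synthesizes `n_singers * n_takes * length(scores)` performances. The
#' default design (16 singers, 3 takes, 2 melodies) yields 96 stimuli of
#' 6-9 s. Also returns `acoustic_truth`: one row per stimulus with the
#' realized generative parameter values (the oracle for every parameter
#' recovery test and the acoustic ground truth for the rating simulators).
#'
#' @param n_singers Number of singers (>= 1).
#' @param n_takes Takes per singer per melody (>= 1).
#' @param scores List of [melody_score()] objects (one per melody).
#' @param seed Integer master seed.
#' @param population_spec Passed to [draw_singer_population()].
#' @param sample_rate,lufs_target Audio settings; see
#'   [synthesize_performance()].
#' @param render Logical; if `FALSE`, skip audio rendering and return only
#'   design + ground-truth tables (fast path for rating-only simulations).
#' @return A `stimulus_set`: list with `performances` (list, `NULL` entries
#'   if `render = FALSE`), `acoustic_truth` (data frame), `singers`,
#'   `scores`.
#' @export
build_stimulus_set <- function(n_singers = 16, n_takes = 3,
                               scores = default_melody_scores(),
                               seed = 1, population_spec = list(),
                               sample_rate = 22050, lufs_target = -14,
                               render = TRUE) {
  stopifnot(n_singers >= 1, n_takes >= 1, length(scores) >= 1)
  singers <- draw_singer_population(n_singers, seed = derive_seed(seed, 1),
                                    spec = population_spec)
  rows <- list()
  performances <- list()
  idx <- 0L
  for (si in seq_len(n_singers)) {
    for (mi in seq_along(scores)) {
      for (tk in seq_len(n_takes)) {
        idx <- idx + 1L
        score <- scores[[mi]]
        take_seed <- derive_seed(seed, 2, idx)
        # take-level realization of singer parameters
        take_params <- with_seed(derive_seed(seed, 3, idx), {
          p <- singers[[si]]
          p$tempo_s_per_beat <- clip(p$tempo_s_per_beat * exp(stats::rnorm(1, 0, 0.03)),
                                     0.47, 0.69)
          p$vibrato_extent_cents <- clip(p$vibrato_extent_cents * exp(stats::rnorm(1, 0, 0.1)),
                                         3, 160)
          p$gap_frac <- clip(p$gap_frac + stats::rnorm(1, 0, 0.03), 0, 0.35)
          p$jitter_pct <- clip(p$jitter_pct * exp(stats::rnorm(1, 0, 0.1)), 0.05, 4)
          p$shimmer_pct <- clip(p$shimmer_pct * exp(stats::rnorm(1, 0, 0.1)), 0.3, 12)
          p
        })
        perf <- if (render) {
          synthesize_performance(score, take_params, take_seed = take_seed,
                                 sample_rate = sample_rate,
                                 lufs_target = lufs_target)
        } else NULL
        errors <- if (render) perf$note_errors_cents else {
          with_seed(take_seed,
                    stats::rnorm(length(score$notes), 0,
                                 take_params$pitch_sd_cents / sqrt(2)))
        }
        stim_id <- sprintf("%s_%s_t%d", take_params$singer_id, score$name, tk)
        if (render) {
          perf$stimulus_id <- stim_id
          perf$take <- tk
        }
        performances[[idx]] <- perf
        rows[[idx]] <- data.frame(
          stimulus_id = stim_id,
          singer_id = take_params$singer_id,
          melody = score$name,
          take = tk,
          pitch_dev_cents = realized_pitch_deviation(errors, score),
          pitch_sd_cents = take_params$pitch_sd_cents,
          vibrato_rate_hz = take_params$vibrato_rate_hz,
          vibrato_extent_cents = take_params$vibrato_extent_cents,
          jitter_pct = take_params$jitter_pct,
          shimmer_pct = take_params$shimmer_pct,
          breath_noise_db = take_params$breath_noise_db,
          spectral_slope_db_oct = take_params$spectral_slope_db_oct,
          formant_band_gain_db = take_params$formant_band_gain_db,
          tempo_s_per_beat = take_params$tempo_s_per_beat,
          bpm = 60 / take_params$tempo_s_per_beat,
          gap_frac = take_params$gap_frac,
          loudness_lufs = lufs_target,
          quality_offset = take_params$quality_offset,
          duration_s = score$total_beats * take_params$tempo_s_per_beat,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(performances = performances,
         acoustic_truth = do.call(rbind, rows),
         singers = singers, scores = scores),
    class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli (%d singers x %d melodies), %s\n",
              nrow(x$acoustic_truth),
              length(unique(x$acoustic_truth$singer_id)),
              length(unique(x$acoustic_truth$melody)),
              if (is.null(x$performances[[1]])) "design only" else "rendered"))
  invisible(x)
}
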