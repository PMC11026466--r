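# Simulated raters. The generative mechanism is mediation: each
# participant forms noisy, idiosyncratic percepts of the stimulus's
# acoustic features (sensitivity * true feature + a shared
# participant-x-stimulus impression + noise, censored into the
# participant's used subrange of the response scale), and liking is a
# weighted sum of those percepts plus a singer quality offset, a
# participant intercept and residual noise. Liking therefore depends on
# the acoustics only through perception, which is what makes the
# perceptual preference model far outperform the acoustic one on these
# data, mirroring the structure found with human raters.

#' Perceptual scale definitions
#'
#' The ten bipolar 1-7 perceptual scales, each with its driving acoustic
#' feature (a column of the stimulus set's `acoustic_truth` table; `NA` for
#' scales with no single clear acoustic correlate) and the population mean
#' sensitivity (signed: e.g. perceived pitch accuracy *decreases* with
#' pitch interval deviation).
#'
#' @return Data frame `scale`, `feature`, `sens_mean`, `idio_loading`.
#' @export
perceptual_scales <- function() {
  data.frame(
    scale = c("pitch_accuracy", "tempo", "loudness", "articulation",
              "breathiness", "resonance", "timbre", "attack",
              "onset_precision", "vibrato"),
    feature = c("pitch_dev_cents", "bpm", "spectral_slope_db_oct",
                "gap_frac", "breath_noise_db", "formant_band_gain_db",
                "spectral_slope_db_oct", "gap_frac", "pitch_dev_cents",
                "vibrato_extent_cents"),
    sens_mean = c(-0.30, 0.35, 0.18, -0.30, 0.35, 0.30, 0.28, 0.10,
                  0.10, 0.35),
    idio_loading = rep(0.7, 10),
    stringsAsFactors = FALSE
  )
}

#' Default liking weights
#'
#' Population-level weights of each perceived attribute in the liking
#' judgment, per melody. Signs follow the preference structure the
#' pipeline is designed to detect: liking is higher for performances
#' perceived as in tune, with full resonance, with some vibrato and with
#' precise, soft onsets; pitch accuracy matters more for the melody with
#' the sustained octave jump; and the articulation preference runs in
#' opposite directions for the two melodies (legato preferred for one,
#' staccato for the other).
#'
#' @param melodies Character vector of the two melody names (in order:
#'   the one preferring staccato/resonance, then the one preferring
#'   legato/pitch accuracy).
#' @return Named list of named numeric weight vectors, one per melody.
#' @export
default_liking_weights <- function(melodies = c("dont_worry_be_happy",
                                                "over_the_rainbow")) {
  w1 <- c(pitch_accuracy = 0.30, tempo = 0.15, loudness = 0.05,
          articulation = -0.30, breathiness = -0.10, resonance = 0.45,
          timbre = 0.10, attack = -0.15, onset_precision = -0.20,
          vibrato = 0.35)
  w2 <- c(pitch_accuracy = 0.55, tempo = 0.15, loudness = 0.05,
          articulation = 0.30, breathiness = -0.10, resonance = 0.20,
          timbre = 0.10, attack = -0.15, onset_precision = -0.20,
          vibrato = 0.05)
  stats::setNames(list(w1, w2), melodies)
}

#' Simulate participant covariates
#'
#' Age, general music sophistication (Gold-MSI, 18 items on 1-7), the five
#' TIPI personality traits, and the five STOMP-R music-preference
#' dimensions (Mellow, Unpretentious, Sophisticated, Intense,
#' Contemporary), each dimension averaged from simulated 1-7 genre
#' ratings.
#'
#' @param n Number of participants.
#' @return Data frame of numeric covariates, one row per participant.
#' @export
simulate_covariates <- function(n) {
  genre_counts <- c(mellow = 3, unpretentious = 3, sophisticated = 7,
                    intense = 4, contemporary = 4)
  stomp <- vapply(genre_counts, function(k) {
    vapply(seq_len(n), function(i)
      mean(clip(round(stats::rnorm(k, 4, 1.5)), 1, 7)), numeric(1))
  }, numeric(n))
  if (n == 1L) stomp <- matrix(stomp, nrow = 1,
                               dimnames = list(NULL, names(genre_counts)))
  data.frame(
    age = clip(round(stats::rnorm(n, 37, 16)), 18, 80),
    gold_msi = clip(round(stats::rnorm(n, 81, 18)), 18, 126),
    tipi_extraversion = clip(round(stats::rnorm(n, 4.2, 1.3) * 2) / 2, 1, 7),
    tipi_agreeableness = clip(round(stats::rnorm(n, 4.8, 1.1) * 2) / 2, 1, 7),
    tipi_conscientiousness = clip(round(stats::rnorm(n, 5.0, 1.1) * 2) / 2, 1, 7),
    tipi_emotional_stability = clip(round(stats::rnorm(n, 4.5, 1.2) * 2) / 2, 1, 7),
    tipi_openness = clip(round(stats::rnorm(n, 5.2, 1.0) * 2) / 2, 1, 7),
    stomp_mellow = stomp[, "mellow"],
    stomp_unpretentious = stomp[, "unpretentious"],
    stomp_sophisticated = stomp[, "sophisticated"],
    stomp_intense = stomp[, "intense"],
    stomp_contemporary = stomp[, "contemporary"]
  )
}

#' Draw a population of simulated raters
#'
#' Each participant gets: per-scale sensitivities (population mean from
#' [perceptual_scales()], between-participant SD `sens_sd`, with a
#' music-sophistication component: more sophisticated participants are
#' more sensitive), perception noise, an idiosyncratic-impression SD,
#' per-scale liking weight multipliers, an intercept, used subranges of
#' the response scales (different participants use different sections),
#' a test-retest consistency in [0, 1], and simulated covariates.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param sens_sd Between-participant sensitivity SD (default 0.3).
#' @param perception_noise_sd Trial-level perceptual noise SD (default 0.5).
#' @param idio_sd SD of the shared participant-x-stimulus impression
#'   (default 0.7).
#' @param liking_noise_sd Residual liking noise SD (default 0.5).
#' @param msi_sens_slope Effect of standardized music sophistication on
#'   sensitivity magnitude (default 0.3).
#' @param consistency_shape Beta shape parameters for the consistency
#'   distribution (default `c(1.8, 1.8)`).
#' @return List of `participant_params` objects.
#' @export
draw_participant_population <- function(n, seed = 1, sens_sd = 0.3,
                                        perception_noise_sd = 0.5,
                                        idio_sd = 0.7,
                                        liking_noise_sd = 0.5,
                                        msi_sens_slope = 0.3,
                                        consistency_shape = c(1.8, 1.8)) {
  sc <- perceptual_scales()
  with_seed(seed, {
    cov <- simulate_covariates(n)
    z_msi <- as.numeric(scale(cov$gold_msi))
    if (n == 1L) z_msi <- 0
    lapply(seq_len(n), function(i) {
      sens <- stats::setNames(
        sc$sens_mean * (1 + msi_sens_slope * z_msi[i]) +
          stats::rnorm(nrow(sc), 0, sens_sd),
        sc$scale)
      lo_p <- 1 + stats::runif(1, 0, 1.5)
      hi_p <- 7 - stats::runif(1, 0, 1.5)
      lo_l <- 1 + stats::runif(1, 0, 2.5)
      hi_l <- 9 - stats::runif(1, 0, 2.5)
      structure(list(
        participant_id = sprintf("p%03d", i),
        sensitivity = sens,
        perception_noise_sd = perception_noise_sd,
        idio_sd = idio_sd,
        weight_multiplier = stats::setNames(
          stats::rnorm(nrow(sc), 1, 0.2), sc$scale),
        intercept = stats::rnorm(1, 0, 0.4),
        liking_noise_sd = liking_noise_sd,
        scale_use_min = lo_p, scale_use_max = hi_p,
        liking_use_min = lo_l, liking_use_max = hi_l,
        consistency = stats::rbeta(1, consistency_shape[1],
                                   consistency_shape[2]),
        covariates = cov[i, , drop = FALSE]
      ), class = "participant_params")
    })
  })
}

# standardized feature matrix (stimuli x scales) from acoustic truth
scale_feature_matrix <- function(truth) {
  sc <- perceptual_scales()
  z <- vapply(seq_len(nrow(sc)), function(j) {
    v <- truth[[sc$feature[j]]]
    if (is.null(v) || stats::sd(v) == 0) return(rep(0, nrow(truth)))
    as.numeric(scale(v))
  }, numeric(nrow(truth)))
  colnames(z) <- sc$scale
  z
}

# latent percepts for one participant over a set of stimuli:
# sens * feature + common stimulus percept + loading * shared impression
# + noise, censored at +/-2.5. `common` is a stimulus x scale matrix of
# percept components shared by all raters but NOT driven by the measured
# features: stimuli have perceptible attributes beyond the extracted
# acoustics, which is why mean ratings agree across raters far better
# than the acoustic features can explain.
participant_percepts <- function(part, z, idio, common = NULL,
                                 noise_scale = 1) {
  sc <- perceptual_scales()
  n_stim <- nrow(z)
  lat <- vapply(seq_len(nrow(sc)), function(j) {
    part$sensitivity[[sc$scale[j]]] * z[, j] +
      (if (is.null(common)) 0 else common[, j]) +
      sc$idio_loading[j] * idio +
      stats::rnorm(n_stim, 0, part$perception_noise_sd * noise_scale)
  }, numeric(n_stim))
  colnames(lat) <- sc$scale
  clip(lat, -2.5, 2.5)
}

# liking latent from censored percepts
liking_latent <- function(part, percepts, melody, quality, weights) {
  core <- vapply(seq_len(nrow(percepts)), function(i) {
    w <- weights[[melody[i]]] * part$weight_multiplier[names(weights[[melody[i]]])]
    sum(w * percepts[i, names(w)])
  }, numeric(1))
  core + quality + part$intercept +
    stats::rnorm(nrow(percepts), 0, part$liking_noise_sd)
}

latent_to_rating <- function(latent, lo, hi, span) {
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  clip(round(mid + half * latent / span), round(lo), round(hi))
}

#' Simulate the lab experiment's ratings
#'
#' Every participant rates every stimulus on liking (1-9) plus the ten
#' 1-7 perceptual scales of [perceptual_scales()]. Percepts are
#' sensitivity-weighted true features plus a shared idiosyncratic
#' impression plus noise, censored into the participant's used subrange;
#' liking is built only from those percepts (plus singer quality,
#' participant intercept and residual noise) — it never sees the acoustic
#' features directly.
#'
#' @param stimuli A `stimulus_set` (audio rendering not required).
#' @param participants List from [draw_participant_population()].
#' @param seed Integer seed.
#' @param weights Liking weights; default [default_liking_weights()] keyed
#'   by the stimulus set's melody names.
#' @param stim_percept_sd SD of the per-stimulus percept component shared
#'   across raters but unexplained by the measured acoustic features
#'   (default 0.45). This is what lets mean ratings agree across raters
#'   more than the acoustic features can account for.
#' @return Long-format rating data frame: `participant_id`, `stimulus_id`,
#'   `singer_id`, `melody`, `take`, `scale`, `value`, `is_repeat`,
#'   `block`, `presentation_order`.
#' @export
simulate_lab_ratings <- function(stimuli, participants, seed = 1,
                                 weights = NULL, stim_percept_sd = 0.45) {
  if (length(participants) == 0L) stop("empty participant list")
  truth <- stimuli$acoustic_truth
  if (is.null(truth)) stop("stimulus set has no acoustic_truth table")
  if (is.null(weights)) {
    mel <- unique(truth$melody)
    defw <- default_liking_weights()
    weights <- if (all(mel %in% names(defw))) defw[mel] else {
      w <- default_liking_weights(melodies = mel[c(1, min(2, length(mel)))])
      if (length(mel) == 1L) w[1] else w
    }
  }
  z <- scale_feature_matrix(truth)
  sc <- perceptual_scales()
  n_stim <- nrow(truth)
  with_seed(seed, {
    common <- matrix(stats::rnorm(n_stim * nrow(sc), 0, stim_percept_sd),
                     n_stim, nrow(sc))
    out <- lapply(participants, function(part) {
      idio <- stats::rnorm(n_stim, 0, part$idio_sd)
      percepts <- participant_percepts(part, z, idio, common)
      lik <- liking_latent(part, percepts, truth$melody,
                           truth$quality_offset, weights)
      perc_ratings <- vapply(seq_len(nrow(sc)), function(j) {
        latent_to_rating(percepts[, j], part$scale_use_min,
                         part$scale_use_max, span = 2.5)
      }, numeric(n_stim))
      lik_rating <- latent_to_rating(lik, part$liking_use_min,
                                     part$liking_use_max, span = 2)
      ord <- sample.int(n_stim)
      data.frame(
        participant_id = part$participant_id,
        stimulus_id = rep(truth$stimulus_id, nrow(sc) + 1L),
        singer_id = rep(truth$singer_id, nrow(sc) + 1L),
        melody = rep(truth$melody, nrow(sc) + 1L),
        take = rep(truth$take, nrow(sc) + 1L),
        scale = rep(c("liking", sc$scale), each = n_stim),
        value = c(lik_rating, as.numeric(perc_ratings)),
        is_repeat = FALSE,
        block = rep(match(truth$melody, unique(truth$melody)), nrow(sc) + 1L),
        presentation_order = rep(ord, nrow(sc) + 1L),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Simulate the online experiment's liking ratings
#'
#' Each participant rates two blocks (one per melody) of one take from
#' each singer (take chosen at random), followed by repeats of a random
#' subset of the block's trials, flagged `is_repeat`. A repeat rating's
#' latent value correlates with the original at the participant's
#' `consistency` parameter (the latent is shrunk toward the participant's
#' mean and re-noised), which directly parameterizes the test-retest
#' statistic. Liking only, on 1-9.
#'
#' @param stimuli A `stimulus_set` covering at least `block_size` singers.
#' @param participants List from [draw_participant_population()].
#' @param seed Integer seed.
#' @param n_repeats Repeats per block (default 8).
#' @param block_size Singers per block (default: all singers).
#' @param weights,stim_percept_sd See [simulate_lab_ratings()].
#' @return Long-format rating data frame (liking rows only).
#' @export
simulate_online_ratings <- function(stimuli, participants, seed = 1,
                                    n_repeats = 8, block_size = NULL,
                                    weights = NULL, stim_percept_sd = 0.45) {
  if (length(participants) == 0L) stop("empty participant list")
  truth <- stimuli$acoustic_truth
  singers <- unique(truth$singer_id)
  melodies <- unique(truth$melody)
  if (is.null(block_size)) block_size <- length(singers)
  if (length(singers) < block_size) {
    stop("fewer singers (", length(singers), ") than the block size (",
         block_size, ")")
  }
  if (is.null(weights)) {
    defw <- default_liking_weights()
    weights <- if (all(melodies %in% names(defw))) defw[melodies] else {
      w <- default_liking_weights(melodies = melodies[c(1, min(2, length(melodies)))])
      if (length(melodies) == 1L) w[1] else w
    }
  }
  z <- scale_feature_matrix(truth)
  n_sc <- nrow(perceptual_scales())
  with_seed(seed, {
    common <- matrix(stats::rnorm(nrow(truth) * n_sc, 0, stim_percept_sd),
                     nrow(truth), n_sc)
    out <- lapply(participants, function(part) {
      rows <- list()
      ri <- 0L
      for (bi in seq_along(melodies)) {
        mel <- melodies[bi]
        chosen <- vapply(sample(singers, block_size), function(sg) {
          cand <- which(truth$singer_id == sg & truth$melody == mel)
          cand[sample.int(length(cand), 1L)]
        }, integer(1))
        idio <- stats::rnorm(length(chosen), 0, part$idio_sd)
        percepts <- participant_percepts(part, z[chosen, , drop = FALSE],
                                         idio, common[chosen, , drop = FALSE])
        lik <- liking_latent(part, percepts, truth$melody[chosen],
                             truth$quality_offset[chosen], weights)
        # repeats: latent re-drawn with correlation = consistency
        rep_idx <- sample.int(length(chosen), min(n_repeats, length(chosen)))
        rho <- part$consistency
        mu <- mean(lik); sdv <- stats::sd(lik)
        if (!is.finite(sdv) || sdv == 0) sdv <- part$liking_noise_sd
        lik_rep <- mu + rho * (lik[rep_idx] - mu) +
          sqrt(max(0, 1 - rho^2)) * sdv *
            stats::rnorm(length(rep_idx))
        r1 <- latent_to_rating(lik, part$liking_use_min,
                               part$liking_use_max, span = 2)
        r2 <- latent_to_rating(lik_rep, part$liking_use_min,
                               part$liking_use_max, span = 2)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          participant_id = part$participant_id,
          stimulus_id = c(truth$stimulus_id[chosen],
                          truth$stimulus_id[chosen][rep_idx]),
          singer_id = c(truth$singer_id[chosen],
                        truth$singer_id[chosen][rep_idx]),
          melody = mel,
          take = c(truth$take[chosen], truth$take[chosen][rep_idx]),
          scale = "liking",
          value = c(r1, r2),
          is_repeat = rep(c(FALSE, TRUE), c(length(chosen), length(rep_idx))),
          block = bi,
          presentation_order = seq_len(length(chosen) + length(rep_idx)),
          stringsAsFactors = FALSE
        )
      }
      do.call(rbind, rows)
    })
    do.call(rbind, out)
  })
}
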