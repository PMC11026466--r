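# Config-driven end-to-end runs: synthesize stimuli, extract acoustic
# profiles, simulate ratings, compute agreement statistics, and fit the
# model suite, writing all intermediate tables and a JSON summary. A
# single mandatory top-level seed is fanned out deterministically to
# per-stage seeds, so re-running a config reproduces every number.

#' Default pipeline configuration
#'
#' @param seed Master seed (mandatory for any stochastic stage).
#' @param design `"lab"` (liking + 10 perceptual scales, every participant
#'   rates every stimulus) or `"online"` (liking only, one take per singer
#'   per block plus repeat trials).
#' @param n_singers,n_takes,n_participants Design sizes. Defaults: 16
#'   singers x 3 takes x 2 melodies = 96 stimuli; 42 (lab) or 326 (online)
#'   participants.
#' @param sample_rate Audio sample rate in Hz.
#' @param lufs_target Loudness normalization target in LUFS.
#' @param extract_features Extract acoustic profiles from the rendered
#'   audio (`TRUE`) or model on the generator's ground-truth feature table
#'   only (`FALSE`, much faster).
#' @param write_audio Write WAV + label-track files for each stimulus.
#' @param out_dir Output directory (`NULL`: nothing written to disk).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, design = c("lab", "online"),
                            n_singers = 16, n_takes = 3,
                            n_participants = NULL, sample_rate = 22050,
                            lufs_target = -14, extract_features = TRUE,
                            write_audio = FALSE, out_dir = NULL) {
  design <- match.arg(design)
  if (is.null(n_participants)) {
    n_participants <- if (design == "lab") 42L else 326L
  }
  structure(list(seed = seed, design = design, n_singers = n_singers,
                 n_takes = n_takes, n_participants = n_participants,
                 sample_rate = sample_rate, lufs_target = lufs_target,
                 extract_features = extract_features,
                 write_audio = write_audio, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$seed)) stop("pipeline config must set a seed")
  do.call(pipeline_config, obj)
}

#' Run the full pipeline
#'
#' Stages: synthesize stimuli -> (optionally) extract acoustic profiles ->
#' simulate ratings -> normalization, filtering and agreement statistics ->
#' preference model suite. All stage seeds derive from the config's master
#' seed; rerunning the same config reproduces all numbers exactly.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `stimuli`, `profiles` (or `NULL`),
#'   `ratings`, `agreement`, `models`, `individual`, `summary` (flat
#'   named list of headline numbers).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  stimuli <- stage("synth", build_stimulus_set(
    n_singers = config$n_singers, n_takes = config$n_takes,
    seed = derive_seed(config$seed, 10),
    sample_rate = config$sample_rate, lufs_target = config$lufs_target,
    render = config$extract_features || config$write_audio))

  profiles <- NULL
  if (config$extract_features) {
    profiles <- stage("extract", extract_profiles(stimuli))
  }
  acoustic <- if (is.null(profiles)) stimuli$acoustic_truth else profiles
  acoustic_terms <- if (is.null(profiles)) {
    c("pitch_dev_cents", "bpm", "formant_band_gain_db", "breath_noise_db",
      "spectral_slope_db_oct", "gap_frac", "vibrato_extent_cents",
      "vibrato_rate_hz", "jitter_pct")
  } else {
    c("pitch_interval_deviation", "bpm", "energy_ratio", "hnr35",
      "vibrato_rate", "vibrato_extent", "jitter_local", "shimmer_local",
      "cpp")
  }

  participants <- stage("participants", draw_participant_population(
    config$n_participants, seed = derive_seed(config$seed, 20)))
  ratings <- stage("ratings", if (config$design == "lab") {
    simulate_lab_ratings(stimuli, participants,
                         seed = derive_seed(config$seed, 30))
  } else {
    simulate_online_ratings(stimuli, participants,
                            seed = derive_seed(config$seed, 30))
  })

  flt <- stage("reliability", filter_participants(ratings))
  norm <- normalize_within_participant(flt$ratings)
  agreement <- stage("agreement", {
    scales <- unique(norm$scale)
    stats::setNames(lapply(scales, function(s) {
      rep_ <- tryCatch(agreement_report(norm, s), error = function(e)
        list(scale = s, alpha_k = NA_real_, icc2_1 = NA_real_,
             mm1_overall = NA_real_, n_raters = NA_integer_,
             n_items = NA_integer_))
      rep_$mm1_individual <- NULL  # distributions are recoverable via mm1()
      rep_
    }), scales)
  })

  models <- stage("models", build_model_suite(norm, acoustic,
                                              acoustic_terms = acoustic_terms))

  individual <- NULL
  if (config$design == "lab") {
    individual <- stage("individual", {
      wide <- model_frame(norm, acoustic)
      acou <- fit_individual_models(wide, acoustic_terms,
                                    model_kind = "acoustic")
      perc <- fit_individual_models(wide, perceptual_scales()$scale,
                                    model_kind = "perceptual")
      cmp <- tryCatch(compare_individual_fits(acou, perc),
                      error = function(e) NULL)  # under-determined design
      list(acoustic = acou, perceptual = perc, comparison = cmp)
    })
  }

  summary <- list(
    seed = config$seed, design = config$design,
    n_stimuli = nrow(stimuli$acoustic_truth),
    n_participants = length(participants),
    n_excluded_participants = length(flt$excluded),
    alpha_liking = agreement$liking$alpha_k,
    marginal_r2_acoustic = models$acoustic$normalized$marginal_r2,
    conditional_r2_acoustic = models$acoustic$normalized$conditional_r2
  )
  if (!is.null(models$perceptual)) {
    summary$marginal_r2_perceptual <- models$perceptual$normalized$marginal_r2
    summary$conditional_r2_perceptual <-
      models$perceptual$normalized$conditional_r2
  }
  if (!is.null(individual) && !is.null(individual$comparison)) {
    summary$individual_t <- individual$comparison$t
    summary$individual_p <- individual$comparison$p
  }

  result <- structure(
    list(config = config, stimuli = stimuli, profiles = profiles,
         ratings = ratings, agreement = agreement, models = models,
         individual = individual, summary = summary),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' Write pipeline outputs to disk
#'
#' Writes the acoustic truth/profile CSVs, ratings CSV, agreement and
#' summary JSONs, and optionally per-stimulus WAV + label tracks.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$stimuli$acoustic_truth,
                   file.path(out_dir, "acoustic_truth.csv"),
                   row.names = FALSE)
  if (!is.null(result$profiles)) {
    write_profiles(result$profiles, file.path(out_dir, "profiles.csv"))
  }
  write_ratings(result$ratings, file.path(out_dir, "ratings.csv"))
  agr <- lapply(result$agreement, function(a)
    a[c("scale", "alpha_k", "icc2_1", "mm1_overall", "n_raters", "n_items")])
  jsonlite::write_json(agr, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(result$config$write_audio)) {
    audio_dir <- file.path(out_dir, "audio")
    dir.create(audio_dir, showWarnings = FALSE)
    for (p in result$stimuli$performances) {
      if (is.null(p)) next
      write_wav(p$samples, file.path(audio_dir, paste0(p$stimulus_id, ".wav")),
                p$sample_rate)
      write_labels(p$labels,
                   file.path(audio_dir, paste0(p$stimulus_id, ".txt")))
    }
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.numeric(v)) format(signif(v, 4)) else as.character(v)))
  }
  invisible(x)
}
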