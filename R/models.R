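# Preference models: linear mixed-effects models of liking with
# marginal/conditional R2 variance decomposition (Nakagawa-style, computed
# here rather than delegated), likelihood ratio tests, per-participant
# regressions ("individual level of prediction"), acoustic sensitivities,
# and the participant-characteristics stepwise regression. Model fitting
# itself delegates to lme4.

#' Standardize predictors
#'
#' Mean-centers and scales each term by one standard deviation (sample SD,
#' n - 1 denominator) before model fitting.
#'
#' @param data Data frame.
#' @param terms Character vector of numeric column names.
#' @return The data frame with the named columns standardized.
#' @export
standardize_predictors <- function(data, terms) {
  for (tm in terms) {
    v <- data[[tm]]
    if (!is.numeric(v)) stop("term is not numeric: ", tm)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero-variance predictor: ", tm)
    data[[tm]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  data
}

#' Specify a mixed preference model
#'
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms (feature
#'   names, `"melody"`, and interaction terms like
#'   `"melody:articulation"`).
#' @param random_intercepts Grouping columns receiving random intercepts
#'   (default participant, singer, and stimulus nested in singer — the
#'   stimulus identifier is unique within singer, so a plain stimulus
#'   intercept realizes the nesting).
#' @param melody_slope_on Optional grouping column receiving a random
#'   melody slope (e.g. `"participant_id"`), as in the perceptual model.
#' @param standardize Standardize numeric fixed terms before fitting?
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed_terms = character(),
                       random_intercepts = c("participant_id", "singer_id",
                                             "stimulus_id"),
                       melody_slope_on = NULL, standardize = TRUE) {
  structure(list(response = response, fixed_terms = fixed_terms,
                 random_intercepts = random_intercepts,
                 melody_slope_on = melody_slope_on,
                 standardize = standardize),
            class = "model_spec")
}

spec_formula <- function(spec) {
  fixed <- if (length(spec$fixed_terms) == 0L) "1"
    else paste(spec$fixed_terms, collapse = " + ")
  rand <- vapply(spec$random_intercepts, function(g)
    sprintf("(1 | %s)", g), character(1))
  if (!is.null(spec$melody_slope_on)) {
    g <- spec$melody_slope_on
    rand <- rand[spec$random_intercepts != g]
    rand <- c(rand, sprintf("(1 + melody | %s)", g))
  }
  stats::as.formula(paste(spec$response, "~", fixed, "+",
                          paste(rand, collapse = " + ")))
}

# variance attributable to the random terms (Johnson 2014 extension of
# Nakagawa & Schielzeth): for each term, the mean over rows of z' V z,
# using the fit's own random-effect model matrices; for intercept-only
# terms this reduces to the term's variance component
random_variances <- function(fit) {
  vc <- lme4::VarCorr(fit)
  mml <- lme4::getME(fit, "mmList")
  vapply(seq_along(vc), function(k) {
    V <- as.matrix(vc[[k]])
    if (identical(dim(V), c(1L, 1L))) return(as.numeric(V))
    mm <- mml[[k]][, colnames(V), drop = FALSE]
    mean(rowSums((mm %*% V) * mm))
  }, numeric(1)) |> stats::setNames(names(vc))
}

#' Fit a mixed preference model
#'
#' Fits the model by (RE)ML via `lme4::lmer` and computes the variance
#' decomposition in-house: `var_fixed` is the variance of the fixed-effect
#' linear predictor over the data; each random term contributes its
#' variance (for random slopes, the average row-wise `z' V z`);
#' `marginal R2 = var_fixed / (var_fixed + sum var_random + var_residual)`
#' and the conditional R2 adds the random variance to the numerator.
#' Predictor collinearity is screened by VIF; a fit with any VIF >= 5 is
#' refused unless `vif_action` is downgraded. Singular random-effect fits
#' are reported with a warning rather than refused.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with all referenced columns.
#' @param reml Fit by REML (default `TRUE`); use `FALSE` (ML) for fits
#'   entering a likelihood ratio test.
#' @param vif_action `"error"` (default), `"warn"` or `"ignore"` when any
#'   VIF >= 5.
#' @return A `mixed_fit` object: coefficients with Wald 95% CIs, variance
#'   components, marginal/conditional R2, log-likelihood, VIFs, and the
#'   underlying `lmerMod` fit.
#' @export
fit_mixed <- function(spec, data, reml = TRUE,
                      vif_action = c("error", "warn", "ignore")) {
  vif_action <- match.arg(vif_action)
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(c(spec$response, spec$random_intercepts),
                  names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  num_terms <- spec$fixed_terms[
    vapply(spec$fixed_terms, function(tm)
      tm %in% names(data) && is.numeric(data[[tm]]), logical(1))]
  if (spec$standardize && length(num_terms)) {
    data <- standardize_predictors(data, num_terms)
  }
  for (g in spec$random_intercepts) data[[g]] <- factor(data[[g]])
  # grouping factors with a single sampled level cannot carry a random
  # intercept; drop them rather than refuse the whole fit
  droppable <- vapply(spec$random_intercepts, function(g)
    nlevels(data[[g]]) < 2L, logical(1))
  if (any(droppable)) {
    warning("dropping random intercepts with < 2 levels: ",
            paste(spec$random_intercepts[droppable], collapse = ", "))
    spec$random_intercepts <- spec$random_intercepts[!droppable]
  }
  if (!is.null(spec$melody_slope_on) &&
      (!spec$melody_slope_on %in% names(data) ||
       nlevels(factor(data[[spec$melody_slope_on]])) < 2L)) {
    spec$melody_slope_on <- NULL
  }
  if (length(spec$random_intercepts) == 0L && is.null(spec$melody_slope_on)) {
    stop("no random-effect grouping factor has 2 or more levels")
  }
  fit <- lme4::lmer(spec_formula(spec), data = data, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  X <- stats::model.matrix(fit)
  beta <- lme4::fixef(fit)
  var_fixed <- if (ncol(X) > 1L) stats::var(as.numeric(X %*% beta)) else 0
  var_random <- random_variances(fit)
  var_residual <- stats::sigma(fit)^2
  tot <- var_fixed + sum(var_random) + var_residual
  vifs <- NULL
  if (ncol(X) > 2L) {
    Xp <- X[, -1, drop = FALSE]
    keep <- apply(Xp, 2, stats::sd) > 0
    Xp <- Xp[, keep, drop = FALSE]
    if (ncol(Xp) > 1L) {
      cmat <- stats::cor(Xp)
      inv <- tryCatch(solve(cmat), error = function(e) NULL)
      if (!is.null(inv)) vifs <- diag(inv)
    }
  }
  if (!is.null(vifs) && any(vifs >= 5)) {
    msg <- paste0("VIF >= 5 for: ",
                  paste(names(vifs)[vifs >= 5], collapse = ", "))
    if (vif_action == "error") stop(msg, " (downgrade vif_action to override)")
    if (vif_action == "warn") warning(msg)
  }
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lower = unname(beta - 1.96 * se),
                      ci_upper = unname(beta + 1.96 * se))
  singular <- lme4::isSingular(fit)
  if (singular) warning("singular random-effects fit (variance component ",
                        "on the boundary); components reported as is")
  ll <- stats::logLik(fit)
  structure(list(
    fit = fit, spec = spec, coefficients = coefs,
    var_fixed = var_fixed, var_random = var_random,
    var_residual = var_residual,
    marginal_r2 = var_fixed / tot,
    conditional_r2 = (var_fixed + sum(var_random)) / tot,
    log_likelihood = as.numeric(ll), df = attr(ll, "df"),
    reml = reml, vif = vifs, singular = singular,
    n_obs = nrow(data)
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s; marginal R2 = %.3f, conditional R2 = %.3f%s\n",
              deparse(spec_formula(x$spec)), x$marginal_r2, x$conditional_r2,
              if (x$singular) " (singular)" else ""))
  invisible(x)
}

#' Likelihood ratio test between nested mixed models
#'
#' `chi2 = 2 * (logLik(full) - logLik(null))` on `df` = difference in
#' parameter counts. Both fits must be ML fits of nested models on the
#' same data.
#'
#' @param null,full `mixed_fit` objects (ML, `reml = FALSE`).
#' @return List `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(null, full) {
  stopifnot(inherits(null, "mixed_fit"), inherits(full, "mixed_fit"))
  if (null$reml || full$reml) {
    stop("LRT requires ML fits (refit with reml = FALSE)")
  }
  if (null$n_obs != full$n_obs) stop("models were fit on different data")
  if (!all(null$spec$fixed_terms %in% full$spec$fixed_terms)) {
    stop("models are not nested: null has terms absent from the full model")
  }
  df <- full$df - null$df
  if (df < 0) stop("full model has fewer parameters than the null")
  chi2 <- max(0, 2 * (full$log_likelihood - null$log_likelihood))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Per-participant regression models
#'
#' Fits an ordinary least-squares model of the response on the given
#' predictors separately for each participant, returning each
#' participant's adjusted R2 ("individual level of prediction") and its
#' Fisher z transform. Participants with fewer than
#' `min_obs_per_predictor` observations per predictor get `NA`.
#'
#' @param data One row per participant x stimulus, with a
#'   `participant_id` column, the response and all predictors.
#' @param predictors Character vector of predictor columns.
#' @param response Response column (default `"liking"`).
#' @param model_kind Label stored with the results (e.g. `"acoustic"`).
#' @param min_obs_per_predictor Minimum observations per predictor
#'   (default 2).
#' @return Data frame `participant_id`, `model_kind`, `adjusted_r2`,
#'   `fisher_z`, `n_obs`.
#' @export
fit_individual_models <- function(data, predictors, response = "liking",
                                  model_kind = "model",
                                  min_obs_per_predictor = 2) {
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  ids <- unique(data$participant_id)
  res <- lapply(ids, function(p) {
    d <- data[data$participant_id == p, ]
    ar2 <- NA_real_
    if (nrow(d) >= min_obs_per_predictor * length(predictors) + 2 &&
        stats::sd(d[[response]]) > 0) {
      m <- stats::lm(fml, data = d)
      ar2 <- summary(m)$adj.r.squared
    }
    data.frame(participant_id = p, model_kind = model_kind,
               adjusted_r2 = ar2,
               fisher_z = if (is.na(ar2)) NA_real_ else fisher_z(ar2),
               n_obs = nrow(d))
  })
  do.call(rbind, res)
}

#' Compare individual acoustic vs perceptual fits
#'
#' Paired t-test on per-participant adjusted R2 values of the two model
#' kinds (acoustic minus perceptual, so a negative t means the perceptual
#' model predicts better).
#'
#' @param acoustic,perceptual Data frames from [fit_individual_models()].
#' @return List `t`, `df`, `p`, `mean_acoustic`, `mean_perceptual`,
#'   `mean_diff`, `n`.
#' @export
compare_individual_fits <- function(acoustic, perceptual) {
  m <- merge(acoustic[, c("participant_id", "adjusted_r2")],
             perceptual[, c("participant_id", "adjusted_r2")],
             by = "participant_id", suffixes = c("_acoustic", "_perceptual"))
  m <- m[stats::complete.cases(m), ]
  tt <- stats::t.test(m$adjusted_r2_acoustic, m$adjusted_r2_perceptual,
                      paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_acoustic = mean(m$adjusted_r2_acoustic),
       mean_perceptual = mean(m$adjusted_r2_perceptual),
       mean_diff = mean(m$adjusted_r2_acoustic - m$adjusted_r2_perceptual),
       n = nrow(m))
}

#' Default acoustic-sensitivity feature/scale pairs
#'
#' The five correlations between an acoustic measurement and the
#' perceptual scale it most directly relates to.
#'
#' @param feature_source `"profile"` for extracted acoustic profiles,
#'   `"truth"` for the simulator's ground-truth table.
#' @return Data frame `feature`, `scale`.
#' @export
sensitivity_pairs <- function(feature_source = c("profile", "truth")) {
  feature_source <- match.arg(feature_source)
  if (feature_source == "profile") {
    data.frame(
      feature = c("pitch_interval_deviation", "bpm", "loudness_lufs",
                  "vibrato_extent", "cpp"),
      scale = c("pitch_accuracy", "tempo", "loudness", "vibrato",
                "breathiness"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      feature = c("pitch_dev_cents", "bpm", "spectral_slope_db_oct",
                  "vibrato_extent_cents", "breath_noise_db"),
      scale = c("pitch_accuracy", "tempo", "loudness", "vibrato",
                "breathiness"),
      stringsAsFactors = FALSE)
  }
}

#' Acoustic sensitivity profiles
#'
#' For each participant, the Pearson correlation between their ratings on
#' each scale and the corresponding acoustic measurement over the stimuli
#' they rated ("acoustic sensitivity"), the Fisher z transform of each,
#' and the mean z across pairs. Pairs where the participant's ratings (or
#' the feature) are constant yield `NA`.
#'
#' @param ratings Long-format rating table (perceptual scales).
#' @param acoustic Data frame with `stimulus_id` plus the feature columns.
#' @param pairs Data frame `feature`, `scale`; default
#'   [sensitivity_pairs()] matched to the available columns.
#' @param use_normalized Correlate normalized (default) or raw ratings.
#' @return Data frame: `participant_id`, per-pair `r_<scale>` and
#'   `z_<scale>` columns, and `mean_sensitivity`.
#' @export
acoustic_sensitivity <- function(ratings, acoustic, pairs = NULL,
                                 use_normalized = TRUE) {
  if (is.null(pairs)) {
    pairs <- sensitivity_pairs("profile")
    if (!all(pairs$feature %in% names(acoustic))) {
      pairs <- sensitivity_pairs("truth")
    }
  }
  miss <- setdiff(pairs$feature, names(acoustic))
  if (length(miss)) stop("acoustic table lacks features: ",
                         paste(miss, collapse = ", "))
  col <- if (use_normalized && "normalized_value" %in% names(ratings))
    "normalized_value" else "value"
  if ("is_repeat" %in% names(ratings)) ratings <- ratings[!ratings$is_repeat, ]
  ids <- unique(ratings$participant_id)
  res <- lapply(ids, function(p) {
    row <- list(participant_id = p)
    zs <- numeric(0)
    for (k in seq_len(nrow(pairs))) {
      rp <- ratings[ratings$participant_id == p &
                      ratings$scale == pairs$scale[k], ]
      m <- merge(rp[, c("stimulus_id", col)],
                 acoustic[, c("stimulus_id", pairs$feature[k])],
                 by = "stimulus_id")
      r <- if (nrow(m) < 3L || stats::sd(m[[col]]) == 0 ||
               stats::sd(m[[pairs$feature[k]]]) == 0) NA_real_
        else stats::cor(m[[col]], m[[pairs$feature[k]]])
      row[[paste0("r_", pairs$scale[k])]] <- r
      z <- if (is.na(r)) NA_real_ else fisher_z(r)
      row[[paste0("z_", pairs$scale[k])]] <- z
      zs <- c(zs, z)
    }
    row$mean_sensitivity <- mean(zs, na.rm = TRUE)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Participant-characteristics regression with stepwise reduction
#'
#' Regresses the (Fisher z-transformed) individual level of prediction on
#' participant covariates, then reduces the model by backward stepwise
#' selection on AIC (`stats::step`): terms are dropped while dropping
#' lowers the AIC.
#'
#' @param data One row per participant: the response plus candidate
#'   predictor columns.
#' @param response Response column name.
#' @param predictors Character vector of candidate predictors (default:
#'   every other numeric column).
#' @return List `full` (lm), `reduced` (lm), `retained` (character),
#'   `aic_full`, `aic_reduced`.
#' @export
characteristics_regression <- function(data, response,
                                       predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          response)
  }
  data <- data[stats::complete.cases(data[, c(response, predictors)]), ]
  if (nrow(data) < 2 * max(2L, length(predictors) %/% 3L)) {
    stop("too few participants for the candidate predictor set")
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  full <- stats::lm(fml, data = data)
  reduced <- stats::step(full, direction = "backward", trace = 0)
  list(full = full, reduced = reduced,
       retained = attr(stats::terms(reduced), "term.labels"),
       aic_full = stats::AIC(full), aic_reduced = stats::AIC(reduced))
}

#' Wide per-trial table for modeling
#'
#' Pivots a long rating table to one row per participant x stimulus with a
#' liking column, one column per perceptual scale (if present), and the
#' design columns; then merges an acoustic feature table by stimulus.
#' Repeat trials are dropped.
#'
#' @param ratings Long-format rating table.
#' @param acoustic Optional acoustic table keyed by `stimulus_id`.
#' @param use_normalized Use normalized values where available.
#' @return Wide data frame.
#' @export
model_frame <- function(ratings, acoustic = NULL, use_normalized = TRUE) {
  if ("is_repeat" %in% names(ratings)) ratings <- ratings[!ratings$is_repeat, ]
  col <- if (use_normalized && "normalized_value" %in% names(ratings))
    "normalized_value" else "value"
  keys <- c("participant_id", "stimulus_id", "singer_id", "melody", "take")
  keys <- intersect(keys, names(ratings))
  wide <- stats::reshape(
    ratings[, c(keys, "scale", col)],
    idvar = keys, timevar = "scale", direction = "wide")
  names(wide) <- sub(paste0("^", col, "\\."), "", names(wide))
  if (!is.null(acoustic)) {
    feat_cols <- setdiff(names(acoustic),
                         c("singer_id", "melody", "take"))
    wide <- merge(wide, acoustic[, feat_cols], by = "stimulus_id")
  }
  wide
}

#' Fit the null / acoustic / perceptual model suite
#'
#' Fits the three preference models on both raw and within-participant
#' normalized liking: the null model (random intercepts only), the
#' acoustic model (stimulus-level acoustic features as fixed effects), and
#' — when perceptual scales are present — the perceptual model (the ten
#' perceptual ratings, melody, and melody interactions with articulation,
#' pitch accuracy, resonance and vibrato, plus a random melody slope over
#' participants). If the table contains repeat trials, the acoustic model
#' is also refit on the consistent-participant subset (test-retest
#' r > 0.5). Likelihood ratio tests of each model against the null use ML
#' refits.
#'
#' @param ratings Long-format rating table (will be normalized/filtered).
#' @param acoustic Acoustic feature table keyed by `stimulus_id`.
#' @param acoustic_terms Fixed-effect feature columns for the acoustic
#'   model (default: the nine extracted-profile features).
#' @param perceptual_terms Perceptual scale columns; default the ten
#'   scales of [perceptual_scales()] when present in the ratings.
#' @param vif_action Passed to [fit_mixed()] (default `"warn"`).
#' @return List with elements `null`, `acoustic`, `perceptual` (each a
#'   list with `raw` and `normalized` `mixed_fit`s), `lrt_acoustic`,
#'   `lrt_perceptual`, optional `acoustic_consistent`, and a `comparison`
#'   data frame of R2 values.
#' @export
build_model_suite <- function(ratings, acoustic,
                              acoustic_terms = c("pitch_interval_deviation",
                                                 "bpm", "energy_ratio",
                                                 "hnr35", "vibrato_rate",
                                                 "vibrato_extent",
                                                 "jitter_local",
                                                 "shimmer_local", "cpp"),
                              perceptual_terms = NULL,
                              vif_action = "warn") {
  flt <- filter_participants(ratings)
  ratings <- normalize_within_participant(flt$ratings)
  have_scales <- setdiff(unique(ratings$scale), "liking")
  if (is.null(perceptual_terms)) {
    perceptual_terms <- intersect(perceptual_scales()$scale, have_scales)
  }
  wide <- model_frame(ratings, acoustic, use_normalized = TRUE)
  wide_raw <- model_frame(ratings, acoustic, use_normalized = FALSE)

  fit_pair <- function(spec_builder) {
    list(normalized = fit_mixed(spec_builder("liking"), wide,
                                vif_action = vif_action),
         raw = fit_mixed(spec_builder("liking"), wide_raw,
                         vif_action = vif_action))
  }
  null_spec <- function(resp) model_spec(resp, character())
  acou_spec <- function(resp) model_spec(resp, acoustic_terms)
  res <- list(null = fit_pair(null_spec), acoustic = fit_pair(acou_spec))

  # LRT on ML refits
  null_ml <- fit_mixed(null_spec("liking"), wide, reml = FALSE)
  acou_ml <- fit_mixed(acou_spec("liking"), wide, reml = FALSE,
                       vif_action = vif_action)
  res$lrt_acoustic <- likelihood_ratio_test(null_ml, acou_ml)

  if (length(perceptual_terms) > 0L) {
    inter <- intersect(c("articulation", "pitch_accuracy", "resonance",
                         "vibrato"), perceptual_terms)
    # fall back on progressively simpler structures when the design is
    # too small to estimate the full one (slope, then interactions)
    candidates <- list(
      list(terms = c(perceptual_terms, "melody", paste0("melody:", inter)),
           slope = "participant_id"),
      list(terms = c(perceptual_terms, "melody", paste0("melody:", inter)),
           slope = NULL),
      list(terms = perceptual_terms, slope = NULL))
    for (cand in candidates) {
      perc_spec <- local({
        cnd <- cand
        function(resp) model_spec(resp, cnd$terms,
                                  melody_slope_on = cnd$slope)
      })
      ok <- tryCatch({
        res$perceptual <- fit_pair(perc_spec)
        perc_ml <- fit_mixed(perc_spec("liking"), wide, reml = FALSE,
                             vif_action = vif_action)
        null_slope_ml <- fit_mixed(
          model_spec("liking", character(),
                     melody_slope_on = cand$slope),
          wide, reml = FALSE)
        res$lrt_perceptual <- likelihood_ratio_test(null_slope_ml, perc_ml)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
    }
    if (!ok) warning("perceptual model could not be estimated on this design")
  }

  if ("is_repeat" %in% names(ratings) && any(ratings$is_repeat)) {
    tr <- test_retest(ratings)
    keep <- tr$participant_id[tr$consistent]
    if (length(keep) >= 3L) {
      wide_c <- wide[wide$participant_id %in% keep, ]
      res$acoustic_consistent <- fit_mixed(acou_spec("liking"), wide_c,
                                           vif_action = vif_action)
      res$test_retest <- tr
    }
  }

  rows <- lapply(names(res)[names(res) %in% c("null", "acoustic", "perceptual")],
                 function(nm) {
    data.frame(model = nm,
               marginal_r2_normalized = res[[nm]]$normalized$marginal_r2,
               conditional_r2_normalized = res[[nm]]$normalized$conditional_r2,
               marginal_r2_raw = res[[nm]]$raw$marginal_r2,
               conditional_r2_raw = res[[nm]]$raw$conditional_r2)
  })
  res$comparison <- do.call(rbind, rows)
  res
}
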