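# Rating normalization, participant filtering, and agreement/consistency
# statistics: within-participant 0-1 normalization, test-retest
# correlation, Krippendorff's alpha (interval), ICC(2,1), and
# mean-minus-one (MM1) leave-one-out agreement.

#' Normalize ratings within each participant
#'
#' Rescales each participant's ratings on each scale to [0, 1] by
#' `(x - min) / (max - min)`, accounting for different rating strategies
#' (different sections of the response scale being used by individual
#' participants). Participants who are constant on a scale get `NA`
#' normalized values there (they are caught by [filter_participants()]).
#'
#' @param ratings Long-format rating data frame with columns
#'   `participant_id`, `scale`, `value`.
#' @return The data frame with a `normalized_value` column added/replaced.
#' @export
normalize_within_participant <- function(ratings) {
  stopifnot(all(c("participant_id", "scale", "value") %in% names(ratings)))
  key <- interaction(ratings$participant_id, ratings$scale, drop = TRUE)
  mins <- stats::ave(ratings$value, key, FUN = min)
  maxs <- stats::ave(ratings$value, key, FUN = max)
  rng <- maxs - mins
  ratings$normalized_value <- ifelse(rng > 0, (ratings$value - mins) / rng,
                                     NA_real_)
  ratings
}

#' Filter out degenerate raters
#'
#' Removes participants whose liking ratings show (near-)zero variance:
#' fewer than `min_distinct` distinct raw values over all their liking
#' trials (default 3, which excludes both an all-"1" rater and a rater
#' using only "8" and "9").
#'
#' @param ratings Long-format rating data frame.
#' @param scale_name Scale on which degeneracy is judged (default
#'   `"liking"`).
#' @param min_distinct Minimum number of distinct raw values required.
#' @return List with `ratings` (filtered) and `excluded` (character vector
#'   of excluded participant ids).
#' @export
filter_participants <- function(ratings, scale_name = "liking",
                                min_distinct = 3) {
  lik <- ratings[ratings$scale == scale_name, ]
  # the threshold cannot exceed the number of trials a participant has
  # (small designs would otherwise exclude everyone)
  degenerate <- tapply(lik$value, lik$participant_id, function(v)
    length(unique(v)) < min(min_distinct, length(v)))
  excluded <- names(degenerate)[degenerate]
  list(ratings = ratings[!(ratings$participant_id %in% excluded), ],
       excluded = excluded)
}

#' Test-retest consistency per participant
#'
#' Pearson correlation between first and repeated presentations of the
#' same stimuli within each participant (repeat trials flagged by the
#' `is_repeat` column). Participants with correlations above `threshold`
#' form the "consistent" subset.
#'
#' @param ratings Long-format rating table with `is_repeat`,
#'   `stimulus_id`, `participant_id`, `scale`, `value`.
#' @param scale_name Scale to analyze (default `"liking"`).
#' @param threshold Consistency threshold (default 0.5).
#' @return Data frame `participant_id`, `r`, `n_pairs`, `consistent`;
#'   participants with fewer than 3 repeat pairs get `NA`.
#' @export
test_retest <- function(ratings, scale_name = "liking", threshold = 0.5) {
  r <- ratings[ratings$scale == scale_name, ]
  if (!"is_repeat" %in% names(r) || !any(r$is_repeat)) {
    stop("no repeat trials present in this rating table")
  }
  ids <- unique(r$participant_id)
  res <- lapply(ids, function(p) {
    rp <- r[r$participant_id == p, ]
    firsts <- rp[!rp$is_repeat, ]
    reps <- rp[rp$is_repeat, ]
    m <- merge(firsts[, c("stimulus_id", "value")],
               reps[, c("stimulus_id", "value")],
               by = "stimulus_id", suffixes = c("_first", "_second"))
    rr <- if (nrow(m) < 3L || stats::sd(m$value_first) == 0 ||
              stats::sd(m$value_second) == 0) NA_real_
      else stats::cor(m$value_first, m$value_second)
    data.frame(participant_id = p, r = rr, n_pairs = nrow(m))
  })
  out <- do.call(rbind, res)
  out$consistent <- !is.na(out$r) & out$r > threshold
  out
}

#' Krippendorff's alpha (interval level)
#'
#' Chance-corrected inter-rater agreement `alpha = 1 - D_o / D_e` with the
#' squared interval difference metric, computed over all pairable values:
#' within each item, every ordered pair of available ratings contributes to
#' the observed disagreement (weighted by `1 / (m_u - 1)` for an item with
#' `m_u` ratings); the expected disagreement pools all pairable values
#' across items. Missing entries are allowed; items with fewer than two
#' ratings are unpairable and ignored. `alpha = 1` indicates perfect
#' agreement, `alpha = 0` agreement at chance level.
#'
#' @param ratings Numeric matrix, raters in rows, items in columns; `NA`
#'   for missing.
#' @return Alpha (scalar, `<= 1`).
#' @export
krippendorff_alpha <- function(ratings) {
  stopifnot(is.matrix(ratings))
  if (nrow(ratings) < 2L || ncol(ratings) < 2L) {
    stop("need at least 2 raters and 2 items")
  }
  m_u <- colSums(!is.na(ratings))
  pairable <- m_u >= 2L
  if (!any(pairable)) stop("no pairable values (every item has < 2 ratings)")
  n <- sum(m_u[pairable])
  # observed disagreement: within-item ordered pairs / (m_u - 1)
  d_o_sum <- 0
  for (u in which(pairable)) {
    x <- ratings[!is.na(ratings[, u]), u]
    m <- length(x)
    ss <- (2 * m * sum(x^2) - 2 * sum(x)^2)  # sum over ordered pairs of (xi-xj)^2
    d_o_sum <- d_o_sum + ss / (m - 1)
  }
  d_o <- d_o_sum / n
  # expected disagreement: ordered pairs over all pooled pairable values
  xs <- unlist(lapply(which(pairable), function(u)
    ratings[!is.na(ratings[, u]), u]), use.names = FALSE)
  d_e <- (2 * n * sum(xs^2) - 2 * sum(xs)^2) / (n * (n - 1))
  if (d_e == 0) {
    # all values identical: no disagreement is possible at all
    return(1)
  }
  1 - d_o / d_e
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)` with `MSR` the
#' between-items mean square, `MSC` the between-raters mean square, `MSE`
#' the residual mean square, `n` items and `k` raters. Items with missing
#' ratings are listwise-deleted.
#'
#' @param ratings Numeric matrix, raters in rows, items in columns.
#' @return ICC(2,1) (scalar, `<= 1`).
#' @export
icc2_1 <- function(ratings) {
  stopifnot(is.matrix(ratings))
  if (nrow(ratings) < 2L) stop("need at least 2 raters")
  complete <- colSums(is.na(ratings)) == 0L
  m <- ratings[, complete, drop = FALSE]
  k <- nrow(m)   # raters
  n <- ncol(m)   # items
  if (n < 2L) stop("fewer than 2 complete items after listwise deletion")
  grand <- mean(m)
  item_means <- colMeans(m)
  rater_means <- rowMeans(m)
  ssr <- k * sum((item_means - grand)^2)        # between items (targets)
  ssc <- n * sum((rater_means - grand)^2)       # between raters (judges)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(denom) || denom == 0) stop("ICC undefined (constant matrix)")
  (msr - mse) / denom
}

#' Mean-minus-one (MM1) agreement
#'
#' For each participant, the Pearson correlation between their ratings and
#' the average ratings of all other participants; individual correlations
#' are Fisher z-transformed (with `|r|` clamped just below 1 to keep the
#' pooling finite), averaged, and transformed back to an overall r.
#' Measures how much each individual agrees with the group.
#'
#' @param ratings Numeric matrix, raters in rows, items in columns; `NA`
#'   allowed (pairwise deletion within each participant's correlation).
#' @return List with `overall` (pooled r), and `individual`: data frame
#'   `participant`, `r`, `z`. Constant participants get `NA`.
#' @export
mm1 <- function(ratings) {
  stopifnot(is.matrix(ratings))
  if (nrow(ratings) < 3L) stop("need at least 3 raters for MM1")
  ids <- rownames(ratings)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ratings)))
  res <- lapply(seq_len(nrow(ratings)), function(i) {
    others <- colMeans(ratings[-i, , drop = FALSE], na.rm = TRUE)
    self <- ratings[i, ]
    okv <- !is.na(self) & !is.na(others)
    r <- if (sum(okv) < 3L || stats::sd(self[okv]) == 0 ||
             stats::sd(others[okv]) == 0) NA_real_
      else stats::cor(self[okv], others[okv])
    data.frame(participant = ids[i], r = r,
               z = if (is.na(r)) NA_real_ else fisher_z(r))
  })
  ind <- do.call(rbind, res)
  list(overall = tanh(mean(ind$z, na.rm = TRUE)), individual = ind)
}

#' Agreement report for one scale
#'
#' Computes Krippendorff's alpha, ICC(2,1) and MM1 for one scale of a
#' long-format rating table (non-repeat trials only), using either raw or
#' within-participant normalized values.
#'
#' @param ratings Long-format rating table.
#' @param scale_name Scale to analyze.
#' @param use_normalized Use the `normalized_value` column (default) or raw
#'   `value`.
#' @return List with `scale`, `alpha_k`, `icc2_1`, `mm1_overall`,
#'   `mm1_individual`, `n_raters`, `n_items`.
#' @export
agreement_report <- function(ratings, scale_name = "liking",
                             use_normalized = TRUE) {
  r <- ratings[ratings$scale == scale_name, ]
  if ("is_repeat" %in% names(r)) r <- r[!r$is_repeat, ]
  col <- if (use_normalized && "normalized_value" %in% names(r))
    "normalized_value" else "value"
  m <- rating_matrix(r, value_col = col)
  mm <- tryCatch(mm1(m), error = function(e)
    list(overall = NA_real_, individual = NULL))
  list(scale = scale_name,
       alpha_k = krippendorff_alpha(m),
       icc2_1 = tryCatch(icc2_1(m), error = function(e) NA_real_),
       mm1_overall = mm$overall,
       mm1_individual = mm$individual,
       n_raters = nrow(m), n_items = ncol(m))
}

#' Long-format ratings to a raters x items matrix
#'
#' @param ratings Long-format rating table (one scale).
#' @param value_col Which column holds the values.
#' @return Numeric matrix, participants in rows, stimuli in columns.
#' @export
rating_matrix <- function(ratings, value_col = "value") {
  ids <- sort(unique(ratings$participant_id))
  items <- sort(unique(ratings$stimulus_id))
  m <- matrix(NA_real_, length(ids), length(items),
              dimnames = list(ids, items))
  # last value wins if duplicated (e.g. averaged upstream)
  m[cbind(match(ratings$participant_id, ids),
          match(ratings$stimulus_id, items))] <- ratings[[value_col]]
  m
}
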