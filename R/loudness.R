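# Integrated loudness per ITU-R BS.1770-4 / EBU R128, mono signals.
# K-weighting = high-shelf "head" pre-filter + RLB high-pass, with
# coefficients derived for the actual sample rate (analog-matched design;
# at 48 kHz these reduce to the coefficients tabulated in the standard).

k_weighting_coefs <- function(sample_rate) {
  # stage 1: high shelf (+~4 dB above ~1.68 kHz)
  f0 <- 1681.9744509555319
  G  <- 3.99984385397
  Q  <- 0.7071752369554196
  K  <- tan(pi * f0 / sample_rate)
  Vh <- 10^(G / 20)
  Vb <- Vh^0.4996667741545416
  a0 <- 1 + K / Q + K^2
  shelf <- list(
    b = c(Vh + Vb * K / Q + K^2, 2 * (K^2 - Vh), Vh - Vb * K / Q + K^2) / a0,
    a = c(1, 2 * (K^2 - 1) / a0, (1 - K / Q + K^2) / a0)
  )
  # stage 2: RLB high-pass (~38 Hz)
  f0 <- 38.13547087602444
  Q  <- 0.5003270373238773
  K  <- tan(pi * f0 / sample_rate)
  a0 <- 1 + K / Q + K^2
  hipass <- list(
    b = c(1, -2, 1),
    a = c(1, 2 * (K^2 - 1) / a0, (1 - K / Q + K^2) / a0)
  )
  list(shelf = shelf, hipass = hipass)
}

k_weight <- function(samples, sample_rate) {
  co <- k_weighting_coefs(sample_rate)
  y <- signal::filter(co$shelf$b, co$shelf$a, samples)
  as.numeric(signal::filter(co$hipass$b, co$hipass$a, y))
}

#' Measure integrated loudness (LUFS)
#'
#' Integrated program loudness of a mono signal per ITU-R BS.1770:
#' K-weighting (high-shelf pre-filter plus RLB high-pass, designed for the
#' given sample rate), 400 ms blocks with 75% overlap, absolute gating at
#' -70 LUFS and relative gating at -10 LU below the absolutely-gated level.
#' A full-scale 997 Hz sine measures -3.01 LUFS.
#'
#' @param samples Numeric vector, mono audio in [-1, 1] (values outside are
#'   allowed; loudness is scale-covariant).
#' @param sample_rate Sample rate in Hz.
#' @return Integrated loudness in LUFS.
#' @export
measure_lufs <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (length(samples) < round(0.4 * sample_rate)) {
    stop("audio shorter than one 400 ms gating block")
  }
  y <- k_weight(samples, sample_rate)
  blk <- round(0.4 * sample_rate)
  hop <- round(0.1 * sample_rate)
  starts <- seq(1L, length(y) - blk + 1L, by = hop)
  ms <- vapply(starts, function(s) mean(y[s:(s + blk - 1L)]^2), numeric(1))
  lb <- -0.691 + 10 * log10(pmax(ms, .Machine$double.xmin))
  keep <- lb > -70
  if (!any(keep)) stop("signal is below the -70 LUFS absolute gate (silence?)")
  rel_thresh <- -0.691 + 10 * log10(mean(ms[keep])) - 10
  keep2 <- keep & (lb > rel_thresh)
  if (!any(keep2)) keep2 <- keep
  -0.691 + 10 * log10(mean(ms[keep2]))
}

#' Normalize audio to a target loudness
#'
#' Applies a single gain so that the integrated loudness of the result
#' equals `target` LUFS.
#'
#' @param samples Mono audio samples.
#' @param sample_rate Sample rate in Hz.
#' @param target Target integrated loudness in LUFS (default -14, the
#'   pipeline's stimulus normalization level).
#' @return Gain-scaled samples.
#' @export
normalize_lufs <- function(samples, sample_rate, target = -14) {
  current <- measure_lufs(samples, sample_rate)
  gain <- 10^((target - current) / 20)
  samples * gain
}
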