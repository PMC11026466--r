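# Acoustic feature extraction: f0 tracking, note segmentation, pitch
# interval deviation in cents, vibrato rate/extent, singer's-formant energy
# ratio, jitter/shimmer, HNR (0-3.5 kHz), cepstral peak prominence,
# spectral tilt, and tempo. Conventions: time in seconds, half-open
# [start, end) note intervals, 0-based note indices in label tracks.

#' Frame-wise f0 tracking by autocorrelation
#'
#' Normalized-autocorrelation pitch tracker with parabolic peak
#' interpolation. Each frame's unbiased autocorrelation is searched over
#' the lag range corresponding to `[fmin, fmax]`; the shortest lag whose
#' peak is within 85% of the best peak is taken (octave-error guard).
#' Frames whose peak correlation falls below `threshold` are flagged
#' unvoiced.
#'
#' @param samples Mono audio.
#' @param sample_rate Sample rate in Hz.
#' @param fmin,fmax f0 search range in Hz.
#' @param window_s Analysis window in seconds (default 0.025).
#' @param hop_s Hop in seconds (default 0.010).
#' @param threshold Periodicity (normalized autocorrelation) threshold
#'   below which a frame is unvoiced (default 0.5).
#' @return An `f0_track`: data frame with columns `time` (s, frame
#'   centers), `f0` (Hz, `NA` where unvoiced), `periodicity`; attribute
#'   `frame_hop` (s).
#' @export
track_f0 <- function(samples, sample_rate, fmin = 150, fmax = 900,
                     window_s = 0.025, hop_s = 0.010, threshold = 0.5) {
  stopifnot(fmin < fmax, fmin > 0)
  n_win <- round(window_s * sample_rate)
  n_hop <- round(hop_s * sample_rate)
  if (length(samples) < n_win) stop("audio shorter than one analysis window")
  lag_min <- max(2L, floor(sample_rate / fmax))
  lag_max <- min(n_win - 2L, ceiling(sample_rate / fmin))
  if (lag_max <= lag_min) stop("f0 search range unresolvable at this window size")
  starts <- seq(1L, length(samples) - n_win + 1L, by = n_hop)
  frames <- matrix(samples[outer(seq_len(n_win) - 1L, starts, `+`)],
                   nrow = n_win)
  frames <- sweep(frames, 2, colMeans(frames))
  n_fft <- 2^ceiling(log2(2 * n_win))
  padded <- rbind(frames, matrix(0, n_fft - n_win, ncol(frames)))
  spec <- stats::mvfft(padded)
  acf_full <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / n_fft
  r0 <- acf_full[1, ]
  r0[r0 <= 0] <- Inf
  # unbiased, normalized acf over the candidate lag range
  lags <- lag_min:lag_max
  norm <- (n_win - lags) / n_win
  racf <- sweep(acf_full[lags + 1L, , drop = FALSE], 2, r0, "/") / norm
  f0 <- rep(NA_real_, ncol(frames))
  peak <- numeric(ncol(frames))
  for (j in seq_len(ncol(frames))) {
    r <- racf[, j]
    loc <- which(diff(sign(diff(r))) < 0) + 1L
    if (length(loc) == 0L) loc <- which.max(r)
    best <- max(r[loc])
    peak[j] <- best
    if (best < threshold) next
    cand <- loc[r[loc] >= 0.85 * best]
    k <- cand[1]
    lag <- lags[k]
    # parabolic interpolation around the peak
    if (k > 1L && k < length(r)) {
      y1 <- r[k - 1L]; y2 <- r[k]; y3 <- r[k + 1L]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom
    }
    f0[j] <- sample_rate / lag
  }
  out <- data.frame(time = (starts - 1L + n_win / 2) / sample_rate,
                    f0 = f0, periodicity = peak)
  attr(out, "frame_hop") <- n_hop / sample_rate
  class(out) <- c("f0_track", class(out))
  out
}

#' Segment a performance into notes
#'
#' Cuts audio into per-note segments according to a label track with
#' half-open `[start, end)` intervals, tracks f0 within each note, and
#' computes the note's mean f0 over the central 80% of voiced frames
#' (avoiding onset/offset glides). Labels must be non-overlapping and lie
#' within the audio duration.
#'
#' @param performance A `performance` object (or any list with `samples`
#'   and `sample_rate`).
#' @param labels Data frame `start_s`, `end_s`, `note_index`; defaults to
#'   the performance's own ground-truth labels.
#' @param ... Passed to [track_f0()].
#' @return List of `note_segment` objects: `note_index`, `start_s`,
#'   `end_s`, `samples`, `sample_rate`, `f0_track`, `mean_f0`.
#' @export
segment_notes <- function(performance, labels = performance$labels, ...) {
  fs <- performance$sample_rate
  dur <- length(performance$samples) / fs
  if (any(labels$end_s <= labels$start_s)) stop("labels must have end_s > start_s")
  ord <- order(labels$start_s)
  labels <- labels[ord, ]
  if (any(labels$start_s[-1] < labels$end_s[-nrow(labels)] - 1e-9)) {
    stop("overlapping labels")
  }
  if (any(labels$start_s < -1e-9) || any(labels$end_s > dur + 1e-6)) {
    stop("labels extend beyond audio duration")
  }
  lapply(seq_len(nrow(labels)), function(i) {
    i0 <- floor(labels$start_s[i] * fs) + 1L
    i1 <- min(floor(labels$end_s[i] * fs), length(performance$samples))
    x <- performance$samples[i0:i1]
    trk <- track_f0(x, fs, ...)
    voiced <- which(!is.na(trk$f0))
    mean_f0 <- NA_real_
    if (length(voiced) >= 3L) {
      # central 80% of voiced frames, mean taken in the cents domain
      lo <- stats::quantile(voiced, 0.1, type = 1)
      hi <- stats::quantile(voiced, 0.9, type = 1)
      core <- voiced[voiced >= lo & voiced <= hi]
      mean_f0 <- cents_to_hz(mean(hz_to_cents(trk$f0[core], 261.626)), 261.626)
    } else if (length(voiced) > 0L) {
      mean_f0 <- mean(trk$f0[voiced])
    }
    structure(list(note_index = labels$note_index[i],
                   start_s = labels$start_s[i], end_s = labels$end_s[i],
                   samples = x, sample_rate = fs,
                   f0_track = trk, mean_f0 = mean_f0),
              class = "note_segment")
  })
}

#' Pitch interval deviation (cents)
#'
#' Mean absolute deviation, in cents, between sung successive intervals and
#' the notated intervals of the melody: each note's mean f0 is converted to
#' cents, successive sung intervals are formed, intervals touching a note
#' flagged `exclude_from_pitch` are dropped, and the absolute deviations
#' from the expected intervals are averaged. Singing 250 cents where the
#' score expects a major second (200 cents) scores 50 cents.
#'
#' @param segments List of `note_segment` objects from [segment_notes()],
#'   or a numeric vector of per-note mean f0 values in Hz.
#' @param score The [melody_score()]; note count must match.
#' @return Mean absolute interval deviation in cents (>= 0).
#' @export
pitch_interval_deviation <- function(segments, score) {
  stopifnot(inherits(score, "melody_score"))
  f0s <- if (is.numeric(segments)) segments else
    vapply(segments, function(s) s$mean_f0, numeric(1))
  if (length(f0s) != length(score$notes)) {
    stop("segment count (", length(f0s), ") does not match score note count (",
         length(score$notes), ")")
  }
  sung_cents <- hz_to_cents(f0s, score$reference_hz)
  dev <- abs(diff(sung_cents) - expected_intervals(score))
  excl <- score_excluded(score)
  keep <- !(excl[-length(excl)] | excl[-1]) & !is.na(dev)
  if (!any(keep)) stop("all intervals excluded from pitch scoring")
  mean(dev[keep])
}

#' Vibrato rate and extent of a sustained note
#'
#' The note's f0 contour is converted to cents, linearly detrended, and the
#' dominant modulation frequency in `rate_range` is located as the
#' (parabolic-interpolated) peak of the zero-padded periodogram of the
#' contour. The extent is the amplitude of a least-squares sinusoid fit at
#' that rate, i.e. half the peak-to-peak f0 excursion in cents. If the
#' fitted extent falls below `floor_cents`, the note is reported as
#' unmodulated: `(0, 0)`.
#'
#' @param segment A `note_segment` with at least 0.5 s of voiced frames.
#' @param rate_range Modulation search band in Hz (default 3-9).
#' @param floor_cents Modulation-depth floor in cents (default 5).
#' @return Named numeric vector `c(rate = Hz, extent = cents)`.
#' @export
vibrato_analyze <- function(segment, rate_range = c(3, 9), floor_cents = 5) {
  trk <- segment$f0_track
  hop <- attr(trk, "frame_hop")
  voiced <- !is.na(trk$f0)
  # longest contiguous voiced run
  runs <- rle(voiced)
  if (!any(runs$values)) stop("note has no voiced frames")
  ends <- cumsum(runs$lengths)
  iv <- which(runs$values)
  best <- iv[which.max(runs$lengths[iv])]
  idx <- (ends[best] - runs$lengths[best] + 1L):ends[best]
  if (length(idx) * hop < 0.5) stop("voiced portion shorter than 0.5 s")
  cents <- hz_to_cents(trk$f0[idx], 261.626)
  tt <- trk$time[idx]
  cents <- as.numeric(stats::residuals(stats::lm(cents ~ tt)))
  n <- length(cents)
  fs_trk <- 1 / hop
  n_fft <- 2^ceiling(log2(max(16 * n, 512)))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- Mod(stats::fft(c(cents * w, rep(0, n_fft - n))))[1:(n_fft / 2)]
  freqs <- (seq_len(n_fft / 2) - 1) * fs_trk / n_fft
  band <- which(freqs >= rate_range[1] & freqs <= rate_range[2])
  k <- band[which.max(X[band])]
  rate <- freqs[k]
  if (k > 1 && k < length(X)) {
    y1 <- X[k - 1]; y2 <- X[k]; y3 <- X[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 1e-12) rate <- rate + 0.5 * (y1 - y3) / denom * fs_trk / n_fft
  }
  fit <- stats::lm(cents ~ sin(2 * pi * rate * tt) + cos(2 * pi * rate * tt))
  extent <- sqrt(sum(stats::coef(fit)[2:3]^2))
  if (!is.finite(extent) || extent < floor_cents) return(c(rate = 0, extent = 0))
  c(rate = as.numeric(rate), extent = as.numeric(extent))
}

#' Singer's-formant energy ratio
#'
#' Power-spectral energy in the 2.4-5.4 kHz band divided by the energy in
#' the 0-10 kHz band. High values indicate a strong reinforcement of the
#' band containing the singer's formant. Requires a sample rate of at
#' least 20 kHz so that the 0-10 kHz band is representable.
#'
#' @param segment A `note_segment` (or any list with `samples` and
#'   `sample_rate`).
#' @param band Numerator band in Hz (default `c(2400, 5400)`).
#' @param total_band Denominator band in Hz (default `c(0, 10000)`).
#' @return Energy ratio in [0, 1].
#' @export
energy_ratio <- function(segment, band = c(2400, 5400),
                         total_band = c(0, 10000)) {
  fs <- segment$sample_rate
  if (fs < 2 * total_band[2]) {
    stop("sample_rate must be >= ", 2 * total_band[2],
         " Hz to represent the 0-10 kHz band")
  }
  x <- segment$samples - mean(segment$samples)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_along(p) - 1) * fs / length(p)
  half <- freqs <= fs / 2
  p <- p[half]; freqs <- freqs[half]
  num <- sum(p[freqs >= band[1] & freqs <= band[2]])
  den <- sum(p[freqs >= total_band[1] & freqs <= total_band[2]])
  if (den <= 0) return(0)
  num / den
}

#' Local jitter (%)
#'
#' Cycle-to-cycle period perturbation:
#' `100 * mean(|p[i+1] - p[i]|) / mean(p)`.
#'
#' @param periods Numeric vector of consecutive glottal periods in seconds
#'   (at least 2).
#' @return Jitter (local) in percent.
#' @export
jitter_local <- function(periods) {
  if (length(periods) < 2L) stop("need at least 2 periods")
  100 * mean(abs(diff(periods))) / mean(periods)
}

#' Local shimmer (%)
#'
#' Cycle-to-cycle amplitude perturbation:
#' `100 * mean(|a[i+1] - a[i]|) / mean(a)`.
#'
#' @param peak_amplitudes Numeric vector of consecutive cycle peak
#'   amplitudes (at least 2).
#' @return Shimmer (local) in percent.
#' @export
shimmer_local <- function(peak_amplitudes) {
  if (length(peak_amplitudes) < 2L) stop("need at least 2 amplitudes")
  100 * mean(abs(diff(peak_amplitudes))) / mean(peak_amplitudes)
}

# Detect glottal cycles of a voiced note. Rough cycle boundaries come from
# upward zero crossings of the band-passed fundamental (amplitude-gated to
# skip silent stretches such as the articulation gap at the note end).
# Cycle timing is then refined on a version low-passed near 3.5*f0: the
# main excitation peak of each cycle is located with parabolic sub-sample
# interpolation, and periods are differences of consecutive peak times —
# a local, per-cycle measurement that neither narrow-band filtering nor
# inter-cycle averaging can smooth. Cycle amplitude is the raw waveform's
# energy over the cycle normalized by the exact (fractional) period,
# proportional to the cycle's amplitude scale and insensitive to
# sample-quantized boundaries.
detect_cycles <- function(segment) {
  fs <- segment$sample_rate
  f0 <- segment$mean_f0
  if (!is.finite(f0)) return(NULL)
  x <- segment$samples
  lo <- 0.65 * f0 / (fs / 2)
  hi <- min(1.45 * f0 / (fs / 2), 0.95)
  bp <- signal::butter(4, c(lo, hi), type = "pass")
  y <- signal::filtfilt(bp, x)
  s <- sign(y)
  up <- which(s[-1] > 0 & s[-length(s)] <= 0)
  if (length(up) < 14L) return(NULL)
  # amplitude gate: discard crossings in silent/unvoiced stretches, where
  # tiny ripples in the band-passed signal produce spurious cycles
  L0 <- round(fs / f0)
  peak_y <- max(abs(y))
  env_ok <- vapply(up, function(n0) {
    max(abs(y[n0:min(n0 + L0, length(y))])) > 0.2 * peak_y
  }, logical(1))
  up <- up[env_ok]
  if (length(up) < 14L) return(NULL)
  # drop edge cycles affected by onset/offset ramps and filter transients
  up <- up[5:(length(up) - 4L)]
  # sub-sample crossing times bound each cycle for the amplitude measure
  frac <- -y[up] / (y[up + 1L] - y[up])
  t_cross <- (up - 1 + frac) / fs
  # zero-phase FIR smoother (quarter-period Hann): averages noise while
  # keeping the timing measurement local to the cycle boundary — longer
  # kernels mix the per-cycle amplitude step (shimmer) into the crossing
  # position and inflate the jitter floor
  n_k <- max(5L, round(0.25 * fs / f0))
  if (n_k %% 2L == 0L) n_k <- n_k + 1L
  w_k <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_k) - 1) / (n_k - 1))
  xm <- as.numeric(stats::filter(x, w_k / sum(w_k), sides = 2))
  xm[is.na(xm)] <- 0
  # refined boundary: upward zero crossing of the smoothed signal nearest
  # each rough crossing, linearly interpolated to sub-sample accuracy.
  # The crossing is the cycle-start landmark, so consecutive period
  # estimates never mix adjacent cycle durations.
  t_ref <- rep(NA_real_, length(up))
  half <- floor(L0 / 3)
  for (k in seq_along(up)) {
    i0 <- max(2L, up[k] - half)
    i1 <- min(length(xm) - 1L, up[k] + half)
    seg <- xm[i0:i1]
    cr <- which(seg[-1] > 0 & seg[-length(seg)] <= 0)
    if (length(cr) == 0L) next
    j <- i0 + cr[which.min(abs(cr + i0 - 1L - up[k]))] - 1L
    if (xm[j + 1L] == xm[j]) next
    t_ref[k] <- (j - 1 - xm[j] / (xm[j + 1L] - xm[j])) / fs
  }
  periods <- diff(t_ref[!is.na(t_ref)])
  ok <- periods > 0.5 / f0 & periods < 2 / f0
  # crossing-to-crossing energy amplitude, exact-period normalized
  cyc_len <- diff(t_cross)
  amps <- rep(NA_real_, length(cyc_len))
  for (k in seq_along(cyc_len)) {
    if (cyc_len[k] < 0.5 / f0 || cyc_len[k] > 2 / f0) next
    i0 <- max(1L, ceiling(t_cross[k] * fs))
    i1 <- min(length(x), floor((t_cross[k] + cyc_len[k]) * fs))
    if (i1 <= i0) next
    amps[k] <- sqrt(sum(x[i0:i1]^2) / (cyc_len[k] * fs))
  }
  if (sum(ok) < 2L || sum(!is.na(amps)) < 2L) return(NULL)
  list(periods = periods[ok], amplitudes = amps[!is.na(amps)])
}

#' Harmonics-to-noise ratio in the 0-3.5 kHz band (dB)
#'
#' The segment is low-passed at 3.5 kHz; per 40 ms frame the normalized
#' cross-correlation `r` at the frame's f0 lag is found, and the frame HNR
#' is `10 * log10(r / (1 - r))`, capped at `cap` dB (the periodic limit
#' would otherwise be infinite). Frame values are averaged over voiced
#' frames.
#'
#' @param segment A voiced `note_segment`.
#' @param cap Ceiling in dB (default 40).
#' @return HNR in dB.
#' @export
hnr35 <- function(segment, cap = 40) {
  fs <- segment$sample_rate
  trk <- segment$f0_track
  voiced_f0 <- trk$f0[!is.na(trk$f0)]
  if (length(voiced_f0) == 0L) stop("unvoiced segment: HNR undefined")
  lp <- signal::butter(6, min(3500 / (fs / 2), 0.95), type = "low")
  x <- signal::filtfilt(lp, segment$samples)
  n_win <- round(0.04 * fs)
  n_hop <- round(0.01 * fs)
  if (length(x) < n_win) n_win <- length(x)
  starts <- seq(1L, length(x) - n_win + 1L, by = n_hop)
  f0_med <- stats::median(voiced_f0)
  vals <- vapply(starts, function(s0) {
    fr <- x[s0:(s0 + n_win - 1L)]
    fr <- fr - mean(fr)
    lag0 <- round(fs / f0_med)
    lags <- max(2L, lag0 - 3L):min(n_win - 2L, lag0 + 3L)
    r <- vapply(lags, function(l) {
      a <- fr[1:(n_win - l)]; b <- fr[(l + 1):n_win]
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den <= 0) return(0)
      sum(a * b) / den
    }, numeric(1))
    max(r)
  }, numeric(1))
  vals <- clip(vals, 1e-6, 1 - 1e-4)
  hnr_frames <- pmin(10 * log10(vals / (1 - vals)), cap)
  # frames with some periodicity only (exclude silence/gaps)
  keep <- vals > 0.3
  if (!any(keep)) stop("no periodic frames found")
  mean(hnr_frames[keep])
}

#' Cepstral peak prominence (dB)
#'
#' A measure of breathiness / overall dysphonia: per 40 ms Hamming frame,
#' the real cepstrum of the log-magnitude spectrum is searched in the
#' quefrency band corresponding to f0 in `[60, 880]` Hz; the prominence is
#' the cepstral peak height above a linear regression fit to the cepstrum
#' over that band, in dB, averaged over frames. Higher values indicate a
#' more strongly periodic (less breathy) voice. The regression baseline and
#' window are configurable; absolute values depend on these conventions.
#'
#' @param segment A `note_segment` of at least 40 ms.
#' @param f0_range Quefrency search band expressed as an f0 range in Hz.
#' @param frame_s,hop_s Frame and hop lengths in seconds.
#' @return CPP in dB.
#' @export
cpp <- function(segment, f0_range = c(60, 880), frame_s = 0.04, hop_s = 0.01) {
  fs <- segment$sample_rate
  n_win <- round(frame_s * fs)
  if (length(segment$samples) < n_win) stop("segment shorter than one 40 ms frame")
  n_hop <- round(hop_s * fs)
  starts <- seq(1L, length(segment$samples) - n_win + 1L, by = n_hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_win) - 1) / (n_win - 1))
  n_fft <- 2^ceiling(log2(n_win))
  q <- (seq_len(n_fft) - 1) / fs
  band <- which(q >= 1 / f0_range[2] & q <= 1 / f0_range[1] & q <= n_fft / 2 / fs)
  if (length(band) < 8L) stop("quefrency band unresolvable at this frame length")
  qb <- q[band]
  # frame RMS gate: analyze only the louder (voiced) frames
  rms <- vapply(starts, function(s0)
    sqrt(mean(segment$samples[s0:(s0 + n_win - 1L)]^2)), numeric(1))
  keep <- rms > 0.1 * max(rms)
  # per-frame log-cepstra are averaged first (smoothed-CPP convention):
  # random cepstral fluctuations of aperiodic frames cancel, while a true
  # f0 peak stays at a fixed quefrency
  ceps <- vapply(starts[keep], function(s0) {
    fr <- segment$samples[s0:(s0 + n_win - 1L)] * w
    S <- 20 * log10(Mod(stats::fft(c(fr, rep(0, n_fft - n_win)))) + 1e-12)
    20 * log10(Mod(stats::fft(S))[band] / n_fft + 1e-12)
  }, numeric(length(band)))
  cb <- rowMeans(ceps)
  base <- stats::lm.fit(cbind(1, qb), cb)
  k <- which.max(cb)
  cb[k] - (base$coefficients[1] + base$coefficients[2] * qb[k])
}

#' Spectral tilt measures (dB)
#'
#' Uncorrected spectral tilt: the amplitude of the first harmonic minus the
#' amplitude of the second harmonic (H1-H2) and minus the peak amplitude in
#' each of three formant search bands (H1-A1, H1-A2, H1-A3). Harmonic
#' amplitudes are taken as the strongest spectral peak within +/-20% of
#' k * f0; formant amplitudes as the strongest peak within the fixed search
#' bands (defaults for a sung /u/). Measures whose target region is above
#' the Nyquist frequency or below the spectral noise floor are returned as
#' `NA` rather than raising an error.
#'
#' @param segment A voiced `note_segment` with known mean f0.
#' @param formant_bands List of three `c(lo, hi)` search bands in Hz.
#' @return Named numeric vector `h1_h2`, `h1_a1`, `h1_a2`, `h1_a3` (dB).
#' @export
spectral_tilt <- function(segment,
                          formant_bands = list(c(250, 600), c(600, 1400),
                                               c(1800, 3200))) {
  fs <- segment$sample_rate
  f0 <- segment$mean_f0
  if (!is.finite(f0)) stop("mean f0 unknown: segment appears unvoiced")
  x <- segment$samples - mean(segment$samples)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  S <- 20 * log10(Mod(stats::fft(x * w)) + 1e-12)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  S <- S[half]; freqs <- freqs[half]
  floor_db <- stats::median(S) + 6
  peak_in <- function(lo, hi) {
    sel <- which(freqs >= lo & freqs <= hi)
    if (length(sel) == 0L) return(NA_real_)
    v <- max(S[sel])
    if (v < floor_db) return(NA_real_)
    v
  }
  h1 <- peak_in(0.8 * f0, 1.2 * f0)
  h2 <- peak_in(1.8 * f0, 2.2 * f0)
  a <- vapply(formant_bands, function(b) peak_in(b[1], b[2]), numeric(1))
  c(h1_h2 = h1 - h2, h1_a1 = h1 - a[1], h1_a2 = h1 - a[2], h1_a3 = h1 - a[3])
}

#' Average tempo of a performance
#'
#' The excerpt's length (span of the note labels) divided by the score's
#' beat count, in seconds per beat; `60 / tempo` gives beats per minute.
#'
#' @param performance A `performance` (or list with `labels`).
#' @param score The [melody_score()]; `total_beats` must be > 0.
#' @return Tempo in seconds per beat.
#' @export
tempo <- function(performance, score) {
  stopifnot(inherits(score, "melody_score"))
  if (score$total_beats <= 0) stop("score has zero beats")
  span <- max(performance$labels$end_s) - min(performance$labels$start_s)
  span / score$total_beats
}

#' One-sided outlier trimming
#'
#' Removes values greater than `mean + k_sd * SD` of the input (one-sided:
#' low values are never removed). Used to discard aberrant jitter/shimmer
#' measurements from very short notes.
#'
#' @param values Numeric vector of at least 3 values.
#' @param k_sd Trim threshold in SD units (default 2).
#' @return List with `kept` (values retained) and `excluded_fraction`.
#' @export
trim_outliers <- function(values, k_sd = 2) {
  if (length(values) < 3L) stop("need at least 3 values to trim")
  thr <- mean(values) + k_sd * stats::sd(values)
  kept <- values[values <= thr]
  list(kept = kept, excluded_fraction = 1 - length(kept) / length(values))
}

#' Extract the full acoustic profile of one performance
#'
#' Runs every extractor and returns a one-row data frame: pitch interval
#' deviation (honoring the score's exclusion flags), vibrato rate/extent
#' and energy ratio (on the score's designated sustained note), jitter and
#' shimmer (note-level values pooled across notes, one-sidedly trimmed at
#' 2 SD, then averaged), HNR35, CPP and spectral tilt (on the sustained
#' note), tempo, mean f0 and integrated loudness.
#'
#' @param performance A `performance`.
#' @param score The [melody_score()] the performance realizes.
#' @param labels Note labels; default the performance's own.
#' @param trim_k SD multiplier for jitter/shimmer trimming (default 2).
#' @return One-row data frame (see [profile_column_order()] source for the
#'   stable column set).
#' @export
extract_profile <- function(performance, score,
                            labels = performance$labels, trim_k = 2) {
  segs <- segment_notes(performance, labels)
  f0s <- vapply(segs, function(s) s$mean_f0, numeric(1))
  pid <- pitch_interval_deviation(f0s, score)

  vib_idx <- vibrato_note_index(score)
  vib <- c(rate = NA_real_, extent = NA_real_)
  er <- NA_real_
  hnr_v <- NA_real_
  cpp_v <- NA_real_
  tilt <- c(h1_h2 = NA_real_, h1_a1 = NA_real_, h1_a2 = NA_real_,
            h1_a3 = NA_real_)
  if (!is.na(vib_idx)) {
    vib_seg <- segs[[vib_idx]]
    vib <- tryCatch(vibrato_analyze(vib_seg),
                    error = function(e) c(rate = NA_real_, extent = NA_real_))
    er <- if (performance$sample_rate >= 20000) energy_ratio(vib_seg) else NA_real_
    hnr_v <- tryCatch(hnr35(vib_seg), error = function(e) NA_real_)
    cpp_v <- tryCatch(cpp(vib_seg), error = function(e) NA_real_)
    tilt <- tryCatch(spectral_tilt(vib_seg),
                     error = function(e) c(h1_h2 = NA_real_, h1_a1 = NA_real_,
                                           h1_a2 = NA_real_, h1_a3 = NA_real_))
  }

  cyc <- lapply(segs, detect_cycles)
  jit_notes <- vapply(cyc, function(cc) {
    if (is.null(cc) || length(cc$periods) < 2L) return(NA_real_)
    jitter_local(cc$periods)
  }, numeric(1))
  shim_notes <- vapply(cyc, function(cc) {
    if (is.null(cc) || length(cc$amplitudes) < 2L) return(NA_real_)
    shimmer_local(cc$amplitudes)
  }, numeric(1))
  pool_trim <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    if (length(v) >= 3L) v <- trim_outliers(v, trim_k)$kept
    mean(v)
  }

  tpo <- tempo(performance, score)
  data.frame(
    stimulus_id = if (!is.null(performance$stimulus_id)) performance$stimulus_id else NA_character_,
    singer_id = if (!is.null(performance$singer_id)) performance$singer_id else NA_character_,
    melody = if (!is.null(performance$melody)) performance$melody else score$name,
    take = if (!is.null(performance$take)) performance$take else NA_integer_,
    pitch_interval_deviation = pid,
    vibrato_rate = unname(vib["rate"]),
    vibrato_extent = unname(vib["extent"]),
    energy_ratio = er,
    jitter_local = pool_trim(jit_notes),
    shimmer_local = pool_trim(shim_notes),
    hnr35 = hnr_v,
    cpp = cpp_v,
    h1_h2 = unname(tilt["h1_h2"]),
    h1_a1 = unname(tilt["h1_a1"]),
    h1_a2 = unname(tilt["h1_a2"]),
    h1_a3 = unname(tilt["h1_a3"]),
    tempo_s_per_beat = tpo,
    bpm = 60 / tpo,
    mean_f0 = mean(f0s, na.rm = TRUE),
    loudness_lufs = measure_lufs(performance$samples, performance$sample_rate),
    stringsAsFactors = FALSE
  )
}

#' Extract acoustic profiles for a whole stimulus set
#'
#' @param stimuli A `stimulus_set` from [build_stimulus_set()] with
#'   rendered audio.
#' @return Data frame, one row per stimulus.
#' @export
extract_profiles <- function(stimuli) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  score_by_name <- stats::setNames(stimuli$scores,
                                   vapply(stimuli$scores, `[[`, "", "name"))
  rows <- lapply(stimuli$performances, function(p) {
    if (is.null(p)) stop("stimulus set was built with render = FALSE")
    extract_profile(p, score_by_name[[p$melody]])
  })
  do.call(rbind, rows)
}
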