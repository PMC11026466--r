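#' Convert frequency to cents
#'
#' Converts a frequency in Hz to cents relative to a reference frequency.
#' 100 cents correspond to one equal-tempered semitone, 1200 cents to one
#' octave. The package-wide default reference is C4 = 261.626 Hz, the lowest
#' reference note used throughout the pitch scoring.
#'
#' @param f Frequency in Hz (vectorised). Must be strictly positive.
#' @param reference_hz Reference frequency in Hz (default 261.626).
#' @return Pitch in cents relative to `reference_hz`.
#' @seealso [cents_to_hz()]
#' @export
#' @examples
#' hz_to_cents(523.252)            # one octave above C4: 1200
#' hz_to_cents(277.183, 261.626)   # one semitone: ~100
hz_to_cents <- function(f, reference_hz = 261.626) {
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("frequencies must be finite and strictly positive")
  }
  if (!is.finite(reference_hz) || reference_hz <= 0) {
    stop("reference_hz must be finite and strictly positive")
  }
  1200 * log2(f / reference_hz)
}

#' Convert cents to frequency
#'
#' Inverse of [hz_to_cents()].
#'
#' @param cents Pitch in cents relative to `reference_hz`.
#' @param reference_hz Reference frequency in Hz.
#' @return Frequency in Hz.
#' @export
cents_to_hz <- function(cents, reference_hz = 261.626) {
  if (!is.finite(reference_hz) || reference_hz <= 0) {
    stop("reference_hz must be finite and strictly positive")
  }
  reference_hz * 2^(cents / 1200)
}

#' Create a note specification
#'
#' One note of a melody score: its target pitch (in cents relative to the
#' score's reference frequency), its duration in beats, and two scoring
#' flags. Notes flagged `exclude_from_pitch` are skipped by the pitch
#' interval deviation computation (used for very short notes whose mean f0
#' cannot be estimated reliably); at most one note per melody may carry
#' `is_vibrato_note`, marking the sustained note on which vibrato and the
#' singer's-formant energy ratio are measured.
#'
#' @param expected_cents Target pitch in cents relative to the reference.
#' @param duration_beats Duration in beats; must be > 0.
#' @param exclude_from_pitch Exclude from pitch-interval scoring?
#' @param is_vibrato_note Is this the vibrato/energy measurement note?
#' @return A `note_spec` list.
#' @export
note_spec <- function(expected_cents, duration_beats = 1,
                      exclude_from_pitch = FALSE, is_vibrato_note = FALSE) {
  stopifnot(is.numeric(expected_cents), length(expected_cents) == 1L,
            is.finite(expected_cents))
  if (!is.numeric(duration_beats) || length(duration_beats) != 1L ||
      !is.finite(duration_beats) || duration_beats <= 0) {
    stop("duration_beats must be a single positive number")
  }
  structure(
    list(expected_cents = expected_cents,
         duration_beats = duration_beats,
         exclude_from_pitch = isTRUE(exclude_from_pitch),
         is_vibrato_note = isTRUE(is_vibrato_note)),
    class = "note_spec"
  )
}

#' Create a melody score
#'
#' A melody score is the notated reference against which sung performances
#' are scored: an ordered list of [note_spec()] notes plus a reference
#' frequency and a total beat count (rests are allowed, so `total_beats`
#' may exceed the sum of note durations).
#'
#' @param name Identifier for the melody.
#' @param notes List of [note_spec()] objects; at least 2.
#' @param reference_hz Reference frequency in Hz (default 261.626).
#' @param total_beats Total length of the excerpt in beats; defaults to the
#'   sum of note durations.
#' @return A `melody_score` object.
#' @export
melody_score <- function(name, notes, reference_hz = 261.626,
                         total_beats = NULL) {
  if (length(notes) < 2L) stop("a melody score needs at least 2 notes")
  if (!all(vapply(notes, inherits, logical(1), "note_spec"))) {
    stop("notes must be a list of note_spec objects")
  }
  if (!is.finite(reference_hz) || reference_hz <= 0) {
    stop("reference_hz must be positive")
  }
  n_vib <- sum(vapply(notes, function(n) n$is_vibrato_note, logical(1)))
  if (n_vib > 1L) stop("at most one note may be flagged is_vibrato_note")
  dur <- sum(vapply(notes, function(n) n$duration_beats, numeric(1)))
  if (is.null(total_beats)) total_beats <- dur
  if (!is.finite(total_beats) || total_beats <= 0) {
    stop("total_beats must be positive")
  }
  structure(
    list(name = name, reference_hz = reference_hz,
         notes = notes, total_beats = total_beats),
    class = "melody_score"
  )
}

#' @export
print.melody_score <- function(x, ...) {
  cat(sprintf("<melody_score> %s: %d notes, %.3g beats, ref %.3f Hz\n",
              x$name, length(x$notes), x$total_beats, x$reference_hz))
  invisible(x)
}

score_cents <- function(score) {
  vapply(score$notes, function(n) n$expected_cents, numeric(1))
}

score_durations <- function(score) {
  vapply(score$notes, function(n) n$duration_beats, numeric(1))
}

score_excluded <- function(score) {
  vapply(score$notes, function(n) n$exclude_from_pitch, logical(1))
}

#' Index of the vibrato measurement note
#'
#' @param score A [melody_score()].
#' @return 1-based index of the note flagged `is_vibrato_note`, or `NA` if
#'   none is flagged.
#' @export
vibrato_note_index <- function(score) {
  idx <- which(vapply(score$notes, function(n) n$is_vibrato_note, logical(1)))
  if (length(idx) == 0L) return(NA_integer_)
  idx[1]
}

#' Expected successive intervals of a melody score
#'
#' Successive differences of the notated pitches, in cents. These are the
#' "correct" intervals (according to musical notation) that sung intervals
#' are compared against.
#'
#' @param score A [melody_score()].
#' @return Numeric vector of length `n_notes - 1`, in cents.
#' @export
#' @examples
#' s <- melody_score("ex", list(note_spec(0), note_spec(200), note_spec(200)))
#' expected_intervals(s)  # 200, 0
expected_intervals <- function(score) {
  stopifnot(inherits(score, "melody_score"))
  cents <- score_cents(score)
  if (length(cents) < 2L) stop("need at least 2 notes to form an interval")
  diff(cents)
}

#' Read a melody score from JSON
#'
#' The file format is a JSON object with fields `name`, `reference_hz`
#' (optional, default 261.626) and `notes`, an array of objects with fields
#' `expected_cents`, `duration_beats`, `exclude_from_pitch` and
#' `is_vibrato_note` (the last two optional, default false).
#'
#' @param path Path to a JSON score file.
#' @return A [melody_score()].
#' @export
read_melody_score <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$name) || is.null(obj$notes)) {
    stop("melody score file must have 'name' and 'notes' fields: ", path)
  }
  ref <- if (is.null(obj$reference_hz)) 261.626 else as.numeric(obj$reference_hz)
  notes <- lapply(obj$notes, function(n) {
    note_spec(
      expected_cents = as.numeric(n$expected_cents),
      duration_beats = if (is.null(n$duration_beats)) 1 else as.numeric(n$duration_beats),
      exclude_from_pitch = isTRUE(n$exclude_from_pitch),
      is_vibrato_note = isTRUE(n$is_vibrato_note)
    )
  })
  tb <- if (is.null(obj$total_beats)) NULL else as.numeric(obj$total_beats)
  melody_score(obj$name, notes, reference_hz = ref, total_beats = tb)
}

#' Write a melody score to JSON
#'
#' @param score A [melody_score()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melody_score <- function(score, path) {
  stopifnot(inherits(score, "melody_score"))
  obj <- list(
    name = score$name,
    reference_hz = score$reference_hz,
    total_beats = score$total_beats,
    notes = lapply(score$notes, function(n) {
      list(expected_cents = n$expected_cents,
           duration_beats = n$duration_beats,
           exclude_from_pitch = n$exclude_from_pitch,
           is_vibrato_note = n$is_vibrato_note)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Built-in default melody scores
#'
#' Two default excerpts approximating the study melodies: the opening phrase
#' of *Over the Rainbow* (with its sustained octave jump as the first
#' interval, vibrato measured on the sustained first note, fourth note
#' excluded from pitch scoring) and the whistled theme of *Don't Worry Be
#' Happy* (vibrato measured on the sustained last note, seventh note
#' excluded). The exact pitch content of the original excerpts is not fully
#' documented, so these note lists are plausible placeholders; every scoring
#' operation is score-driven, so analyses remain correct for any
#' user-supplied score file (see [read_melody_score()]).
#'
#' @return Named list of two [melody_score()] objects,
#'   `over_the_rainbow` and `dont_worry_be_happy`.
#' @export
default_melody_scores <- function() {
  otr <- melody_score(
    "over_the_rainbow",
    list(
      # "Some-"  sustained low tonic, vibrato/energy note
      note_spec(0,    2, is_vibrato_note = TRUE),
      # "-where" octave jump
      note_spec(1200, 2),
      note_spec(1100, 1),
      note_spec(700,  0.5, exclude_from_pitch = TRUE),  # very short passing note
      note_spec(900,  0.5),
      note_spec(1100, 1),
      note_spec(1200, 2),
      note_spec(900,  1.5),
      note_spec(700,  2.5)
    )
  )
  dwbh <- melody_score(
    "dont_worry_be_happy",
    list(
      note_spec(1200, 1),
      note_spec(1200, 1),
      note_spec(1200, 1),
      note_spec(900,  1),
      note_spec(1200, 1.5),
      note_spec(900,  1),
      note_spec(700,  0.5, exclude_from_pitch = TRUE),  # short ornament
      note_spec(900,  1),
      note_spec(700,  1),
      note_spec(400,  1),
      # sustained final note, vibrato/energy note
      note_spec(600,  3, is_vibrato_note = TRUE)
    )
  )
  list(over_the_rainbow = otr, dont_worry_be_happy = dwbh)
}
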