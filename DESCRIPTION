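Package: singpref
Title: Acoustic and Perceptual Analysis of Singing Voice Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying why listeners prefer some singing voices over
    others. Implements acoustic analysis of short a cappella performances
    (pitch interval deviation in cents, vibrato rate and extent, singer's
    formant energy ratio, jitter, shimmer, harmonics-to-noise ratio, cepstral
    peak prominence, spectral tilt, tempo, and EBU R128 / ITU BS.1770
    loudness normalization), inter-rater reliability statistics
    (Krippendorff's alpha, ICC(2,1), mean-minus-one agreement, test-retest
    consistency), and linear mixed-effects preference models with
    marginal/conditional R2 variance decomposition. Includes a fully
    controllable synthetic-performance and rater simulator so the whole
    pipeline can be exercised end-to-end by parameter recovery, without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
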