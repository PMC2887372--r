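Package: micromelody
Title: Micromelody Discrimination Training and Melodic Vocal-Accuracy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the link between fine-grained pitch
    discrimination and singing accuracy. Generates seven-note sub-semitone
    "micromelody" stimuli (pure-tone or harmonic) and renders them to audio;
    runs two-alternative same/different test batteries and 2-down-1-up
    adaptive discrimination staircases with coarse and fine phases; segments
    sung-melody fundamental-frequency traces into notes with a Viterbi path
    over a frequency-state matrix and summarises each note by the middle-80%
    mean and standard deviation in cents; computes five melodic performance
    measures (absolute error, absolute contour error, contour score, absolute
    interval magnitude, absolute interval difference) plus simple-singing
    accuracy and stability; and simulates singers, listeners and whole
    two-group training cohorts so the full pipeline can be exercised and
    validated without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
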