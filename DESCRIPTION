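Package: svrand
Title: Weak-Randomness (Santha-Vazirani) Estimation for Heart-Rate Interval Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to treat the human heart rate as a weak source of
    randomness. Reads annotated RR-interval (beat-to-beat) recordings,
    discretizes them into binary sequences by acceleration sign, change
    magnitude, or three-beat monotonicity, optionally excises the heart's
    periodic acceleration/deceleration trends, and estimates the epsilon
    parameter of the underlying epsilon-Santha-Vazirani source from
    overlapping substring frequencies, with a harmonic-weighted aggregate
    over history lengths. Includes simulators for Santha-Vazirani sources
    of known bias and heart-rate-like RR series, De Bruijn validation
    sequences, and cohort-level summaries by sex and age decade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
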