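Package: kayakpace
Title: Pacing-Profile Analysis for Sprint Kayak Racing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling how sprint-kayak pacing profiles evolve over
    an athlete's career. Per-50m split times are converted to race-normalised
    segment velocities, smoothed with a B-spline basis, and summarised by
    functional principal component (fPCA) scores. A multi-sequence hidden
    Markov model with covariate-dependent Gaussian emissions (age group and
    event type shift the state-conditional means) is fitted to each athlete's
    score trajectory by EM with random restarts, the number of states is
    selected by AIC, and careers are decoded with the Viterbi algorithm.
    Includes goodness-of-fit diagnostics (geometric sojourn times, residual
    RMSE), career timelines, and a fully seeded synthetic-data generator that
    reproduces the statistical structure the pipeline assumes.
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
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
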