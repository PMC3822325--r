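Package: eyewrite
Title: Via-Point Features and Bayesian Recognition for Cursive Eye Writing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for cursive characters written with smooth-pursuit
    eye movements. Raw gaze records (time, position, pupil diameter) are smoothed
    with a binomial filter, cleaned of intrusive saccades by acceleration
    thresholding, and summarized as sequences of via-points (velocity
    zero-crossings carrying relative displacement and velocity) plus auxiliary
    features (letter size, high-frequency spectral energy, pupil statistics).
    A fully discrete Bayesian generative model over these features, learned by
    Laplace succession laws with Gaussian histogram smoothing and truncated
    discrete normal fits, supports online character recognition with entropy
    tracking, unknown-symbol (novelty) detection through a uniform background
    class, and motor-disability assessment from trajectory size, tremor energy
    and pupil dynamics. A seedable generator of eye-writing-like trajectories
    with a three-level impairment manipulation provides a reproducible test bed.
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
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
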