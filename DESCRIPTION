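Package: zmlentropy
Title: Entropy Estimation for Symbolic Sequences via Constrained
    Zipf-Mandelbrot-Li Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Shannon entropy and entropy-rate estimation for symbolic
    sequences (text, DNA, protein, arbitrary token streams) under severe
    undersampling.  Implements analytic Zipf-Mandelbrot-Li (ZML)
    rank-probability models and two linguistically constrained variants
    (no adjacent repeated letters; reduced continuation branching), a
    coincidence-counting estimator that infers the alphabet size from the
    mean distance between repeats of a ranked symbol, invertible
    distance-to-alphabet-size calibration (closed form or fitted by
    simulation), plug-in and Miller-Madow baselines, n-gram block and
    conditional entropy rates, and a Dvoretzky-Kiefer-Wolfowitz sample-size
    planner quantifying the sample savings of rank-based estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
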