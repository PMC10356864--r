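Package: mozear
Title: Auditory Biophysics and Expression Noise-Floor Analysis for Mosquito Hearing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing laser-Doppler-vibrometry (LDV) recordings of
    the mosquito antennal flagellum and for calling expressed transcripts in
    Johnston's-organ RNA-seq above a simulation-derived count noise floor.
    The LDV side classifies flagellar mechanical states (quiescent,
    self-sustained oscillation, transient) by fitting a mixed arcsine-normal
    amplitude distribution, extracts spontaneous-oscillation frequency and
    amplitude by FFT, fits the driven damped harmonic oscillator to
    SNIP-extracted chirp-response envelopes, and estimates steady-state
    flagellar stiffness from force-step responses, with a nonparametric
    statistics layer (median/MAD, Wilcoxon rank-sum with Holm correction,
    chi-squared). The RNA-seq side estimates a Poisson noise floor for
    transcript counts by repeated hold-out read simulation and quantification,
    and calls transcripts expressed by Poisson tail tests with
    Benjamini-Hochberg correction. A synthetic-data module generates all
    inputs (traces, chirps, force steps, toy transcriptomes and read sets)
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    minpack.lm,
    deSolve,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
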