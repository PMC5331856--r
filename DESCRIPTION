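Package: noteERP
Title: Simulation and Analysis of Fast-Rate Auditory ERP Experiments with
    Musical Note Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build 4 Hz guitar-note stimulus sequences (patterned
    scale runs, matched random permutations, and a two-note oddball stream),
    render them to audio, simulate multichannel EEG recordings containing
    the evoked responses such sequences elicit, and analyse the recordings
    with a conventional event-related potential (ERP) pipeline: zero-phase
    Butterworth band-pass filtering, mastoid re-referencing, epoching with
    artifact and packet-loss rejection, group-guided peak windowing, and
    full-width-at-half-maximum (FWHM) mean-amplitude extraction.  A small
    statistics layer runs the planned paired t-tests, percent-modulation
    contrasts, and Pearson correlations under Holm-Bonferroni control.
    The simulator retains ground truth so injected condition effects and
    latent subject-level correlations can be recovered and checked.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
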