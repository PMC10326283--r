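Package: ecogspeech
Title: Linear Decoding of Overt Speech from Electrocorticographic Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for continuous decoding of overt speech from
    multichannel cortical recordings. Implements vocoder analysis and synthesis of
    the speech signal (order-24 mel cepstrum on an all-pass frequency warp, F0
    extraction, excitation-driven resynthesis), neural spectral feature extraction
    (common median reference, 10 Hz band powers to 200 Hz plus a 0.5-5 Hz
    component, temporal context and delay windowing), estimation of a speaker's
    articulatory trajectories by dynamic time warping transfer from a reference
    electromagnetic-articulography corpus, five linear decoders (ordinary least
    squares, three ridge variants with L-curve or cross-validated regularization,
    and partial least squares), a feedforward articulatory-to-acoustic synthesizer
    with fine-tuning, and a cross-validated evaluation framework with chance
    levels, Wilcoxon signed-rank and Quade-Conover statistics. A synthetic-data
    generator produces paired reference/patient corpora with known ground truth so
    the full pipeline is testable without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
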