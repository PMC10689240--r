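Package: socialphot
Title: Fiber-Photometry and Circuit Quantification for Social-Behavior Neuroscience
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk calcium (fiber-photometry) recordings
    during social behavior and for the anatomical and electrophysiological
    quantification that accompanies such studies. Converts raw fluorescence to
    baseline-corrected dF/F and whole-trace z-scores (Fz), builds peri-event
    time histograms aligned to behavior onsets and offsets with pointwise
    one-sample tests corrected by Benjamini-Hochberg FDR, computes stimulus
    preference indices, trial-response rates and latencies, quantifies
    monosynaptic rabies input fractions, normalized axonal projection
    intensities and double-label overlap fractions, and detects and classifies
    optogenetically evoked postsynaptic currents. A synthetic-data module
    generates photometry sessions, behavior bout tables, region count tables
    and voltage-clamp sweeps with known ground truth so every stage can be
    validated without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
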