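Package: statecortex
Title: State-Dependent Laminar Analysis of Thalamocortical Spiking and Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for state-dependent auditory thalamocortical
    electrophysiology: current-source-density (CSD) laminar alignment of
    multichannel local field potentials, waveform-based classification of
    narrow- and broad-spiking cortical units into depth classes, UP-state
    detection from smoothed multiunit activity, synchronized/desynchronized
    epoch construction around basal-forebrain stimulation, spectral depth
    profiles and band-power modulation indices, evoked spike-count
    reliability statistics (mean, variance, Fano factor), mean spike time
    and normalized PSTHs, pairwise spike-count correlations, and click-train
    phase locking (vector strength, Rayleigh test). Includes a synthetic
    session generator with known ground truth so every stage of the
    pipeline is verifiable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
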