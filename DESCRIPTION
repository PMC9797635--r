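Package: DATquant
Title: ROI-Based Semi-Quantification of Striatal DAT-SPECT on a Digital Phantom
Version: 0.9.0
Authors@R:
    person("Alex", "Morgan", email = "alex.morgan@example.org",
           role = c("aut", "cre"))
Description: Simulates SPECT acquisitions of a digital anthropomorphic
    striatal phantom (caudate and putamen wells inside a brain-shell
    background, Gaussian system blur, Poisson counting noise, Gaussian
    post-filter) and implements five region-of-interest semi-quantification
    methods for dopamine-transporter imaging: manual anatomical ROIs with a
    low-count reference (binding potential index), the TwoBox trapezoidal
    template specific binding ratio, the ThreeBox rectangular template total
    binding potential index, and structural-VOI quantification with
    geometric transfer matrix partial-volume correction (MRI-like and
    CT-like variants). Method accuracy and precision are evaluated with
    Lin's concordance correlation coefficient per activity level, Pearson
    correlation and least-squares regression against the known fills.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
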