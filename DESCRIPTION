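Package: stratmix
Title: Lagrangian Sediment Mixing and Single-Specimen Isotope Record Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the formation of deep-sea sedimentary proxy records under
    bioturbation. A Lagrangian particle model mixes a point event of sediment
    under depth-dependent diffusivity with ongoing sedimentation; the resulting
    median displacement profile is convolved with per-clade plankton abundance
    histories and carbon-isotope scenarios to form post-mixing records of
    single-specimen d13C. Includes empirical abundance fitting for Site-690-like
    depth series, stratified sampling of single individuals, detection of
    intermediate-value specimens across a carbon isotope excursion onset, and a
    Monte-Carlo assessment of the probability that an onset of given duration
    leaves no intermediate values in the sampled record.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
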