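Package: armassess
Title: Upper-Limb Posture Measurement and Rehabilitation Assessment
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Marker-less upper-limb motion analysis for rehabilitation
    assessment. Fuses synchronized two-camera skeleton streams into a single
    world-frame stream, denoises them (median plus zero-phase Butterworth
    filtering), fits a 9 degree-of-freedom per-arm rigid-body model by
    crossbreed particle swarm optimization of the inverse kinematics,
    quantifies the reachable workspace as relative surface areas on a
    shoulder-centered unit sphere, and regresses a continuous movement-quality
    score with a spatial-temporal graph convolutional network extended by
    ConvLSTM-derived self-attention maps. Includes a synthetic motion and
    sensor simulator (16-action exercise protocol, two camera views, noise,
    occlusion) so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
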