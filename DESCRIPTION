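Package: myograsp
Title: Myoelectric Pattern Recognition and Grasp Control for an
    Underactuated Prosthetic Hand
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for two-channel surface electromyography (sEMG) driven
    prosthetic hand control: a seeded synthetic sEMG generator with
    gesture-dependent activation envelopes, band-pass and powerline-notch
    signal conditioning, sliding-window time-domain feature extraction
    (iEMG, RMS, MAV, zero crossings, variance, minimum), Fisher linear
    discriminant analysis implemented from first principles with a
    baseline-classifier comparison harness, a simulated dual-loop
    (position and current) grasp controller, and loop-closure kinematics
    of the hand's underactuated finger linkage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    rpart,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    class,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
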