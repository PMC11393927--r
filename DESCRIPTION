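Package: lexidiag
Title: Simulation-Based Diagnosis and Guided-Reading Therapy for Dyslexia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the visual and temporal conditions of correct
    reading. Provides a parametric virtual reader (simultaneous letter
    capacity as a function of fixation time, required verbal reaction time,
    visual-field defects and compensatory gaze strategies), an adaptive
    tachistoscopic pseudoword staircase that recovers those parameters, a
    formal classification of irreplaceable-necessary and
    replaceable-sufficient reading conditions from monotone outcome oracles,
    text segmentation with fixation and saccade planning that respects
    unsplittable grapheme clusters, and a simulator comparing unguided with
    computer-guided segmented reading, including error-reduction and Hedges g
    effect-size accounting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
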