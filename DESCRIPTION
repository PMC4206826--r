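Package: calpop
Title: Population Calcium Imaging Analysis of Dopamine-Modulated Cortical Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-photon population calcium imaging of
    cortical responses under paired sensory and dopaminergic stimulation.
    Implements dF/F extraction with sliding-median baselines, calcium
    transient quantification (summed response, peak, exponential decay
    constant), population-vector cosine pattern similarity across stimulus
    repetitions, occurrence reliability via Cronbach's alpha, and a
    mixed-design inference layer (split-plot repeated-measures ANOVA with
    Ryan's stepwise post hoc, paired t tests with Holm's adjustment).
    Includes a minimal movie-to-traces front end (rigid registration, cell
    detection, astrocyte exclusion) and a synthetic-data generator with
    ground truth that emulates paired-conditioning experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
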