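Package: nigratarget
Title: Dual Subthalamic Nucleus and Substantia Nigra Trajectory Planning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry, engagement scoring and machine-learned targeting rules for
    deep brain stimulation lead trajectories that aim at the subthalamic nucleus
    (STN) while engaging the substantia nigra pars reticulata (SNr) or pars
    compacta (SNc). Provides synthetic subcortical anatomy and electrode cohorts,
    trajectory feature extraction in a native AC-PC frame (midsagittal and AC-PC
    plane angles, offsets from the Bejjani origin on the plane of maximal red
    nucleus cross-section), atlas-based contact and trajectory engagement
    classification with virtual lead extension, volume-of-activated-tissue
    overlap profiles, Gaussian process classifiers with expectation-propagation
    inference for engagement probability maps and rule extraction, and a
    logistic depth rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
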