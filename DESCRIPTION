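Package: carotidflow
Title: Carotid Artery Hemodynamics from Pulsatile Velocity Waveforms
Version: 0.1.0
Authors@R:
    person("Clinical Hemodynamics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates endothelial shear stress (ESS) at the carotid artery
    from centerline Doppler velocity waveforms using the Womersley solution
    for pulsatile flow in a rigid tube, classifies the flow regime by
    Reynolds number, and reproduces a repeated-measures exercise-physiology
    analysis: linear mixed-effects models with Satterthwaite denominator
    degrees of freedom, Holm-corrected paired post-hoc comparisons with
    Hedges' g effect sizes, bootstrap coefficient-of-variation reliability,
    and condition-level Reynolds confidence intervals. Includes a seeded,
    participant-structured synthetic waveform generator calibrated to
    published condition-level ESS distributions, and a command-line pipeline
    (simulate, compute-ess, analyze) tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    data.table,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
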