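Package: objdens
Title: Natural Statistics of Object Density and Weight-Expectation Psychophysics
Version: 0.1.0
Authors@R: person("objdens", "maintainers", email = "maintainers@objdens.org", role = c("aut", "cre"))
Description: Tools for characterizing the empirical relationship between the
    volume and density of everyday liftable objects and for comparing it
    against human weight-expectation judgments. Implements loaders for
    environmental object tables, enclosed-volume computation for watertight
    triangle meshes, log-log correlation and power-law fitting of density
    against volume, full-factorial small/large pair-ratio machinery with
    weight- and density-ratio line fits, a ratio-report psychophysics
    analysis stack (response normalization, Lilliefors normality checks,
    one-sample t-tests, split-plot mixed-design ANOVA, Benjamini-Hochberg
    false discovery rate correction, Cohen's d, perceptual ratio-line fits),
    seeded generative models for synthetic object populations and observer
    cohorts, and a config-driven pipeline that writes report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
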