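Package: onhmorph
Title: Optic Nerve Head Morphometry and Longitudinal Ocular-Hypertension
    Analysis from Segmented OCT Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes optic nerve head (ONH) structural measures from
    segmented optical coherence tomography (OCT) surfaces: the Bruch's
    membrane opening (BMO) reference plane and area, mean anterior lamina
    cribrosa depth (LCD), rim-constrained minimum rim width (BMO-MRW), and
    lamina cribrosa visibility. Also provides the longitudinal analysis
    used in primate microbead ocular-hypertension studies: weekly-to-monthly
    intraocular pressure aggregation, per-interval structural-change
    statistics, group summaries, and primate-controlled Pearson partial
    correlation with Fisher z inference. A synthetic phantom and cohort
    generator with analytically known ground truth makes every stage
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
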