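Package: membranekit
Title: Yeast Membrane Model Composition, Bilayer Structural Properties,
    Lipidomics Summaries and Weak-Acid Uptake Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing yeast plasma-membrane bilayer model
    compositions with very-long-chain glycerophospholipid substitution,
    estimating structural membrane properties (area per lipid, phosphate-plane
    thickness, deuterium order parameter) from coordinate frames, summarizing
    shotgun-lipidomics species tables into strain-level metrics (chain length,
    saturation, headgroup shape classes), and analysing weak-acid (acetic
    acid) equilibrium and uptake kinetics via the Henderson-Hasselbalch
    relation and saturating or linear regressions. Includes synthetic bilayer
    and lipidome generators with analytically known ground truth, GRO-format
    coordinate I/O, and a hydrogen mass repartitioning utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
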