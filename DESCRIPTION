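Package: ionNTCP
Title: Dosimetric and NTCP Comparison of Photon, Proton and Helium Ion Treatment Plans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired comparison of radiotherapy treatment plans across
    photon, proton and helium ion modalities from exported dose-volume
    histograms (DVHs). Provides a plain-text DVH interchange format, the
    standard dosimetric indices (Dx quantiles, mean dose, homogeneity index,
    inhomogeneity coefficient, integral dose), generalized equivalent uniform
    dose (gEUD) and Lyman-Kutcher-Burman normal tissue complication
    probability (NTCP) for auditory and endocrine endpoints, exact paired
    nonparametric statistics (Friedman and Wilcoxon signed-rank tests with
    permutation-exact p-values), and a seeded synthetic cohort generator with
    a voxel-level oracle for validating DVH-derived quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, StatisticalMethod
RoxygenNote: 7.3.3
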