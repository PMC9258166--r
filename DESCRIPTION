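Package: oplsage
Title: Two-Group Metabolomics Discrimination and Age-Dependent Pathway
    Analysis with OPLS
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for two-group targeted-metabolomics studies: NIPALS
    PLS-DA and OPLS estimators with cross-validated predictability (Q2)
    and variable-influence-on-projection (VIP) scores, permutation and
    bootstrap model validation with an overfitting diagnostic, a
    four-step VIP/PCA biomarker selection procedure with bootstrap
    stability filtering, group-stratified Spearman screening of
    principal-component scores against age under Bonferroni control,
    metabolite-set over-representation analysis, and a synthetic cohort
    generator with planted block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
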