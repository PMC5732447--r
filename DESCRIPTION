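Package: liverqmr
Title: Multiparametric Quantitative MR Analysis of Hepatic Ischemia-Reperfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise fitting of intravoxel incoherent motion (IVIM)
    bi-exponential diffusion, diffusion-tensor mean diffusivity and
    fractional anisotropy, and multi-echo R2* relaxometry for quantitative
    liver MRI, together with a synthetic two-group phantom cohort generator
    (Gaussian-copula dependence, Rician noise), a six-ROI summarization
    protocol, and the cohort statistics used in small-animal
    ischemia-reperfusion studies: two-way random-effects intraclass
    correlation, pooled t and Mann-Whitney U group comparisons, Pearson and
    Spearman correlation, and percent-change summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    optparse
Config/testthat/edition: 3
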