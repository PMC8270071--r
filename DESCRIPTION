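Package: aacscore
Title: Semi-Quantitative Abdominal Aortic Calcification Scoring from CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated pipeline for grading abdominal aortic calcification
    (AAC) severity on contrast-enhanced CT angiography. Measures the
    calcified fraction of the anterior and posterior aortic walls over the
    segment between the inferior mesenteric artery and the iliac
    bifurcation, maps the fractions onto a six-point severity score, and
    computes a reference Agatston-style calcium score over the same
    segment. Includes sagittal slab maximum-intensity-projection
    reformatting with bone-window display mapping, a synthetic
    contrast-CTA phantom generator with analytic ground truth, and
    inter-rater agreement statistics (two-way ANOVA intraclass
    correlation with F-based confidence intervals, and Spearman rank
    correlation with exact permutation p-values at small n).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    png,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
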