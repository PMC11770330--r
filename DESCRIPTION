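Package: disconnectr
Title: Tract-Based Lesion Disconnection Factors and Post-Stroke Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping structural disconnection from binary lesion
    masks (infarcts and white matter hyperintensities) against a streamline
    tract atlas, discovering latent disconnection factors with a variational
    latent Dirichlet allocation model selected by cross-run stability, and
    relating factor loadings to post-stroke cognitive impairment with
    logistic, likelihood-ratio, permutation canonical-correlation and
    random-intercept mixed logistic analyses. Includes a synthetic cohort
    generator (template geometry, streamline atlas, lesion masks,
    planted-factor disconnection corpora and cognitive outcomes) so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
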