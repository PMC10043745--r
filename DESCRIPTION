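Package: costshare
Title: Inferring Insurance Cost-Sharing Mechanisms and Modelling Follow-On
    Breast Imaging Utilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how commercial insurance cost-sharing design
    relates to the use of follow-on diagnostic breast imaging after a
    screening mammogram, built around administrative claims data.  Provides a
    synthetic claims generator with known ground truth; construction of
    screening-mammogram episodes of care from claims (index events,
    inclusion and exclusion rules, Charlson comorbidity scoring,
    out-of-pocket cost tabulation); inference of each plan's cost-sharing
    mechanism from claims via a (mode copay, mode coinsurance, maximum
    deductible) triplet and min-max-scaled k-means with a deterministic
    origin-seeded cluster; a two-part hurdle model combining logistic
    regression with a zero-truncated negative binomial count model fitted
    from the likelihood, with delta-method average marginal effects and
    optional Duan smearing; and summary reporting tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
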