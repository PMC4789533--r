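Package: factconn
Title: Deterministic Tractography Connectomics with Permutation Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural-connectivity analysis pipeline for diffusion tensor
    imaging: log-linear tensor fitting, FACT (fiber assignment by continuous
    tracking) deterministic streamline tractography, fiber-count connectome
    construction over a motor-related parcellation, edge-wise permutation
    testing with max-statistic family-wise error control, Holm-Bonferroni
    corrected Spearman screening against clinical scores, and leave-one-out
    cross-validated linear support-vector classification. Ships synthetic
    diffusion phantoms and synthetic patient cohorts with planted effects so
    the whole pipeline is testable without access-controlled imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
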