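Package: htcpamd
Title: EMR-Based Phenotyping and SNP Association for Age-Related Macular
    Degeneration Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based high-throughput clinical phenotyping (HTCP) of
    electronic medical record (EMR) extracts to select age-related macular
    degeneration (AMD) cases (wet and dry subtypes) and controls from
    ICD-9 diagnosis codes, CPT/HCPCS procedure codes and medication
    orders; chart-review validation metrics (positive and negative
    predictive value, false negative rate) that certify such an
    algorithm; covariate-adjusted additive allelic-dosage logistic
    regression and pooled allelic odds ratios for candidate-SNP
    case-control association; and a synthetic EMR cohort and
    case-control genotype simulator with planted ground truth for
    end-to-end testing without any real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
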