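Package: gvhdgrade
Title: Consensus Grading and Course Classification of Graft-Versus-Host
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A validated rule engine for graft-versus-host disease (GvHD)
    assessment after allogeneic hematopoietic cell transplantation.
    Implements per-organ acute staging and five overall acute grading
    systems (MAGIC, Keystone/modified Glucksberg, Minnesota, IBMTR and
    original Glucksberg), MAGIC diagnostic-confidence levels, the NIH 2014
    chronic GvHD global severity score with the lung exception and legacy
    Seattle categories, and longitudinal course classification (GvHD type,
    onset, activity status and steroid-response categories) over dated
    patient timelines. Ships a versioned JSON patient-record schema,
    reviewable YAML rule files with rule tracing, a seeded synthetic-cohort
    generator with constructive ground-truth labels, and cross-system
    concordance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
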