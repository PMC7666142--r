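Package: ratepart
Title: Group-Specific Bacterioplankton Growth Rates and Mortality
    Partitioning from Manipulation Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates net growth rates of bacterioplankton groups from
    cell-abundance time courses in seasonal dilution/size-fractionation
    microcosm experiments, and partitions them into gross growth, grazing
    mortality, resource-limitation constraint and viral mortality with a
    four-treatment linear budget (control, predator-reduced, diluted and
    virus-reduced incubations). Includes response ratios quantifying the
    relative effects of grazing, resources, viruses and light, a synthetic
    microcosm generator with known ground truth for validation, and the
    comparative statistics used in such studies (one-way ANOVA with Tukey
    HSD, Ward hierarchical clustering, one-way PERMANOVA, and rate-range
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
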