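Package: methvar
Title: Longitudinal Methylome Variability: Variably Methylated Probes and Private Epimutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of longitudinal DNA methylation variability from
    Illumina beta-value matrices in a two-timepoint, two-group cohort design.
    Implements variably methylated probe (VMP) detection by group-median
    comparison of per-subject longitudinal beta differences, private
    epimutation detection by per-CpG variance F-tests with
    Benjamini-Hochberg FDR control followed by individual outlier calling
    against the group median, array-level probe and sample quality-control
    filters, and a synthetic longitudinal cohort generator with known
    planted truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
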