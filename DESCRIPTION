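Package: poolscreen
Title: Ratiometric Analysis of Pooled Isogenic Knockout Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multiplexed, sequence-based ratiometric
    viability screens run on pooled isogenic knockout cell lines. Covers the
    full path from barcoded paired-end amplicon reads (14-nt unique molecular
    identifiers, plate and well barcodes, integrated gRNA sequences used as
    cell-line barcodes) through mismatch-tolerant demultiplexing and UID
    deduplication to per-well abundance ratios, plate-wise Z-scores,
    staurosporine non-specific-killing filters, an in-silico down-sampling
    power analysis, and two-background majority hit calling. Includes a
    generative simulator of the pooled co-culture screen for power studies and
    validation, and a CRISPR knockout-validation classifier (out-of-frame
    indel calling from UID-collapsed amplicons, exon-skip rescue logic, and
    RNA-evidence rules).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
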