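Package: credo
Title: Confident RNA-Editing Discovery from Matched Tumor-Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical discovery of highly confident A-to-I (read as A-to-G)
    RNA-editing sites from allele counts of RNA and DNA sequencing of matched
    normal and tumor samples across a cohort. Implements a zero-confidence
    filter based on exact one-sided binomial upper confidence bounds of the
    alternative-allele probability in DNA, strand-bias and depth candidate
    filters, subtraction of called DNA variants, odds-ratio plus Fisher exact
    test discovery between matched samples (or RNA versus DNA in single-sample
    mode), cross-individual recurrence aggregation, dbSNP-overlap
    false-positive assessment, ADAR differential-expression flagging, and
    Kaplan-Meier / log-rank survival association of editing markers. A
    synthetic matched-cohort simulator with planted editing events, germline
    SNPs, sequencing error and strand artifacts provides ground truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
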