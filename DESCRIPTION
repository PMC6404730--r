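Package: tatadom
Title: TBP-Promoter Affinity Modelling of Regulatory SNPs and
    Dominance/Subordination Candidate Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the expression-direction effect of single nucleotide
    polymorphisms in the 70 bp core promoter region upstream of the
    transcription start site from a three-step model of TATA-binding
    protein (TBP) binding to the promoter (sliding, site-specific stopping,
    DNA bending). Allele affinities (-ln KD with uncertainty) are compared
    with a Fisher Z-score; significant shifts are mapped through curated
    protein-phenotype polarity annotations to candidate SNP markers of
    social dominance or subordination. Includes exact binomial dichotomy
    tests (equiprobable and 4:1 neutral-drift nulls), a chi-squared
    equal-split test, dyadic mouse contest scoring with per-maternal-strain
    cross tabulation, and a synthetic-data module generating promoters,
    variants, annotations and contest records with controlled structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
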