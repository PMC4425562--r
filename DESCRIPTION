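Package: sideroseq
Title: Expression Signatures and Variant Triage for Low-Risk Myelodysplastic
    Syndromes with Ring Sideroblasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for integrative expression and targeted
    resequencing studies of low-risk myelodysplastic syndromes (MDS),
    in particular refractory anemia with ring sideroblasts (RARS).
    Provides permutation-based differential expression in the style of
    Significance Analysis of Microarrays (SAM) with fudge-factor search
    and empirical q-values; an empirical-Bayes moderated t engine; a
    random-subsampling consensus signature selector with a permutation
    global association test; gene-list overlap odds ratios, exact and
    chi-square contingency tests, and hypergeometric / EASE functional
    enrichment; and a targeted-capture variant triage cascade with
    codon-level amino-acid-change annotation and two-SNP haplotype
    case-control comparison.  A synthetic cohort generator with known
    ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    Biostrings,
    fgsea,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    limma,
    seqinr,
    jsonlite
Config/testthat/edition: 3
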