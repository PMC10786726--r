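Package: apobecsig
Title: APOBEC Mutational-Signature, Context and Chromosomal-Instability
    Analysis for Targeted-Therapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of the computational analyses used to
    study APOBEC3B-driven mutagenesis in lung cancer under tyrosine kinase
    inhibitor therapy: pyrimidine-oriented trinucleotide and pentanucleotide
    context classification of somatic substitutions (TCN, TCW, RTCW, YTCW),
    96-channel mutation catalogs and signature refitting with a contribution
    cutoff, multi-caller somatic variant filter cascades, multi-region
    copy-number intratumor heterogeneity and chromosome-missegregation
    statistics, and exact small-sample nonparametric tests. A synthetic-data
    module generates reference sequences, signature-mixture mutation catalogs,
    paired pre-/post-treatment cohorts, caller evidence and multi-region
    copy-number profiles so every stage is testable without controlled-access
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
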