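Package: ubtftd
Title: Detection, Annotation and Clonal Analysis of UBTF Exon-13 Tandem Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the study of internal tandem duplications (TDs) of the
    UBTF gene in acute myeloid leukemia. Provides a synthetic gene-model and
    read/trace/cohort simulator, an in-silico capillary fragment-analysis
    screen, a soft-clip and coverage based TD caller with breakpoint
    reconstruction and variant allele fraction estimation, splice-aware
    in-frame annotation with cohort-level minimal duplicated region analysis,
    copy-number-corrected clonal evolution inference from paired diagnosis
    and relapse samples, and exact contingency statistics with
    Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
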