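Package: mmrsplice
Title: Splicing Assay Interpretation and Multifactorial Classification of
    Mismatch Repair Gene Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting the effect of mismatch repair (MMR) gene
    sequence variants on mRNA splicing and for integrating splicing and
    protein functional assay observations into InSiGHT five-class variant
    classifications. Provides HGVS c. substitution parsing against transcript
    models, donor/acceptor splice-site scoring with sliding-window analysis
    and native-loss/de-novo-gain categorization, categorization of mRNA
    splicing assay outcomes (complete/incomplete/unknown extent) and of
    in vitro MMR repair activity (deficient/moderate/proficient), Bayesian
    multifactorial likelihood combination with posterior-to-class mapping,
    a qualitative decision-tree rule engine with a splicing-contribution
    determination, variant-table I/O with dataset summarization, and a
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
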