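# mmrsplice

Interpretation of mRNA splicing assays for mismatch repair (MMR) gene
variant classification.

Loss-of-function variants in the MMR genes (*MLH1*, *MSH2*, *MSH6*,
*PMS2*) cause Lynch syndrome, and a substantial fraction of reported
variants act by disrupting mRNA splicing rather than by changing the
protein directly. Clinical laboratories therefore combine three kinds of
evidence: bioinformatic splice-site predictions, patient-RNA or minigene
splicing assays, and in vitro MMR repair-activity (CIMRA) measurements,
all folded into the InSiGHT five-class scheme (1 benign ... 3 VUS ... 5
pathogenic). `mmrsplice` implements that computation end to end for
curators and method developers: from an HGVS `c.` description and a
transcript model to a class, a posterior probability, and a determination
of whether the splicing assay was decisive.

## What it computes

**Splice-site prediction.** Donor sites are scored over 9-base windows
(last 3 exonic + first 6 intronic bases), acceptors over 23-base windows
(last 20 intronic + first 3 exonic). For a variant, a sliding-window
analysis scores every window containing the variant base and keeps the
maximum alternate-sequence score `alt`, with `diff = ref − alt` for the
same window on the reference. Predictions are categorized into
native-loss and de-novo-gain groups (minimal / moderate / high) using the
published thresholds, e.g. *native loss high* when `diff ≥ 1.15` and
`alt < 6.2`, *gain high* when `diff < 0` and `alt > 8.5` (thresholds are
MaxEntScan-scale and configurable; a trainable log-odds weight-matrix
scorer and a plain-text matrix-file format are provided).

**Assay categorization.** Splicing assays are categorized by allele
attribution: *complete* impact (variant allele yields only aberrant
transcript), *incomplete* (full-length transcript also expressed),
*unknown* extent, or *none*. Repair activity (percent of wild type) maps
to deficient / moderate / proficient with gene-specific thresholds
(MLH1/MSH2: <23% and ≥70%; MSH6/PMS2: <18% and ≥100%).

**Classification.** The multifactorial likelihood engine combines a prior
probability with independent likelihood ratios in odds form,

    posterior odds = prior/(1−prior) × ∏ LRᵢ ,

maps the posterior to classes at 0.001 / 0.05 / 0.95 / 0.99, and runs a
qualitative decision tree in parallel (loss-of-function types are
pathogenic outright; canonical IVS±1/2 variants are at least likely
pathogenic, upgradeable by allele-specific complete impact; a complete
impact with a frameshift/PTC product is a demonstrated null allele; a
clean assay with NMD inhibition supports likely benign for silent and
intronic variants). The splicing-contribution flag answers: would the
class change if the splicing assay were removed?

## Worked example

The packaged 24-variant study table can be re-classified from its raw
assay observations:

```r
library(mmrsplice)
tab <- table1_fixture()
cl  <- classify_variants(tab)
cl[cl$cdna %in% c("c.793C>T", "c.2154A>G", "c.454-13A>G"),
   c("gene", "cdna", "impact", "class", "contributes", "rationale")]
#>  gene        cdna   impact class contributes                 rationale
#>  MLH1    c.793C>T complete     5         yes  complete_ptc_null_allele
#>  MSH2   c.2154A>G     none     2         yes      no_aberration_benign
#>  MLH1 c.454-13A>G  unknown     4         yes aberration_unknown_extent
```

`c.793C>T` expresses only the frameshift transcript r.791_884del from the
variant allele, which the rule engine treats as a demonstrated null
allele (class 5, splicing decisive). `c.2154A>G` is a silent variant with
no aberration under NMD inhibition (class 2). `c.454-13A>G` causes exon
skipping but the extent could not be attributed to the allele, so it
stops at likely pathogenic.

```r
summarize_variants(tab)
#> Variant dataset summary: 24 record(s), 24 unique variant(s)
#>   by gene: MLH1 11, MSH2 10, MSH6 3, PMS2 0
#>   by type: missense 12, silent 5, splice_site 3, intronic 4
#>   splicing impact: complete 2, incomplete 4, unknown 5, none 13
#>   splicing contributed to classification for 9/24 variants
#>   deficient repair activity classified 4/5: 5/5 (100%)
```

Single-bundle classification and the Bayes engine are available directly:

```r
e <- evidence_bundle("missense", splicing_impact = "complete",
                     allele_specific = TRUE,
                     aberrant_transcript_frame = "ptc_or_frameshift",
                     nmd_inhibitor_used = TRUE)
apply_rules(e)
#> InSiGHT class 5 (qualitative)
#>   rules fired: complete_ptc_null_allele

combine_posterior(0.1, c(tumor = 8, segregation = 15, functional = 10))
#> [1] 0.9925558
```

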