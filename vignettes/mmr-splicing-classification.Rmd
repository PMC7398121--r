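---
title: "Methods: splicing evidence and multifactorial classification of MMR gene variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing evidence and multifactorial classification of MMR gene variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrsplice)
```

## Scope and model

`mmrsplice` models the interpretation chain used in Lynch-syndrome
variant curation: a sequence variant described at the cDNA level is
located on a transcript model, scored for its predicted effect on splice
sites, joined with laboratory observations (mRNA assays and repair-activity
assays), and classified on the InSiGHT five-class scale by a quantitative
Bayesian combination and a qualitative decision tree run in parallel.

The package assumes plus-strand transcript models carrying the
transcript-sense pre-mRNA; genomic strand handling and liftover are out
of scope. HGVS coordinates are 1-based with +1 at the A of the ATG
initiation codon; coordinates are converted to internal pre-mRNA indices
in a single function (`cdna_to_premrna()`), so the HGVS conventions
(no position zero, `+k`/`-k` intron offsets anchored at exon edges) live
at one boundary only. Internal indexing is 1-based inclusive, the natural
convention for R string handling. Only substitutions are fully modelled;
other edit kinds are recognized and rejected with a distinct error, since
the assay-interpretation logic downstream does not need them.

## Splice-site scoring and categorization

Two window geometries are fixed by the biology: donors are scored on
9-mers (last 3 exonic + first 6 intronic bases), acceptors on 23-mers
(last 20 intronic + first 3 exonic bases). Two scorer implementations
share this interface: a trainable position weight matrix
(`train_wmm()`; per position `log2((count + c)/(N + 4c)) − log2(bg)` with
pseudocount `c = 0.5` and uniform background by default) and a
plain-text matrix file loader (`load_score_matrix()`), which accepts any
externally calibrated position score grid of the same shape. All
categorization logic is scorer-agnostic.

The sliding-window analysis (`swa_scan()`) scores every window
containing the variant base on the alternate sequence and reports the
maximum as `alt`, with `diff = ref − alt` computed on the same (argmax)
window; ties go to the lowest window start so results are deterministic.
The native-site analysis (`native_delta()`) instead scores the fixed
window of the annotated site overlapping the variant; a variant touching
no native window returns a no-overlap marker and native loss defaults to
minimal, since no score change at an annotated site is possible. Both
views are reported in parallel (`predict_splicing()`) and categorized
independently: the literature does not prescribe a single merged call
when a native-site weakening and a de-novo gain overlap the same
variant, and cryptic-site activation is naturally represented as a gain
whose window anchor differs from every native site.

The published category predicates overlap when read literally (for
example `diff < 0` with `alt < 6.2` satisfies both a minimal and a
moderate clause). They are resolved into a total precedence ladder:

* native loss — `diff < 0` → minimal; `alt > 8.5` → minimal;
  `6.2 ≤ alt ≤ 8.5` → moderate iff `diff ≥ 1.15`, else minimal;
  `alt < 6.2` → high iff `diff ≥ 1.15`, else moderate.
  A score that improves, or remains strong, cannot indicate loss.
* gain — high iff `diff < 0` and `alt > 8.5`; moderate iff `diff < 0`,
  `6.2 ≤ alt ≤ 8.5` **and** the alternate outscores the closest native
  site of the same kind (the published phrasing omits the conjunction;
  it is implemented as a logical AND); ties with the native score are
  minimal, the conservative reading.

The thresholds (1.15 score units for a substantive drop; 6.2 and 8.5 for
the weak/strong score bands) are calibrated to MaxEntScan-scale scores
and are configuration (`splice_thresholds()`), not constants: the
built-in weight-matrix scorer lives on a different scale, so category
tests feed `(diff, alt)` pairs directly and real analyses should pair
the thresholds with an appropriately calibrated matrix.

## Assay categorization

Splicing impact is determined by allele attribution: complete (variant
allele expresses only aberrant transcript), incomplete (full-length also
present), unknown (aberration seen, attribution not assessable), none.
Attribution is only assessable when the variant base is observable in
the cDNA or an allele-specific technique was used; the constructor
(`splicing_assay_result()`) enforces this, and the quantitative
"minimal residual full-length" judgment is delegated to the data
producer as a yes/no/not-assessable field because no numeric cutoff is
established. r. transcript descriptions are kept verbatim; the only
parsing applied is a deletion/duplication-span frame heuristic
(span length mod 3) used by the rule engine to decide whether the
aberrant product is PTC/frameshift.

Repair activity categorizes as deficient / moderate / proficient with
gene-specific thresholds (MLH1/MSH2 23 and 70 percent of wild type,
MSH6 18 and 100; PMS2 borrows the MSH6 thresholds in lieu of a
calibrated PMS2 functional LR, its penetrance being the closer match).
The moderate band is closed-open, `[deficient, proficient)`, forced by
the published inequalities. When several published activity values exist
for one variant, the highest (most conservative) is used.

## Classification

The quantitative route multiplies prior odds by independent likelihood
ratios (tumor characteristics, segregation, functional) and maps the
posterior to classes at 0.001 / 0.05 / 0.95 / 0.99. The inner cut-offs
are the published likely-pathogenic and likely-benign bounds; the outer
two come from the IARC scheme that the InSiGHT rules adopt, and all four
are configuration (`class_cutoffs()`). Boundary assignment: exactly 0.95
is class 4, exactly 0.05 is class 3. The combination is computed in
log-odds space; it is permutation-invariant and strictly increasing in
each LR. The CIMRA-activity-to-LR calibration is laboratory-specific
and not published in closed form, so it is accepted as configuration
(step map over function categories, or a monotone piecewise-linear
table); with no calibration the functional LR is 1.0,
evidence-neutral.

The qualitative route is an ordered rule walk; the first terminal rule
fires:

1. frameshift/nonsense variant types → class 5 regardless of splicing
   results;
2. canonical IVS±1/2 dinucleotide → class 4, upgraded to 5 only by an
   allele-specific demonstration of complete impact;
3. complete impact with a PTC/frameshift product → class 5 (a complete
   call already rests on allele-specific evidence, so this is a
   demonstrated null allele);
4. aberration with unknown extent and a PTC/frameshift product →
   class 4 (the missing allele-specific quantification is exactly what
   separates this from class 5);
5. no aberration for silent/intronic variants → class 2 if an NMD
   inhibitor was used, otherwise capped at VUS;
6. incomplete impact contributes nothing on its own; deficient or
   proficient repair activity is recorded as supporting context and
   flows through the quantitative route.

Reconciliation of the two routes is deliberately explicit: on the same
side of the VUS band the class farther from VUS wins (5 over 4 on the
pathogenic side, 1 over 2 on the benign side); a VUS route never
overrides a non-VUS one; opposite sides give class 3 with a conflict
flag rather than a silent override. The "more pathogenic wins" shortcut
was rejected because it would let a weaker likely-benign call override a
quantitative benign classification. The splicing-contribution flag is
computed operationally: classify with the assay evidence, classify
again with it stripped (location-based evidence and clinical LRs
remain), and report whether the class changed.

## The packaged study table

`table1_fixture()` transcribes the 24-variant assay study (12 missense,
5 silent, 3 canonical splice-site, 4 other intronic variants in
MLH1/MSH2/MSH6) with its observed transcripts, attribution fields,
printed classes and contribution flags. The per-variant clinical
likelihood ratios behind the printed classes are not published in the
main text, so the fixture carries a reconstructed minimal set of
LR values consistent with each printed class (flagged in its `notes`
column); the regression test then demands that the engine reproduce
every printed impact, class and contribution flag from the raw
observation columns. Repair-activity percentages for the fixture's
missense rows are likewise plausible reconstructions placed in the
published category, not measured values.

## Synthetic data

The generator emulates the collated splicing-assay dataset, not any
particular gene's sequence: per record it draws gene (48/34/11/7% for
MLH1/MSH2/MSH6/PMS2), variant type (the published mix over 671
variants), splice-region membership, native-loss and gain prediction
categories, then the aberration flag, then the impact split
(92/33/116 over complete/incomplete/unknown) with consistent assay
columns. Canonical-dinucleotide records are always aberrant.

The published conditional rates are defined on two different margins:
native-loss conditionals (98/80/21%) among splice-region variants, gain
conditionals (50/43/35%) among all variants, and the two margins are not
mutually consistent under independence. The generator therefore uses
native-loss-driven base rates plus a mean-zero gain adjustment, solves
the outside-splice-region baseline so the overall rate matches the gain
margin, and deflates the non-canonical high-category base rate so the
pooled high-category rate stays at its configured value despite the
forced-aberrant canonical records. Configured rates of exactly 0 or 1
are preserved deterministically. The summarizer conditions its
cross-tabulations the same way the rates are defined, so configured
rates are recovered within binomial noise.

What passing tests on synthetic data do **not** show: the generator has
no sequences behind its records (prediction categories are drawn, not
scored), no NMD kinetics, no transcript quantification, and no
correlation structure between variant type and clinical evidence. It
validates the bookkeeping and the conditional structure of the pipeline,
not the biology.

Toy transcripts (`generate_transcript()`) are random sequences with
GT..AG introns and consensus donor (`CAG|GTAAGT`) and acceptor
(pyrimidine tract + `CAG|` + 3 exonic bases) junctions; training windows
are consensus copies with independent per-base corruption at rate
`1 − consensus_strength` (default 0.1, enough to give the weight matrix
realistic spread while keeping junctions the clear optimum).

## Numerical choices and problem sizes

Scores are plain doubles; matrix files store 17 significant digits so a
write/load round trip is exact to scoring precision. Window-score ties
break to the lowest start; activity-value ties keep input order;
percentages round half away from zero to integers, matching the
reporting style of the field. The posterior is computed via `plogis` on
the log-odds sum, stable for extreme LR products.

The test suite sizes were chosen to make the statistical checks sharp at
interactive runtimes: 10^5 random score triples for category
totality/exclusivity, ≥50 random transcript/variant pairs (each against
an exhaustive enumeration oracle, for both scorer implementations), and
a 5000-variant synthetic table whose six conditional aberration rates
must each fall within three binomial standard errors of their configured
values. Cross-study conflict handling uses severity order complete >
incomplete > unknown > none for headline tallies and reports conflicts
separately, since the field has no agreed merge rule.

## Limitations

Exonic splicing enhancer/silencer effects are not predicted (the
motivating analyses found available ESE/ESS tools too unspecific), so
splice-region triage here will miss purely regulatory exonic
spliceogenic variants. The rule engine covers the splicing and
functional arms of the InSiGHT criteria, not the full criteria document
(population frequency, co-occurrence, exon-specific priors). Accessions
are opaque labels; reference-sequence version mismatches surface as
reference-allele errors, strict by default and downgradable to warnings.
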