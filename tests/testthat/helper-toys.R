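# Hand-built two-exon transcript with fully known coordinates:
#   exon1 1..12 (CDS starts at 1), intron1 of 30 nt (GT...AG), exon2 13..21.
# mRNA: ATGAAACCCGGG | GTTCCCTAA  (21 nt CDS, stop at the end)
toy_two_exon <- function() {
  exon1 <- "ATGAAACCCGGG"
  intron1 <- paste0("GTAAGT", strrep("T", 20), "CCAG")   # 30 nt
  exon2 <- "GTTCCCTAA"
  transcript_model("MLH1", "TOY_2EX",
                   exons = rbind(c(1L, 12L), c(13L, 21L)),
                   intron_lengths = 30L,
                   premrna_seq = paste0(exon1, intron1, exon2),
                   cds_offset = 0L)
}

# Single-exon one-codon-of-interest toy: ATG GGG TAA
toy_codon <- function() {
  transcript_model("MLH1", "TOY_1EX", exons = cbind(1L, 9L),
                   intron_lengths = integer(0),
                   premrna_seq = "ATGGGGTAA", cds_offset = 0L)
}

# Independent sliding-window oracle: enumerate every window of the scorer's
# length containing the variant base on the alternate sequence, take the
# max (first on ties), pair with the same window on the reference.
enumerate_swa <- function(v, t, scorer) {
  idx <- cdna_to_premrna(t, v$cdna_pos, v$intron_offset, v$utr)
  alt <- t$premrna_seq
  stopifnot(substr(alt, idx, idx) == v$ref_allele)
  substr(alt, idx, idx) <- v$alt_allele
  L <- scorer$window_len
  n <- nchar(alt)
  best <- -Inf; best_start <- NA_integer_
  for (s in seq(max(1L, idx - L + 1L), min(idx, n - L + 1L))) {
    sc <- score_windows(scorer, substr(alt, s, s + L - 1L))
    if (sc > best) { best <- sc; best_start <- s }
  }
  list(alt_score = best,
       ref_score = score_windows(scorer,
                                 substr(t$premrna_seq, best_start, best_start + L - 1L)),
       anchor = best_start)
}

# Raw published category predicates, evaluated directly (vectorized); used
# to cross-check the precedence ladder.
raw_native_predicates <- function(diff, alt) {
  cbind(minimal = diff < 0 | alt > 8.5 | (diff < 1.15 & alt >= 6.2 & alt <= 8.5),
        moderate = (diff >= 1.15 & alt >= 6.2 & alt <= 8.5) |
                   (diff < 1.15 & alt < 6.2),
        high = diff >= 1.15 & alt < 6.2)
}

raw_gain_predicates <- function(diff, alt, native) {
  cbind(minimal = diff > 0 | alt < 6.2 |
          (diff < 0 & alt >= 6.2 & alt <= 8.5 & alt < native),
        moderate = diff < 0 & alt >= 6.2 & alt <= 8.5 & alt > native,
        high = diff < 0 & alt > 8.5)
}

# Pick a random valid substitution on a transcript, anywhere a full scorer
# window fits.
random_variant <- function(t, margin = 25L) {
  n <- nchar(t$premrna_seq)
  idx <- sample(seq(margin, n - margin), 1L)
  loc <- premrna_to_cdna(t, idx)
  ref <- substr(t$premrna_seq, idx, idx)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  off <- if (loc$offset > 0L) paste0("+", loc$offset)
         else if (loc$offset < 0L) as.character(loc$offset) else ""
  parse_cdna(paste0("c.", loc$pos, off, ref, ">", alt))
}
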