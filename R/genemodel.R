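#' Construct a transcript model
#'
#' A transcript model anchors HGVS cDNA coordinates (c.; +1 is the A of the
#' ATG initiation codon) on a pre-mRNA sequence. Exons are given as cDNA
#' coding-coordinate spans; `intron_lengths` gives the length of the intron
#' following each junction (one fewer than the number of exons).
#'
#' @param gene_symbol Gene symbol, e.g. "MLH1".
#' @param accession Transcript accession; treated as an opaque label.
#' @param exons Two-column matrix or data frame of `(cdna_start, cdna_end)`
#'   coding-coordinate spans, one row per exon, strictly increasing and
#'   contiguous. A 5' UTR inside exon 1 is expressed through `cds_offset`,
#'   in which case exon 1 starts at coding coordinate `1 - cds_offset`
#'   (HGVS has no position 0; internally the gap is handled centrally).
#' @param intron_lengths Integer vector of intron lengths, one per junction.
#' @param premrna_seq Pre-mRNA sequence over {A,C,G,T}: exon1, intron1,
#'   exon2, ... Length must equal the sum of exon and intron lengths.
#' @param cds_offset Number of transcript bases before the A of the ATG
#'   (5' UTR length carried in exon 1). Default 0.
#' @param cds_length Length of the coding sequence in bases; positions past
#'   it are 3' UTR (c.*N). Defaults to the full transcript after the offset.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_symbol, accession, exons, intron_lengths,
                             premrna_seq, cds_offset = 0L, cds_length = NULL) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (cdna_start, cdna_end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("cdna_start", "cdna_end")
  premrna_seq <- toupper(premrna_seq)
  if (grepl("[^ACGT]", premrna_seq)) stop("premrna_seq must be over {A,C,G,T}")
  cds_offset <- as.integer(cds_offset)
  if (cds_offset < 0L) stop("cds_offset must be non-negative")

  # exon lengths in transcript space; HGVS coding coordinates skip 0, so a
  # span crossing the ATG (start <= -1, end >= 1) is one base shorter than
  # end - start + 1
  span_len <- function(s, e) (e - s + 1L) - as.integer(s < 0L & e > 0L)
  exon_len <- span_len(exons[, 1L], exons[, 2L])
  if (any(exon_len <= 0L)) stop("exon spans must be non-empty and increasing")
  n_ex <- nrow(exons)
  if (length(intron_lengths) == n_ex) {
    if (intron_lengths[n_ex] != 0L) stop("no intron can follow the last exon")
    intron_lengths <- intron_lengths[-n_ex]
  }
  if (length(intron_lengths) != n_ex - 1L)
    stop("need one intron length per junction (n_exons - 1)")
  intron_lengths <- as.integer(intron_lengths)
  if (n_ex > 1L && any(intron_lengths <= 0L)) stop("intron lengths must be positive")

  total <- sum(exon_len) + sum(intron_lengths)
  if (nchar(premrna_seq) != total)
    stop(sprintf("premrna_seq length %d != exon+intron total %d",
                 nchar(premrna_seq), total))

  # contiguity in coding coordinates (accounting for the missing 0)
  if (n_ex > 1L) {
    nxt <- exons[-n_ex, 2L] + 1L
    nxt[nxt == 0L] <- 1L
    if (any(exons[-1L, 1L] != nxt))
      stop("exon spans must be contiguous and strictly increasing")
  }
  first_start <- exons[1L, 1L]
  expect_start <- if (cds_offset > 0L) -cds_offset else 1L
  if (first_start != expect_start)
    stop(sprintf("exon 1 must start at coding coordinate %d given cds_offset %d",
                 expect_start, cds_offset))

  mrna_len <- sum(exon_len)
  if (is.null(cds_length)) cds_length <- mrna_len - cds_offset
  cds_length <- as.integer(cds_length)
  if (cds_length < 1L || cds_offset + cds_length > mrna_len)
    stop("cds_length out of range for this transcript")

  structure(list(
    gene_symbol = gene_symbol, accession = accession,
    exons = exons, exon_lengths = exon_len,
    intron_lengths = intron_lengths, premrna_seq = premrna_seq,
    cds_offset = cds_offset, cds_length = cds_length,
    cum_exon = cumsum(exon_len),
    cum_intron = cumsum(c(0L, intron_lengths))
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript model %s (%s): %d exon(s), mRNA %d nt, pre-mRNA %d nt, CDS offset %d\n",
              x$accession, x$gene_symbol, nrow(x$exons),
              sum(x$exon_lengths), nchar(x$premrna_seq), x$cds_offset))
  invisible(x)
}

# Centralized HGVS -> transcript coordinate conversion. `pos` is the printed
# coding coordinate (always positive here), `utr` disambiguates c.-N / c.*N.
# Returns the 1-based position on the mature transcript (exons concatenated).
coding_to_mrna <- function(t, pos, utr = "none") {
  pos <- as.integer(pos)
  if (pos < 1L) stop("coding coordinate magnitude must be >= 1")
  m <- switch(utr,
    none  = t$cds_offset + pos,
    five  = t$cds_offset - pos + 1L,
    three = t$cds_offset + t$cds_length + pos,
    stop("unknown utr flag: ", utr)
  )
  if (m < 1L || m > sum(t$exon_lengths))
    stop(sprintf("coordinate %s%d outside transcript (mRNA length %d)",
                 switch(utr, none = "c.", five = "c.-", three = "c.*"),
                 pos, sum(t$exon_lengths)))
  m
}

exon_of <- function(t, mrna_pos) {
  findInterval(mrna_pos - 1L, c(0L, t$cum_exon), rightmost.closed = FALSE)
}

#' Map a cDNA coordinate (with optional intron offset) to a pre-mRNA index
#'
#' The single conversion point between HGVS 1-based coding coordinates and
#' the transcript model's internal 1-based pre-mRNA indexing.
#'
#' @param t A `transcript_model`.
#' @param pos Positive coding-coordinate magnitude.
#' @param offset Signed intron offset (0 = exonic; +k after a donor; -k
#'   before an acceptor).
#' @param utr One of "none", "five" (c.-N), "three" (c.*N).
#' @return 1-based index into `t$premrna_seq`.
#' @export
cdna_to_premrna <- function(t, pos, offset = 0L, utr = "none") {
  m <- coding_to_mrna(t, pos, utr)
  e <- exon_of(t, m)
  base <- m + t$cum_intron[e]
  offset <- as.integer(offset)
  if (offset == 0L) return(base)
  if (offset > 0L) {
    # position must be the last base of an exon with a following intron
    if (e >= nrow(t$exons) || m != t$cum_exon[e])
      stop(sprintf("position %d is not an exon end; '+%d' offset invalid", pos, offset))
    if (offset > t$intron_lengths[e])
      stop(sprintf("offset +%d exceeds intron %d length %d", offset, e, t$intron_lengths[e]))
    base + offset
  } else {
    if (e <= 1L || m != t$cum_exon[e - 1L] + 1L)
      stop(sprintf("position %d is not an exon start; '%d' offset invalid", pos, offset))
    if (-offset > t$intron_lengths[e - 1L])
      stop(sprintf("offset %d exceeds intron %d length %d", offset, e - 1L,
                   t$intron_lengths[e - 1L]))
    base + offset
  }
}

#' Map a pre-mRNA index back to a cDNA coordinate
#'
#' Inverse of [cdna_to_premrna()]. Exonic indices map to `(pos, 0)`;
#' intronic indices map to the nearer junction, the 5' half to `+k` after
#' the donor and the 3' half to `-k` before the acceptor (ties to the donor).
#'
#' @param t A `transcript_model`.
#' @param idx 1-based index into the pre-mRNA.
#' @return List with `pos`, `offset`, `utr`.
#' @export
premrna_to_cdna <- function(t, idx) {
  idx <- as.integer(idx)
  if (idx < 1L || idx > nchar(t$premrna_seq)) stop("pre-mRNA index out of range")
  n_ex <- nrow(t$exons)
  mrna_from <- function(m) {
    co <- t$cds_offset
    if (m <= co) list(pos = co - m + 1L, utr = "five")
    else if (m > co + t$cds_length) list(pos = m - co - t$cds_length, utr = "three")
    else list(pos = m - co, utr = "none")
  }
  for (e in seq_len(n_ex)) {
    ex_start <- (if (e == 1L) 1L else t$cum_exon[e - 1L] + 1L) + t$cum_intron[e]
    ex_end <- t$cum_exon[e] + t$cum_intron[e]
    if (idx >= ex_start && idx <= ex_end) {
      m <- idx - t$cum_intron[e]
      r <- mrna_from(m)
      return(list(pos = r$pos, offset = 0L, utr = r$utr))
    }
    if (e < n_ex && idx > ex_end && idx < ex_end + t$intron_lengths[e] + 1L) {
      k <- idx - ex_end
      ilen <- t$intron_lengths[e]
      if (k <= (ilen + 1L) %/% 2L) {
        r <- mrna_from(t$cum_exon[e])
        return(list(pos = r$pos, offset = k, utr = r$utr))
      } else {
        r <- mrna_from(t$cum_exon[e] + 1L)
        return(list(pos = r$pos, offset = -(ilen - k + 1L), utr = r$utr))
      }
    }
  }
  stop("unreachable")  # nocov
}

mrna_seq <- function(t) {
  n_ex <- nrow(t$exons)
  parts <- character(n_ex)
  for (e in seq_len(n_ex)) {
    st <- (if (e == 1L) 1L else t$cum_exon[e - 1L] + 1L) + t$cum_intron[e]
    parts[e] <- substr(t$premrna_seq, st, t$cum_exon[e] + t$cum_intron[e])
  }
  paste0(parts, collapse = "")
}

#' Parse an HGVS cDNA substitution
#'
#' Supports the `c.` substitution grammar with optional intron offsets and
#' UTR coordinates, tolerating internal whitespace ("c.1661 + 5G > C" is
#' read as "c.1661+5G>C"). Other edit kinds (del, dup, ins, delins) are
#' recognized but rejected with a distinct "unsupported" error.
#'
#' @param raw HGVS cDNA description, e.g. "c.454-13A>G".
#' @return An object of class `cdna_variant` with fields `raw`, `cdna_pos`,
#'   `intron_offset`, `utr`, `ref_allele`, `alt_allele`, `edit_kind`.
#' @export
parse_cdna <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  compact <- gsub("[[:space:]]+", "", raw)
  if (!startsWith(compact, "c."))
    stop(sprintf("cannot parse '%s': expected 'c.' prefix", raw))
  body <- substring(compact, 3L)
  if (grepl("(del|dup|ins|inv)", body, ignore.case = TRUE))
    stop(sprintf("unsupported edit kind in '%s': only substitutions are supported", raw),
         call. = FALSE)
  m <- regmatches(body, regexec(
    "^(\\*[0-9]+|-[0-9]+|[0-9]+)([+-][0-9]+)?([ACGTacgt])>([ACGTacgt])$", body))[[1]]
  if (length(m) == 0L) {
    tok <- sub("^(\\*?-?[0-9]+([+-][0-9]+)?)?", "", body)
    if (!nzchar(tok)) tok <- body
    stop(sprintf("cannot parse '%s': unexpected token '%s'", raw, tok), call. = FALSE)
  }
  pos_tok <- m[2]
  utr <- "none"
  if (startsWith(pos_tok, "*")) { utr <- "three"; pos_tok <- substring(pos_tok, 2L) }
  else if (startsWith(pos_tok, "-")) { utr <- "five"; pos_tok <- substring(pos_tok, 2L) }
  off <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  ref <- toupper(m[4]); alt <- toupper(m[5])
  if (ref == alt)
    stop(sprintf("cannot parse '%s': reference and alternate alleles are identical", raw),
         call. = FALSE)
  structure(list(raw = raw, cdna_pos = as.integer(pos_tok), intron_offset = off,
                 utr = utr, ref_allele = ref, alt_allele = alt,
                 edit_kind = "substitution"),
            class = "cdna_variant")
}

#' Format a parsed cDNA variant in canonical compact form
#' @param x A `cdna_variant`.
#' @param ... Unused.
#' @export
format.cdna_variant <- function(x, ...) {
  pos <- switch(x$utr, none = as.character(x$cdna_pos),
                five = paste0("-", x$cdna_pos), three = paste0("*", x$cdna_pos))
  off <- if (x$intron_offset > 0L) paste0("+", x$intron_offset)
         else if (x$intron_offset < 0L) as.character(x$intron_offset) else ""
  paste0("c.", pos, off, x$ref_allele, ">", x$alt_allele)
}

#' @export
print.cdna_variant <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

# Splice-region window geometry: last 20 bases of the intron (acceptor side),
# first 6 bases of the intron (donor side), first/last 3 bases of the exon.
.splice_region <- list(intron_donor = 6L, intron_acceptor = 20L, exon_edge = 3L)

#' Annotate the region containing a variant
#'
#' Flags canonical IVS+/-1/2 dinucleotides and membership in the splice-site
#' region, defined as the last 20 bases of the intron (acceptor side), the
#' first 6 bases of the intron (donor side), or the first/last 3 bases of
#' the exon.
#'
#' @param v A `cdna_variant`.
#' @param t A `transcript_model`.
#' @return An object of class `region_annotation` with fields
#'   `containing_feature`, `dist_to_donor`, `dist_to_acceptor`,
#'   `is_canonical_dinucleotide`, `in_splice_region`, `region_side`.
#' @export
locate <- function(v, t) {
  idx <- cdna_to_premrna(t, v$cdna_pos, v$intron_offset, v$utr)  # range check
  off <- v$intron_offset
  n_ex <- nrow(t$exons)
  if (off == 0L) {
    m <- coding_to_mrna(t, v$cdna_pos, v$utr)
    e <- exon_of(t, m)
    d_don <- t$cum_exon[e] - m                     # bases to last base of exon
    d_acc <- m - (if (e == 1L) 1L else t$cum_exon[e - 1L] + 1L)
    near_donor <- e < n_ex && d_don < .splice_region$exon_edge
    near_acc <- e > 1L && d_acc < .splice_region$exon_edge
    side <- if (near_donor && near_acc) (if (d_don <= d_acc) "donor" else "acceptor")
            else if (near_donor) "donor" else if (near_acc) "acceptor" else "none"
    ann <- list(containing_feature = paste0("exon_", e),
                dist_to_donor = d_don, dist_to_acceptor = d_acc,
                is_canonical_dinucleotide = FALSE,
                in_splice_region = near_donor || near_acc, region_side = side)
  } else if (off > 0L) {
    m <- coding_to_mrna(t, v$cdna_pos, v$utr)
    e <- exon_of(t, m)
    ann <- list(containing_feature = paste0("intron_", e),
                dist_to_donor = off, dist_to_acceptor = -(t$intron_lengths[e] - off + 1L),
                is_canonical_dinucleotide = off <= 2L,
                in_splice_region = off <= .splice_region$intron_donor,
                region_side = "donor")
  } else {
    m <- coding_to_mrna(t, v$cdna_pos, v$utr)
    e <- exon_of(t, m)
    ann <- list(containing_feature = paste0("intron_", e - 1L),
                dist_to_donor = t$intron_lengths[e - 1L] + off + 1L,
                dist_to_acceptor = off,
                is_canonical_dinucleotide = off >= -2L,
                in_splice_region = -off <= .splice_region$intron_acceptor,
                region_side = "acceptor")
  }
  ann$premrna_index <- idx
  structure(ann, class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("%s%s%s (donor %+d, acceptor %+d)\n", x$containing_feature,
              if (x$is_canonical_dinucleotide) ", canonical dinucleotide" else "",
              if (x$in_splice_region) paste0(", splice region (", x$region_side, ")") else "",
              x$dist_to_donor, x$dist_to_acceptor))
  invisible(x)
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Call the coding consequence of a substitution
#'
#' Exonic CDS substitutions are typed by codon comparison under the standard
#' genetic code (silent, missense, nonsense, stoploss, initiation_codon);
#' intronic substitutions are split into `splice_site` (canonical IVS+/-1/2)
#' versus `intronic`; UTR positions return `utr`.
#'
#' @param v A `cdna_variant`.
#' @param t A `transcript_model`.
#' @param strict_ref If TRUE (default) a mismatch between `v$ref_allele` and
#'   the transcript sequence is an error; if FALSE it is a warning.
#' @return A single character value: one of "missense", "silent", "nonsense",
#'   "splice_site", "intronic", "initiation_codon", "stoploss", "utr".
#' @export
consequence <- function(v, t, strict_ref = TRUE) {
  idx <- cdna_to_premrna(t, v$cdna_pos, v$intron_offset, v$utr)
  seen <- substr(t$premrna_seq, idx, idx)
  if (seen != v$ref_allele) {
    msg <- sprintf("reference mismatch at %s: transcript has %s, variant states %s",
                   format(v), seen, v$ref_allele)
    if (strict_ref) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (v$intron_offset != 0L) {
    ann <- locate(v, t)
    return(if (ann$is_canonical_dinucleotide) "splice_site" else "intronic")
  }
  if (v$utr != "none") return("utr")
  pos <- v$cdna_pos
  if (pos > t$cds_length) stop("exonic position beyond CDS without '*' notation")
  cds <- substr(mrna_seq(t), t$cds_offset + 1L, t$cds_offset + t$cds_length)
  ci <- (pos - 1L) %/% 3L            # 0-based codon index
  within <- (pos - 1L) %% 3L + 1L
  ref_codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- v$alt_allele
  tab <- .codon_table()
  ref_aa <- tab[[ref_codon]]; alt_aa <- tab[[alt_codon]]
  if (ci == 0L && alt_codon != "ATG") return("initiation_codon")
  if (ref_aa == "*" && alt_aa != "*") return("stoploss")
  if (alt_aa == "*" && ref_aa != "*") return("nonsense")
  if (ref_aa == alt_aa) return("silent")
  "missense"
}

#' Write a transcript model as FASTA plus a plain-text structure sidecar
#'
#' The sidecar holds tab-separated `key value` header lines (`gene`,
#' `accession`, `cds_offset`, optionally `cds_length`) followed by one exon
#' per line: `cdna_start  cdna_end  following_intron_length` (0 after the
#' last exon).
#'
#' @param t A `transcript_model`.
#' @param fasta_path Output FASTA path (pre-mRNA sequence).
#' @param structure_path Output sidecar path.
#' @export
write_transcript_model <- function(t, fasta_path, structure_path) {
  seq <- Biostrings::DNAStringSet(t$premrna_seq)
  names(seq) <- t$accession
  Biostrings::writeXStringSet(seq, fasta_path, width = 70L)
  n_ex <- nrow(t$exons)
  introns <- c(t$intron_lengths, 0L)
  lines <- c(paste0("gene\t", t$gene_symbol),
             paste0("accession\t", t$accession),
             paste0("cds_offset\t", t$cds_offset),
             paste0("cds_length\t", t$cds_length),
             vapply(seq_len(n_ex), function(e)
               paste(t$exons[e, 1L], t$exons[e, 2L], introns[e], sep = "\t"),
               character(1)))
  writeLines(lines, structure_path)
  invisible(c(fasta_path, structure_path))
}

#' Read a transcript model from FASTA plus structure sidecar
#' @param fasta_path FASTA with the pre-mRNA sequence (first record used).
#' @param structure_path Sidecar written by [write_transcript_model()].
#' @return A `transcript_model`.
#' @export
read_transcript_model <- function(fasta_path, structure_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) < 1L) stop("FASTA contains no sequence")
  lines <- readLines(structure_path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  hdr <- list(); ex <- list()
  for (p in parts) {
    if (p[[1]] %in% c("gene", "accession", "cds_offset", "cds_length")) {
      hdr[[p[[1]]]] <- p[[2]]
    } else {
      ex[[length(ex) + 1L]] <- as.integer(p[1:3])
    }
  }
  for (k in c("gene", "accession", "cds_offset"))
    if (is.null(hdr[[k]])) stop("structure sidecar missing header key: ", k)
  exm <- do.call(rbind, ex)
  transcript_model(
    gene_symbol = hdr$gene, accession = hdr$accession,
    exons = exm[, 1:2, drop = FALSE], intron_lengths = exm[, 3L],
    premrna_seq = as.character(seqs[[1L]]),
    cds_offset = as.integer(hdr$cds_offset),
    cds_length = if (!is.null(hdr$cds_length)) as.integer(hdr$cds_length) else NULL)
}
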