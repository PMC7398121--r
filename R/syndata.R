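#' Configuration of the synthetic variant-table generator
#'
#' Defaults mirror the composition and conditional aberration rates of the
#' collated 671-variant splicing-assay dataset: gene mix MLH1 48% / MSH2
#' 34% / MSH6 11% / PMS2 7%; variant-type mix over missense (328), silent
#' (75), canonical splice-site (86), other intronic (129), frameshift (25),
#' nonsense (24), initiation-codon (2) and stoploss (2) variants; aberration
#' rates of 98/80/21% by native-loss category among splice-region variants
#' and 50/43/35% by de-novo-gain category over all variants; and an
#' impact split of 92 complete / 33 incomplete / 116 unknown among aberrant
#' variants. Canonical-dinucleotide variants are always aberrant.
#'
#' @param seed Integer RNG seed; all draws flow from it.
#' @param n_variants Number of records to generate.
#' @param gene_proportions Named simplex over MLH1/MSH2/MSH6/PMS2.
#' @param type_proportions Named simplex over variant types.
#' @param splice_region_given_noncanonical Probability that a non-canonical
#'   variant lies in the splice-site region (last 20 intronic / first 6
#'   intronic / first-last 3 exonic bases). Default 153/585.
#' @param native_loss_priors Simplex over high/moderate/minimal for
#'   splice-region non-canonical variants (default 86/15/52 over 153);
#'   canonical variants are always "high", variants outside the splice
#'   region always "minimal".
#' @param gain_priors Simplex over high/moderate/minimal (default
#'   26/7/638 over 671).
#' @param aberration_given_native_loss Named rates (high, moderate,
#'   minimal), conditioned on splice-region membership.
#' @param aberration_given_gain Named rates (high, moderate, minimal), over
#'   all variants.
#' @param impact_split Unnormalized weights for complete/incomplete/unknown
#'   among aberrant records.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L, n_variants = 5000L,
    gene_proportions = c(MLH1 = 0.48, MSH2 = 0.34, MSH6 = 0.11, PMS2 = 0.07),
    type_proportions = c(missense = 328, silent = 75, splice_site = 86,
                         intronic = 129, frameshift = 25, nonsense = 24,
                         initiation_codon = 2, stoploss = 2) / 671,
    splice_region_given_noncanonical = 153 / 585,
    native_loss_priors = c(high = 86, moderate = 15, minimal = 52) / 153,
    gain_priors = c(high = 26, moderate = 7, minimal = 638) / 671,
    aberration_given_native_loss = c(high = 0.98, moderate = 0.80, minimal = 0.21),
    aberration_given_gain = c(high = 0.50, moderate = 0.43, minimal = 0.35),
    impact_split = c(complete = 92, incomplete = 33, unknown = 116)) {
  norm <- function(p) {
    if (any(p < 0)) stop("proportions must be non-negative")
    p / sum(p)
  }
  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              gene_proportions = norm(gene_proportions),
              type_proportions = norm(type_proportions),
              splice_region_given_noncanonical = splice_region_given_noncanonical,
              native_loss_priors = norm(native_loss_priors),
              gain_priors = norm(gain_priors),
              aberration_given_native_loss = aberration_given_native_loss,
              aberration_given_gain = aberration_given_gain,
              impact_split = norm(impact_split))
  rates <- c(cfg$aberration_given_native_loss, cfg$aberration_given_gain,
             cfg$splice_region_given_noncanonical)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(cfg, class = "simulation_config")
}

# Solve the per-record aberration probabilities so that every configured
# conditional rate holds marginally in the generated table:
#  - canonical records are forced aberrant, so the non-canonical
#    native-loss-high base rate is deflated to keep the pooled high-category
#    rate at its configured value;
#  - the outside-splice-region baseline is solved so the overall aberration
#    rate equals the one implied by the gain margin;
#  - a mean-zero gain-category adjustment is added on top (the two published
#    margins are not consistent under independence, so a pure product model
#    cannot satisfy both).
aberration_model <- function(cfg) {
  tp <- cfg$type_proportions
  p_can <- if ("splice_site" %in% names(tp)) tp[["splice_site"]] else 0
  p_non <- 1 - p_can
  p_sr <- p_non * cfg$splice_region_given_noncanonical
  p_out <- p_non - p_sr
  nl <- cfg$native_loss_priors
  r_nl <- cfg$aberration_given_native_loss
  r_g <- cfg$aberration_given_gain
  gp <- cfg$gain_priors

  w <- p_can / (p_can + p_sr * nl[["high"]])             # canonical share of "high"
  a_high <- max(0, (r_nl[["high"]] - w) / (1 - w))
  m_target <- sum(gp * r_g[names(gp)])                   # overall aberration rate
  sr_part <- p_sr * (nl[["high"]] * a_high + nl[["moderate"]] * r_nl[["moderate"]] +
                     nl[["minimal"]] * r_nl[["minimal"]])
  a_out <- if (p_out > 0) (m_target - p_can - sr_part) / p_out else 0
  if (a_out < 0 || a_out > 1) {
    warning("configured margins force the outside-splice-region baseline to ",
            signif(a_out, 3), "; clipping to [0, 1]")
    a_out <- min(1, max(0, a_out))
  }
  delta <- (r_g[names(gp)] - m_target) / p_non           # mean-zero over gain priors
  list(a_high = a_high, a_moderate = r_nl[["moderate"]],
       a_minimal_sr = r_nl[["minimal"]], a_out = a_out, delta = delta)
}

#' Generate a synthetic variant table
#'
#' Draws, per record: gene, variant type, splice-region membership,
#' native-loss and gain prediction categories, then the aberration flag at
#' the configured conditional rates (canonical-dinucleotide records are
#' always aberrant), then the impact split among aberrant records, with
#' consistent assay columns (r. transcript strings, allele attribution,
#' NMD-inhibitor use). Deterministic for a fixed config: the same seed
#' yields an identical table.
#'
#' @param cfg A [simulation_config()].
#' @return Data frame of variant records (see [read_variant_table()]).
#' @export
generate_variant_table <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)
  n <- cfg$n_variants
  mod <- aberration_model(cfg)

  gene <- sample(names(cfg$gene_proportions), n, TRUE, cfg$gene_proportions)
  vtype <- sample(names(cfg$type_proportions), n, TRUE, cfg$type_proportions)
  canonical <- vtype == "splice_site"
  splice_region <- canonical |
    (!canonical & stats::runif(n) < cfg$splice_region_given_noncanonical)
  nl_cat <- rep("minimal", n)
  sel <- splice_region & !canonical
  nl_cat[sel] <- sample(names(cfg$native_loss_priors), sum(sel), TRUE,
                        cfg$native_loss_priors)
  nl_cat[canonical] <- "high"
  gain_cat <- sample(names(cfg$gain_priors), n, TRUE, cfg$gain_priors)

  base <- ifelse(canonical, 1,
          ifelse(splice_region & nl_cat == "high", mod$a_high,
          ifelse(splice_region & nl_cat == "moderate", mod$a_moderate,
          ifelse(splice_region, mod$a_minimal_sr, mod$a_out))))
  # certainty is preserved: a configured conditional rate of exactly 0 or 1
  # is deterministic and not perturbed by the gain adjustment
  p_ab <- ifelse(canonical | base >= 1, 1,
          ifelse(base <= 0, 0, pmin(1, pmax(0, base + mod$delta[gain_cat]))))
  aberration <- as.integer(stats::runif(n) < p_ab)

  impact <- rep("", n)
  ab <- aberration == 1
  impact[ab] <- sample(names(cfg$impact_split), sum(ab), TRUE, cfg$impact_split)

  # cDNA descriptions: unique positions; offsets consistent with location
  pos <- 3L * seq_len(n) + 3L        # inside a long nominal CDS, codon-start free
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  offset <- integer(n)
  intr <- vtype == "intronic"
  offset[canonical] <- sample(c(1L, 2L, -1L, -2L), sum(canonical), TRUE)
  offset[intr & splice_region] <- sample(c(3L:6L, -(3L:20L)),
                                         sum(intr & splice_region), TRUE)
  offset[intr & !splice_region] <- sample(c(7L:40L, -(21L:60L)),
                                          sum(intr & !splice_region), TRUE)
  off_txt <- ifelse(offset > 0L, paste0("+", offset),
                    ifelse(offset < 0L, as.character(offset), ""))
  cdna <- paste0("c.", pos, off_txt, ref, ">", alt)

  transcripts <- rep("", n)
  if (any(ab)) {
    span_start <- pos[ab] - sample(10:400, sum(ab), TRUE)
    span_start <- pmax(span_start, 1L)
    span_len <- sample(20:300, sum(ab), TRUE)
    transcripts[ab] <- sprintf("r.%d_%ddel", span_start, span_start + span_len - 1L)
  }
  allele_specific <- as.integer(impact %in% c("complete", "incomplete"))
  full_length_alt <- ifelse(impact == "complete", "no",
                     ifelse(impact == "incomplete", "yes",
                     ifelse(impact == "unknown", "na", "")))

  data.frame(gene = gene, cdna = cdna, protein = "",
             variant_type = vtype,
             splice_region = as.integer(splice_region),
             native_loss_cat = nl_cat, gain_cat = gain_cat,
             aberration = as.numeric(aberration),
             transcripts = transcripts,
             allele_specific = as.numeric(allele_specific),
             nmd_inhibitor = 1,
             full_length_alt = full_length_alt,
             percent_wt = NA_real_, assay_source = "",
             prior = 0.1, lr_tumor = NA_real_, lr_segregation = NA_real_,
             lr_functional = NA_real_,
             insight_class = NA_integer_, contributes = "",
             study_source = "synthetic", notes = "",
             stringsAsFactors = FALSE)
}

#' Generate a toy transcript model with consensus splice sites
#'
#' Builds a random plus-strand pre-mRNA with GT..AG introns whose junctions
#' carry donor (CAG|GTAAGT) and acceptor (pyrimidine tract + CAG|GTT)
#' consensus sequences, plus training windows for scorer fitting: per
#' junction, windows equal to the consensus with independent per-base
#' corruption at rate `1 - consensus_strength`.
#'
#' @param seed Integer RNG seed.
#' @param n_exons Number of exons (>= 2).
#' @param exon_len_range,intron_len_range Length ranges; exons must be at
#'   least 9 nt and introns at least 26 nt so every scorer window fits.
#' @param consensus_strength In [0, 1]; 1 makes all training windows
#'   identical to the consensus.
#' @param n_train Training windows per junction.
#' @param gene_symbol,accession Labels for the model.
#' @return List with `transcript` (a `transcript_model`), `donor_windows`,
#'   `acceptor_windows`.
#' @export
generate_transcript <- function(seed = 1L, n_exons = 4L,
                                exon_len_range = c(60L, 120L),
                                intron_len_range = c(60L, 150L),
                                consensus_strength = 0.9,
                                n_train = 25L,
                                gene_symbol = "TOY1", accession = "TOY_0001") {
  if (n_exons < 2L) stop("need at least 2 exons")
  if (exon_len_range[1L] < 9L) stop("exons must be at least 9 nt")
  if (intron_len_range[1L] < 26L) stop("introns must be at least 26 nt")
  if (consensus_strength < 0 || consensus_strength > 1)
    stop("consensus_strength must lie in [0, 1]")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  donor_consensus <- "CAGGTAAGT"                     # 3 exonic + 6 intronic
  acceptor_consensus <- "TCTTTCTTTTTTTTTTTCAGGTT"    # 20 intronic + 3 exonic
  rand_seq <- function(len) paste(sample(bases, len, TRUE), collapse = "")
  corrupt <- function(w, rate) {
    if (rate <= 0) return(w)
    ch <- strsplit(w, "")[[1]]
    hit <- stats::runif(length(ch)) < rate
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L),
                      character(1))
    paste(ch, collapse = "")
  }
  exon_len <- sample(seq(exon_len_range[1L], exon_len_range[2L]), n_exons, TRUE)
  intron_len <- sample(seq(intron_len_range[1L], intron_len_range[2L]),
                       n_exons - 1L, TRUE)
  exons <- lapply(exon_len, rand_seq)
  introns <- lapply(intron_len, rand_seq)
  for (j in seq_len(n_exons - 1L)) {
    e <- exons[[j]]
    substr(e, nchar(e) - 2L, nchar(e)) <- substr(donor_consensus, 1L, 3L)
    exons[[j]] <- e
    i <- introns[[j]]
    substr(i, 1L, 6L) <- substr(donor_consensus, 4L, 9L)
    substr(i, nchar(i) - 19L, nchar(i)) <- substr(acceptor_consensus, 1L, 20L)
    introns[[j]] <- i
    e2 <- exons[[j + 1L]]
    substr(e2, 1L, 3L) <- substr(acceptor_consensus, 21L, 23L)
    exons[[j + 1L]] <- e2
  }
  # force an ATG at the CDS start so the toy model is translatable
  e1 <- exons[[1L]]
  substr(e1, 1L, 3L) <- "ATG"
  exons[[1L]] <- e1
  pre <- paste(unlist(Map(function(e, i) paste0(e, i),
                          exons, c(introns, list("")))), collapse = "")
  ends <- cumsum(exon_len)
  starts <- c(1L, ends[-n_exons] + 1L)
  cds_len <- sum(exon_len) - sum(exon_len) %% 3L
  t <- transcript_model(gene_symbol, accession,
                        exons = cbind(starts, ends),
                        intron_lengths = intron_len,
                        premrna_seq = pre, cds_offset = 0L,
                        cds_length = cds_len)
  rate <- 1 - consensus_strength
  donor_windows <- unlist(lapply(seq_len(n_exons - 1L), function(j)
    vapply(seq_len(n_train), function(k) corrupt(donor_consensus, rate),
           character(1))))
  acceptor_windows <- unlist(lapply(seq_len(n_exons - 1L), function(j)
    vapply(seq_len(n_train), function(k) corrupt(acceptor_consensus, rate),
           character(1))))
  list(transcript = t, donor_windows = donor_windows,
       acceptor_windows = acceptor_windows)
}
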