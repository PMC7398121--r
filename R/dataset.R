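.mandatory_cols <- c("gene", "cdna", "variant_type")
.known_genes <- c("MLH1", "MSH2", "MSH6", "PMS2")
.variant_types <- c("missense", "silent", "nonsense", "frameshift",
                    "in_frame_indel", "splice_site", "intronic",
                    "initiation_codon", "stoploss")
.numeric_cols <- c("splice_region", "aberration", "allele_specific",
                   "nmd_inhibitor", "percent_wt", "prior", "lr_tumor",
                   "lr_segregation", "lr_functional")

#' Read a variant table
#'
#' Tab-delimited, UTF-8, header-validated. Mandatory columns: `gene`,
#' `cdna`, `variant_type`. Recognized optional columns: `protein`,
#' `splice_region`, `native_loss_cat`, `gain_cat`, `aberration` (0/1),
#' `transcripts` (semicolon-joined r. strings), `allele_specific` (0/1),
#' `nmd_inhibitor` (0/1), `full_length_alt` (yes/no/na), `percent_wt`,
#' `assay_source`, `prior`, `lr_tumor`, `lr_segregation`, `lr_functional`,
#' `insight_class`, `contributes` (yes/no), `study_source`, `notes`.
#' Unknown columns are preserved as passthrough. Empty string means absent;
#' nothing is imputed.
#'
#' @param path File path.
#' @return Data frame of variant records.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  miss <- setdiff(.mandatory_cols, names(df))
  if (length(miss))
    stop("variant table missing mandatory column(s): ", paste(miss, collapse = ", "))
  err_row <- function(i, msg)
    stop(sprintf("variant table %s, line %d: %s", path, i + 1L, msg), call. = FALSE)
  for (i in seq_len(nrow(df))) {
    if (!df$gene[i] %in% .known_genes)
      err_row(i, paste0("unknown gene '", df$gene[i], "'"))
    if (!df$variant_type[i] %in% .variant_types)
      err_row(i, paste0("unknown variant_type '", df$variant_type[i], "'"))
    if ("full_length_alt" %in% names(df) &&
        !df$full_length_alt[i] %in% c("", "yes", "no", "na"))
      err_row(i, paste0("invalid full_length_alt '", df$full_length_alt[i], "'"))
    if ("contributes" %in% names(df) &&
        !df$contributes[i] %in% c("", "yes", "no"))
      err_row(i, paste0("invalid contributes '", df$contributes[i], "'"))
    if (all(c("aberration", "transcripts") %in% names(df)) &&
        identical(df$aberration[i], "0") && nzchar(df$transcripts[i]))
      err_row(i, "aberration=0 but aberrant transcripts listed")
    if (all(c("aberration", "full_length_alt") %in% names(df)) &&
        identical(df$aberration[i], "0") &&
        df$full_length_alt[i] %in% c("yes", "no"))
      err_row(i, "impact recorded without an aberration")
  }
  for (cl in intersect(.numeric_cols, names(df))) {
    v <- df[[cl]]
    bad <- nzchar(v) & is.na(suppressWarnings(as.numeric(v)))
    if (any(bad))
      err_row(which(bad)[1L], paste0("non-numeric value in column ", cl))
    df[[cl]] <- suppressWarnings(as.numeric(v))
  }
  if ("insight_class" %in% names(df))
    df$insight_class <- suppressWarnings(as.integer(df$insight_class))
  df
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: tab-delimited, UTF-8, empty string for
#' absent values. `write_variant_table(read_variant_table(p), q)` is the
#' canonical form; writing it again is byte-identical.
#'
#' @param records Data frame of variant records.
#' @param path Output path.
#' @export
write_variant_table <- function(records, path) {
  out <- records
  for (cl in names(out)) {
    v <- out[[cl]]
    if (is.numeric(v)) {
      s <- vapply(v, function(x) {
        if (is.na(x)) "" else if (is.integer(v) || x == round(x))
          format(x, scientific = FALSE) else format(x, digits = 15)
      }, character(1))
      out[[cl]] <- s
    } else {
      v[is.na(v)] <- ""
      out[[cl]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' The 24-variant splicing-assay study table
#'
#' The packaged transcription of the study's summary table: 24 MLH1/MSH2/
#' MSH6 variants (12 missense, 5 silent, 3 canonical splice-site, 4 other
#' intronic) with their observed aberrant transcripts, allele-attribution
#' observations, the printed InSiGHT class and whether splicing contributed
#' to it. The clinical/functional likelihood-ratio columns are a
#' reconstructed minimal evidence set consistent with each printed class
#' (the underlying per-variant clinical evidence is not published in the
#' main text); the `notes` column flags them as such.
#'
#' @return Data frame of 24 variant records.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_variants.tsv", package = "mmrsplice",
                      mustWork = TRUE)
  read_variant_table(path)
}

pct_round <- function(num, den) {
  if (is.na(den) || den == 0) return(NA_real_)
  x <- 100 * num / den
  sign(x) * floor(abs(x) + 0.5)      # half away from zero
}

.impact_severity <- c(none = 1L, unknown = 2L, incomplete = 3L, complete = 4L)

derive_impact <- function(records) {
  n <- nrow(records)
  imp <- rep(NA_character_, n)
  if (!"aberration" %in% names(records)) return(imp)
  has_fla <- "full_length_alt" %in% names(records)
  for (i in seq_len(n)) {
    ab <- records$aberration[i]
    if (is.na(ab)) next
    fla <- if (has_fla && !is.na(records$full_length_alt[i]) &&
               nzchar(records$full_length_alt[i]))
      records$full_length_alt[i] else "na"
    imp[i] <- if (ab == 0) "none" else
      switch(fla, no = "complete", yes = "incomplete", "unknown")
  }
  imp
}

#' Summarize a variant dataset
#'
#' Deterministic cross-tabulations in the style of the study's Results:
#' counts by gene and variant type, splicing-impact tallies, the
#' splicing-contributes rate per variant type, the native-loss-category vs
#' aberration table (restricted to splice-region variants, the way the
#' published conditionals are defined), the gain-category vs aberration
#' table (all variants), and the deficient-function vs class 4/5 rate.
#' Variants reported by several studies share a key (gene + cDNA); each
#' tabulation counts unique keys, uses the most severe impact (complete >
#' incomplete > unknown > none) for the headline tally, and reports
#' conflicting impact calls separately. Records lacking an attribute are
#' excluded from that tabulation's denominator. Percentages are integers,
#' rounded half away from zero.
#'
#' @param records Data frame of variant records.
#' @return An object of class `mmr_summary`.
#' @export
summarize_variants <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(structure(list(n_records = 0L, n_variants = 0L), class = "mmr_summary"))
  }
  key <- paste(records$gene, gsub("[[:space:]]", "", records$cdna), sep = ":")
  records$impact <- derive_impact(records)

  # collapse to unique variants: most severe impact, first value elsewhere
  first_val <- function(x) {
    x <- x[!is.na(x) & (is.numeric(x) | nzchar(as.character(x)))]
    if (length(x)) x[[1]] else NA
  }
  ord <- order(match(records$impact, names(.impact_severity)),
               decreasing = TRUE, na.last = TRUE)
  uniq <- records[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  n_conflict <- sum(tapply(records$impact, key, function(x)
    length(unique(x[!is.na(x)])) > 1L))

  tab_pct <- function(cat, ab) {
    keep <- !is.na(cat) & nzchar(cat) & !is.na(ab)
    cat <- cat[keep]; ab <- ab[keep]
    lv <- c("high", "moderate", "minimal")
    out <- lapply(stats::setNames(lv, lv), function(g) {
      den <- sum(cat == g); num <- sum(cat == g & ab == 1)
      c(aberrant = num, total = den, pct = pct_round(num, den))
    })
    out
  }
  g <- uniq
  impact_tally <- table(factor(g$impact,
                               levels = c("complete", "incomplete", "unknown", "none")))
  type_counts <- table(factor(g$variant_type, levels = .variant_types))
  gene_counts <- table(factor(g$gene, levels = .known_genes))

  contrib <- NULL
  if ("contributes" %in% names(g)) {
    hasc <- !is.na(g$contributes) & nzchar(g$contributes)
    contrib <- list(
      yes = sum(g$contributes[hasc] == "yes"),
      total = sum(hasc),
      by_type = lapply(stats::setNames(.variant_types, .variant_types), function(ty) {
        sel <- hasc & g$variant_type == ty
        c(yes = sum(g$contributes[sel] == "yes"), total = sum(sel),
          pct = pct_round(sum(g$contributes[sel] == "yes"), sum(sel)))
      }))
  }

  native_tab <- NULL
  if (all(c("native_loss_cat", "aberration") %in% names(g)) &&
      any(nzchar(g$native_loss_cat), na.rm = TRUE)) {
    sr <- if ("splice_region" %in% names(g))
      !is.na(g$splice_region) & g$splice_region == 1 else rep(TRUE, nrow(g))
    native_tab <- tab_pct(g$native_loss_cat[sr], g$aberration[sr])
  }
  gain_tab <- NULL
  if (all(c("gain_cat", "aberration") %in% names(g)) &&
      any(nzchar(g$gain_cat), na.rm = TRUE))
    gain_tab <- tab_pct(g$gain_cat, g$aberration)

  func_tab <- NULL
  if (all(c("percent_wt", "insight_class", "gene") %in% names(g))) {
    hasf <- !is.na(g$percent_wt) & !is.na(g$insight_class)
    if (any(hasf)) {
      fcat <- mapply(categorize_function, g$gene[hasf], g$percent_wt[hasf])
      cls45 <- g$insight_class[hasf] >= 4L
      func_tab <- list(
        deficient_class45 = sum(fcat == "deficient" & cls45),
        deficient_total = sum(fcat == "deficient"),
        deficient_class45_pct = pct_round(sum(fcat == "deficient" & cls45),
                                          sum(fcat == "deficient")),
        counts = table(function_category = fcat, class = g$insight_class[hasf]))
    }
  }
  n_aberrant <- if ("aberration" %in% names(g))
    sum(g$aberration == 1, na.rm = TRUE) else NA_integer_

  structure(list(
    n_records = nrow(records), n_variants = nrow(uniq),
    n_impact_conflicts = as.integer(n_conflict),
    gene_counts = gene_counts, type_counts = type_counts,
    impact_tally = impact_tally, n_aberrant = n_aberrant,
    contributes = contrib, native_loss_vs_aberration = native_tab,
    gain_vs_aberration = gain_tab, function_vs_class = func_tab
  ), class = "mmr_summary")
}

#' @export
print.mmr_summary <- function(x, ...) {
  cat(sprintf("Variant dataset summary: %d record(s), %d unique variant(s)",
              x$n_records, x$n_variants))
  if (isTRUE(x$n_impact_conflicts > 0))
    cat(sprintf(" (%d cross-study impact conflict(s))", x$n_impact_conflicts))
  cat("\n")
  if (x$n_records == 0L) return(invisible(x))
  cat("  by gene:", paste(sprintf("%s %d", names(x$gene_counts), x$gene_counts),
                          collapse = ", "), "\n")
  tc <- x$type_counts[x$type_counts > 0]
  cat("  by type:", paste(sprintf("%s %d", names(tc), tc), collapse = ", "), "\n")
  cat("  splicing impact:",
      paste(sprintf("%s %d", names(x$impact_tally), x$impact_tally), collapse = ", "),
      "\n")
  if (!is.null(x$contributes))
    cat(sprintf("  splicing contributed to classification for %d/%d variants\n",
                x$contributes$yes, x$contributes$total))
  show_tab <- function(tab, label) {
    if (is.null(tab)) return()
    cat("  aberration by", label, "category:\n")
    for (g in names(tab))
      cat(sprintf("    %-8s %d/%d (%s%%)\n", g, tab[[g]][["aberrant"]],
                  tab[[g]][["total"]],
                  ifelse(is.na(tab[[g]][["pct"]]), "-", tab[[g]][["pct"]])))
  }
  show_tab(x$native_loss_vs_aberration, "native-loss (splice-region variants)")
  show_tab(x$gain_vs_aberration, "de-novo gain")
  if (!is.null(x$function_vs_class))
    cat(sprintf("  deficient repair activity classified 4/5: %d/%d (%s%%)\n",
                x$function_vs_class$deficient_class45,
                x$function_vs_class$deficient_total,
                x$function_vs_class$deficient_class45_pct))
  invisible(x)
}
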