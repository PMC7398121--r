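#' Record an mRNA splicing-assay observation
#'
#' Captures what a patient-RNA or minigene assay observed for one variant:
#' whether any aberrant transcript was seen, the RNA-level (r.) descriptions
#' of aberrant transcripts, and whether the full-length transcript could be
#' shown to carry (or lack) the variant allele. Allele attribution is only
#' assessable when the variant base is observable in the cDNA (exonic
#' marker) or an allele-specific technique was used.
#'
#' @param aberration_detected Logical: any splicing aberration observed.
#' @param aberrant_transcripts Character vector of r. descriptions (verbatim,
#'   including bracketed multi-transcript notation).
#' @param has_exonic_marker Logical: variant base observable in cDNA.
#' @param full_length_contains_alt "yes", "no" or "na" (not assessable).
#' @param allele_specific_method Logical: an allele-specific technique was
#'   used.
#' @param nmd_inhibitor_used Logical: cells were treated with a
#'   nonsense-mediated-decay inhibitor so PTC-bearing transcripts are
#'   observable.
#' @return An object of class `splicing_assay_result`.
#' @export
splicing_assay_result <- function(aberration_detected,
                                  aberrant_transcripts = character(),
                                  has_exonic_marker = FALSE,
                                  full_length_contains_alt = c("na", "yes", "no"),
                                  allele_specific_method = FALSE,
                                  nmd_inhibitor_used = FALSE) {
  full_length_contains_alt <- match.arg(full_length_contains_alt)
  aberrant_transcripts <- aberrant_transcripts[nzchar(aberrant_transcripts)]
  if (!aberration_detected && length(aberrant_transcripts) > 0L)
    stop("inconsistent record: aberrant transcripts listed but no aberration flagged")
  if (full_length_contains_alt != "na" &&
      !(has_exonic_marker || allele_specific_method))
    stop(paste("full_length_contains_alt is only assessable with an exonic",
               "marker or an allele-specific method"))
  structure(list(aberration_detected = isTRUE(aberration_detected),
                 aberrant_transcripts = aberrant_transcripts,
                 has_exonic_marker = isTRUE(has_exonic_marker),
                 full_length_contains_alt = full_length_contains_alt,
                 allele_specific_method = isTRUE(allele_specific_method),
                 nmd_inhibitor_used = isTRUE(nmd_inhibitor_used)),
            class = "splicing_assay_result")
}

#' Categorize the splicing impact of a variant allele
#'
#' `none`: no aberration detected. `complete`: aberration detected and the
#' variant allele produces no (or minimal) full-length transcript.
#' `incomplete`: aberration detected but the variant allele also expresses
#' full-length transcript. `unknown`: aberration detected but allele
#' attribution was not assessable.
#'
#' @param r A `splicing_assay_result`.
#' @return One of "none", "complete", "incomplete", "unknown".
#' @export
categorize_splicing_impact <- function(r) {
  stopifnot(inherits(r, "splicing_assay_result"))
  if (!r$aberration_detected) return("none")
  switch(r$full_length_contains_alt,
         no = "complete", yes = "incomplete", na = "unknown")
}

#' Gene-specific repair-activity thresholds
#'
#' Deficient below the first threshold, proficient at or above the second,
#' moderate in the closed-open band between (forced by the published
#' inequalities "<23" and ">=70"). MLH1/MSH2: <23% deficient, >=70%
#' proficient. MSH6: <18%, >=100%. PMS2 uses the MSH6 thresholds in lieu of
#' a calibrated PMS2 functional likelihood ratio (its penetrance is closer
#' to MSH6 than to MLH1/MSH2).
#'
#' @return Named list of `c(deficient_below, proficient_at_or_above)` per
#'   gene.
#' @export
mmr_function_thresholds <- function() {
  list(MLH1 = c(23, 70), MSH2 = c(23, 70), MSH6 = c(18, 100), PMS2 = c(18, 100))
}

#' Categorize MMR repair activity
#'
#' @param gene_symbol One of MLH1, MSH2, MSH6, PMS2.
#' @param percent_wt_activity Repair activity as percent of wild type
#'   (finite, >= 0).
#' @param thresholds See [mmr_function_thresholds()].
#' @return "deficient", "moderate" or "proficient".
#' @export
categorize_function <- function(gene_symbol, percent_wt_activity,
                                thresholds = mmr_function_thresholds()) {
  th <- thresholds[[gene_symbol]]
  if (is.null(th)) stop("unknown gene symbol: ", gene_symbol)
  if (!is.finite(percent_wt_activity) || percent_wt_activity < 0)
    stop("percent_wt_activity must be finite and >= 0")
  if (percent_wt_activity < th[1L]) "deficient"
  else if (percent_wt_activity >= th[2L]) "proficient"
  else "moderate"
}

#' Most conservative published activity value
#'
#' When no calibrated repair-assay data exist for a variant, the highest
#' published activity value is used (most conservative, i.e. least
#' supportive of pathogenicity). Ties keep the first record in input order.
#'
#' @param results Non-empty list of records, each a list with `gene_symbol`
#'   and `percent_wt_activity` (and optionally `assay_source`).
#' @return The selected record.
#' @export
best_published_activity <- function(results) {
  if (length(results) == 0L) stop("empty result list")
  genes <- unique(vapply(results, `[[`, character(1), "gene_symbol"))
  if (length(genes) != 1L) stop("mixed genes in activity results: ",
                                paste(genes, collapse = ", "))
  act <- vapply(results, `[[`, numeric(1), "percent_wt_activity")
  results[[which.max(act)]]   # which.max returns the first maximum
}

#' Reading-frame heuristic for aberrant transcripts
#'
#' Parses r. deletion/duplication spans out of verbatim RNA-level
#' descriptions (including bracketed multi-transcript notation) and calls
#' the aberrant product PTC/frameshift when any span length is not a
#' multiple of 3, in-frame when all spans are, and unknown when no span can
#' be parsed. This deliberately stops short of full RNA-HGVS parsing.
#'
#' @param r_strings Character vector of r. descriptions, e.g.
#'   "r.791_884del" or "r.[791_1038del, 923a>c]".
#' @return "ptc_or_frameshift", "in_frame" or "unknown".
#' @export
transcript_frame <- function(r_strings) {
  r_strings <- r_strings[nzchar(r_strings)]
  if (length(r_strings) == 0L) return("unknown")
  txt <- paste(r_strings, collapse = " ")
  m <- regmatches(txt, gregexpr("([0-9]+)_([0-9]+)(del|dup)", txt))[[1]]
  if (length(m) == 0L) return("unknown")
  spans <- vapply(m, function(s) {
    nums <- as.integer(regmatches(s, gregexpr("[0-9]+", s))[[1]])
    nums[2L] - nums[1L] + 1L
  }, integer(1))
  if (any(spans %% 3L != 0L)) "ptc_or_frameshift" else "in_frame"
}
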