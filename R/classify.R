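#' Posterior probability cut-offs of the five-class scheme
#'
#' Class 5 (pathogenic) above 0.99; class 4 (likely pathogenic) at 0.95 up
#' to 0.99; class 3 (VUS) from 0.05 up to but excluding 0.95; class 2
#' (likely benign) from 0.001 up to but excluding 0.05; class 1 (benign)
#' below 0.001. The 0.95/0.05 cut-offs are the published likely-pathogenic /
#' likely-benign bounds; the outer 0.99/0.001 bounds come from the IARC
#' scheme the classification rules adopt. Boundary assignment: exactly 0.95
#' is class 4 (inclusive on the pathogenic side), exactly 0.05 is class 3
#' (class 2 requires strictly below 0.05).
#'
#' @param benign Below this: class 1.
#' @param likely_benign Below this (and at/above `benign`): class 2.
#' @param likely_pathogenic At/above this: class 4.
#' @param pathogenic Above this: class 5.
#' @return Named list of cut-offs.
#' @export
class_cutoffs <- function(benign = 0.001, likely_benign = 0.05,
                          likely_pathogenic = 0.95, pathogenic = 0.99) {
  stopifnot(benign < likely_benign, likely_benign < likely_pathogenic,
            likely_pathogenic <= pathogenic)
  list(benign = benign, likely_benign = likely_benign,
       likely_pathogenic = likely_pathogenic, pathogenic = pathogenic)
}

#' Combine a prior with likelihood ratios into a posterior probability
#'
#' Multifactorial likelihood combination in odds form: posterior odds are
#' the prior odds times the product of the independent likelihood ratios;
#' the result is mapped back to a probability. Order-invariant; computed in
#' log space for numerical stability.
#'
#' @param prior Prior probability of pathogenicity, in (0, 1).
#' @param lrs Numeric vector of positive likelihood ratios (tumor
#'   characteristics, segregation, functional, ...). May be empty (returns
#'   the prior).
#' @return Posterior probability of pathogenicity.
#' @export
combine_posterior <- function(prior, lrs = numeric()) {
  if (!is.finite(prior) || prior <= 0 || prior >= 1)
    stop("prior must lie strictly inside (0, 1)")
  lrs <- as.numeric(lrs)
  if (length(lrs) && (anyNA(lrs) || any(lrs <= 0)))
    stop("all likelihood ratios must be positive")
  log_odds <- log(prior) - log1p(-prior) + sum(log(lrs))
  stats::plogis(log_odds)
}

#' Map a posterior probability to an InSiGHT class
#'
#' @param p Posterior probability in [0, 1].
#' @param cutoffs See [class_cutoffs()].
#' @return Integer class 1-5.
#' @export
posterior_to_class <- function(p, cutoffs = class_cutoffs()) {
  if (!is.finite(p) || p < 0 || p > 1) stop("posterior must lie in [0, 1]")
  co <- cutoffs
  if (p > co$pathogenic) 5L
  else if (p >= co$likely_pathogenic) 4L
  else if (p >= co$likely_benign) 3L
  else if (p >= co$benign) 2L
  else 1L
}

#' Functional likelihood ratio from repair activity
#'
#' The calibration mapping percent-of-wild-type repair activity to a
#' likelihood ratio is supplied as configuration (it is laboratory- and
#' gene-specific and not built in). Two forms are accepted: a step
#' calibration, `list(type = "step", values = c(deficient = , moderate = ,
#' proficient = ))` applied through [categorize_function()]; or a monotone
#' piecewise-linear table, `list(type = "linear", percent = ..., lr = ...)`
#' interpolated (constant beyond the ends). With no calibration the LR is
#' 1.0 (evidence-neutral) unless `strict = TRUE`.
#'
#' @param percent_wt Percent of wild-type activity.
#' @param gene_symbol Gene (used by the step form's thresholds).
#' @param calibration Calibration object or NULL.
#' @param strict If TRUE, a missing calibration is a configuration error.
#' @return A positive likelihood ratio.
#' @export
functional_lr <- function(percent_wt, gene_symbol, calibration = NULL,
                          strict = FALSE) {
  if (is.null(calibration)) {
    if (strict) stop("no functional-LR calibration configured")
    return(1.0)
  }
  lr <- switch(calibration$type,
    step = {
      cat <- categorize_function(gene_symbol, percent_wt)
      v <- calibration$values[[cat]]
      if (is.null(v)) stop("step calibration missing value for category: ", cat)
      v
    },
    linear = {
      o <- order(calibration$percent)
      stats::approx(calibration$percent[o], calibration$lr[o], xout = percent_wt,
                    rule = 2)$y
    },
    stop("unknown calibration type: ", calibration$type))
  if (!is.finite(lr) || lr <= 0) stop("calibration produced a non-positive LR")
  lr
}

#' Assemble the evidence available for one variant
#'
#' @param variant_type One of missense, silent, nonsense, frameshift,
#'   in_frame_indel, splice_site, intronic, initiation_codon, stoploss.
#' @param prior_prob Prior probability of pathogenicity (default 0.1).
#' @param likelihood_ratios Named numeric vector of clinical/functional LRs
#'   (may be empty; empty means no quantitative evidence).
#' @param splicing_impact "complete", "incomplete", "unknown", "none", or NA
#'   when no splicing assay was run.
#' @param nmd_inhibitor_used Logical (NA if unknown).
#' @param allele_specific Logical: the splicing impact call rests on an
#'   allele-specific demonstration.
#' @param aberrant_transcript_frame "ptc_or_frameshift", "in_frame",
#'   "unknown", or NA.
#' @param function_category "deficient", "moderate", "proficient", or NA.
#' @param is_canonical Logical: variant hits an IVS+/-1/2 dinucleotide
#'   (defaults to `variant_type == "splice_site"`).
#' @return An object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(variant_type,
                            prior_prob = 0.1,
                            likelihood_ratios = numeric(),
                            splicing_impact = NA_character_,
                            nmd_inhibitor_used = NA,
                            allele_specific = FALSE,
                            aberrant_transcript_frame = NA_character_,
                            function_category = NA_character_,
                            is_canonical = identical(variant_type, "splice_site")) {
  types <- c("missense", "silent", "nonsense", "frameshift", "in_frame_indel",
             "splice_site", "intronic", "initiation_codon", "stoploss")
  if (!variant_type %in% types)
    stop("unknown variant_type: ", variant_type)
  if (!is.finite(prior_prob) || prior_prob <= 0 || prior_prob >= 1)
    stop("prior_prob must lie in (0, 1)")
  likelihood_ratios <- likelihood_ratios[!is.na(likelihood_ratios)]
  if (length(likelihood_ratios) && any(likelihood_ratios <= 0))
    stop("all likelihood ratios must be positive")
  if (!is.na(splicing_impact) &&
      !splicing_impact %in% c("complete", "incomplete", "unknown", "none"))
    stop("invalid splicing_impact: ", splicing_impact)
  structure(list(variant_type = variant_type, prior_prob = prior_prob,
                 likelihood_ratios = likelihood_ratios,
                 splicing_impact = splicing_impact,
                 nmd_inhibitor_used = nmd_inhibitor_used,
                 allele_specific = isTRUE(allele_specific),
                 aberrant_transcript_frame = aberrant_transcript_frame,
                 function_category = function_category,
                 is_canonical = isTRUE(is_canonical)),
            class = "evidence_bundle")
}

# Qualitative decision-tree walk: returns list(class = int or NA, rationale).
# The first matching terminal rule sets the qualitative class.
qualitative_class <- function(e) {
  fired <- character()
  note <- function(id) fired <<- c(fired, id)
  impact <- e$splicing_impact

  # Predicted loss-of-function variant types are pathogenic regardless of
  # splicing assay results.
  if (e$variant_type %in% c("frameshift", "nonsense")) {
    note("lof_variant_type")
    return(list(class = 5L, rationale = fired))
  }
  # Canonical IVS+/-1/2 dinucleotide: at least likely pathogenic; a
  # demonstrated allele-specific complete impact upgrades to pathogenic.
  if (e$is_canonical) {
    note("canonical_dinucleotide")
    if (identical(impact, "complete") && e$allele_specific) {
      note("allele_specific_complete_upgrade")
      return(list(class = 5L, rationale = fired))
    }
    return(list(class = 4L, rationale = fired))
  }
  # Complete impact with a PTC/frameshift product is a demonstrated null
  # allele (a complete call already rests on allele-specific evidence).
  if (identical(impact, "complete") &&
      identical(e$aberrant_transcript_frame, "ptc_or_frameshift")) {
    note("complete_ptc_null_allele")
    return(list(class = 5L, rationale = fired))
  }
  # Aberration demonstrated but extent unknown, PTC/frameshift product:
  # likely pathogenic; the missing allele-specific quantification is what
  # separates this from class 5.
  if (identical(impact, "unknown") &&
      identical(e$aberrant_transcript_frame, "ptc_or_frameshift")) {
    note("aberration_unknown_extent")
    return(list(class = 4L, rationale = fired))
  }
  # No aberration for an intronic/silent variant is benign-direction
  # evidence, but only when NMD was inhibited so degradation of aberrant
  # transcripts cannot mask an effect.
  if (identical(impact, "none") && e$variant_type %in% c("intronic", "silent")) {
    if (isTRUE(e$nmd_inhibitor_used)) {
      note("no_aberration_benign")
      return(list(class = 2L, rationale = fired))
    }
    note("nmd_uninhibited_vus_cap")
    return(list(class = 3L, rationale = fired))
  }
  # Incomplete impact does not contribute on its own.
  if (identical(impact, "incomplete")) note("incomplete_noncontributory")
  # Functional evidence for missense variants flows through the quantitative
  # route (functional LR); deficient function alone is supporting only, and
  # proficient function with normal splicing is no automatic benign call.
  if (identical(e$variant_type, "missense") && !is.na(e$function_category)) {
    if (identical(e$function_category, "deficient")) note("function_deficient_support")
    if (identical(e$function_category, "proficient") && identical(impact, "none"))
      note("function_proficient_no_benign_call")
  }
  list(class = NA_integer_, rationale = fired)
}

#' Classify one variant from its evidence bundle
#'
#' Runs the qualitative decision-tree rules and, when likelihood ratios are
#' present, the quantitative multifactorial combination, then reconciles the
#' two: on the same side of the VUS band the class farther from VUS wins
#' (class 5 over 4; class 1 over 2); a VUS result never overrides a
#' non-VUS one; opposite sides yield class 3 with an explicit conflict flag.
#'
#' @param e An `evidence_bundle`.
#' @param cutoffs See [class_cutoffs()].
#' @return An object of class `mmr_classification` with fields
#'   `insight_class`, `basis` ("qualitative", "quantitative", "combined"),
#'   `posterior_prob`, `qualitative_class`, `quantitative_class`,
#'   `conflict`, `rationale`.
#' @export
apply_rules <- function(e, cutoffs = class_cutoffs()) {
  stopifnot(inherits(e, "evidence_bundle"))
  if (identical(e$splicing_impact, "none") &&
      identical(e$aberrant_transcript_frame, "ptc_or_frameshift"))
    stop("contradictory bundle: impact 'none' with an aberrant-transcript frame call")
  q <- qualitative_class(e)
  post <- NA_real_; quant <- NA_integer_
  if (length(e$likelihood_ratios) > 0L) {
    post <- combine_posterior(e$prior_prob, e$likelihood_ratios)
    quant <- posterior_to_class(post, cutoffs)
  }
  qual <- q$class
  rationale <- q$rationale
  side <- function(cl) if (is.na(cl) || cl == 3L) 0L else if (cl >= 4L) 1L else -1L
  sq <- side(qual); sp <- side(quant)
  conflict <- FALSE
  if (sq == 0L && sp == 0L) {
    cls <- 3L
    basis <- if (!is.na(quant)) "combined" else "qualitative"
  } else if (sq != 0L && sp != 0L && sq != sp) {
    cls <- 3L; conflict <- TRUE; basis <- "combined"
    rationale <- c(rationale, "qualitative_quantitative_conflict")
  } else if (sq != 0L && sp != 0L) {
    cls <- if (sq > 0L) max(qual, quant) else min(qual, quant)
    basis <- "combined"
  } else if (sq != 0L) {
    cls <- qual; basis <- "qualitative"
  } else {
    cls <- quant; basis <- "quantitative"
  }
  if (length(rationale) == 0L) rationale <- "insufficient_evidence"
  structure(list(insight_class = as.integer(cls), basis = basis,
                 posterior_prob = post,
                 qualitative_class = qual, quantitative_class = quant,
                 conflict = conflict, rationale = rationale),
            class = "mmr_classification")
}

#' @export
print.mmr_classification <- function(x, ...) {
  cat(sprintf("InSiGHT class %d (%s%s)%s\n", x$insight_class, x$basis,
              if (!is.na(x$posterior_prob))
                sprintf(", posterior %.4g", x$posterior_prob) else "",
              if (x$conflict) " [qualitative/quantitative conflict]" else ""))
  cat("  rules fired:", paste(x$rationale, collapse = ", "), "\n")
  invisible(x)
}

# Strip splicing-assay evidence from a bundle; the variant's location-based
# evidence (canonical dinucleotide, variant type) and the clinical and
# functional quantitative evidence remain.
strip_splicing <- function(e) {
  e$splicing_impact <- NA_character_
  e$aberrant_transcript_frame <- NA_character_
  e$nmd_inhibitor_used <- NA
  e$allele_specific <- FALSE
  e
}

#' Does splicing evidence change the classification?
#'
#' TRUE iff classifying with and without the splicing-assay evidence yields
#' different classes.
#'
#' @param e An `evidence_bundle`.
#' @param cutoffs See [class_cutoffs()].
#' @return Logical flag.
#' @export
splicing_contribution <- function(e, cutoffs = class_cutoffs()) {
  with_s <- apply_rules(e, cutoffs)$insight_class
  without_s <- apply_rules(strip_splicing(e), cutoffs)$insight_class
  with_s != without_s
}

# Build an evidence bundle from one row of a variant table (see
# read_variant_table for the column vocabulary).
bundle_from_record <- function(row, prior = 0.1, calibration = NULL) {
  num <- function(x) suppressWarnings(as.numeric(x))
  lrs <- c(tumor_characteristics = num(row[["lr_tumor"]]),
           segregation = num(row[["lr_segregation"]]),
           functional = num(row[["lr_functional"]]))
  pw <- num(row[["percent_wt"]])
  if (is.na(lrs[["functional"]]) && !is.na(pw) && !is.null(calibration))
    lrs[["functional"]] <- functional_lr(pw, row[["gene"]], calibration)
  lrs <- lrs[!is.na(lrs)]
  aberr <- num(row[["aberration"]])
  impact <- NA_character_
  transcripts <- character()
  if (!is.na(aberr)) {
    transcripts <- trimws(strsplit(
      if (is.na(row[["transcripts"]])) "" else row[["transcripts"]], ";")[[1]])
    asr <- splicing_assay_result(
      aberration_detected = aberr == 1,
      aberrant_transcripts = transcripts,
      has_exonic_marker = isTRUE(num(row[["allele_specific"]]) == 1),
      full_length_contains_alt =
        if (is.na(row[["full_length_alt"]]) || !nzchar(row[["full_length_alt"]]))
          "na" else row[["full_length_alt"]],
      allele_specific_method = isTRUE(num(row[["allele_specific"]]) == 1),
      nmd_inhibitor_used = isTRUE(num(row[["nmd_inhibitor"]]) == 1))
    impact <- categorize_splicing_impact(asr)
  }
  fc <- NA_character_
  if (!is.na(pw)) fc <- categorize_function(row[["gene"]], pw)
  pr <- num(row[["prior"]])
  evidence_bundle(
    variant_type = row[["variant_type"]],
    prior_prob = if (!is.na(pr)) pr else prior,
    likelihood_ratios = lrs,
    splicing_impact = impact,
    nmd_inhibitor_used = if (is.na(aberr)) NA else
      isTRUE(num(row[["nmd_inhibitor"]]) == 1),
    allele_specific = isTRUE(num(row[["allele_specific"]]) == 1),
    aberrant_transcript_frame = if (length(transcripts))
      transcript_frame(transcripts) else NA_character_,
    function_category = fc)
}

#' Classify every variant in a table
#'
#' Builds an evidence bundle per row (deriving splicing impact and function
#' category from the assay columns) and applies the rule engine.
#'
#' @param records Data frame from [read_variant_table()] or
#'   [table1_fixture()].
#' @param prior Default prior probability for rows without a `prior` column.
#' @param calibration Optional functional-LR calibration (see
#'   [functional_lr()]).
#' @param cutoffs See [class_cutoffs()].
#' @return `records` with added columns `impact`, `class`, `posterior`,
#'   `contributes` ("yes"/"no"), `conflict`, `basis`, `rationale`.
#' @export
classify_variants <- function(records, prior = 0.1, calibration = NULL,
                              cutoffs = class_cutoffs()) {
  n <- nrow(records)
  out <- records
  out$impact <- NA_character_
  out$class <- NA_integer_
  out$posterior <- NA_real_
  out$contributes <- NA_character_
  out$conflict <- FALSE
  out$basis <- NA_character_
  out$rationale <- NA_character_
  for (i in seq_len(n)) {
    row <- as.list(records[i, , drop = FALSE])
    row <- lapply(row, function(x) if (length(x)) x[[1]] else NA)
    e <- bundle_from_record(row, prior, calibration)
    cl <- apply_rules(e, cutoffs)
    out$impact[i] <- if (is.na(e$splicing_impact)) NA_character_ else e$splicing_impact
    out$class[i] <- cl$insight_class
    out$posterior[i] <- cl$posterior_prob
    out$contributes[i] <- if (splicing_contribution(e, cutoffs)) "yes" else "no"
    out$conflict[i] <- cl$conflict
    out$basis[i] <- cl$basis
    out$rationale[i] <- paste(cl$rationale, collapse = ";")
  }
  out
}
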