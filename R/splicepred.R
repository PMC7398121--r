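#' Train a position weight-matrix splice-site scorer
#'
#' Builds a log-odds weight matrix from aligned site windows: per position i
#' and base b, `weight = log2((count + pseudocount) / (N + 4 * pseudocount))
#' - log2(background_b)`. A window's score is the sum of its per-position
#' weights. Donor scorers use 9-base windows (last 3 exonic + first 6
#' intronic bases); acceptor scorers use 23-base windows (last 20 intronic +
#' first 3 exonic bases).
#'
#' @param site_windows Character vector of equal-length windows over
#'   {A,C,G,T}.
#' @param site_kind "donor" or "acceptor".
#' @param background Named base frequencies (A,C,G,T); default uniform.
#' @param pseudocount Positive training pseudocount; default 0.5.
#' @return An object of class `splice_scorer` (subclass `wmm_scorer`).
#' @export
train_wmm <- function(site_windows, site_kind = c("donor", "acceptor"),
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount = 0.5) {
  site_kind <- match.arg(site_kind)
  if (length(site_windows) == 0L) stop("empty training set")
  site_windows <- toupper(site_windows)
  lens <- unique(nchar(site_windows))
  if (length(lens) != 1L) stop("training windows have mixed lengths")
  if (any(grepl("[^ACGT]", site_windows))) stop("training windows must be over {A,C,G,T}")
  if (!isTRUE(pseudocount > 0)) stop("pseudocount must be > 0")
  background <- background[c("A", "C", "G", "T")]
  if (anyNA(background)) stop("background must name frequencies for A, C, G, T")
  L <- lens
  n <- length(site_windows)
  mat <- matrix(unlist(strsplit(site_windows, "")), nrow = n, byrow = TRUE)
  weights <- matrix(0, nrow = 4L, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(L)) {
    counts <- table(factor(mat[, i], levels = c("A", "C", "G", "T")))
    weights[, i] <- log2((as.numeric(counts) + pseudocount) / (n + 4 * pseudocount)) -
      log2(background)
  }
  structure(list(site_kind = site_kind, window_len = L, weights = weights,
                 pseudocount = pseudocount, background = background),
            class = c("wmm_scorer", "splice_scorer"))
}

#' Score windows with a splice-site scorer
#' @param scorer A `splice_scorer`.
#' @param windows Character vector of windows of exactly `scorer$window_len`.
#' @return Numeric vector of log-odds scores (bits).
#' @export
score_windows <- function(scorer, windows) {
  stopifnot(inherits(scorer, "splice_scorer"))
  windows <- toupper(windows)
  if (any(nchar(windows) != scorer$window_len))
    stop(sprintf("windows must have length %d", scorer$window_len))
  if (any(grepl("[^ACGT]", windows))) stop("windows must be over {A,C,G,T}")
  vapply(strsplit(windows, ""), function(b)
    sum(scorer$weights[cbind(match(b, c("A", "C", "G", "T")), seq_along(b))]),
    numeric(1))
}

#' @export
print.splice_scorer <- function(x, ...) {
  cat(sprintf("%s splice-site scorer (%s), window %d nt\n",
              x$site_kind, class(x)[1L], x$window_len))
  invisible(x)
}

#' Write a scorer's weight matrix to a plain-text file
#'
#' Format: header lines `site_kind=donor|acceptor` and `window_len=N`,
#' then one row per window position with four whitespace-delimited columns
#' (A C G T).
#'
#' @param scorer A `splice_scorer`.
#' @param path Output path.
#' @export
write_score_matrix <- function(scorer, path) {
  stopifnot(inherits(scorer, "splice_scorer"))
  lines <- c(paste0("site_kind=", scorer$site_kind),
             paste0("window_len=", scorer$window_len),
             apply(t(scorer$weights), 1L, function(r)
               paste(formatC(r, digits = 17, format = "g"), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Load a splice-site scorer from a weight-matrix file
#' @param path File written in the format of [write_score_matrix()].
#' @return A `splice_scorer` (subclass `matrix_scorer`).
#' @export
load_score_matrix <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- grepl("=", lines, fixed = TRUE)
  hdr <- strsplit(lines[kv], "=", fixed = TRUE)
  keys <- vapply(hdr, `[`, character(1), 1L)
  vals <- vapply(hdr, `[`, character(1), 2L)
  site_kind <- vals[match("site_kind", keys)]
  window_len <- as.integer(vals[match("window_len", keys)])
  if (is.na(site_kind) || !site_kind %in% c("donor", "acceptor"))
    stop("matrix file: missing or invalid site_kind header")
  if (is.na(window_len) || window_len < 1L)
    stop("matrix file: missing or invalid window_len header")
  rows <- strsplit(lines[!kv], "[[:space:]]+")
  if (length(rows) != window_len)
    stop(sprintf("matrix file: expected %d weight rows, found %d",
                 window_len, length(rows)))
  if (any(vapply(rows, length, integer(1)) != 4L))
    stop("matrix file: each weight row must have 4 columns (A C G T)")
  w <- t(vapply(rows, function(r) as.numeric(r), numeric(4)))
  if (anyNA(w)) stop("matrix file: non-numeric weight entry")
  weights <- t(w)
  dimnames(weights) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(site_kind = site_kind, window_len = window_len, weights = weights),
            class = c("matrix_scorer", "splice_scorer"))
}

# Substitute the variant base into the pre-mRNA; checks the stated reference.
alt_premrna <- function(v, t, strict_ref = TRUE) {
  idx <- cdna_to_premrna(t, v$cdna_pos, v$intron_offset, v$utr)
  seen <- substr(t$premrna_seq, idx, idx)
  if (seen != v$ref_allele) {
    msg <- sprintf("reference mismatch at %s: transcript has %s, variant states %s",
                   format(v), seen, v$ref_allele)
    if (strict_ref) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  alt <- t$premrna_seq
  substr(alt, idx, idx) <- v$alt_allele
  list(idx = idx, ref_seq = t$premrna_seq, alt_seq = alt)
}

splice_delta <- function(ref_score, alt_score, site_kind, anchor = NA_integer_,
                         no_overlap = FALSE) {
  structure(list(ref_score = ref_score, alt_score = alt_score,
                 diff = ref_score - alt_score, site_kind = site_kind,
                 window_anchor = anchor, no_overlap = no_overlap),
            class = "splice_site_delta")
}

#' @export
print.splice_site_delta <- function(x, ...) {
  if (x$no_overlap) cat(sprintf("%s delta: no native-window overlap\n", x$site_kind))
  else cat(sprintf("%s delta: ref %.3f, alt %.3f, diff %.3f (window at pre-mRNA %d)\n",
                   x$site_kind, x$ref_score, x$alt_score, x$diff, x$window_anchor))
  invisible(x)
}

#' Sliding-window analysis around a variant
#'
#' Scores every window of the scorer's length that contains the variant base
#' on the alternate sequence, takes the maximum (ties broken by the lowest
#' window start), and pairs it with the score of the same window on the
#' reference sequence. This is the de-novo/overall component of the
#' sliding-window analysis; [native_delta()] gives the annotated-site
#' component.
#'
#' @param v A `cdna_variant`.
#' @param t A `transcript_model`.
#' @param scorer A `splice_scorer`.
#' @param strict_ref Passed to the reference-allele check.
#' @return A `splice_site_delta` with `ref_score`, `alt_score`,
#'   `diff = ref_score - alt_score`, and the argmax window start
#'   (`window_anchor`, 1-based pre-mRNA).
#' @export
swa_scan <- function(v, t, scorer, strict_ref = TRUE) {
  s <- alt_premrna(v, t, strict_ref)
  L <- scorer$window_len
  n <- nchar(s$ref_seq)
  if (n < L) stop("sequence too short for scorer window")
  starts <- max(1L, s$idx - L + 1L):min(s$idx, n - L + 1L)
  if (length(starts) == 0L || min(starts) > max(starts))
    stop("variant too close to sequence end for any full window")
  alt_wins <- substring(s$alt_seq, starts, starts + L - 1L)
  alt_scores <- score_windows(scorer, alt_wins)
  best <- which.max(alt_scores)          # which.max takes the first maximum
  anchor <- starts[best]
  ref_score <- score_windows(scorer, substr(s$ref_seq, anchor, anchor + L - 1L))
  splice_delta(ref_score, alt_scores[best], scorer$site_kind, anchor)
}

# 1-based pre-mRNA start positions of every annotated native-site window.
native_site_windows <- function(t, site_kind) {
  n_ex <- nrow(t$exons)
  if (n_ex < 2L) return(integer(0))
  if (site_kind == "donor") {
    # last 3 exonic + first 6 intronic bases at each internal exon end
    ends <- t$cum_exon[seq_len(n_ex - 1L)] + t$cum_intron[seq_len(n_ex - 1L)]
    ends - 2L
  } else {
    # last 20 intronic + first 3 exonic bases at each internal exon start
    starts <- t$cum_exon[seq_len(n_ex - 1L)] + t$cum_intron[seq_len(n_ex - 1L) + 1L] + 1L
    starts - 20L
  }
}

#' Reference-vs-alternate score of the native splice site nearest a variant
#'
#' Scores the fixed window of the annotated native site of the scorer's kind
#' that contains the variant base (donor: terminal 3 exonic + first 6
#' intronic bases; acceptor: last 20 intronic + first 3 exonic bases) on the
#' reference and the alternate sequence. If the variant overlaps no native
#' window of that kind, a no-overlap marker is returned (native loss then
#' defaults to minimal).
#'
#' @inheritParams swa_scan
#' @return A `splice_site_delta`; `no_overlap = TRUE` when the variant
#'   touches no native window of this kind.
#' @export
native_delta <- function(v, t, scorer, strict_ref = TRUE) {
  s <- alt_premrna(v, t, strict_ref)
  L <- scorer$window_len
  anchors <- native_site_windows(t, scorer$site_kind)
  hit <- anchors[s$idx >= anchors & s$idx <= anchors + L - 1L]
  if (length(hit) == 0L)
    return(splice_delta(NA_real_, NA_real_, scorer$site_kind, no_overlap = TRUE))
  a <- hit[1L]
  ref_score <- score_windows(scorer, substr(s$ref_seq, a, a + L - 1L))
  alt_score <- score_windows(scorer, substr(s$alt_seq, a, a + L - 1L))
  splice_delta(ref_score, alt_score, scorer$site_kind, a)
}

#' Categorization thresholds for splice predictions
#'
#' Defaults are calibrated to MaxEntScan-scale scores (diff threshold 1.15,
#' score band 6.2-8.5); scorers on other scales should supply their own.
#'
#' @param diff_min Minimum reference-minus-alternate drop considered a
#'   substantive native-site weakening.
#' @param alt_low Alternate score below which a site is considered weak.
#' @param alt_high Alternate score above which a site is considered strong.
#' @return A named list of thresholds.
#' @export
splice_thresholds <- function(diff_min = 1.15, alt_low = 6.2, alt_high = 8.5) {
  stopifnot(alt_low <= alt_high)
  list(diff_min = diff_min, alt_low = alt_low, alt_high = alt_high)
}

#' Categorize predicted native splice-site loss
#'
#' Resolves the published predicate set into a total precedence ladder:
#' improving or strong alternates cannot indicate loss (minimal first),
#' then the drop size and residual strength grade moderate vs high:
#' diff < 0 -> minimal; alt > 8.5 -> minimal; 6.2 <= alt <= 8.5 -> moderate
#' iff diff >= 1.15 else minimal; alt < 6.2 -> high iff diff >= 1.15 else
#' moderate.
#'
#' @param d A `splice_site_delta`, or a list/vector with `diff` and
#'   `alt_score` elements.
#' @param thresholds See [splice_thresholds()].
#' @return "minimal", "moderate" or "high".
#' @export
categorize_native_loss <- function(d, thresholds = splice_thresholds()) {
  if (isTRUE(d$no_overlap)) return("minimal")
  diff <- d$diff; alt <- d$alt_score
  if (!is.finite(diff) || !is.finite(alt)) stop("non-finite scores")
  th <- thresholds
  if (diff < 0) return("minimal")
  if (alt > th$alt_high) return("minimal")
  if (alt >= th$alt_low) {                      # 6.2 <= alt <= 8.5
    if (diff >= th$diff_min) "moderate" else "minimal"
  } else {                                      # alt < 6.2
    if (diff >= th$diff_min) "high" else "moderate"
  }
}

#' Categorize predicted de-novo splice-site gain
#'
#' High: score improves (diff < 0) and the alternate site is strong
#' (alt > 8.5). Moderate: score improves into the intermediate band
#' (6.2 <= alt <= 8.5) and the alternate site outscores the closest
#' annotated native site of the same kind. Minimal otherwise; ties with the
#' native score are minimal (conservative).
#'
#' @param d A `splice_site_delta` (diff = ref - alt; improvement is
#'   diff < 0).
#' @param nearest_native_score Score of the closest annotated native site of
#'   the same kind on the reference sequence.
#' @param thresholds See [splice_thresholds()].
#' @return "minimal", "moderate" or "high".
#' @export
categorize_gain <- function(d, nearest_native_score,
                            thresholds = splice_thresholds()) {
  diff <- d$diff; alt <- d$alt_score
  if (!is.finite(diff) || !is.finite(alt)) stop("non-finite scores")
  th <- thresholds
  if (diff < 0 && alt > th$alt_high) return("high")
  if (diff < 0 && alt >= th$alt_low && alt <= th$alt_high &&
      is.finite(nearest_native_score) && alt > nearest_native_score)
    return("moderate")
  "minimal"
}

#' Full splice prediction for one variant
#'
#' Runs the native-site delta and the sliding-window scan for both site
#' kinds and categorizes native loss and de-novo gain in parallel, the way
#' the two predictions are used as parallel annotations.
#'
#' @param v A `cdna_variant`.
#' @param t A `transcript_model`.
#' @param donor_scorer,acceptor_scorer `splice_scorer`s of the two kinds.
#' @param thresholds See [splice_thresholds()].
#' @param strict_ref Passed to the reference-allele check.
#' @return List with per-kind deltas and the worst-case `native_loss` and
#'   `gain` categories across the two kinds.
#' @export
predict_splicing <- function(v, t, donor_scorer, acceptor_scorer,
                             thresholds = splice_thresholds(),
                             strict_ref = TRUE) {
  stopifnot(donor_scorer$site_kind == "donor", acceptor_scorer$site_kind == "acceptor")
  sev <- c(minimal = 1L, moderate = 2L, high = 3L)
  worst <- function(a, b) names(sev)[max(sev[[a]], sev[[b]])]
  out <- list()
  for (kind in c("donor", "acceptor")) {
    sc <- if (kind == "donor") donor_scorer else acceptor_scorer
    nd <- native_delta(v, t, sc, strict_ref)
    sw <- swa_scan(v, t, sc, strict_ref)
    anchors <- native_site_windows(t, kind)
    nearest <- NA_real_
    if (length(anchors)) {
      a <- anchors[which.min(abs(anchors - sw$window_anchor))]
      nearest <- score_windows(sc, substr(t$premrna_seq, a, a + sc$window_len - 1L))
    }
    out[[kind]] <- list(
      native = nd, scan = sw, nearest_native_score = nearest,
      native_loss = categorize_native_loss(nd, thresholds),
      gain = categorize_gain(sw, nearest, thresholds))
  }
  list(donor = out$donor, acceptor = out$acceptor,
       native_loss = worst(out$donor$native_loss, out$acceptor$native_loss),
       gain = worst(out$donor$gain, out$acceptor$gain))
}
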