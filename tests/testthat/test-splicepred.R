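test_that("weight-matrix training: degenerate counts make the training word the per-position argmax", {
  w <- train_wmm(rep("CAGGTAAGT", 10L), "donor")
  expect_equal(w$window_len, 9L)
  consensus <- strsplit("CAGGTAAGT", "")[[1]]
  argmax <- rownames(w$weights)[apply(w$weights, 2L, which.max)]
  expect_identical(argmax, consensus)
  # per-position argmax implies the word maximizes the additive score
  best <- sum(apply(w$weights, 2L, max))
  expect_equal(score_windows(w, "CAGGTAAGT"), best)
})

test_that("scores are additive over per-position lookups", {
  w <- train_wmm(c("CAGGTAAGT", "CAGGTGAGT", "AAGGTAAGT"), "donor")
  probe <- "TTTGTAAGC"
  manual <- sum(vapply(1:9, function(i)
    w$weights[substr(probe, i, i), i], numeric(1)))
  expect_equal(score_windows(w, probe), manual)
})

test_that("trained scores match an independent count-and-log oracle", {
  train <- c("CAGGTAAGT", "CAGGTGAGT", "AAGGTAAGT")
  pc <- 0.5
  bg <- c(A = 0.3, C = 0.2, G = 0.3, T = 0.2)
  w <- train_wmm(train, "donor", background = bg, pseudocount = pc)
  probes <- c("CAGGTAAGT", "TTTTTTTTT", "ACGTACGTA", "AAGGTGAGT", "GGGGTAAGT")
  oracle <- function(win) {
    s <- 0
    for (i in 1:9) {
      b <- substr(win, i, i)
      cnt <- sum(substr(train, i, i) == b)
      s <- s + log2((cnt + pc) / (length(train) + 4 * pc)) - log2(bg[[b]])
    }
    s
  }
  for (p in probes) expect_equal(score_windows(w, p), oracle(p), tolerance = 1e-12)
})

test_that("training rejects empty or mixed-length input", {
  expect_error(train_wmm(character(), "donor"), "empty")
  expect_error(train_wmm(c("CAGGTAAGT", "CAGG"), "donor"), "mixed")
  expect_error(train_wmm("CAGGTAAGT", "donor", pseudocount = 0), "pseudocount")
})

test_that("matrix files round-trip and score exactly", {
  set.seed(5)
  w <- train_wmm(replicate(20, paste(sample(c("A", "C", "G", "T"), 23, TRUE),
                                     collapse = "")), "acceptor")
  f <- withr::local_tempfile(fileext = ".mat")
  write_score_matrix(w, f)
  m <- load_score_matrix(f)
  expect_s3_class(m, "matrix_scorer")
  expect_identical(m$site_kind, "acceptor")
  wins <- replicate(100, paste(sample(c("A", "C", "G", "T"), 23, TRUE), collapse = ""))
  expect_equal(score_windows(m, wins), score_windows(w, wins), tolerance = 1e-12)

  # all-zero matrix scores every window 0
  zf <- withr::local_tempfile()
  writeLines(c("site_kind=donor", "window_len=9",
               rep(paste(rep("0", 4), collapse = " "), 9)), zf)
  z <- load_score_matrix(zf)
  expect_equal(score_windows(z, wins <- substr(wins, 1, 9)), rep(0, 100))

  # known 4x9 grid: dot-product oracle for CAGGTAAGT
  gf <- withr::local_tempfile()
  grid <- matrix(seq(0.1, 3.6, by = 0.1), nrow = 9, ncol = 4)  # rows=positions
  writeLines(c("site_kind=donor", "window_len=9",
               apply(grid, 1L, paste, collapse = " ")), gf)
  g <- load_score_matrix(gf)
  b <- match(strsplit("CAGGTAAGT", "")[[1]], c("A", "C", "G", "T"))
  expect_equal(score_windows(g, "CAGGTAAGT"), sum(grid[cbind(1:9, b)]),
               tolerance = 1e-12)

  # malformed grids are rejected
  bad <- withr::local_tempfile()
  writeLines(c("site_kind=donor", "window_len=9",
               rep("0 0 0", 9)), bad)
  expect_error(load_score_matrix(bad), "4 columns")
})

test_that("sliding-window scan equals exhaustive window enumeration for both scorer types", {
  set.seed(99)
  gen <- generate_transcript(seed = 17, n_exons = 4L)
  wmm_d <- train_wmm(gen$donor_windows, "donor")
  wmm_a <- train_wmm(gen$acceptor_windows, "acceptor")
  f <- withr::local_tempfile(); write_score_matrix(wmm_d, f)
  loaded_d <- load_score_matrix(f)
  scorers <- list(wmm_d, wmm_a, loaded_d)
  for (rep_i in 1:18) {
    t <- generate_transcript(seed = 100 + rep_i, n_exons = 3L)$transcript
    v <- random_variant(t)
    for (sc in scorers) {
      got <- swa_scan(v, t, sc)
      want <- enumerate_swa(v, t, sc)
      expect_equal(got$alt_score, want$alt_score, tolerance = 1e-12)
      expect_equal(got$ref_score, want$ref_score, tolerance = 1e-12)
      expect_identical(got$window_anchor, want$anchor)
      expect_equal(got$diff, got$ref_score - got$alt_score)
    }
  }
})

test_that("native-site delta scores the fixed annotated window and flags non-overlap", {
  t <- toy_two_exon()
  don <- train_wmm(rep("CAGGTAAGT", 5L), "donor")
  # IVS+1 of the donor after exon 1: window = exon terminal 3 + first 6 intronic
  v <- parse_cdna("c.12+1G>A")
  d <- native_delta(v, t, don)
  expect_false(d$no_overlap)
  expect_identical(d$window_anchor, 10L)        # pre-mRNA 10..18
  win <- substr(t$premrna_seq, 10, 18)
  expect_identical(win, "GGGGTAAGT")            # exon1 ends GGG, intron starts GTAAGT
  expect_equal(d$ref_score, score_windows(don, win))
  alt_win <- win; substr(alt_win, 3, 3) <- "A"
  expect_equal(d$alt_score, score_windows(don, alt_win))
  expect_equal(d$diff, d$ref_score - d$alt_score)

  # deep-intronic variant overlaps no donor window -> marker, minimal loss
  far <- parse_cdna("c.12+10T>C")
  d2 <- native_delta(far, t, don)
  expect_true(d2$no_overlap)
  expect_identical(categorize_native_loss(d2), "minimal")

  # a self-identical substitution is rejected upstream at parse time
  expect_error(parse_cdna("c.12+1G>G"), "identical")
})

test_that("native-loss categorization reproduces the published worked examples", {
  ex <- function(diff, alt) categorize_native_loss(list(diff = diff, alt_score = alt))
  expect_identical(ex(2.0, 5.0), "high")
  expect_identical(ex(-0.5, 9.0), "minimal")
  expect_identical(ex(1.5, 7.0), "moderate")
  expect_identical(ex(0.5, 5.0), "moderate")
})

test_that("gain categorization reproduces the published worked examples and the tie rule", {
  ex <- function(diff, alt, nat)
    categorize_gain(list(diff = diff, alt_score = alt), nat)
  expect_identical(ex(-3.0, 9.0, 7.0), "high")
  expect_identical(ex(-1.0, 7.0, 5.0), "moderate")
  expect_identical(ex(0.5, 10.0, 7.0), "minimal")
  expect_identical(ex(-1.0, 7.0, 7.0), "minimal")   # tie -> conservative
})

test_that("category ladders are total, exclusive, and consistent with the raw predicates", {
  set.seed(2024)
  n <- 1e5
  diff <- stats::runif(n, -5, 5)
  alt <- stats::runif(n, 0, 14)
  nat <- stats::runif(n, 0, 14)
  nl <- vapply(seq_len(n), function(i)
    categorize_native_loss(list(diff = diff[i], alt_score = alt[i])), character(1))
  gn <- vapply(seq_len(n), function(i)
    categorize_gain(list(diff = diff[i], alt_score = alt[i]), nat[i]), character(1))
  # totality: every triple gets exactly one category per axis
  expect_true(all(nl %in% c("minimal", "moderate", "high")))
  expect_true(all(gn %in% c("minimal", "moderate", "high")))
  # consistency with the raw predicates: the assigned category's predicate
  # holds whenever any predicate holds, and uniquely-matching cases agree
  rn <- raw_native_predicates(diff, alt)
  hit <- rn[cbind(seq_len(n), match(nl, colnames(rn)))]
  expect_true(all(hit | rowSums(rn) == 0L))
  uniq <- rowSums(rn) == 1L
  expect_identical(nl[uniq], colnames(rn)[apply(rn[uniq, ], 1L, which.max)])
  rg <- raw_gain_predicates(diff, alt, nat)
  hitg <- rg[cbind(seq_len(n), match(gn, colnames(rg)))]
  expect_true(all(hitg | rowSums(rg) == 0L))
  uniqg <- rowSums(rg) == 1L
  expect_identical(gn[uniqg], colnames(rg)[apply(rg[uniqg, ], 1L, which.max)])
  # no-predicate gain cases fall to minimal (documented tie/boundary rule)
  expect_true(all(gn[rowSums(rg) == 0L] == "minimal"))
})

test_that("with a weak alternate site, increasing diff never weakens the native-loss call", {
  set.seed(31)
  sev <- c(minimal = 1L, moderate = 2L, high = 3L)
  for (alt in stats::runif(20, 0, 6.19)) {
    diffs <- sort(stats::runif(25, -3, 3))
    cats <- vapply(diffs, function(d)
      categorize_native_loss(list(diff = d, alt_score = alt)), character(1))
    expect_true(all(diff(sev[cats]) >= 0L))
  }
})

test_that("parallel prediction reports native loss and gain independently", {
  gen <- generate_transcript(seed = 23, n_exons = 3L, consensus_strength = 0.95)
  t <- gen$transcript
  don <- train_wmm(gen$donor_windows, "donor")
  acc <- train_wmm(gen$acceptor_windows, "acceptor")
  v <- random_variant(t)
  p <- predict_splicing(v, t, don, acc)
  expect_named(p, c("donor", "acceptor", "native_loss", "gain"))
  expect_true(p$native_loss %in% c("minimal", "moderate", "high"))
  expect_true(p$gain %in% c("minimal", "moderate", "high"))
  expect_s3_class(p$donor$scan, "splice_site_delta")
})
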