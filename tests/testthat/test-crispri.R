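two_family_annotation <- function(n_b = 200, n_2 = 100, spacing = 1000) {
  starts_b <- seq(1, by = spacing, length.out = n_b)
  starts_2 <- seq(starts_b[n_b] + spacing, by = spacing, length.out = n_2)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(starts_b, starts_2), width = 400))
  S4Vectors::mcols(gr)$family <- rep(c("LTR2B", "LTR2"), c(n_b, n_2))
  RepeatAnnotation(gr)
}

test_that("peak classes partition the peak set under family precedence", {
  rep_ann <- two_family_annotation()
  fam <- S4Vectors::mcols(rep_ann)$family
  on_b <- GenomicRanges::resize(
    GenomicRanges::granges(rep_ann[fam == "LTR2B"][1:187]), 100, fix = "center")
  on_2 <- GenomicRanges::resize(
    GenomicRanges::granges(rep_ann[fam == "LTR2"][1:90]), 100, fix = "center")
  offs <- GenomicRanges::shift(
    GenomicRanges::resize(GenomicRanges::granges(
      rep_ann[fam == "LTR2"][91:100]), 100, fix = "center"), 500)
  off2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = seq(350000, by = 700, length.out = 108), width = 100))
  peaks <- c(on_b, on_2, offs, off2)
  cls <- classify_dcas9_peaks(peaks, rep_ann, c("LTR2B", "LTR2"))
  expect_equal(unname(cls$counts),
               c(187L, 90L, 118L))
  expect_equal(sum(cls$counts), length(peaks))
  # a peak overlapping both families takes the first family in the list
  both <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    GenomicRanges::start(rep_ann[fam == "LTR2"][1]) - 50, width = 900))
  spanning <- GenomicRanges::reduce(c(
    GenomicRanges::granges(rep_ann[fam == "LTR2B"][200]),
    GenomicRanges::granges(rep_ann[fam == "LTR2"][1])), min.gapwidth = 1e6)
  cls2 <- classify_dcas9_peaks(spanning, rep_ann, c("LTR2B", "LTR2"))
  expect_equal(cls2$class, "LTR2B")
})

test_that("classification equals brute-force reclassification on random peaks", {
  set.seed(101)
  rep_ann <- two_family_annotation(30, 20, spacing = 600)
  fam <- S4Vectors::mcols(rep_ann)$family
  b_df <- data.frame(
    chrom = "chr1",
    start = GenomicRanges::start(rep_ann[fam == "LTR2B"]),
    end = GenomicRanges::end(rep_ann[fam == "LTR2B"]))
  l2_df <- data.frame(
    chrom = "chr1",
    start = GenomicRanges::start(rep_ann[fam == "LTR2"]),
    end = GenomicRanges::end(rep_ann[fam == "LTR2"]))
  got <- list(); expected <- list()
  for (run in seq_len(50)) {
    df <- random_intervals_df(25, chroms = c(chr1 = 40000), max_len = 300)
    peaks <- df_to_gr(df)
    cls <- classify_dcas9_peaks(peaks, rep_ann, c("LTR2B", "LTR2"))
    exp_run <- vapply(seq_len(nrow(df)), function(i) {
      hit_b <- any(df$start[i] <= b_df$end & b_df$start <= df$end[i])
      hit_2 <- any(df$start[i] <= l2_df$end & l2_df$start <= df$end[i])
      if (hit_b) "LTR2B" else if (hit_2) "LTR2" else "off_target"
    }, character(1))
    got[[run]] <- cls$class
    expected[[run]] <- exp_run
  }
  expect_equal(unlist(got), unlist(expected))
})

test_that("signal ratio: identity, closed form and antisymmetry", {
  gl <- GenomeLayout(c(chr1 = 10000))
  track <- function(level) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 10000), score = level)
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 4200))
  same <- signal_log2_ratio(track(2), track(2), peak, gl)
  expect_equal(same$log2_ratio, 0)
  # sg exactly 4x control with large signals: ratio tends to 2
  big <- signal_log2_ratio(track(400), track(100), peak, gl,
                           pseudocount = 1e-9)
  expect_equal(big$log2_ratio, 2, tolerance = 1e-6)
  small_pc <- signal_log2_ratio(track(400), track(100), peak, gl,
                                pseudocount = 1)
  expect_lt(abs(small_pc$log2_ratio - 2), 1e-4)
  # swapping tracks flips the sign
  ab <- signal_log2_ratio(track(3), track(7), peak, gl)
  ba <- signal_log2_ratio(track(7), track(3), peak, gl)
  expect_equal(ab$log2_ratio, -ba$log2_ratio)
  # windows are +-500 bp around the integer midpoint, truncated at ends
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  tr <- signal_log2_ratio(track(1), track(1), edge, gl)
  expect_true(tr$truncated)
})

test_that("window signal sums per-base coverage over the 1 kb window", {
  gl <- GenomeLayout(c(chr1 = 10000))
  # piecewise track: 10 over [4001,4500], 1 elsewhere
  tr_sg <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 4001, 4501), c(4000, 4500, 10000)),
    score = c(1, 10, 1))
  tr_ct <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
                                  score = 1)
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 4200))
  # centre0 = floor((4000 + 4200)/2) = 4100; window 0-based [3600, 4600)
  res <- signal_log2_ratio(tr_sg, tr_ct, peak, gl, pseudocount = 0)
  expect_equal(res$signal_ctrl, 1000)
  expect_equal(res$signal_sg, 400 * 1 + 500 * 10 + 100 * 1)
  expect_equal(res$log2_ratio, log2(5500 / 1000))
})

test_that("planted CRISPRi effects separate on- from off-target ratios", {
  ds <- ds_compact
  cls <- classify_dcas9_peaks(ds$dcas9, ds$repeats, c("LTR2B", "LTR2"))
  on <- cls$class != "off_target"
  k27 <- signal_log2_ratio(ds$tracks$H3K27ac_sg, ds$tracks$H3K27ac_ctrl,
                           ds$dcas9, ds$genome)
  k9 <- signal_log2_ratio(ds$tracks$H3K9me3_sg, ds$tracks$H3K9me3_ctrl,
                          ds$dcas9, ds$genome)
  expect_lt(stats::median(k27$log2_ratio[on]),
            stats::median(k27$log2_ratio[!on]))
  expect_gt(stats::median(k9$log2_ratio[on]),
            stats::median(k9$log2_ratio[!on]))
  expect_lt(stats::median(k27$log2_ratio[on]), 0)
  expect_gt(stats::median(k9$log2_ratio[on]), 0)
})

test_that("proximal genes respect the 50 kb boundary", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(151000, 153001), width = 1000))
  S4Vectors::mcols(genes)$gene_id <- c("near", "far")
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101999, 102000))
  # gaps: "near" is 49 kb away, "far" is 51 kb away
  res <- proximal_genes(peak, genes, max_dist = 50000)
  expect_equal(res$gene_id, "near")
  expect_equal(res$distance, 48999)
  de <- data.frame(gene_id = "near", log2FC = -2, padj = 0.001)
  res2 <- proximal_genes(peak, genes, de_table = de)
  expect_equal(res2$log2FC, -2)
})

test_that("guide matching counts exact, mismatched and reverse-complement hits", {
  guide <- "ACGTACGTACGTACGTACGT"
  seqs <- c(
    e1 = paste0("TTTT", guide, "TTTT"),                       # exact
    e2 = paste0("TTTT", oracle_revcomp(guide), "TTTT"),       # revcomp
    e3 = paste0("TTTT", sub("^AC", "GG", guide), "TTTT"),     # 2 mismatches
    e4 = paste0("TTTT", sub("^ACGT", "GGGG", guide), "TTTT"), # 4 mismatches
    e5 = paste(rep("A", 40), collapse = ""))
  fams <- stats::setNames(rep("LTR2B", 5), names(seqs))
  gt0 <- predict_guide_targets(guide, seqs, fams, max_mismatches = 0)
  expect_equal(unname(gt0$recognised), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  gt2 <- predict_guide_targets(guide, seqs, fams, max_mismatches = 2)
  expect_equal(gt2$per_family$n_recognised, 3L)
  expect_equal(gt2$per_family$fraction, 3 / 5)
})

test_that("guide counts equal the Hamming oracle and survive revcomp", {
  set.seed(102)
  acc_got <- list(); acc_exp <- list(); acc_rc <- list()
  for (run in seq_len(40)) {
    guides <- vapply(1:2, function(i)
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = ""),
      character(1))
    seqs <- vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
      character(1))
    names(seqs) <- sprintf("e%d", 1:8)
    fams <- stats::setNames(rep("F", 8), names(seqs))
    k <- sample(0:2, 1)
    gt <- predict_guide_targets(guides, seqs, fams, max_mismatches = k)
    expected <- vapply(seqs, function(s) oracle_guide_hits(guides, s, k),
                       logical(1))
    rc <- vapply(seqs, oracle_revcomp, character(1))
    gt_rc <- predict_guide_targets(guides, rc, fams, max_mismatches = k)
    acc_got[[run]] <- unname(gt$recognised)
    acc_exp[[run]] <- unname(expected)
    acc_rc[[run]] <- unname(gt_rc$recognised)
  }
  expect_equal(unlist(acc_got), unlist(acc_exp))
  expect_equal(unlist(acc_rc), unlist(acc_exp))
})

test_that("PAM requirement restricts matches when enabled", {
  guide <- "ACGTACGTACGTACGTACGT"
  seqs <- c(pam_ok = paste0("TT", guide, "CGGTT"),   # NGG right of match
            pam_bad = paste0("TT", guide, "CTTTT"))
  fams <- stats::setNames(rep("F", 2), names(seqs))
  gt <- predict_guide_targets(guide, seqs, fams, max_mismatches = 0,
                              pam = "NGG")
  expect_equal(unname(gt$recognised), c(TRUE, FALSE))
})
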