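meme_fixture <- function() {
  path <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF GATA_LIKE", "",
    "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
    " 0.0 0.0 1.0 0.0",
    " 1.0 0.0 0.0 0.0",
    " 0.0 0.0 0.0 1.0",
    " 1.0 0.0 0.0 0.0",
    "",
    "MOTIF MIXED", "",
    "letter-probability matrix: alength= 4 w= 3 nsites= 10 E= 0",
    " 0.25 0.25 0.25 0.25",
    " 0.5 0.5 0.0 0.0",
    " 0.1 0.2 0.3 0.4"), path)
  path
}

test_that("MEME minimal format parses motifs and background", {
  pwms <- read_meme(meme_fixture())
  expect_equal(names(pwms), c("GATA_LIKE", "MIXED"))
  expect_equal(ncol(pwms$GATA_LIKE$matrix), 4L)
  expect_equal(unname(pwms$GATA_LIKE$background),
               c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(pwms$GATA_LIKE$matrix["G", 1]), 1)
  expect_equal(unname(pwms$MIXED$matrix["T", 3]), 0.4)
  expect_true(all(abs(colSums(pwms$MIXED$matrix) - 1) < 1e-9))
})

test_that("a uniform PWM over uniform background scores zero everywhere", {
  pwm <- structure(list(
    motif_id = "flat",
    matrix = matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL)),
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)), class = "pwm")
  hits <- scan_pwm("ACGTACGTACGT", pwm, threshold = 0)
  # every window on both strands is a hit with score 0
  expect_equal(nrow(hits), 2 * (12 - 5 + 1))
  expect_true(all(hits$score == 0))
})

test_that("a consensus-only PWM scores sum(log2(1/bg)) at its exact site", {
  pwm <- pwm_from_consensus("GATA")
  hits <- scan_pwm("CCCCGATACCCC", pwm, threshold = 6)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 4L)   # 0-based offset of GATA
  expect_equal(fwd$score, 4 * log2(1 / 0.25))  # = 8
})

test_that("scan matches the exhaustive per-window oracle on random inputs", {
  set.seed(81)
  for (rep in seq_len(60)) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
    m <- matrix(stats::rexp(32), 4, 8,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m <- sweep(m, 2, colSums(m), "/")
    pwm <- structure(list(motif_id = "r", matrix = m,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25)),
                     class = "pwm")
    thr <- stats::runif(1, -2, 6)
    hits <- scan_pwm(seq, pwm, threshold = thr)
    fwd_scores <- oracle_pwm_scores(seq, pwm)
    rev_scores <- oracle_pwm_scores(oracle_revcomp(seq), pwm)
    nw <- length(fwd_scores)
    exp_fwd <- which(!is.na(fwd_scores) & fwd_scores >= thr) - 1L
    exp_rev <- nw - which(!is.na(rev_scores) & rev_scores >= thr)
    mk <- function(off, strand, score) data.frame(
      offset = off, strand = rep(strand, length(off)), score = score)
    expected <- rbind(mk(exp_fwd, "+", fwd_scores[exp_fwd + 1]),
                      mk(exp_rev, "-", rev_scores[nw - exp_rev]))
    expected <- expected[order(expected$offset, expected$strand), ]
    got <- as.data.frame(hits)[order(hits$offset, hits$strand),
                               c("offset", "strand", "score")]
    expect_equal(got$offset, expected$offset)
    expect_equal(got$strand, expected$strand)
    expect_equal(got$score, expected$score)
  }
})

test_that("windows with ambiguous bases are skipped and counted", {
  pwm <- pwm_from_consensus("ACGT")
  hits <- scan_pwm("ACGTNACGT", pwm, threshold = 0)
  expect_true(all(hits$offset %in% c(0L, 5L)))
  expect_gt(attr(hits, "n_skipped"), 0L)
})

test_that("plus-strand scores equal reverse-complement minus-strand scores", {
  set.seed(82)
  for (rep in seq_len(30)) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    pwm <- pwm_from_consensus(paste(sample(c("A", "C", "G", "T"), 6,
                                           replace = TRUE), collapse = ""))
    h1 <- scan_pwm(seq, pwm, threshold = -100)
    h2 <- scan_pwm(oracle_revcomp(seq), pwm, threshold = -100)
    # a + hit at offset o maps to a - hit at (n - L - o) on the complement
    n <- nchar(seq); L <- 6
    mapped <- data.frame(offset = n - L - h1$offset,
                         strand = ifelse(h1$strand == "+", "-", "+"),
                         score = h1$score)
    mapped <- mapped[order(mapped$offset, mapped$strand), ]
    h2 <- h2[order(h2$offset, h2$strand), ]
    expect_equal(mapped$offset, h2$offset)
    expect_equal(mapped$score, h2$score)
  }
})

test_that("family motif frequency is the recount of elements with hits", {
  fams <- c(e1 = "A", e2 = "A", e3 = "B", e4 = "B", e5 = "B")
  hits <- list(e1 = data.frame(offset = 1), e2 = data.frame()[0, ],
               e3 = data.frame(offset = 1), e4 = data.frame(offset = 2),
               e5 = data.frame()[0, ])
  tab <- motif_family_frequency(hits, fams)
  expect_equal(tab$fraction[tab$family == "A"], 0.5)
  expect_equal(tab$fraction[tab$family == "B"], 2 / 3)
})

test_that("planted consensus motifs are recovered at their offsets", {
  ds <- ds_compact
  pm <- ds$config$planted_motifs
  for (j in seq_len(nrow(pm))) {
    pwm <- pwm_from_consensus(pm$consensus[j], motif_id = "planted")
    cmap <- consensus_motif_map(ds$consensus[pm$family[j]], list(pwm),
                                threshold = 6)
    expect_true(pm$offset[j] %in% cmap$offset[cmap$strand == "+"])
  }
  # reverse-complementing the consensus mirrors offsets and strands
  pwm <- pwm_from_consensus(pm$consensus[1], motif_id = "planted")
  fam <- pm$family[1]
  rc <- stats::setNames(oracle_revcomp(ds$consensus[[fam]]), fam)
  fwd_map <- consensus_motif_map(ds$consensus[fam], list(pwm), threshold = 6)
  rc_map <- consensus_motif_map(rc, list(pwm), threshold = 6)
  n <- nchar(ds$consensus[[fam]]); L <- nchar(pm$consensus[1])
  expect_setequal(n - L - fwd_map$offset, rc_map$offset)
})

test_that("DHS+/- motif contrast separates classes and excludes intermediates", {
  els <- sprintf("e%02d", 1:40)
  dhs <- matrix(0L, nrow = 40, ncol = 8,
                dimnames = list(els, paste0("A", 1:8)))
  dhs[1:10, 1:6] <- 1L   # DHS+ (>= 5 samples)
  dhs[11:15, 1:2] <- 1L  # intermediate: excluded from the contrast
  hits_perfect <- stats::setNames(c(rep(TRUE, 10), rep(FALSE, 30)), els)
  hits_flat <- stats::setNames(rep(TRUE, 40), els)
  res <- dhs_motif_contrast(list(perfect = hits_perfect, flat = hits_flat),
                            dhs, min_pos_samples = 5)
  expect_equal(res$n_pos, c(10L, 10L))
  expect_equal(res$n_neg, c(25L, 25L))
  expect_lt(res$q[res$motif_id == "perfect"], 0.001)
  expect_equal(res$freq_pos[res$motif_id == "flat"], 1)
  expect_equal(res$freq_neg[res$motif_id == "flat"], 1)
  expect_equal(res$p[res$motif_id == "flat"], 1)
  expect_error(dhs_motif_contrast(list(m = hits_flat), dhs,
                                  min_pos_samples = 100), "non-empty")
})
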