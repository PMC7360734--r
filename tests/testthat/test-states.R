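marks4 <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K9me3")

# hand-built mark peak sets over three elements on a 1 kb chromosome
state_fixture <- function() {
  el <- df_to_gr(data.frame(chrom = "chrA", start = c(1, 301, 601),
                            end = c(100, 400, 700)))
  S4Vectors::mcols(el)$family <- c("F1", "F1", "F2")
  S4Vectors::mcols(el)$element_id <- c("e1", "e2", "e3")
  peak_at <- function(i) data.frame(chrom = "chrA",
                                    start = c(1, 301, 601)[i] + 10,
                                    end = c(1, 301, 601)[i] + 40)
  sets <- list(
    PeakSet("a1", "H3K27ac", "AML", df_to_gr(peak_at(1))),
    PeakSet("a2", "H3K27ac", "AML", df_to_gr(peak_at(1))),
    PeakSet("a1", "H3K4me1", "AML", df_to_gr(rbind(peak_at(1), peak_at(2)))),
    PeakSet("a2", "H3K4me1", "AML", df_to_gr(peak_at(2))),
    PeakSet("a1", "H3K4me3", "AML", df_to_gr(peak_at(3))),
    PeakSet("a2", "H3K4me3", "AML", df_to_gr(peak_at(3))),
    PeakSet("a1", "H3K9me3", "AML", GenomicRanges::GRanges()),
    PeakSet("a2", "H3K9me3", "AML", GenomicRanges::GRanges()),
    PeakSet("d1", "H3K27ac", "differentiated", df_to_gr(peak_at(3))),
    PeakSet("d1", "H3K4me1", "differentiated", GenomicRanges::GRanges()),
    PeakSet("d1", "H3K4me3", "differentiated", GenomicRanges::GRanges()),
    PeakSet("d1", "H3K9me3", "differentiated", GenomicRanges::GRanges()))
  list(el = el, sets = sets)
}

test_that("mark overlap fractions are direct per-group ratios", {
  fx <- state_fixture()
  f <- mark_overlap_fractions(fx$el, fx$sets)
  expect_equal(f$fractions["e1", "H3K27ac.AML"], 2 / 2)
  expect_equal(f$fractions["e2", "H3K27ac.AML"], 0)
  expect_equal(f$fractions["e1", "H3K4me1.AML"], 1 / 2)
  expect_equal(f$fractions["e2", "H3K4me1.AML"], 2 / 2)
  expect_equal(f$fractions["e3", "H3K4me3.AML"], 1)
  expect_equal(f$fractions["e3", "H3K27ac.differentiated"], 1)
  expect_equal(unname(f$n_samples["H3K27ac.AML"]), 2L)
  expect_equal(f$family_means["F1", "H3K27ac.AML"], 0.5)
})

test_that("fractions equal brute-force recounts on random fixtures", {
  set.seed(51)
  el_df <- random_intervals_df(15)
  el <- df_to_gr(el_df)
  S4Vectors::mcols(el)$family <- "F"
  S4Vectors::mcols(el)$element_id <- sprintf("e%02d", 1:15)
  peak_store <- list()
  sets <- list()
  for (mk in marks4) for (sid in c("a1", "a2", "a3", "d1")) {
    df <- random_intervals_df(6)
    peak_store[[paste(mk, sid)]] <- df
    grp <- if (grepl("^a", sid)) "AML" else "differentiated"
    sets[[length(sets) + 1L]] <- PeakSet(sid, mk, grp, df_to_gr(df))
  }
  f <- mark_overlap_fractions(el, sets)
  got <- c(); expected <- c()
  for (i in seq_len(15)) for (mk in marks4) {
    n_hit <- sum(vapply(c("a1", "a2", "a3"), function(sid) {
      df <- peak_store[[paste(mk, sid)]]
      any(df$chrom == el_df$chrom[i] & df$start <= el_df$end[i] &
            el_df$start[i] <= df$end)
    }, logical(1)))
    got <- c(got, f$fractions[i, paste0(mk, ".AML")])
    expected <- c(expected, n_hit / 3)
  }
  expect_equal(got, expected)
})

test_that("the state rule covers all 16 indicator combinations", {
  # independent rule table: K4me3 wins, then K4me1&K27ac, K4me1, K9me3
  grid <- expand.grid(K27ac = c(FALSE, TRUE), K4me1 = c(FALSE, TRUE),
                      K4me3 = c(FALSE, TRUE), K9me3 = c(FALSE, TRUE))
  expected <- with(grid, ifelse(K4me3, "promoter_like",
                    ifelse(K4me1 & K27ac, "active_enhancer",
                    ifelse(K4me1, "primed_enhancer",
                    ifelse(K9me3, "heterochromatic", "unmarked")))))
  fr <- cbind(ifelse(grid$K27ac, 1, 0), ifelse(grid$K4me1, 1, 0),
              ifelse(grid$K4me3, 1, 0), ifelse(grid$K9me3, 1, 0))
  colnames(fr) <- paste0(marks4, ".AML")
  fr <- cbind(fr, matrix(0, 16, 4,
                         dimnames = list(NULL,
                                         paste0(marks4, ".differentiated"))))
  rownames(fr) <- sprintf("c%02d", 1:16)
  feats <- structure(list(fractions = fr,
                          counts = fr * 10L,
                          n_samples = stats::setNames(rep(10L, 8),
                                                      colnames(fr))),
                     class = "state_features")
  got <- classify_state(feats, min_frac = 0.5)
  expect_equal(unname(got), expected)
  # the headline combination: K4me1 + K27ac without K4me3 is active enhancer
  expect_equal(unname(got[grid$K27ac & grid$K4me1 & !grid$K4me3 &
                            !grid$K9me3]), "active_enhancer")
  # K4me3 together with K4me1 is promoter-like (K4me3 precedence)
  expect_true(all(got[grid$K4me3 & grid$K4me1] == "promoter_like"))
})

test_that("marked-element counts apply the >=2-AML-sample convention", {
  counts <- matrix(0L, nrow = 5, ncol = 8,
                   dimnames = list(paste0("e", 1:5),
                                   c(paste0(marks4, ".AML"),
                                     paste0(marks4, ".differentiated"))))
  counts[, "H3K4me1.AML"] <- c(3L, 2L, 1L, 0L, 5L)
  counts[, "H3K27ac.AML"] <- c(2L, 0L, 1L, 0L, 3L)
  feats <- structure(list(fractions = counts / 10,
                          counts = counts,
                          n_samples = stats::setNames(rep(10L, 8),
                                                      colnames(counts))),
                     class = "state_features")
  expect_equal(count_marked_elements(feats, "H3K4me1"), 3L)
  expect_equal(count_marked_elements(feats, "H3K27ac"), 2L)
  expect_equal(count_marked_elements(feats, c("H3K4me1", "H3K27ac")), 2L)
  expect_equal(count_marked_elements(feats, "H3K4me1", min_samples = 1), 4L)
  expect_error(count_marked_elements(feats, "H3K27me3"), "unknown mark")
})

test_that("k-means recovers separable blobs with stable renumbering", {
  set.seed(52)
  n <- 60
  truth <- rep(1:2, each = n / 2)
  m <- matrix(0.03, nrow = n, ncol = 8,
              dimnames = list(sprintf("e%02d", 1:n),
                              c(paste0(marks4, ".AML"),
                                paste0(marks4, ".differentiated"))))
  m[truth == 1, "H3K27ac.AML"] <- 0.8
  m[truth == 1, "H3K4me1.AML"] <- 0.8
  m <- m + matrix(stats::runif(n * 8, 0, 0.02), n, 8)
  cl <- cluster_elements(m, k = 2, seed = 5)
  # renumbering puts the high-H3K27ac blob first
  expect_equal(unname(cl[truth == 1]), rep(1L, n / 2))
  expect_equal(unname(cl[truth == 2]), rep(2L, n / 2))
  # duplicate rows always share a label
  m2 <- rbind(m, m[1:5, ])
  rownames(m2) <- c(rownames(m), paste0("dup", 1:5))
  cl2 <- cluster_elements(m2, k = 2, seed = 5)
  expect_equal(unname(cl2[paste0("dup", 1:5)]), unname(cl2[rownames(m)[1:5]]))
  # label assignment is stable under row shuffling (up to renumbering)
  perm <- sample(n)
  cl3 <- cluster_elements(m[perm, ], k = 2, seed = 11)
  expect_equal(as.integer(cl3[rownames(m)]), as.integer(cl))
  expect_error(cluster_elements(m, k = 100, seed = 1), "exceeds")
})
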