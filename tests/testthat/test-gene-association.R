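mk_elements <- function(df, ids = NULL) {
  gr <- df_to_gr(df)
  S4Vectors::mcols(gr)$family <- "F"
  S4Vectors::mcols(gr)$element_id <-
    if (is.null(ids)) sprintf("e%d", seq_along(gr)) else ids
  gr
}

mk_genes <- function(df, ids = NULL) {
  gr <- df_to_gr(df)
  S4Vectors::mcols(gr)$gene_id <-
    if (is.null(ids)) sprintf("g%d", seq_along(gr)) else ids
  gr
}

test_that("gene-element distance is the nearest-end gap, zero on overlap", {
  # 0-based: gene (1000,2000), element (2500,2600) -> gap 500
  genes <- mk_genes(data.frame(chrom = "chrA", start = 1001, end = 2000))
  el <- mk_elements(data.frame(chrom = "chrA", start = 2501, end = 2600))
  pairs <- genes_near_elements(genes, el, max_dist = 50000)
  expect_equal(pairs$distance, 500)
  # element inside the gene span -> distance 0
  el0 <- mk_elements(data.frame(chrom = "chrA", start = 1200, end = 1300))
  expect_equal(genes_near_elements(genes, el0)$distance, 0)
  # beyond the cutoff the pair is dropped
  far <- mk_elements(data.frame(chrom = "chrA", start = 60000, end = 60100))
  expect_equal(nrow(genes_near_elements(genes, far, max_dist = 50000)), 0L)
})

test_that("distances equal the brute-force min-gap oracle and are symmetric", {
  set.seed(71)
  got <- list(); fwd <- list(); rev <- list(); zero_ok <- list()
  for (rep in seq_len(300)) {
    g_df <- random_intervals_df(5, chroms = c(chrA = 5000))
    e_df <- random_intervals_df(5, chroms = c(chrA = 5000))
    pairs <- genes_near_elements(mk_genes(g_df), mk_elements(e_df),
                                 max_dist = 10000)
    i <- as.integer(sub("g", "", pairs$gene_id))
    j <- as.integer(sub("e", "", pairs$element_id))
    d1 <- mapply(function(a, b) oracle_distance(g_df$start[a], g_df$end[a],
                                                e_df$start[b], e_df$end[b]),
                 i, j)
    d2 <- mapply(function(a, b) oracle_distance(e_df$start[b], e_df$end[b],
                                                g_df$start[a], g_df$end[a]),
                 i, j)
    got[[rep]] <- pairs$distance
    fwd[[rep]] <- d1
    rev[[rep]] <- d2
    zero_ok[[rep]] <- (d1 == 0) == (g_df$start[i] <= e_df$end[j] + 1 &
                                      e_df$start[j] <= g_df$end[i] + 1)
  }
  expect_gt(length(unlist(got)), 1000)  # >= 1000 random pair instances
  expect_equal(unlist(got), as.numeric(unlist(fwd)))
  expect_equal(unlist(fwd), unlist(rev))
  expect_true(all(unlist(zero_ok)))
})

test_that("per-gene contrast computes log2 difference and the flag rule", {
  expr <- stats::setNames(c(2.5, 2.5, 0.3, 0.3, 0.3), paste0("s", 1:5))
  dhs <- stats::setNames(c(1, 1, 0, 0, 0), paste0("s", 1:5))
  got <- per_gene_dhs_contrast("g1", "e1", expr, dhs)
  expect_equal(got$mean_pos, 2.5)
  expect_equal(got$mean_neg, 0.3)
  expect_equal(got$log2_diff, 2.2)
  expect_true(got$flagged)  # >4-fold (log2_diff > 2) and mean_pos > 0
  # identical expression in both groups: no flag
  same <- per_gene_dhs_contrast("g1", "e1",
                                stats::setNames(rep(1.5, 5), paste0("s", 1:5)),
                                dhs)
  expect_equal(same$log2_diff, 0)
  expect_false(same$flagged)
  # large difference but non-positive DHS+ mean: no flag
  neg <- per_gene_dhs_contrast("g1", "e1",
                               stats::setNames(c(-0.5, -0.5, -3, -3, -3),
                                               paste0("s", 1:5)), dhs)
  expect_gt(neg$log2_diff, 2)
  expect_false(neg$flagged)
  # degenerate split: undefined sentinel, not flagged
  allpos <- per_gene_dhs_contrast("g1", "e1", expr,
                                  stats::setNames(rep(1, 5), paste0("s", 1:5)))
  expect_true(is.na(allpos$log2_diff))
  expect_false(allpos$flagged)
})

test_that("contrast values equal hand-computed group means on random data", {
  set.seed(72)
  for (rep in seq_len(100)) {
    n <- 8
    expr <- stats::setNames(round(stats::rnorm(n, 2, 1), 3), paste0("s", 1:n))
    dhs <- stats::setNames(rbinom(n, 1, 0.5), paste0("s", 1:n))
    if (sum(dhs) %in% c(0, n)) next
    got <- per_gene_dhs_contrast("g", "e", expr, dhs)
    expect_equal(got$mean_pos, mean(expr[dhs == 1]))
    expect_equal(got$mean_neg, mean(expr[dhs == 0]))
    expect_equal(got$log2_diff, mean(expr[dhs == 1]) - mean(expr[dhs == 0]))
  }
})

test_that("expression grouping applies the DHS-positive precedence rule", {
  genes <- mk_genes(data.frame(chrom = "chrA",
                               start = c(1, 3001, 6001, 9001),
                               end = c(1000, 4000, 7000, 10000)))
  el <- mk_elements(data.frame(chrom = "chrA",
                               start = c(1100, 4100, 7100, 9100),
                               end = c(1200, 4200, 7200, 9200)),
                    ids = c("both", "amlonly", "closed", "closed2"))
  pairs <- genes_near_elements(genes, el, max_dist = 500)
  dhs <- rbind(both = c(1, 1, 0, 1), amlonly = c(1, 1, 0, 0),
               closed = c(0, 0, 0, 0), closed2 = c(0, 0, 0, 0))
  colnames(dhs) <- c("A1", "A2", "A3", "D1")
  groups <- c(A1 = "AML", A2 = "AML", A3 = "AML", D1 = "differentiated")
  expr <- matrix(c(5, 5, 5, 0,
                   3, 3, 3, 0,
                   1, 1, 1, 0,
                   1, 1, 1, 0), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), colnames(dhs)))
  res <- group_expression_by_dhs(pairs, expr, dhs, groups = groups)
  expect_equal(names(res$aml_and_diff), "g1")
  expect_equal(names(res$aml_only), "g2")
  expect_equal(sort(names(res$no_dhs)), c("g3", "g4"))
  expect_equal(unname(res$aml_and_diff["g1"]), 5)
  # a gene near both a DHS+ and a DHS- element joins the DHS+ class once
  pairs2 <- rbind(pairs,
                  data.frame(gene_id = "g2", element_id = "closed",
                             family = "F", distance = 100))
  res2 <- group_expression_by_dhs(pairs2, expr, dhs, groups = groups)
  expect_equal(names(res2$aml_only), "g2")
  expect_equal(unname(res2$counts), c(1L, 1L, 2L))
})

test_that("planted expression shifts order the group medians", {
  # 10 genes near open elements carry a +2 log2 shift in DHS+ samples;
  # 10 genes near closed elements stay at baseline
  set.seed(73)
  n_open <- 10; n_closed <- 10
  genes <- mk_genes(data.frame(
    chrom = "chrA", start = seq(1, by = 5000, length.out = 20),
    end = seq(1, by = 5000, length.out = 20) + 999))
  el <- mk_elements(data.frame(
    chrom = "chrA", start = seq(1, by = 5000, length.out = 20) + 1200,
    end = seq(1, by = 5000, length.out = 20) + 1300))
  pairs <- genes_near_elements(genes, el, max_dist = 500)
  samples <- c(paste0("A", 1:10), "D1")
  groups <- stats::setNames(c(rep("AML", 10), "differentiated"), samples)
  dhs <- matrix(0L, nrow = 20, ncol = 11,
                dimnames = list(sprintf("e%d", 1:20), samples))
  dhs[1:n_open, 1:5] <- 1L
  expr <- matrix(stats::rnorm(20 * 11, 2, 0.5), nrow = 20,
                 dimnames = list(sprintf("g%d", 1:20), samples))
  expr[1:n_open, 1:5] <- expr[1:n_open, 1:5] + 2
  res <- group_expression_by_dhs(pairs, expr, dhs, groups = groups)
  open_vals <- c(res$aml_and_diff, res$aml_only)
  expect_equal(length(open_vals), n_open)
  expect_gt(stats::median(open_vals), stats::median(res$no_dhs))
})
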