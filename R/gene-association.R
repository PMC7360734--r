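#' Pair genes with repeat elements within a distance cutoff
#'
#' Distance is 0 when the gene span and the element overlap, otherwise the
#' gap between their nearest ends; pairs farther than `max_dist` are dropped.
#' The whole gene span is used (the stringent proximal-regulation reading);
#' set `use_tss = TRUE` to measure from the gene's TSS instead.
#'
#' @param genes `GRanges` of gene spans with a `gene_id` metadata column
#'   (stranded if `use_tss`).
#' @param elements Repeat annotation `GRanges` with `element_id`.
#' @param max_dist Maximum separation in bp (default 50000).
#' @param use_tss Measure distance from the gene TSS rather than the span.
#' @return data.frame `gene_id, element_id, family, distance`.
#' @export
genes_near_elements <- function(genes, elements, max_dist = 50000,
                                use_tss = FALSE) {
  if (is.null(S4Vectors::mcols(genes)$gene_id)) stop("genes need a gene_id column")
  g <- if (use_tss) GenomicRanges::resize(genes, width = 1L, fix = "start") else genes
  ov <- GenomicRanges::findOverlaps(g, elements, maxgap = max_dist,
                                    ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  d <- GenomicRanges::distance(g[qh], elements[sh], ignore.strand = TRUE)
  keep <- d <= max_dist
  data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id[qh][keep],
    element_id = S4Vectors::mcols(elements)$element_id[sh][keep],
    family = S4Vectors::mcols(elements)$family[sh][keep],
    distance = as.numeric(d[keep]),
    stringsAsFactors = FALSE
  )
}

#' Expression of genes grouped by the DHS status of their nearby elements
#'
#' Partitions genes near repeat elements into three classes by the chromatin
#' status of those elements: near an element open in AML and also in
#' differentiated cells, near an element open in AML only, or near elements
#' open in no sample. A gene near any open element is assigned to an open
#' class (AML-with-differentiated takes precedence over AML-only); each gene
#' is counted once. Returns each class's per-gene mean expression across AML
#' samples.
#'
#' @param pairs Gene-element pairs from [genes_near_elements].
#' @param expr Numeric matrix, genes x samples, log2-scale normalized
#'   expression.
#' @param dhs_matrix Binary element-by-sample matrix from
#'   [build_overlap_matrix] (its `groups` attribute, or the `groups`
#'   argument, identifies AML vs differentiated columns). Elements absent
#'   from the matrix count as never-open.
#' @param groups Named group vector; defaults to `attr(dhs_matrix, "groups")`.
#' @param min_pos_samples AML samples required for an element to count as
#'   DHS-positive (default 2).
#' @return List of class `dhs_expression_groups` with numeric vectors
#'   `aml_and_diff`, `aml_only`, `no_dhs` (named by gene), counts, and
#'   `n_skipped` genes missing from the matrix.
#' @export
group_expression_by_dhs <- function(pairs, expr, dhs_matrix, groups = NULL,
                                    min_pos_samples = 2) {
  if (is.null(groups)) groups <- attr(dhs_matrix, "groups")
  if (is.null(groups)) stop("sample groups are required")
  aml_cols <- intersect(colnames(dhs_matrix), names(groups)[groups == "AML"])
  diff_cols <- intersect(colnames(dhs_matrix),
                         names(groups)[groups == "differentiated"])
  aml_expr_cols <- intersect(colnames(expr), names(groups)[groups == "AML"])
  if (length(aml_expr_cols) == 0L) stop("expression matrix has no AML samples")
  el_aml <- rowSums(dhs_matrix[, aml_cols, drop = FALSE])
  el_diff <- rowSums(dhs_matrix[, diff_cols, drop = FALSE])
  status <- function(el) {
    if (!el %in% rownames(dhs_matrix)) return("no_dhs")
    if (el_aml[el] >= min_pos_samples) {
      if (el_diff[el] >= 1L) "aml_and_diff" else "aml_only"
    } else "no_dhs"
  }
  pairs$status <- vapply(pairs$element_id, status, character(1))
  prec <- c(aml_and_diff = 1L, aml_only = 2L, no_dhs = 3L)
  by_gene <- tapply(prec[pairs$status], pairs$gene_id, min)
  gene_class <- names(prec)[by_gene]
  names(gene_class) <- names(by_gene)
  known <- names(gene_class) %in% rownames(expr)
  n_skipped <- sum(!known)
  if (n_skipped > 0L)
    warning(n_skipped, " gene(s) missing from the expression matrix; skipped")
  gene_class <- gene_class[known]
  mean_expr <- rowMeans(expr[names(gene_class), aml_expr_cols, drop = FALSE])
  out <- lapply(c(aml_and_diff = "aml_and_diff", aml_only = "aml_only",
                  no_dhs = "no_dhs"),
                function(cl) mean_expr[gene_class == cl])
  structure(c(out, list(counts = lengths(out[1:3]), n_skipped = n_skipped)),
            class = "dhs_expression_groups")
}

#' Per-gene expression contrast between DHS-positive and DHS-negative samples
#'
#' For one gene-element pair, splits the AML samples by whether the element
#' carries a DHS, and contrasts the gene's mean log2 expression between the
#' two sides. With expression on a log2 (vst-like) scale, a greater-than-
#' fourfold difference is `log2_diff > 2`; a pair is flagged when additionally
#' the DHS-positive mean is above zero.
#'
#' @param gene_id,element_id Identifiers for the pair.
#' @param expr_row Named numeric vector: the gene's expression per sample.
#' @param dhs_row Named 0/1 vector: the element's DHS status per sample.
#' @param samples Samples to use (default: intersection of the two vectors'
#'   names; restrict to AML samples upstream).
#' @return One-row data.frame `gene_id, element_id, n_dhs_pos, n_dhs_neg,
#'   mean_pos, mean_neg, log2_diff, flagged`. When either side is empty the
#'   means and difference are `NA` and the pair is not flagged.
#' @export
per_gene_dhs_contrast <- function(gene_id, element_id, expr_row, dhs_row,
                                  samples = NULL) {
  if (is.null(samples)) samples <- intersect(names(expr_row), names(dhs_row))
  if (length(samples) == 0L) stop("no shared samples between expression and DHS")
  pos <- samples[dhs_row[samples] > 0]
  neg <- samples[dhs_row[samples] == 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    return(data.frame(gene_id = gene_id, element_id = element_id,
                      n_dhs_pos = length(pos), n_dhs_neg = length(neg),
                      mean_pos = NA_real_, mean_neg = NA_real_,
                      log2_diff = NA_real_, flagged = FALSE,
                      stringsAsFactors = FALSE))
  }
  mean_pos <- mean(expr_row[pos]); mean_neg <- mean(expr_row[neg])
  log2_diff <- mean_pos - mean_neg
  data.frame(gene_id = gene_id, element_id = element_id,
             n_dhs_pos = length(pos), n_dhs_neg = length(neg),
             mean_pos = mean_pos, mean_neg = mean_neg,
             log2_diff = log2_diff,
             flagged = log2_diff > 2 & mean_pos > 0,
             stringsAsFactors = FALSE)
}

#' DHS contrasts for all gene-element pairs
#'
#' Applies [per_gene_dhs_contrast] across a pair table, restricted to AML
#' samples present in both the expression matrix and the DHS matrix.
#'
#' @param pairs Gene-element pairs from [genes_near_elements].
#' @param expr Genes x samples log2 expression matrix.
#' @param dhs_matrix Element-by-sample binary matrix.
#' @param groups Named group vector; default `attr(dhs_matrix, "groups")`.
#' @return data.frame with one row per pair (genes or elements missing from
#'   the matrices are skipped with a warning count).
#' @export
dhs_contrast_table <- function(pairs, expr, dhs_matrix, groups = NULL) {
  if (is.null(groups)) groups <- attr(dhs_matrix, "groups")
  aml <- names(groups)[groups == "AML"]
  samples <- intersect(intersect(colnames(expr), colnames(dhs_matrix)), aml)
  ok <- pairs$gene_id %in% rownames(expr) &
    pairs$element_id %in% rownames(dhs_matrix)
  if (any(!ok))
    warning(sum(!ok), " pair(s) missing from expression or DHS matrix; skipped")
  pairs <- pairs[ok, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    per_gene_dhs_contrast(pairs$gene_id[i], pairs$element_id[i],
                          expr[pairs$gene_id[i], ],
                          dhs_matrix[pairs$element_id[i], ],
                          samples = samples))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
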