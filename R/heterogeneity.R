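#' Binary element-by-sample overlap matrix
#'
#' Marks, for each repeat element and each sample, whether the element is
#' overlapped by at least one peak in that sample. Elements overlapped in no
#' sample are dropped (there is nothing to correlate on an all-zero row).
#'
#' @param elements Repeat annotation `GRanges` with `element_id`.
#' @param dhs_sets List of [PeakSet] objects (>= 2 samples).
#' @return Integer 0/1 matrix, rows named by `element_id`, columns by sample
#'   id in input order. Attribute `groups` carries each column's group.
#' @export
build_overlap_matrix <- function(elements, dhs_sets) {
  if (length(dhs_sets) < 2L) stop("need at least 2 samples")
  ids <- vapply(dhs_sets, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  m <- vapply(dhs_sets, function(p) {
    as.integer(GenomicRanges::countOverlaps(elements, p$peaks,
                                            ignore.strand = TRUE) > 0L)
  }, integer(length(elements)))
  if (length(elements) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(S4Vectors::mcols(elements)$element_id, ids)
  keep <- rowSums(m) > 0L
  if (!any(keep)) stop("no element overlaps any peak in any sample")
  m <- m[keep, , drop = FALSE]
  attr(m, "groups") <- stats::setNames(
    vapply(dhs_sets, function(p) p$group, character(1)), ids)
  m
}

#' Inter-sample correlation of binary overlap patterns
#'
#' Pearson correlation of 0/1 columns (the phi coefficient) or the Jaccard
#' index of shared positive elements. A constant column has no Pearson
#' correlation; affected pairs are set to `NA` and flagged.
#'
#' @param m Binary element-by-sample matrix from [build_overlap_matrix].
#' @param method `"pearson"` or `"jaccard"`.
#' @return Symmetric sample-by-sample matrix with unit diagonal. Attribute
#'   `constant_columns` names columns with zero variance (Pearson only).
#' @export
sample_correlation <- function(m, method = c("pearson", "jaccard")) {
  method <- match.arg(method)
  if (ncol(m) < 2L) stop("need at least 2 columns")
  if (method == "pearson") {
    const <- apply(m, 2, function(v) stats::var(v) == 0)
    cc <- suppressWarnings(stats::cor(m, method = "pearson"))
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
    diag(cc) <- 1
    attr(cc, "constant_columns") <- colnames(m)[const]
    return(cc)
  }
  inter <- crossprod(m)
  tot <- colSums(m)
  union <- outer(tot, tot, "+") - inter
  jac <- ifelse(union == 0, NA_real_, inter / union)
  diag(jac) <- 1
  jac
}

#' Permutation test comparing within-group pairwise correlations
#'
#' Tests whether samples sharing a mutation are better inter-correlated than
#' samples without it. The statistic is
#' `median(within-mutated pair correlations) - median(within-wildtype pair
#' correlations)`; between-group pairs enter neither set. The null permutes
#' mutation labels over samples (not over pairs, which are not independent),
#' giving a one-sided add-one permutation p-value.
#'
#' @param corr Symmetric sample correlation matrix with dimnames.
#' @param mut_labels Named logical vector over the samples of `corr`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return A list of class `correlation_comparison`: `statistic`,
#'   `median_mut`, `median_wt`, `within_mut`, `within_wt`, `p_perm`, `n_perm`,
#'   `n_mut`, `n_wt`.
#' @export
mutation_correlation_test <- function(corr, mut_labels, n_perm = 10000,
                                      seed = NULL) {
  samples <- colnames(corr)
  if (is.null(samples) || !all(samples %in% names(mut_labels)))
    stop("corr must have sample dimnames covered by mut_labels")
  lab <- as.logical(mut_labels[samples])
  n_mut <- sum(lab); n_wt <- sum(!lab)
  if (n_mut < 2L || n_wt < 2L)
    stop("need at least 2 mutated and 2 non-mutated samples")
  ut <- upper.tri(corr)
  pair_i <- row(corr)[ut]; pair_j <- col(corr)[ut]
  vals <- corr[ut]
  stat_for <- function(l) {
    wm <- l[pair_i] & l[pair_j]
    ww <- !l[pair_i] & !l[pair_j]
    stats::median(vals[wm], na.rm = TRUE) - stats::median(vals[ww], na.rm = TRUE)
  }
  observed <- stat_for(lab)
  if (!is.null(seed)) set.seed(as.integer(seed))
  null_stats <- vapply(seq_len(n_perm), function(b) stat_for(sample(lab)),
                       numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  structure(
    list(statistic = observed,
         median_mut = stats::median(vals[lab[pair_i] & lab[pair_j]], na.rm = TRUE),
         median_wt = stats::median(vals[!lab[pair_i] & !lab[pair_j]], na.rm = TRUE),
         within_mut = vals[lab[pair_i] & lab[pair_j]],
         within_wt = vals[!lab[pair_i] & !lab[pair_j]],
         p_perm = p, n_perm = n_perm, n_mut = n_mut, n_wt = n_wt),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(paste0("correlation_comparison: median within-mut %.3f vs",
                     " within-wt %.3f (diff %.3f), p_perm = %.4g [%d perms]\n"),
              x$median_mut, x$median_wt, x$statistic, x$p_perm, x$n_perm))
  invisible(x)
}
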