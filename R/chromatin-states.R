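#' Per-element histone-mark overlap fractions by sample group
#'
#' For each element and each mark-by-group combination, the fraction of that
#' group's samples whose peak set overlaps the element. The resulting
#' eight-dimensional profile (four marks x AML/differentiated) is the feature
#' vector for state classification and clustering.
#'
#' @param elements Repeat annotation `GRanges` with `element_id` (and
#'   `family`, used for the per-family averages).
#' @param marksets List of [PeakSet] objects whose `assay` is one of the four
#'   marks and whose `group` is `"AML"` or `"differentiated"`.
#' @param marks Marks to profile.
#' @return A list of class `state_features`: `fractions` (elements x 8 matrix
#'   with columns `<mark>.<group>`), `counts` (same shape, integer overlap
#'   counts), `n_samples` (named vector per mark.group), `family` (per
#'   element), `family_means` (family x 8 matrix). Missing mark-group
#'   combinations give `NA` columns and are listed in `missing_combinations`.
#' @export
mark_overlap_fractions <- function(elements, marksets,
                                   marks = c("H3K27ac", "H3K4me1",
                                             "H3K4me3", "H3K9me3")) {
  groups_use <- c("AML", "differentiated")
  combos <- expand.grid(mark = marks, group = groups_use,
                        stringsAsFactors = FALSE)
  key <- paste(combos$mark, combos$group, sep = ".")
  n_el <- length(elements)
  counts <- matrix(0L, nrow = n_el, ncol = nrow(combos),
                   dimnames = list(S4Vectors::mcols(elements)$element_id, key))
  n_samples <- stats::setNames(integer(nrow(combos)), key)
  for (ps in marksets) {
    k <- paste(ps$assay, ps$group, sep = ".")
    if (!k %in% key) next
    counts[, k] <- counts[, k] +
      as.integer(GenomicRanges::countOverlaps(elements, ps$peaks,
                                              ignore.strand = TRUE) > 0L)
    n_samples[k] <- n_samples[k] + 1L
  }
  fractions <- sweep(counts, 2, pmax(n_samples, 1L), "/")
  missing <- key[n_samples == 0L]
  fractions[, missing] <- NA_real_
  fam <- S4Vectors::mcols(elements)$family
  family_means <- if (!is.null(fam))
    apply(fractions, 2, function(col) tapply(col, fam, mean)) else NULL
  if (!is.null(family_means) && length(unique(fam)) == 1L) {
    family_means <- matrix(family_means, nrow = 1L,
                           dimnames = list(unique(fam), key))
  }
  structure(
    list(fractions = fractions, counts = counts, n_samples = n_samples,
         family = fam, family_means = family_means,
         missing_combinations = missing),
    class = "state_features"
  )
}

#' K-means clustering of element mark profiles
#'
#' Standard k-means (Euclidean, random restarts keeping the best inertia) on
#' the mark-fraction matrix, with cluster labels renumbered by descending
#' cluster mean of the AML H3K27ac fraction so that numbering is stable across
#' seeds and element orderings.
#'
#' @param features A `state_features` object or a numeric matrix.
#' @param k Number of clusters (>= 2). The paper-scale analyses use small k;
#'   default 6.
#' @param seed Integer seed.
#' @param nstart Random restarts (default 10).
#' @return Integer cluster labels (1..k) named by element; attribute
#'   `centers` carries the renumbered cluster centres, `tot_withinss` the
#'   inertia.
#' @export
cluster_elements <- function(features, k = 6, seed = NULL, nstart = 10) {
  m <- if (inherits(features, "state_features")) features$fractions else features
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(m)) stop("k exceeds the number of elements")
  if (!is.null(seed)) set.seed(as.integer(seed))
  km <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100)
  ord_col <- grep("H3K27ac.AML", colnames(m), fixed = TRUE)
  score <- if (length(ord_col) == 1L) km$centers[, ord_col] else rowMeans(km$centers)
  relabel <- match(seq_len(k), order(score, decreasing = TRUE))
  labels <- relabel[km$cluster]
  names(labels) <- rownames(m)
  attr(labels, "centers") <- km$centers[order(score, decreasing = TRUE), ,
                                        drop = FALSE]
  attr(labels, "tot_withinss") <- km$tot.withinss
  labels
}

#' Within-sum-of-squares elbow report for choosing k
#'
#' @param features As in [cluster_elements].
#' @param k_range Candidate k values.
#' @param seed,nstart Passed to [stats::kmeans].
#' @return data.frame of `k` and `tot_withinss`.
#' @export
cluster_elbow <- function(features, k_range = 2:10, seed = NULL, nstart = 10) {
  m <- if (inherits(features, "state_features")) features$fractions else features
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  if (!is.null(seed)) set.seed(as.integer(seed))
  tws <- vapply(k_range, function(k)
    stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100)$tot.withinss,
    numeric(1))
  data.frame(k = k_range, tot_withinss = tws)
}

#' Chromatin-state call from AML mark indicators
#'
#' An element counts as "marked" by a histone modification when its AML
#' overlap fraction reaches `min_frac` (by default two samples' worth). The
#' rule table gives H3K4me3 precedence (promoter-like chromatin, since H3K4me1
#' enhancer signatures rarely co-occur with H3K4me3), then active enhancer
#' (H3K4me1 with H3K27ac), primed enhancer (H3K4me1 alone), heterochromatic
#' (H3K9me3), else unmarked.
#'
#' @param features A `state_features` object.
#' @param min_frac Marked-indicator threshold on the AML fraction; default
#'   `2 / n_AML_samples`.
#' @return Character vector of states per element, levels `promoter_like`,
#'   `active_enhancer`, `primed_enhancer`, `heterochromatic`, `unmarked`.
#' @export
classify_state <- function(features, min_frac = NULL) {
  stopifnot(inherits(features, "state_features"))
  f <- features$fractions
  aml_cols <- paste0(c("H3K27ac", "H3K4me1", "H3K4me3", "H3K9me3"), ".AML")
  if (any(!aml_cols %in% colnames(f)) || anyNA(f[, aml_cols]))
    stop("AML fractions must be defined for all four marks")
  if (is.null(min_frac)) {
    n_aml <- features$n_samples[paste0("H3K27ac", ".AML")]
    min_frac <- 2 / max(n_aml, 1L)
  }
  marked <- f[, aml_cols, drop = FALSE] >= min_frac
  colnames(marked) <- c("K27ac", "K4me1", "K4me3", "K9me3")
  state <- ifelse(marked[, "K4me3"], "promoter_like",
           ifelse(marked[, "K4me1"] & marked[, "K27ac"], "active_enhancer",
           ifelse(marked[, "K4me1"], "primed_enhancer",
           ifelse(marked[, "K9me3"], "heterochromatic", "unmarked"))))
  stats::setNames(state, rownames(f))
}

#' Count elements marked in at least `min_samples` AML samples
#'
#' @param features A `state_features` object.
#' @param mark One of the profiled marks, or a character vector of two marks
#'   for the pairwise-intersection count.
#' @param min_samples Minimum number of AML samples with overlap (default 2).
#' @return Integer count of elements meeting the threshold for the mark (or
#'   for both marks when two are given).
#' @export
count_marked_elements <- function(features, mark, min_samples = 2) {
  stopifnot(inherits(features, "state_features"))
  cols <- paste0(mark, ".AML")
  bad <- !cols %in% colnames(features$counts)
  if (any(bad)) stop("unknown mark: ", paste(mark[bad], collapse = ", "))
  ok <- features$counts[, cols, drop = FALSE] >= min_samples
  sum(rowSums(ok) == length(cols))
}
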