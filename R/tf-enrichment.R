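#' TF ChIP-seq peak enrichment at repeat families vs shuffled elements
#'
#' For each family, counts elements bound by at least one TF peak, then
#' repeats the count on a single seeded length-preserving shuffle of the
#' family's elements ([shuffle_intervals]) as the control. The 2x2 table
#' (bound/unbound x real/shuffled) gives a two-sided Fisher exact p; the
#' enrichment value is the ratio of bound fractions (real over shuffled, with
#' a small guard when no shuffled element is bound).
#'
#' @param tf_peaks A [PeakSet] whose assay names the TF (e.g. `"TF:SPI1"`).
#' @param elements Repeat annotation `GRanges`.
#' @param genome A [GenomeLayout] for the element shuffle.
#' @param seed Integer seed for the control shuffle.
#' @param n_shuffles Number of shuffled controls; the default single shuffle
#'   matches the published design, larger values average the control count.
#' @return data.frame with one row per family: `tf, family, n_elements,
#'   n_bound, frac_bound, n_bound_shuffled, frac_bound_shuffled, enrichment,
#'   odds_ratio, p` (no multiplicity adjustment here; see
#'   [aggregate_tf_enrichment]).
#' @export
tf_family_enrichment <- function(tf_peaks, elements, genome, seed = NULL,
                                 n_shuffles = 1) {
  stopifnot(inherits(tf_peaks, "PeakSet"))
  fam <- S4Vectors::mcols(elements)$family
  families <- sort(unique(fam))
  if (length(families) == 0L) stop("no families in the annotation")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- lapply(families, function(f) {
    el <- elements[fam == f]
    n <- length(el)
    if (n == 0L) stop("family with 0 elements: ", f)
    bound <- sum(GenomicRanges::countOverlaps(el, tf_peaks$peaks,
                                              ignore.strand = TRUE) > 0L)
    shuf_bound <- vapply(seq_len(n_shuffles), function(b) {
      sh <- shuffle_intervals(el, genome, seed = NULL)
      sum(GenomicRanges::countOverlaps(sh, tf_peaks$peaks,
                                       ignore.strand = TRUE) > 0L)
    }, numeric(1))
    ctrl <- round(mean(shuf_bound))
    tab <- matrix(c(bound, n - bound, ctrl, n - ctrl), nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    # continuity-corrected sample odds ratio (finite for degenerate tables)
    or_cc <- ((bound + 0.5) * (n - ctrl + 0.5)) /
      ((n - bound + 0.5) * (ctrl + 0.5))
    eps <- 0.5 / n
    data.frame(
      tf = sub("^TF:", "", tf_peaks$assay),
      family = f, n_elements = n,
      n_bound = bound, frac_bound = bound / n,
      n_bound_shuffled = ctrl, frac_bound_shuffled = ctrl / n,
      enrichment = (bound / n) / max(ctrl / n, eps),
      odds_ratio = or_cc, p = ft$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate TF enrichment over replicates and select TFs
#'
#' Combines per-replicate [tf_family_enrichment] tables: per (TF, family),
#' enrichment values are averaged across technical/biological replicates and
#' the replicate p-values combined by their median; BH adjustment is applied
#' across the whole TF-by-family grid. A TF is selected for a family when the
#' adjusted p is below `alpha` and it binds at least `min_frac` of the
#' family's elements.
#'
#' @param results List of data.frames from [tf_family_enrichment] (replicates
#'   of the same TF share the `tf` value).
#' @param min_frac Minimum bound fraction (default 0.05).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return data.frame `tf, family, n_replicates, n_bound, frac_bound,
#'   enrichment, odds_ratio, p, q, selected`, plus the vector of selected TFs
#'   in attribute `selected_tfs`.
#' @export
aggregate_tf_enrichment <- function(results, min_frac = 0.05, alpha = 0.05) {
  combined <- do.call(rbind, results)
  sp <- split(combined, paste(combined$tf, combined$family, sep = "\r"))
  rows <- lapply(sp, function(d) data.frame(
    tf = d$tf[1], family = d$family[1], n_replicates = nrow(d),
    n_bound = mean(d$n_bound), frac_bound = mean(d$frac_bound),
    enrichment = mean(d$enrichment), odds_ratio = mean(d$odds_ratio),
    p = stats::median(d$p), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$selected <- out$q < alpha & out$frac_bound >= min_frac
  out <- out[order(out$tf, out$family), ]
  rownames(out) <- NULL
  attr(out, "selected_tfs") <- sort(unique(out$tf[out$selected]))
  out
}
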