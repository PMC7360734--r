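#' Two-tailed add-one empirical p-value
#'
#' Counts null statistics at least as extreme as the observation in either
#' tail, with the add-one correction so that p is never zero:
#' `p = min(1, 2 * min((1 + #{null >= obs}) / (N + 1),
#'                     (1 + #{null <= obs}) / (N + 1)))`.
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Non-empty numeric vector of null statistics.
#' @return Empirical p-value in `(0, 1]`.
#' @examples
#' empirical_p(10, rep(10, 999))   # 1
#' empirical_p(50, rep(10, 999))   # 0.002
#' @export
empirical_p <- function(observed, null_values) {
  if (length(null_values) == 0L) stop("null_values must be non-empty")
  n <- length(null_values)
  upper <- (1 + sum(null_values >= observed)) / (n + 1)
  lower <- (1 + sum(null_values <= observed)) / (n + 1)
  min(1, 2 * min(upper, lower))
}

#' Permutation test for repeat-family enrichment of one sample's peaks
#'
#' For each repeat family, counts the sample's peaks overlapping family
#' elements, then compares against a null built by re-placing the whole peak
#' set uniformly in mappable space `n_shuffles` times ([shuffle_intervals]).
#' One set of shuffles serves all families, so family counts share coherent
#' null realisations. Fold enrichment is observed over the null mean (with a
#' small guard when the null mean is zero), and the p-value is the two-tailed
#' add-one empirical p ([empirical_p]).
#'
#' A family passes the significance filters when `p < 0.05`, fold `> 2`, and
#' more than 20 distinct family copies are overlapped by peaks.
#'
#' @param dhs A [PeakSet] (typically DNase).
#' @param repeats Repeat annotation `GRanges` (see [RepeatAnnotation]).
#' @param genome A [GenomeLayout].
#' @param n_shuffles Number of random controls (default 1000).
#' @param seed Integer seed for the shuffle null.
#' @param p_max,fold_min,min_elements_hit The three pass filters.
#' @return A data.frame of class `enrichment_result`, one row per family with
#'   at least one element: `family, sample_id, observed, elements_hit,
#'   null_mean, null_sd, n_shuffles, fold, p_empirical, null_zero, passes`.
#' @export
family_dhs_enrichment <- function(dhs, repeats, genome, n_shuffles = 1000,
                                  seed = NULL, p_max = 0.05, fold_min = 2,
                                  min_elements_hit = 20) {
  stopifnot(inherits(dhs, "PeakSet"), n_shuffles >= 1)
  families <- sort(unique(S4Vectors::mcols(repeats)$family))
  obs <- family_overlap_table(dhs$peaks, repeats, families)
  if (!is.null(seed)) set.seed(as.integer(seed))
  # all shuffle realisations are placed in one batch (independent uniform
  # placements), so a single overlap pass yields the whole null matrix
  n_pk <- length(dhs$peaks)
  nf <- length(families)
  all_shuf <- shuffle_intervals(rep(GenomicRanges::granges(dhs$peaks),
                                    n_shuffles), genome)
  hits <- GenomicRanges::findOverlaps(all_shuf, repeats, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  fi <- match(S4Vectors::mcols(repeats)$family, families)[
    S4Vectors::subjectHits(hits)]
  pair <- unique((as.numeric(qh) - 1) * nf + fi)  # one per (peak, family)
  q_of_pair <- (pair - 1) %/% nf + 1
  f_of_pair <- (pair - 1) %% nf + 1
  b_of_pair <- (q_of_pair - 1) %/% max(n_pk, 1L) + 1
  null_counts <- matrix(
    tabulate((b_of_pair - 1) * nf + f_of_pair, nbins = n_shuffles * nf),
    nrow = n_shuffles, ncol = nf, byrow = TRUE,
    dimnames = list(NULL, families))
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2, stats::sd)
  eps <- 0.5 / n_shuffles
  fold <- obs$n_query_hit / pmax(null_mean, eps)
  p <- vapply(seq_along(families), function(j)
    empirical_p(obs$n_query_hit[j], null_counts[, j]), numeric(1))
  res <- data.frame(
    family = families,
    sample_id = dhs$sample_id,
    observed = obs$n_query_hit,
    elements_hit = obs$n_elements_hit,
    null_mean = null_mean,
    null_sd = null_sd,
    n_shuffles = n_shuffles,
    fold = fold,
    p_empirical = p,
    null_zero = null_mean == 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$passes <- res$p_empirical < p_max & res$fold > fold_min &
    res$elements_hit > min_elements_hit
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Select repeat families enriched across a sample cohort
#'
#' A family is selected when it passes the per-sample enrichment filters in at
#' least one cell-line sample and in strictly more than `min_aml_frac` of the
#' AML samples.
#'
#' @param results Either a named list of [family_dhs_enrichment] tables (names
#'   are sample ids) or a single combined data.frame with a `sample_id`
#'   column.
#' @param groups Named character vector mapping every sample id to its group
#'   (`"AML"`, `"cell_line"`, `"differentiated"`, `"CD34"`).
#' @param min_aml_frac Fraction of AML samples that must pass (strict `>`;
#'   default 0.10).
#' @return A list of class `family_selection`: `selected` (character vector),
#'   `pass_matrix` (families x samples logical), `n_aml`, `aml_pass_frac`,
#'   `cell_line_pass`.
#' @export
select_families <- function(results, groups, min_aml_frac = 0.10) {
  if (is.data.frame(results)) {
    combined <- results
  } else {
    combined <- do.call(rbind, lapply(results, as.data.frame))
  }
  samples <- unique(combined$sample_id)
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0L)
    stop("sample(s) absent from groups: ", paste(missing, collapse = ", "))
  if (!any(groups[samples] == "cell_line") || !any(groups[samples] == "AML"))
    stop("need at least one cell_line and one AML sample")
  families <- sort(unique(combined$family))
  pass <- matrix(FALSE, nrow = length(families), ncol = length(samples),
                 dimnames = list(families, samples))
  pass[cbind(match(combined$family, families),
             match(combined$sample_id, samples))] <- combined$passes
  aml <- samples[groups[samples] == "AML"]
  cl <- samples[groups[samples] == "cell_line"]
  aml_frac <- rowMeans(pass[, aml, drop = FALSE])
  cl_pass <- rowSums(pass[, cl, drop = FALSE]) >= 1L
  selected <- families[cl_pass & aml_frac > min_aml_frac]
  structure(
    list(selected = selected, pass_matrix = pass, n_aml = length(aml),
         aml_pass_frac = aml_frac, cell_line_pass = cl_pass),
    class = "family_selection"
  )
}

#' @export
print.family_selection <- function(x, ...) {
  cat("family_selection:", length(x$selected), "of", nrow(x$pass_matrix),
      "families selected\n")
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
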