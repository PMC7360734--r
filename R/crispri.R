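#' Classify dCas9 peaks as on-target family hits or off-target
#'
#' Assigns each peak exactly one class by walking the target-family
#' precedence list: the first listed family whose elements the peak overlaps
#' wins; peaks overlapping none are off-target. Class counts always partition
#' the peak set.
#'
#' @param peaks A [PeakSet] (dCas9 ChIP-seq) or a plain `GRanges`.
#' @param repeats Repeat annotation `GRanges`.
#' @param target_families Ordered character vector of on-target families,
#'   highest precedence first (e.g. `c("LTR2B", "LTR2")`).
#' @return List of class `dcas9_classification`: `class` (character per
#'   peak), `counts` (named vector over `c(target_families, "off_target")`),
#'   `peaks` (the `GRanges`).
#' @export
classify_dcas9_peaks <- function(peaks, repeats, target_families) {
  if (length(target_families) == 0L) stop("target_families must be non-empty")
  gr <- if (inherits(peaks, "PeakSet")) peaks$peaks else peaks
  fam <- S4Vectors::mcols(repeats)$family
  cls <- rep("off_target", length(gr))
  for (f in rev(target_families)) {
    hit <- GenomicRanges::countOverlaps(gr, repeats[fam == f],
                                        ignore.strand = TRUE) > 0L
    cls[hit] <- f  # earlier families overwrite later ones (reversed loop)
  }
  counts <- stats::setNames(
    vapply(c(target_families, "off_target"), function(f) sum(cls == f),
           integer(1)),
    c(target_families, "off_target"))
  stopifnot(sum(counts) == length(gr))
  structure(list(class = cls, counts = counts, peaks = gr),
            class = "dcas9_classification")
}

#' @export
print.dcas9_classification <- function(x, ...) {
  cat("dCas9 peak classification (", length(x$peaks), " peaks):\n", sep = "")
  for (f in names(x$counts)) cat(sprintf("  %-12s %d\n", f, x$counts[f]))
  invisible(x)
}

# total coverage (sum of per-base values) of a bedGraph-style track over a
# window; track is a GRanges with a numeric score column
window_signal <- function(track, window) {
  ov <- GenomicRanges::findOverlaps(window, track, ignore.strand = TRUE)
  if (length(ov) == 0L) return(0)
  t_hit <- track[S4Vectors::subjectHits(ov)]
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    rep(window, length(t_hit)), t_hit))
  sum(S4Vectors::mcols(t_hit)$score * w)
}

#' Log2 signal ratio at peaks between two coverage tracks
#'
#' For each peak, sums per-base coverage of the sgRNA-condition and control
#' tracks over a window of `±halfwidth` bp around the peak centre (centre =
#' integer midpoint; window truncated and flagged at chromosome ends) and
#' reports `log2((signal_sg + pseudocount) / (signal_ctrl + pseudocount))`.
#' Tracks are assumed normalized (e.g. per-million) upstream.
#'
#' @param cov_sg,cov_ctrl Coverage tracks as `GRanges` with a `score` column
#'   (bedGraph via [rtracklayer::import] works directly).
#' @param peaks `GRanges` of dCas9 peaks (or a [PeakSet]).
#' @param genome Optional [GenomeLayout] used to truncate windows at
#'   chromosome ends.
#' @param halfwidth Window half-width in bp (default 500, i.e. 1 kb windows).
#' @param pseudocount Added to both signals (default 1).
#' @return data.frame `chrom, start, end, signal_sg, signal_ctrl, log2_ratio,
#'   truncated`.
#' @export
signal_log2_ratio <- function(cov_sg, cov_ctrl, peaks, genome = NULL,
                              halfwidth = 500, pseudocount = 1.0) {
  gr <- if (inherits(peaks, "PeakSet")) peaks$peaks else peaks
  # 0-based centre = floor((start0 + end0) / 2); window [centre-h, centre+h)
  centre0 <- floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
  wstart <- centre0 - halfwidth + 1
  wend <- centre0 + halfwidth
  truncated <- wstart < 1
  wstart <- pmax(wstart, 1)
  if (!is.null(genome)) {
    lim <- genome$chroms[as.character(GenomicRanges::seqnames(gr))]
    truncated <- truncated | wend > lim
    wend <- pmin(wend, lim)
  }
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = wstart, end = wend))
  sg <- vapply(seq_along(win), function(i) window_signal(cov_sg, win[i]),
               numeric(1))
  ctrl <- vapply(seq_along(win), function(i) window_signal(cov_ctrl, win[i]),
                 numeric(1))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    signal_sg = sg, signal_ctrl = ctrl,
    log2_ratio = log2((sg + pseudocount) / (ctrl + pseudocount)),
    truncated = truncated, stringsAsFactors = FALSE
  )
}

#' Genes proximal to dCas9 peaks: putative direct CRISPRi targets
#'
#' @param peaks `GRanges` of dCas9 peaks (or a [PeakSet]); a
#'   `dcas9_classification` may be given to annotate the nearest peak class.
#' @param genes `GRanges` of gene spans with `gene_id`.
#' @param max_dist Maximum gene-to-peak distance in bp (default 50000).
#' @param de_table Optional data.frame with columns `gene_id, log2FC, padj`
#'   joined onto the result.
#' @return data.frame `gene_id, distance, nearest_peak_class` (plus DE
#'   columns when supplied), one row per gene within range.
#' @export
proximal_genes <- function(peaks, genes, max_dist = 50000, de_table = NULL) {
  cls <- NULL
  if (inherits(peaks, "dcas9_classification")) {
    cls <- peaks$class
    peaks <- peaks$peaks
  } else if (inherits(peaks, "PeakSet")) peaks <- peaks$peaks
  ov <- GenomicRanges::findOverlaps(genes, peaks, maxgap = max_dist,
                                    ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  d <- as.numeric(GenomicRanges::distance(genes[qh], peaks[sh],
                                          ignore.strand = TRUE))
  keep <- d <= max_dist
  qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
  if (length(qh) == 0L)
    return(data.frame(gene_id = character(0), distance = numeric(0),
                      nearest_peak_class = character(0)))
  ord <- order(qh, d)
  first <- !duplicated(qh[ord])
  out <- data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id[qh[ord][first]],
    distance = d[ord][first],
    nearest_peak_class = if (is.null(cls)) NA_character_
                         else cls[sh[ord][first]],
    stringsAsFactors = FALSE
  )
  if (!is.null(de_table))
    out <- merge(out, de_table, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Predict multi-copy sgRNA targets across a repeat family's sequences
#'
#' An element is recognised when any guide's protospacer matches either
#' strand of the element sequence with at most `max_mismatches` mismatches
#' (Hamming distance; IUPAC ambiguity codes never match, so they count as
#' mismatches). An optional PAM pattern (e.g. `"NGG"`) can be required
#' immediately 3' of the protospacer match; dCas9-KRAB binding studies
#' usually omit it, so it is off by default.
#'
#' @param guides Character vector of protospacer sequences (typically 20 nt).
#' @param element_seqs Named `Biostrings::DNAStringSet` (or character vector)
#'   of element sequences, names = element ids.
#' @param families Named character vector mapping element ids to families.
#' @param max_mismatches Maximum Hamming mismatches (default 2).
#' @param pam Optional PAM pattern required 3' of the match (IUPAC, e.g.
#'   `"NGG"`); `NULL` disables the check.
#' @return List of class `guide_targets`: `per_family` (data.frame `family,
#'   n_elements, n_recognised, fraction`), `recognised` (named logical per
#'   element), `n_skipped` (elements shorter than the protospacer).
#' @export
predict_guide_targets <- function(guides, element_seqs, families,
                                  max_mismatches = 2, pam = NULL) {
  seqs <- Biostrings::DNAStringSet(element_seqs)
  ids <- names(seqs)
  if (is.null(ids) || !all(ids %in% names(families)))
    stop("element sequences must be named by ids present in families")
  glen <- nchar(guides)
  too_short <- Biostrings::width(seqs) < min(glen)
  n_skipped <- sum(too_short)
  recog <- stats::setNames(rep(FALSE, length(seqs)), ids)
  use <- which(!too_short)
  for (g in guides) {
    pat <- Biostrings::DNAString(g)
    pats <- list(`+` = pat, `-` = Biostrings::reverseComplement(pat))
    for (strand in names(pats)) {
      if (is.null(pam)) {
        cnt <- Biostrings::vcountPattern(pats[[strand]], seqs[use],
                                         max.mismatch = max_mismatches,
                                         fixed = TRUE)
        recog[use][cnt > 0L] <- TRUE
      } else {
        # PAM sits 3' of the protospacer: right of a + match, left
        # (reverse-complemented) of a - match
        for (i in use) {
          if (recog[i]) next
          m <- Biostrings::matchPattern(pats[[strand]], seqs[[i]],
                                        max.mismatch = max_mismatches,
                                        fixed = TRUE)
          if (length(m) == 0L) next
          ok <- vapply(seq_along(m), function(k) {
            if (strand == "+") {
              s0 <- IRanges::end(m)[k] + 1L
              e0 <- s0 + nchar(pam) - 1L
              if (e0 > length(seqs[[i]])) return(FALSE)
              ctx <- seqs[[i]][s0:e0]
            } else {
              e0 <- IRanges::start(m)[k] - 1L
              s0 <- e0 - nchar(pam) + 1L
              if (s0 < 1L) return(FALSE)
              ctx <- Biostrings::reverseComplement(seqs[[i]][s0:e0])
            }
            Biostrings::countPattern(pam, ctx, fixed = FALSE) > 0L
          }, logical(1))
          if (any(ok)) recog[i] <- TRUE
        }
      }
    }
  }
  fam <- families[ids]
  tab_n <- table(fam)
  tab_r <- tapply(recog, fam, sum)
  per_family <- data.frame(
    family = names(tab_n),
    n_elements = as.integer(tab_n),
    n_recognised = as.integer(tab_r[names(tab_n)]),
    fraction = as.numeric(tab_r[names(tab_n)] / tab_n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(per_family = per_family, recognised = recog,
                 n_skipped = n_skipped),
            class = "guide_targets")
}

#' @export
print.guide_targets <- function(x, ...) {
  cat("guide_targets:\n")
  print(x$per_family, row.names = FALSE)
  invisible(x)
}
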