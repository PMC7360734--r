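#' Read transcript models from a GTF file
#'
#' Reads exon features from a StringTie-style GTF via
#' [rtracklayer::import] and returns one row per exon with its transcript id.
#'
#' @param path GTF path.
#' @param sample_id Optional sample id attached to every transcript.
#' @return data.frame with columns `transcript_id, sample_id, chrom, start,
#'   end, strand` (1-based closed coordinates), exons sorted within
#'   transcript.
#' @export
read_transcripts_gtf <- function(path, sample_id = NA_character_) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  df <- data.frame(
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df[order(df$transcript_id, df$start), ]
}

# split an exon table into per-transcript metadata, validating strand
transcript_table <- function(exons) {
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(exons))) stop("exon table lacks required columns")
  if (any(!exons$strand %in% c("+", "-")))
    stop("unstranded transcript(s): strand must be + or -")
  exons
}

#' Transcription start sites of transcript models
#'
#' The TSS of a plus-strand transcript is the first base of its first exon;
#' for a minus-strand transcript, the last base of its last exon.
#'
#' @param exons Exon data.frame (`transcript_id, chrom, start, end, strand`,
#'   1-based closed; optional `sample_id`).
#' @param multi_exon_only Keep only transcripts with >= 2 exons (the spliced
#'   transcripts used for promoter discovery). Default `TRUE`.
#' @return data.frame with one row per transcript: `transcript_id, sample_id,
#'   chrom, tss` (1-based position of the start base), `strand, n_exons`.
#' @export
transcript_tss <- function(exons, multi_exon_only = TRUE) {
  exons <- transcript_table(exons)
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  rows <- lapply(sp, function(idx) {
    e <- exons[idx, ]
    e <- e[order(e$start), ]
    tss <- if (e$strand[1] == "+") e$start[1] else e$end[nrow(e)]
    data.frame(
      transcript_id = e$transcript_id[1],
      sample_id = if ("sample_id" %in% names(e)) e$sample_id[1] else NA_character_,
      chrom = e$chrom[1], tss = tss, strand = e$strand[1],
      n_exons = nrow(e), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (multi_exon_only) out <- out[out$n_exons >= 2L, ]
  out
}

#' Element hits of transcript start sites
#'
#' A TSS hits an element when it falls within the element interval
#' (half-open: the element start base counts, the base just past the end does
#' not). Returns per-sample hit counts and the element-level hit table used
#' for promoter selection.
#'
#' @param tss data.frame from [transcript_tss] (needs `sample_id`).
#' @param elements Repeat annotation `GRanges` with `element_id`.
#' @return List: `per_sample` (data.frame `sample_id, n_transcripts` counting
#'   distinct transcripts with TSS in any element), `hits` (data.frame
#'   `transcript_id, sample_id, element_id, family, strand`).
#' @export
element_tss_hits <- function(tss, elements) {
  pts <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$tss, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(pts, elements, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  hits <- data.frame(
    transcript_id = tss$transcript_id[qh],
    sample_id = tss$sample_id[qh],
    element_id = S4Vectors::mcols(elements)$element_id[sh],
    family = S4Vectors::mcols(elements)$family[sh],
    strand = tss$strand[qh],
    stringsAsFactors = FALSE
  )
  all_samples <- unique(tss$sample_id)
  uh <- unique(hits[, c("sample_id", "transcript_id")])
  n_tx <- vapply(all_samples, function(s) sum(uh$sample_id == s), integer(1))
  n_tx <- unname(n_tx)
  per_sample <- data.frame(sample_id = all_samples, n_transcripts = n_tx,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(per_sample = per_sample, hits = hits)
}

#' Select elements acting as AML-specific promoters
#'
#' An element (together with a transcript strand) is called an AML-specific
#' promoter when spliced transcripts start inside it in at least `min_aml`
#' AML samples and in no differentiated sample. Cross-sample transcript
#' identity is taken at the element level: transcripts from different samples
#' match when they start in the same element on the same strand.
#'
#' @param hits Hit table from [element_tss_hits].
#' @param groups Named character vector mapping sample ids to groups.
#' @param min_aml Minimum number of AML samples with a TSS (default 2).
#' @return data.frame with one row per (element, strand):
#'   `element_id, family, strand, n_aml, n_diff, aml_samples, selected`.
#' @export
aml_specific_promoters <- function(hits, groups, min_aml = 2) {
  missing <- setdiff(unique(hits$sample_id), names(groups))
  if (length(missing))
    stop("sample(s) absent from groups: ", paste(missing, collapse = ", "))
  hits$group <- groups[hits$sample_id]
  keyed <- unique(hits[, c("element_id", "family", "strand", "sample_id", "group")])
  sp <- split(keyed, paste(keyed$element_id, keyed$strand))
  rows <- lapply(sp, function(h) {
    aml <- unique(h$sample_id[h$group == "AML"])
    dif <- unique(h$sample_id[h$group == "differentiated"])
    data.frame(
      element_id = h$element_id[1], family = h$family[1], strand = h$strand[1],
      n_aml = length(aml), n_diff = length(dif),
      aml_samples = paste(sort(aml), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$selected <- out$n_aml >= min_aml & out$n_diff == 0L
  out[order(out$element_id, out$strand), ]
}

#' Does a spliced transcript splice into an annotated gene?
#'
#' `TRUE` when any exon after the first in transcription order overlaps an
#' annotated gene exon on the same strand.
#'
#' @param exons Exon data.frame for one transcript (>= 2 exons).
#' @param gene_exons `GRanges` of annotated gene exons (stranded).
#' @return Logical scalar.
#' @export
splices_into_annotated_gene <- function(exons, gene_exons) {
  exons <- transcript_table(exons)
  if (length(unique(exons$transcript_id)) != 1L)
    stop("expected exons of a single transcript")
  if (nrow(exons) < 2L) stop("transcript must be multi-exon")
  e <- exons[order(exons$start), ]
  downstream <- if (e$strand[1] == "+") e[-1L, ] else e[-nrow(e), ]
  gr <- GenomicRanges::GRanges(
    seqnames = downstream$chrom,
    ranges = IRanges::IRanges(start = downstream$start, end = downstream$end),
    strand = downstream$strand
  )
  ge <- gene_exons[as.character(GenomicRanges::strand(gene_exons)) ==
                     e$strand[1]]
  length(GenomicRanges::findOverlaps(gr, ge, ignore.strand = TRUE)) > 0L
}
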