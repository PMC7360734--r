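#' Genome layout: chromosome sizes plus excluded regions
#'
#' A `GenomeLayout` defines the space over which intervals live and, crucially,
#' the space over which the permutation null shuffles them: all chromosome
#' positions not covered by an excluded (unmappable) region. Excluded regions
#' are merged, sorted and clipped to chromosome bounds on construction, and the
#' complementary mappable gaps are precomputed.
#'
#' @param chroms Named numeric vector of chromosome lengths in bp (all > 0),
#'   or a two-column data.frame (name, length) as read from a chrom.sizes file.
#' @param excluded A [GenomicRanges::GRanges] of regions to exclude from the
#'   shuffle space (e.g. unmappable regions), or `NULL` for none.
#' @return An object of class `GenomeLayout` with components `chroms` (named
#'   integer-valued vector), `excluded` (merged `GRanges`) and `mappable`
#'   (`GRanges` of the allowed gaps).
#' @examples
#' gl <- GenomeLayout(c(chr1 = 1e6, chr2 = 5e5))
#' sum(GenomicRanges::width(gl$mappable))
#' @export
GenomeLayout <- function(chroms, excluded = NULL) {
  if (is.data.frame(chroms)) {
    chroms <- stats::setNames(as.numeric(chroms[[2]]), as.character(chroms[[1]]))
  }
  if (is.null(names(chroms)) || any(names(chroms) == "") || anyDuplicated(names(chroms)))
    stop("chromosome lengths must carry unique non-empty names")
  if (any(!is.finite(chroms)) || any(chroms <= 0))
    stop("all chromosome lengths must be positive")
  chroms <- round(chroms)
  si <- GenomeInfoDb::Seqinfo(seqnames = names(chroms), seqlengths = chroms)
  genome_gr <- GenomicRanges::GRanges(
    seqnames = names(chroms),
    ranges = IRanges::IRanges(start = 1L, end = as.integer(chroms)),
    seqinfo = si
  )
  if (is.null(excluded)) {
    excl <- GenomicRanges::GRanges(seqinfo = si)
  } else {
    if (!methods::is(excluded, "GRanges")) stop("excluded must be a GRanges or NULL")
    bad <- !as.character(GenomicRanges::seqnames(excluded)) %in% names(chroms)
    if (any(bad))
      stop("excluded region on unknown chromosome: ",
           paste(unique(as.character(GenomicRanges::seqnames(excluded))[bad]), collapse = ", "))
    over_end <- GenomicRanges::end(excluded) >
      chroms[as.character(GenomicRanges::seqnames(excluded))]
    if (any(over_end))
      stop("excluded interval extends beyond its chromosome")
    excl <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(excluded)),
      ranges = IRanges::ranges(excluded), seqinfo = si
    )
    excl <- GenomicRanges::reduce(GenomicRanges::sort(excl))
  }
  mappable <- GenomicRanges::setdiff(genome_gr, excl)
  structure(
    list(chroms = chroms, excluded = excl, mappable = mappable),
    class = "GenomeLayout"
  )
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chroms), "chromosome(s),",
      format(sum(x$chroms), big.mark = ","), "bp;",
      length(x$excluded), "excluded region(s) covering",
      format(sum(GenomicRanges::width(x$excluded)), big.mark = ","), "bp\n")
  invisible(x)
}

is_genome_layout <- function(x) inherits(x, "GenomeLayout")

#' Check that intervals fall within chromosome bounds of a layout
#'
#' @param gr A `GRanges`.
#' @param genome A [GenomeLayout].
#' @param what Label used in error messages.
#' @return Invisibly `gr`; errors if any interval is out of bounds or on an
#'   unknown chromosome.
#' @export
validate_intervals <- function(gr, genome, what = "interval") {
  chr <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !chr %in% names(genome$chroms)
  if (any(unknown))
    stop(what, " on chromosome absent from genome layout: ",
         paste(unique(chr[unknown]), collapse = ", "))
  if (any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > genome$chroms[chr]))
    stop(what, " outside chromosome bounds")
  invisible(gr)
}

#' Peak set for one sample and assay
#'
#' Bundles one sample's peak calls with its assay and biological group, the
#' observational unit of all per-sample analyses.
#'
#' @param sample_id Sample identifier.
#' @param assay Assay label, e.g. `"DNase"`, `"H3K27ac"`, `"H3K4me1"`,
#'   `"H3K4me3"`, `"H3K9me3"`, `"TF:SPI1"`, `"dCas9"`.
#' @param group One of `"AML"`, `"cell_line"`, `"differentiated"`, `"CD34"`.
#' @param peaks `GRanges` of peak intervals; sorted on construction.
#' @param genome Optional [GenomeLayout] used to bounds-check the peaks.
#' @return An object of class `PeakSet`.
#' @export
PeakSet <- function(sample_id, assay, group, peaks, genome = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  group <- match.arg(group, c("AML", "cell_line", "differentiated", "CD34"))
  if (!methods::is(peaks, "GRanges")) stop("peaks must be a GRanges")
  if (!is.null(genome)) validate_intervals(peaks, genome, "peak")
  peaks <- GenomicRanges::sort(peaks, ignore.strand = TRUE)
  structure(
    list(sample_id = sample_id, assay = assay, group = group, peaks = peaks),
    class = "PeakSet"
  )
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet %s [%s, %s]: %d peak(s)\n",
              x$sample_id, x$assay, x$group, length(x$peaks)))
  invisible(x)
}

#' Repeat annotation constructor
#'
#' Validates a `GRanges` of repeat elements carrying `family` and `element_id`
#' metadata columns, the units of all enrichment and association analyses.
#'
#' @param gr `GRanges` with metadata columns `family` (non-empty labels) and
#'   `element_id` (unique keys). If `element_id` is missing, stable ids of the
#'   form `family_i` are assigned.
#' @return The validated `GRanges` (class unchanged).
#' @export
RepeatAnnotation <- function(gr) {
  if (!methods::is(gr, "GRanges")) stop("repeat annotation must be a GRanges")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$family) || any(is.na(mc$family)) || any(mc$family == ""))
    stop("every repeat element needs a non-empty family label")
  if (is.null(mc$element_id)) {
    S4Vectors::mcols(gr)$element_id <- paste0(mc$family, "_", seq_along(gr))
  }
  if (anyDuplicated(S4Vectors::mcols(gr)$element_id))
    stop("element_id values must be unique")
  gr
}
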