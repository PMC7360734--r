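#' Read genomic intervals from standard annotation formats
#'
#' Supports BED3/BED6 and narrowPeak (0-based half-open, passed through), the
#' BED-with-family dialect in which column 4 carries a repeat-family label, and
#' RepeatMasker `.out` tables (1-based inclusive coordinates, converted).
#' All coordinates are returned as `GRanges` (1-based closed), so a BED line
#' `start end` becomes `[start+1, end]`.
#'
#' @param path Path to the file.
#' @param format One of `"BED"`, `"narrowPeak"`, `"RepeatMaskerOut"`.
#' @param genome Optional [GenomeLayout]; if given, coordinates are
#'   bounds-checked and an out-of-bounds record is an error.
#' @param family If `TRUE` and `format = "BED"`, the name column is interpreted
#'   as a repeat-family label and a [RepeatAnnotation] is returned.
#' @return A `GRanges`; for `RepeatMaskerOut` or `family = TRUE`, a
#'   `GRanges` with `family` and `element_id` metadata columns.
#' @export
read_intervals <- function(path, format = c("BED", "narrowPeak", "RepeatMaskerOut"),
                           genome = NULL, family = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- switch(format,
    BED = read_bed_like(path, min_cols = 3L, family = family),
    narrowPeak = read_bed_like(path, min_cols = 10L, family = FALSE),
    RepeatMaskerOut = read_rmsk_out(path)
  )
  if (!is.null(genome)) validate_intervals(gr, genome, basename(path))
  gr
}

# BED / narrowPeak share a tab-separated 0-based half-open layout; parsed line
# by line so malformed records can be reported with their line number.
read_bed_like <- function(path, min_cols, family) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (family) gr <- RepeatAnnotation(gr)
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols))
    stop("malformed line ", idx[which(nf < min_cols)[1]], " in ", basename(path),
         ": expected >= ", min_cols, " tab-separated fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0
  if (any(bad))
    stop("malformed line ", idx[which(bad)[1]], " in ", basename(path),
         ": invalid coordinates")
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, character(1), 4L) else NULL
  score <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L))) else NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, character(1), 6L) else NULL
  if (!is.null(strand)) {
    oks <- strand %in% c("+", "-", ".")
    if (any(!oks))
      stop("malformed line ", idx[which(!oks)[1]], " in ", basename(path),
           ": invalid strand")
    strand[strand == "."] <- "*"
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = if (is.null(strand)) "*" else strand
  )
  if (family) {
    if (is.null(name)) stop("BED-with-family dialect requires a name column in ", basename(path))
    S4Vectors::mcols(gr)$family <- name
    gr <- RepeatAnnotation(gr)
  } else {
    if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
    if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  }
  gr
}

# RepeatMasker .out: whitespace-separated, three header lines, coordinates
# 1-based inclusive; column 5 = chromosome, 6/7 = begin/end, 9 = strand
# (+ or C), 10 = matching repeat, 11 = repeat class/family.
read_rmsk_out <- function(path) {
  lines <- readLines(path)
  body <- which(grepl("^\\s*[0-9]", lines))
  if (length(body) == 0L)
    return(RepeatAnnotation(GenomicRanges::GRanges(
      family = character(0), element_id = character(0))))
  fields <- strsplit(trimws(lines[body]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed line ", body[which(nf < 11L)[1]], " in ", basename(path),
         ": expected >= 11 whitespace-separated fields")
  chrom <- vapply(fields, `[[`, character(1), 5L)
  begin1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 6L)))
  end1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 7L)))
  bad <- is.na(begin1) | is.na(end1) | begin1 < 1 | end1 < begin1
  if (any(bad))
    stop("malformed line ", body[which(bad)[1]], " in ", basename(path),
         ": invalid coordinates")
  strand <- vapply(fields, `[[`, character(1), 9L)
  strand <- ifelse(strand == "C", "-", ifelse(strand == "+", "+", "*"))
  fam <- vapply(fields, `[[`, character(1), 10L)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = begin1, end = end1),
    strand = strand
  )
  S4Vectors::mcols(gr)$family <- fam
  RepeatAnnotation(gr)
}

#' Read a chrom.sizes file into a GenomeLayout
#'
#' @param path Two-column TSV of chromosome name and length.
#' @param excluded_bed Optional BED file of excluded regions.
#' @return A [GenomeLayout].
#' @export
read_genome_layout <- function(path, excluded_bed = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  excl <- if (is.null(excluded_bed)) NULL else read_intervals(excluded_bed, "BED")
  GenomeLayout(stats::setNames(tab$length, tab$chrom), excluded = excl)
}

#' Write intervals as BED6
#'
#' Emits 0-based half-open coordinates; missing names become `"."`, missing
#' scores `0`, unstranded intervals `"."`.
#'
#' @param gr `GRanges` to write. A `family` metadata column, when present,
#'   takes precedence over `name` for the BED name field.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_bed6 <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  name <- if (!is.null(mc$family)) as.character(mc$family)
          else if (!is.null(mc$name)) as.character(mc$name)
          else rep(".", length(gr))
  score <- if (!is.null(mc$score)) mc$score else rep(0, length(gr))
  score[is.na(score)] <- 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score, strand = strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
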