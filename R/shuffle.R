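#' Length-preserving random placement of intervals in mappable space
#'
#' The permutation-null engine. Each input interval is re-placed, keeping its
#' length, uniformly at random over every genome position where it fits
#' entirely inside a mappable gap (outside excluded regions and chromosome
#' ends). Placement is genome-wide by default: a chromosome is chosen with
#' probability proportional to its number of valid start positions for that
#' interval length, so the null is uniform over all valid placements.
#' Shuffled intervals are placed independently and may therefore overlap one
#' another, matching common shuffle semantics.
#'
#' @param intervals `GRanges` to shuffle; only the lengths are used.
#' @param genome A [GenomeLayout] defining the allowed space.
#' @param seed Integer seed; the same seed gives bit-identical output.
#'   `NULL` leaves the RNG state alone.
#' @param per_chromosome If `TRUE`, each interval is re-placed only within its
#'   chromosome of origin.
#' @return A `GRanges` with the same number of intervals and the same multiset
#'   of widths, strand and metadata dropped.
#' @export
shuffle_intervals <- function(intervals, genome, seed = NULL,
                              per_chromosome = FALSE) {
  stopifnot(is_genome_layout(genome))
  n <- length(intervals)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0L) return(GenomicRanges::GRanges())
  gaps_chr <- as.character(GenomicRanges::seqnames(genome$mappable))
  gaps_start <- GenomicRanges::start(genome$mappable)
  gaps_width <- GenomicRanges::width(genome$mappable)
  widths <- GenomicRanges::width(intervals)
  out_chr <- character(n)
  out_start <- numeric(n)

  place <- function(idx, gap_sel) {
    # capacities: number of valid start positions per gap for this length
    w <- widths[idx[1]]
    cap <- pmax(0, gaps_width[gap_sel] - w + 1)
    total <- sum(cap)
    if (total == 0)
      stop("interval of length ", w, " (index ", idx[1],
           ") does not fit in any allowed gap")
    cum <- cumsum(cap)
    u <- ceiling(stats::runif(length(idx)) * total)
    u[u < 1] <- 1
    g <- findInterval(u - 1, cum) + 1L
    offset <- u - c(0, cum)[g]  # 1-based offset within the gap
    out_chr[idx] <<- gaps_chr[gap_sel][g]
    out_start[idx] <<- gaps_start[gap_sel][g] + offset - 1
    invisible(NULL)
  }

  if (per_chromosome) {
    ichr <- as.character(GenomicRanges::seqnames(intervals))
    for (grp in split(seq_len(n), paste(ichr, widths))) {
      place(grp, which(gaps_chr == ichr[grp[1]]))
    }
  } else {
    all_gaps <- seq_along(gaps_chr)
    for (grp in split(seq_len(n), widths)) place(grp, all_gaps)
  }
  # restore input order (split() groups by width)
  GenomicRanges::GRanges(
    seqnames = out_chr,
    ranges = IRanges::IRanges(start = out_start, width = widths)
  )
}

#' Count query/subject overlaps for one repeat family
#'
#' @param query `GRanges` of query intervals (e.g. one sample's DHSs).
#' @param subject Repeat annotation `GRanges` with a `family` column.
#' @param family Family label to count against.
#' @return Named integer vector: `n_query_hit` (queries intersecting at least
#'   one family element by >= 1 bp) and `n_elements_hit` (distinct family
#'   elements intersected by at least one query). A query touching several
#'   elements is counted once.
#' @export
count_overlaps_family <- function(query, subject, family) {
  fam <- S4Vectors::mcols(subject)$family
  if (is.null(fam)) stop("subject lacks a family column")
  if (!family %in% fam) stop("unknown family label: ", family)
  el <- subject[fam == family]
  hits <- GenomicRanges::findOverlaps(query, el, minoverlap = 1L,
                                      ignore.strand = TRUE)
  c(n_query_hit = length(unique(S4Vectors::queryHits(hits))),
    n_elements_hit = length(unique(S4Vectors::subjectHits(hits))))
}

# Per-family counts of query intervals hitting each family, and of distinct
# elements hit, in one findOverlaps pass. Returns a data.frame over `families`.
family_overlap_table <- function(query, subject, families = NULL) {
  fam <- S4Vectors::mcols(subject)$family
  if (is.null(families)) families <- sort(unique(fam))
  hits <- GenomicRanges::findOverlaps(query, subject, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  hfam <- fam[sh]
  qcount <- tapply(qh, factor(hfam, levels = families),
                   function(v) length(unique(v)))
  ecount <- tapply(sh, factor(hfam, levels = families),
                   function(v) length(unique(v)))
  data.frame(
    family = families,
    n_query_hit = as.integer(ifelse(is.na(qcount), 0L, qcount)),
    n_elements_hit = as.integer(ifelse(is.na(ecount), 0L, ecount)),
    stringsAsFactors = FALSE
  )
}
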