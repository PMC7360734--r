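#' Read PWMs from a MEME-format motif file
#'
#' Parses the MEME minimal motif format (as distributed by HOCOMOCO and
#' produced by the MEME suite): a `MOTIF` line per motif followed by a
#' `letter-probability matrix` block, with an optional
#' `Background letter frequencies` line. Probabilities are per position over
#' A, C, G, T.
#'
#' @param path Path to the motif file.
#' @return Named list of PWM objects, each a list with `motif_id`, `matrix`
#'   (4 x L, rows A/C/G/T, columns summing to 1) and `background` (length-4
#'   probability vector).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) >= 1L) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[seq(2, length(toks), by = 2)]))
    nms <- toks[seq(1, length(toks), by = 2)]
    if (!anyNA(vals) && all(c("A", "C", "G", "T") %in% nms))
      bg <- vals[match(c("A", "C", "G", "T"), nms)]
    names(bg) <- c("A", "C", "G", "T")
  }
  motif_i <- grep("^MOTIF", lines)
  pwms <- list()
  for (mi in motif_i) {
    id <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    li <- mi + 1L
    while (li <= length(lines) && !grepl("^letter-probability matrix", lines[li]))
      li <- li + 1L
    if (li > length(lines))
      stop("motif ", id, ": no letter-probability matrix block")
    rows <- list()
    li <- li + 1L
    while (li <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[li])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[li]), "\\s+")[[1]])
      li <- li + 1L
    }
    if (length(rows) == 0L) stop("motif ", id, ": empty probability matrix")
    m <- t(do.call(rbind, rows))
    rownames(m) <- c("A", "C", "G", "T")
    if (any(abs(colSums(m) - 1) > 1e-6))
      stop("motif ", id, ": columns must sum to 1")
    pwms[[id]] <- structure(list(motif_id = id, matrix = m, background = bg),
                            class = "pwm")
  }
  pwms
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "of length", ncol(x$matrix), "\n")
  invisible(x)
}

# log2-odds score matrix with pseudo-probability smoothing of zero entries
pwm_score_matrix <- function(pwm, pseudo = 1e-4) {
  m <- pwm$matrix
  m[m <= 0] <- pseudo
  log2(m / pwm$background)
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of the sequence (and of its reverse complement) as the
#' sum over positions of `log2(p_motif(base) / p_background(base))`, with
#' zero probabilities smoothed to 1e-4 before the log. Windows containing a
#' non-ACGT base are skipped and counted. A window is a hit when its score
#' reaches `threshold`.
#'
#' @param seq A character string or `Biostrings::DNAString`.
#' @param pwm A PWM from [read_meme] or [pwm_from_consensus].
#' @param threshold Minimum log2-odds score for a hit (default 6).
#' @return data.frame of class `motif_hits`: `offset` (0-based from sequence
#'   start of the hit window's leftmost base in original coordinates),
#'   `strand`, `score`. Attribute `n_skipped` counts windows skipped for
#'   ambiguous bases.
#' @export
scan_pwm <- function(seq, pwm, threshold = 6) {
  s <- toupper(as.character(seq))
  L <- ncol(pwm$matrix)
  n <- nchar(s)
  if (n < L) stop("sequence shorter than the motif")
  sm <- pwm_score_matrix(pwm)
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  score_strand <- function(codes) {
    nw <- length(codes) - L + 1L
    sc <- numeric(nw)
    ok <- rep(TRUE, nw)
    for (j in seq_len(L)) {
      cj <- codes[j:(j + nw - 1L)]
      ok <- ok & !is.na(cj)
      contrib <- sm[cbind(cj, j)]
      contrib[is.na(contrib)] <- 0
      sc <- sc + contrib
    }
    list(score = sc, ok = ok)
  }
  fwd <- score_strand(code)
  # reverse complement: A<->T (1<->4), C<->G (2<->3)
  rc_code <- rev(5L - code)
  rev_ <- score_strand(rc_code)
  nw <- n - L + 1L
  mk <- function(off, strand, score) data.frame(
    offset = off, strand = rep(strand, length(off)), score = score,
    stringsAsFactors = FALSE)
  hits <- rbind(
    mk(which(fwd$ok & fwd$score >= threshold) - 1L, "+",
       fwd$score[fwd$ok & fwd$score >= threshold]),
    mk(nw - which(rev_$ok & rev_$score >= threshold), "-",
       rev_$score[rev_$ok & rev_$score >= threshold])
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_skipped") <- sum(!fwd$ok) + sum(!rev_$ok)
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' Build a degenerate PWM from a consensus string
#'
#' Probability 1 on the consensus base at each position (before smoothing);
#' convenient for planting and recovering motifs in synthetic sequences.
#'
#' @param consensus ACGT string.
#' @param motif_id Identifier.
#' @param background Background probabilities (default uniform).
#' @return A PWM object.
#' @export
pwm_from_consensus <- function(consensus, motif_id = consensus,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T"))) stop("consensus must be ACGT")
  m <- matrix(0, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- 1
  structure(list(motif_id = motif_id, matrix = m, background = background),
            class = "pwm")
}

#' Fraction of each family's elements bearing a motif
#'
#' @param hits_per_element Named list: per element, a `motif_hits` table (or
#'   anything whose `nrow` > 0 indicates at least one hit).
#' @param families Named character vector mapping element ids to family
#'   labels.
#' @return data.frame `family, n_elements, n_with_hit, fraction`.
#' @export
motif_family_frequency <- function(hits_per_element, families) {
  ids <- names(hits_per_element)
  if (is.null(ids) || !all(ids %in% names(families)))
    stop("hits must be named by element ids present in families")
  has_hit <- vapply(hits_per_element, function(h) NROW(h) > 0L, logical(1))
  fam <- families[ids]
  tab_n <- table(fam)
  tab_hit <- tapply(has_hit, fam, sum)
  data.frame(
    family = names(tab_n),
    n_elements = as.integer(tab_n),
    n_with_hit = as.integer(tab_hit[names(tab_n)]),
    fraction = as.numeric(tab_hit[names(tab_n)] / tab_n),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Map motif locations on family consensus sequences
#'
#' Runs [scan_pwm] for every (consensus, PWM) combination and collects hit
#' offsets, for locating TF motifs on family consensus sequences.
#'
#' @param consensus Named character vector (or `DNAStringSet`) of consensus
#'   sequences per family.
#' @param pwms List of PWMs.
#' @param threshold Log2-odds hit threshold (default 6).
#' @return data.frame `family, motif_id, offset, strand, score`.
#' @export
consensus_motif_map <- function(consensus, pwms, threshold = 6) {
  seqs <- stats::setNames(as.character(consensus), names(consensus))
  rows <- list()
  for (f in names(seqs)) {
    for (p in pwms) {
      h <- scan_pwm(seqs[[f]], p, threshold)
      if (nrow(h))
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, motif_id = p$motif_id, h, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(family = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif frequency contrast between open and closed elements
#'
#' Splits elements into DHS-positive (open in at least `min_pos_samples` AML
#' samples) and DHS-negative (open in none); elements in between are
#' excluded. For each motif, compares hit frequencies between the classes
#' with a two-sided Fisher exact test, BH-adjusted across motifs.
#'
#' @param hits_by_motif Named list: per motif, a named logical vector (or a
#'   list of `motif_hits`) over element ids indicating a hit.
#' @param dhs_matrix Binary element-by-sample matrix restricted to AML
#'   samples (or carrying a `groups` attribute; non-AML columns are dropped).
#' @param min_pos_samples DHS-positive threshold (default 5).
#' @param all_elements Optional character vector of all element ids scanned;
#'   defaults to the union of hit names and matrix rows. Elements absent from
#'   the matrix count as DHS-negative.
#' @return data.frame `motif_id, n_pos, n_neg, freq_pos, freq_neg,
#'   odds_ratio, p, q`.
#' @export
dhs_motif_contrast <- function(hits_by_motif, dhs_matrix, min_pos_samples = 5,
                               all_elements = NULL) {
  groups <- attr(dhs_matrix, "groups")
  if (!is.null(groups)) {
    aml <- intersect(colnames(dhs_matrix), names(groups)[groups == "AML"])
    dhs_matrix <- dhs_matrix[, aml, drop = FALSE]
  }
  counts <- rowSums(dhs_matrix)
  if (is.null(all_elements)) {
    all_elements <- unique(c(rownames(dhs_matrix),
                             unlist(lapply(hits_by_motif, names))))
  }
  n_dhs <- stats::setNames(rep(0, length(all_elements)), all_elements)
  n_dhs[intersect(all_elements, names(counts))] <-
    counts[intersect(all_elements, names(counts))]
  pos <- all_elements[n_dhs >= min_pos_samples]
  neg <- all_elements[n_dhs == 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both DHS-positive and DHS-negative classes must be non-empty")
  rows <- lapply(names(hits_by_motif), function(mid) {
    h <- hits_by_motif[[mid]]
    if (!is.logical(h)) h <- vapply(h, function(x) NROW(x) > 0L, logical(1))
    hp <- sum(h[pos], na.rm = TRUE); hn <- sum(h[neg], na.rm = TRUE)
    tab <- matrix(c(hp, length(pos) - hp, hn, length(neg) - hn), nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(motif_id = mid, n_pos = length(pos), n_neg = length(neg),
               freq_pos = hp / length(pos), freq_neg = hn / length(neg),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
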