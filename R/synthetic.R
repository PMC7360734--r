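#' Configuration for the synthetic epigenome generator
#'
#' Defines a fully self-contained toy dataset emulating the statistical
#' structure the analysis assumes: a small genome with excluded regions,
#' repeat families with consensus-derived sequences, per-sample DNase and
#' histone peak sets in which planted families carry elevated overlap
#' probability in AML samples, expression shifted near planted-active
#' elements, a mutation subgroup with correlated accessibility patterns, and
#' CRISPRi coverage tracks with depleted H3K27ac / gained H3K9me3 at targeted
#' elements. Every planted effect is recorded in a ground-truth manifest.
#'
#' @param seed Master seed; the whole dataset is a deterministic function of
#'   the config.
#' @param n_chroms,chrom_length Genome shape (default 2 x 1 Mb).
#' @param excluded_fraction Fraction of each chromosome masked as unmappable
#'   (one block per chromosome; default 0.05).
#' @param families data.frame `name, n_copies, length, divergence` describing
#'   the repeat families; divergence is the i.i.d. per-base substitution rate
#'   from consensus (no indels, so motif offsets stay exact).
#' @param n_aml_samples,n_diff_samples,n_cell_lines Cohort sizes.
#' @param background_peak_rate Background peaks per mappable bp per sample
#'   (default 1e-4, about 190 peaks on the default genome).
#' @param peak_width Width of generated peaks in bp.
#' @param enriched_families data.frame `name, overlap_prob_aml,
#'   overlap_prob_diff`: per-element Bernoulli probability that a family copy
#'   carries a DHS in an AML (or cell-line) vs differentiated sample. The
#'   default 0.18 against the background hit rate of the default genome is
#'   roughly a threefold overlap rate.
#' @param planted_motifs data.frame `consensus, family, offset`: motif strings
#'   written into family consensus sequences at fixed offsets.
#' @param n_genes,gene_length Gene models placed uniformly in mappable space.
#' @param n_links,link_delta_log2,link_sigma,link_n_active Enhancer-gene
#'   links: `n_links` genes near a non-enriched-family element get
#'   `link_delta_log2` added in the `link_n_active` AML samples where the
#'   element is planted active, with N(0, `link_sigma`) noise.
#' @param expr_baseline_mean,expr_baseline_sd Per-gene baseline on the log2
#'   (vst-like) scale.
#' @param state_probs Named proportions of planted chromatin states over
#'   elements.
#' @param mark_emission Matrix states x marks of per-AML-sample overlap
#'   probabilities; differentiated samples use `diff_emission` throughout.
#' @param diff_emission Flat mark probability in differentiated samples.
#' @param mutation Label, member count and target pairwise correlation of the
#'   planted mutation subgroup (members share accessibility profiles).
#' @param crispri Target families, H3K27ac depletion fraction, H3K9me3 gain
#'   factor, off-target peak count and protospacer length for the CRISPRi
#'   arm.
#' @param modules Which optional dataset arms to generate (genome, repeats,
#'   sequences and DNase peak sets are always produced). Trimming the list
#'   speeds up simulation studies that only exercise the DNase arm.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    n_chroms = 2,
    chrom_length = 1e6,
    excluded_fraction = 0.05,
    families = data.frame(
      name = c("LTR2B", "LTR2", "LTR5B", "LTR12C", "MER41B"),
      n_copies = c(300, 150, 200, 250, 100),
      length = c(400, 400, 350, 500, 300),
      divergence = c(0.10, 0.10, 0.12, 0.15, 0.15),
      stringsAsFactors = FALSE),
    n_aml_samples = 30,
    n_diff_samples = 10,
    n_cell_lines = 3,
    background_peak_rate = 1e-4,
    peak_width = 150,
    enriched_families = data.frame(
      name = "LTR2B", overlap_prob_aml = 0.18, overlap_prob_diff = 0.0,
      stringsAsFactors = FALSE),
    planted_motifs = data.frame(
      consensus = c("GAGGAAGTGA", "CCTTATCTGG"),
      family = c("LTR2B", "LTR5B"),
      offset = c(120, 80), stringsAsFactors = FALSE),
    n_genes = 80,
    gene_length = 3000,
    n_links = 10,
    link_delta_log2 = 3,
    link_sigma = 0.5,
    link_n_active = 10,
    expr_baseline_mean = 2,
    expr_baseline_sd = 1,
    state_probs = c(active_enhancer = 0.2, primed_enhancer = 0.2,
                    unmarked = 0.6),
    mark_emission = rbind(
      active_enhancer = c(H3K27ac = 0.70, H3K4me1 = 0.70,
                          H3K4me3 = 0.03, H3K9me3 = 0.02),
      primed_enhancer = c(H3K27ac = 0.05, H3K4me1 = 0.70,
                          H3K4me3 = 0.03, H3K9me3 = 0.02),
      unmarked = c(H3K27ac = 0.03, H3K4me1 = 0.03,
                   H3K4me3 = 0.03, H3K9me3 = 0.03)),
    diff_emission = 0.03,
    mutation = list(label = "NPM1", n_members = 12,
                    correlation_strength = 0.6),
    crispri = list(target_families = c("LTR2B", "LTR2"),
                   k27ac_depletion = 0.5, k9me3_gain = 2.0,
                   n_offtarget_peaks = 20, guide_length = 20),
    modules = c("marks", "transcripts", "expression", "crispri")) {
  stopifnot(nrow(families) >= 1, all(families$n_copies > 0),
            all(families$divergence >= 0 & families$divergence < 1),
            all(enriched_families$overlap_prob_aml >= 0 &
                  enriched_families$overlap_prob_aml <= 1),
            abs(sum(state_probs) - 1) < 1e-8,
            mutation$n_members <= n_aml_samples)
  if (!all(enriched_families$name %in% families$name))
    stop("enriched_families must name configured families")
  if (!all(rownames(mark_emission) == names(state_probs)))
    stop("mark_emission rows must match state_probs names")
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# uniform placement of n non-overlapping intervals of length len in mappable
# space; relies on the shuffle engine for uniform valid positions
place_elements <- function(n, len, genome, existing = NULL, max_tries = 60) {
  template <- GenomicRanges::GRanges(
    seqnames = names(genome$chroms)[1],
    ranges = IRanges::IRanges(start = rep(1L, n), width = len))
  placed <- GenomicRanges::GRanges()
  for (i in seq_len(max_tries)) {
    need <- n - length(placed)
    if (need == 0L) break
    cand <- shuffle_intervals(template[seq_len(need)], genome)
    blockers <- c(placed, existing)
    if (length(blockers))
      cand <- cand[GenomicRanges::countOverlaps(cand, blockers,
                                                ignore.strand = TRUE) == 0L]
    if (length(cand) > 1L)  # drop self-overlaps within the batch
      cand <- cand[GenomicRanges::countOverlaps(cand, cand,
                                                ignore.strand = TRUE) == 1L]
    placed <- c(placed, cand)
  }
  if (length(placed) < n)
    stop("could not place ", n, " elements of length ", len,
         " in the mappable space")
  GenomicRanges::sort(placed[seq_len(n)])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) mutate_copies(seq, rate, 1L)

# n copies of a consensus with i.i.d. substitutions; a hit base is shifted by
# 1-3 positions in the ACGT alphabet, i.e. uniform over the other three bases
mutate_copies <- function(seq, rate, n) {
  alph <- c("A", "C", "G", "T")
  code <- match(strsplit(seq, "")[[1]], alph)
  L <- length(code)
  m <- matrix(rep(code, each = n), nrow = n)
  hit <- stats::runif(n * L) < rate
  if (any(hit)) {
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    m[hit] <- ((m[hit] - 1L + shift) %% 4L) + 1L
  }
  apply(m, 1, function(r) paste(alph[r], collapse = ""))
}

# peak placed at a fixed internal offset of an element, emulating the
# localized accessibility footprint within a family
element_peak <- function(el_start, el_end, width, offset = 50L) {
  s <- pmin(el_start + offset, pmax(el_end - width + 1L, el_start))
  IRanges::IRanges(start = s, width = width)
}

#' Generate the synthetic dataset
#'
#' Deterministically expands a [synthetic_config] into an in-memory dataset
#' holding every input the analysis modules consume, together with the
#' ground-truth manifest of planted effects. Use [write_synthetic] to emit
#' the standard-format files.
#'
#' @param config A [synthetic_config].
#' @return A list of class `synthetic_dataset`; see the manifest under
#'   `$truth` and the components `genome, repeats, element_seqs, consensus,
#'   samples, dhs, marks, transcripts, genes, expr, guides, dcas9, tracks,
#'   de_table`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(config$seed))
  chroms <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  excl_len <- round(config$excluded_fraction * config$chrom_length)
  excluded <- if (excl_len > 0) GenomicRanges::GRanges(
    seqnames = names(chroms),
    ranges = IRanges::IRanges(
      start = round(config$chrom_length * 0.4),
      width = excl_len)) else NULL
  genome <- GenomeLayout(chroms, excluded)

  ## repeat annotation
  fams <- config$families
  el_list <- list()
  existing <- GenomicRanges::GRanges()
  for (i in seq_len(nrow(fams))) {
    gr <- place_elements(fams$n_copies[i], fams$length[i], genome,
                         existing = existing)
    S4Vectors::mcols(gr)$family <- fams$name[i]
    existing <- c(existing, GenomicRanges::granges(gr))
    el_list[[i]] <- gr
  }
  repeats <- GenomicRanges::sort(do.call(c, el_list))
  S4Vectors::mcols(repeats)$element_id <-
    paste0(S4Vectors::mcols(repeats)$family, "_",
           stats::ave(seq_along(repeats),
                      S4Vectors::mcols(repeats)$family, FUN = seq_along))
  el_id <- S4Vectors::mcols(repeats)$element_id
  el_fam <- S4Vectors::mcols(repeats)$family

  ## consensus + element sequences (LTR2 consensus derives from LTR2B, so
  ## guides designed on LTR2B cross-react with a minority of LTR2 copies)
  consensus <- character(0)
  for (i in seq_len(nrow(fams))) {
    nm <- fams$name[i]
    consensus[nm] <- if (nm == "LTR2" && "LTR2B" %in% names(consensus)) {
      mutate_seq(consensus[["LTR2B"]], 0.17)
    } else random_dna(fams$length[i])
  }
  for (j in seq_len(nrow(config$planted_motifs))) {
    pm <- config$planted_motifs[j, ]
    if (!pm$family %in% names(consensus)) next
    s <- consensus[[pm$family]]
    substr(s, pm$offset + 1L, pm$offset + nchar(pm$consensus)) <- pm$consensus
    consensus[pm$family] <- s
  }
  div <- stats::setNames(fams$divergence, fams$name)
  seq_chr <- character(length(repeats))
  for (nm in fams$name) {
    idx <- which(el_fam == nm)
    seq_chr[idx] <- mutate_copies(consensus[[nm]], div[[nm]], length(idx))
  }
  element_seqs <- Biostrings::DNAStringSet(seq_chr)
  names(element_seqs) <- el_id

  ## cohort
  aml_ids <- sprintf("AML%02d", seq_len(config$n_aml_samples))
  diff_ids <- sprintf("DIFF%02d", seq_len(config$n_diff_samples))
  cl_ids <- c("HL-60", "OCI-AML3", "MOLM-13",
              sprintf("CL%02d", seq_len(max(0, config$n_cell_lines - 3))))
  cl_ids <- cl_ids[seq_len(config$n_cell_lines)]
  groups <- stats::setNames(
    c(rep("AML", length(aml_ids)), rep("differentiated", length(diff_ids)),
      rep("cell_line", length(cl_ids))),
    c(aml_ids, diff_ids, cl_ids))
  members <- sort(sample(aml_ids, config$mutation$n_members))
  samples <- data.frame(sample_id = names(groups), group = unname(groups),
                        stringsAsFactors = FALSE)
  samples[[config$mutation$label]] <- samples$sample_id %in% members

  ## enhancer-gene links: genes near a non-enriched-family element
  # genes avoid each other but may contain repeat copies, as real genes do
  genes_gr <- place_elements(config$n_genes, config$gene_length, genome)
  S4Vectors::mcols(genes_gr)$gene_id <-
    sprintf("GENE%03d", seq_len(config$n_genes))
  non_enriched <- which(!el_fam %in% config$enriched_families$name)
  near <- GenomicRanges::findOverlaps(genes_gr, repeats[non_enriched],
                                      maxgap = 50000, ignore.strand = TRUE)
  cand_genes <- unique(S4Vectors::queryHits(near))
  n_links <- if ("expression" %in% config$modules) config$n_links else 0L
  # one distinct element per link: a shared element would couple two links'
  # activity patterns and break the planted DHS/expression correspondence
  link_genes <- integer(0)
  link_el_idx <- integer(0)
  for (g in sample(cand_genes)) {
    if (length(link_genes) >= n_links) break
    hits <- non_enriched[S4Vectors::subjectHits(near)[
      S4Vectors::queryHits(near) == g]]
    hits <- setdiff(hits, link_el_idx)
    if (length(hits) == 0L) next
    link_genes <- c(link_genes, g)
    link_el_idx <- c(link_el_idx, hits[1])
  }
  ord <- order(link_genes)
  link_genes <- link_genes[ord]
  link_el_idx <- link_el_idx[ord]
  links <- data.frame(
    gene_id = S4Vectors::mcols(genes_gr)$gene_id[link_genes],
    element_id = el_id[link_el_idx],
    delta_log2 = rep(config$link_delta_log2, length(link_genes)),
    sigma = rep(config$link_sigma, length(link_genes)),
    stringsAsFactors = FALSE)
  link_active <- matrix(FALSE, nrow = nrow(links), ncol = length(aml_ids),
                        dimnames = list(links$element_id, aml_ids))
  for (r in seq_len(nrow(links)))
    link_active[r, sample(aml_ids, config$link_n_active)] <- TRUE

  ## DHS activity per element x sample (Bernoulli planting; mutation-subgroup
  ## members copy a shared profile with probability sqrt(strength) so their
  ## pairwise correlation approaches the configured strength)
  n_el <- length(repeats)
  p_aml <- stats::setNames(rep(0, nrow(fams)), fams$name)
  p_diff <- p_aml
  for (j in seq_len(nrow(config$enriched_families))) {
    ef <- config$enriched_families[j, ]
    p_aml[ef$name] <- ef$overlap_prob_aml
    p_diff[ef$name] <- ef$overlap_prob_diff
  }
  rho <- sqrt(config$mutation$correlation_strength)
  shared_profile <- stats::runif(n_el) < p_aml[el_fam]
  activity <- function(sample_id) {
    grp <- groups[[sample_id]]
    p <- if (grp == "differentiated") p_diff[el_fam] else p_aml[el_fam]
    act <- stats::runif(n_el) < p
    if (sample_id %in% members) {
      use_shared <- stats::runif(n_el) < rho
      act[use_shared] <- shared_profile[use_shared]
    }
    if (grp %in% c("AML")) {
      li <- match(links$element_id, el_id)
      act[li] <- link_active[, sample_id]
    }
    act
  }
  background_peaks <- function() {
    n_bg <- stats::rpois(1, config$background_peak_rate *
                           sum(GenomicRanges::width(genome$mappable)))
    if (n_bg == 0L) return(GenomicRanges::GRanges())
    shuffle_intervals(GenomicRanges::GRanges(
      seqnames = names(chroms)[1],
      ranges = IRanges::IRanges(start = rep(1L, n_bg),
                                width = config$peak_width)), genome)
  }
  dhs_active <- matrix(FALSE, nrow = n_el, ncol = length(groups),
                       dimnames = list(el_id, names(groups)))
  dhs <- list()
  for (sid in names(groups)) {
    act <- activity(sid)
    dhs_active[, sid] <- act
    on <- which(act)
    peaks_el <- if (length(on)) GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(repeats)[on],
      ranges = element_peak(GenomicRanges::start(repeats)[on],
                            GenomicRanges::end(repeats)[on],
                            config$peak_width)) else GenomicRanges::GRanges()
    dhs[[sid]] <- PeakSet(sid, "DNase", groups[[sid]],
                          c(peaks_el, background_peaks()), genome)
  }

  ## chromatin states and histone mark peak sets (AML + differentiated)
  states <- sample(names(config$state_probs), n_el, replace = TRUE,
                   prob = config$state_probs)
  marks <- list()
  mark_names <- colnames(config$mark_emission)
  if ("marks" %in% config$modules) for (sid in c(aml_ids, diff_ids)) {
    grp <- groups[[sid]]
    for (mk in mark_names) {
      p <- if (grp == "AML") config$mark_emission[states, mk]
           else rep(config$diff_emission, n_el)
      on <- which(stats::runif(n_el) < p)
      peaks_el <- if (length(on)) GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(repeats)[on],
        ranges = element_peak(GenomicRanges::start(repeats)[on],
                              GenomicRanges::end(repeats)[on],
                              config$peak_width)) else GenomicRanges::GRanges()
      bg <- background_peaks()
      marks[[paste(mk, sid, sep = ".")]] <-
        PeakSet(sid, mk, grp, c(peaks_el, bg[seq_len(min(50, length(bg)))]),
                genome)
    }
  }

  ## element-derived transcripts: AML-specific promoter elements carry a TSS
  ## in >= 2 AML samples and none in differentiated cells; shared promoter
  ## elements also fire in differentiated samples
  enr_idx <- which(el_fam %in% config$enriched_families$name)
  if (length(enr_idx) == 0L) enr_idx <- seq_len(min(n_el, 50L))
  prom_pool <- setdiff(enr_idx, match(links$element_id, el_id))
  prom_specific <- sort(sample(prom_pool, min(8L, length(prom_pool))))
  prom_shared <- sort(sample(setdiff(prom_pool, prom_specific),
                             min(4L, length(setdiff(prom_pool,
                                                    prom_specific)))))
  tx_rows <- list()
  emit_tx <- function(ei, sid) {
    strand <- if (GenomicRanges::start(repeats)[ei] %% 2 == 0) "+" else "-"
    if (strand == "+") {
      tss <- GenomicRanges::start(repeats)[ei] + 50L
      ex <- data.frame(start = c(tss, tss + 300L),
                       end = c(tss + 99L, tss + 499L))
    } else {
      tss <- GenomicRanges::end(repeats)[ei] - 50L
      ex <- data.frame(start = c(tss - 499L, tss - 99L),
                       end = c(tss - 300L, tss))
    }
    tid <- paste0("TX_", el_id[ei], "_", sid)
    data.frame(transcript_id = tid, sample_id = sid,
               chrom = as.character(GenomicRanges::seqnames(repeats))[ei],
               start = ex$start, end = ex$end, strand = strand,
               stringsAsFactors = FALSE)
  }
  prom_truth <- list()
  if (!"transcripts" %in% config$modules) prom_specific <- prom_shared <-
    integer(0)
  for (ei in prom_specific) {
    in_samples <- sort(sample(aml_ids, sample(2:5, 1)))
    for (sid in in_samples) tx_rows[[length(tx_rows) + 1L]] <- emit_tx(ei, sid)
    prom_truth[[el_id[ei]]] <- list(aml = in_samples,
                                    diff = character(0), specific = TRUE)
  }
  for (ei in prom_shared) {
    in_aml <- sort(sample(aml_ids, 3))
    in_diff <- sort(sample(diff_ids, 2))
    for (sid in c(in_aml, in_diff))
      tx_rows[[length(tx_rows) + 1L]] <- emit_tx(ei, sid)
    prom_truth[[el_id[ei]]] <- list(aml = in_aml, diff = in_diff,
                                    specific = FALSE)
  }
  transcripts <- if (length(tx_rows)) do.call(rbind, tx_rows) else NULL

  ## expression (log2 vst-like scale)
  expr <- NULL
  if ("expression" %in% config$modules) {
    expr_samples <- c(aml_ids, diff_ids)
    baseline <- stats::rnorm(config$n_genes, config$expr_baseline_mean,
                             config$expr_baseline_sd)
    expr <- matrix(stats::rnorm(config$n_genes * length(expr_samples),
                                0, config$link_sigma),
                   nrow = config$n_genes,
                   dimnames = list(S4Vectors::mcols(genes_gr)$gene_id,
                                   expr_samples))
    expr <- expr + baseline
    for (r in seq_len(nrow(links))) {
      on <- aml_ids[link_active[r, ]]
      expr[links$gene_id[r], on] <- expr[links$gene_id[r], on] +
        config$link_delta_log2
    }
  }

  ## CRISPRi arm: guides from the first target family's consensus, dCas9
  ## peaks at recognised copies plus random off-target peaks
  guides <- dcas9 <- tracks <- de_table <- NULL
  gt <- list(recognised = stats::setNames(logical(n_el), el_id))
  bound_idx <- integer(0)
  if ("crispri" %in% config$modules) {
  cr <- config$crispri
  gfam <- cr$target_families[1]
  gl <- cr$guide_length
  gstart <- 1L + nchar(consensus[[gfam]]) %/% 3
  guides <- substr(consensus[[gfam]], gstart, gstart + gl - 1L)
  fam_map <- stats::setNames(el_fam, el_id)
  gt <- predict_guide_targets(guides, element_seqs, fam_map,
                              max_mismatches = 2)
  bound_idx <- which(gt$recognised & el_fam %in% cr$target_families)
  centre <- floor((GenomicRanges::start(repeats)[bound_idx] - 1 +
                     GenomicRanges::end(repeats)[bound_idx]) / 2)
  on_target_peaks <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(repeats)[bound_idx],
    ranges = IRanges::IRanges(start = centre - 99L, width = 200L))
  off_target_peaks <- if (cr$n_offtarget_peaks > 0) {
    cand <- shuffle_intervals(GenomicRanges::GRanges(
      seqnames = names(chroms)[1],
      ranges = IRanges::IRanges(start = rep(1L, cr$n_offtarget_peaks * 3),
                                width = 200L)), genome)
    cand <- cand[GenomicRanges::countOverlaps(
      cand, repeats[el_fam %in% cr$target_families],
      ignore.strand = TRUE) == 0L]
    cand[seq_len(min(cr$n_offtarget_peaks, length(cand)))]
  } else GenomicRanges::GRanges()
  dcas9 <- PeakSet("K562_LTR2Bsg", "dCas9", "cell_line",
                   c(on_target_peaks, off_target_peaks), genome)

  ## coverage tracks: piecewise-constant bedGraph-style signal, with the
  ## planted depletion/gain applied fully at on-target windows and at 30%
  ## strength at off-target windows
  flat_gr <- GenomicRanges::GRanges(
    seqnames = names(chroms),
    ranges = IRanges::IRanges(start = 1L, end = as.integer(chroms)))
  track_from_layers <- function(base_level, layers) {
    # layers: list of list(windows, level); earlier layers take precedence
    if (length(layers) == 0L) {
      out <- flat_gr
      S4Vectors::mcols(out)$score <- base_level
      return(out)
    }
    wins <- lapply(layers, function(l) GenomicRanges::reduce(l$windows))
    if (length(wins) > 1L) for (i in 2:length(wins))
      for (j in 1:(i - 1L))
        wins[[i]] <- GenomicRanges::setdiff(wins[[i]], wins[[j]])
    rest <- GenomicRanges::setdiff(flat_gr, do.call(c, wins))
    S4Vectors::mcols(rest)$score <- base_level
    out <- rest
    for (i in seq_along(wins)) {
      w <- wins[[i]]
      if (length(w) == 0L) next
      S4Vectors::mcols(w)$score <- layers[[i]]$level
      out <- c(out, w)
    }
    GenomicRanges::sort(out)
  }
  grow <- function(gr, pad) GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = pmax(GenomicRanges::start(gr) - pad, 1L),
                              end = pmin(GenomicRanges::end(gr) + pad,
                                         chroms[as.character(
                                           GenomicRanges::seqnames(gr))])))
  on_win <- grow(on_target_peaks, 200L)
  off_win <- grow(off_target_peaks, 200L)
  k27_hi <- 5
  depl <- cr$k27ac_depletion
  gain <- cr$k9me3_gain
  tracks <- list(
    H3K27ac_ctrl = track_from_layers(1, list(
      list(windows = c(on_win, off_win), level = k27_hi))),
    # off-target windows see only 30% of the planted epigenetic effect
    H3K27ac_sg = track_from_layers(1, list(
      list(windows = on_win, level = k27_hi * (1 - depl)),
      list(windows = off_win, level = k27_hi * (1 - 0.3 * depl)))),
    H3K9me3_ctrl = track_from_layers(1, list()),
    H3K9me3_sg = track_from_layers(1, list(
      list(windows = on_win, level = gain),
      list(windows = off_win, level = 1 + 0.3 * (gain - 1))))
  )

  ## differential-expression table consumed by the CRISPRi gene-target join
  near_genes <- proximal_genes(dcas9$peaks, genes_gr, max_dist = 50000)
  de_table <- data.frame(
    gene_id = S4Vectors::mcols(genes_gr)$gene_id, stringsAsFactors = FALSE)
  de_table$log2FC <- ifelse(de_table$gene_id %in% near_genes$gene_id,
                            -1.5, 0) + stats::rnorm(nrow(de_table), 0, 0.1)
  de_table$padj <- ifelse(de_table$gene_id %in% near_genes$gene_id,
                          1e-4, stats::runif(nrow(de_table), 0.2, 1))
  }  # end crispri module

  truth <- list(
    enriched_families = config$enriched_families$name,
    dhs_active = dhs_active,
    links = cbind(links, n_active = rowSums(link_active)),
    link_active = link_active,
    states = stats::setNames(states, el_id),
    mutation_label = config$mutation$label,
    mutation_members = members,
    promoter_elements = prom_truth,
    guide_recognised = names(gt$recognised)[gt$recognised],
    dcas9_target_elements = el_id[bound_idx],
    planted_motifs = config$planted_motifs
  )
  structure(
    list(config = config, genome = genome, repeats = repeats,
         consensus = consensus, element_seqs = element_seqs,
         samples = samples, groups = groups, dhs = dhs, marks = marks,
         transcripts = transcripts, genes = genes_gr, expr = expr,
         guides = guides, dcas9 = dcas9, tracks = tracks,
         de_table = de_table, truth = truth),
    class = "synthetic_dataset"
  )
}

#' Draw a fresh DNase sample from a synthetic dataset's planted model
#'
#' Generates one new DNase [PeakSet] under the dataset's planted per-family
#' overlap probabilities and background peak rate, without the
#' mutation-subgroup or enhancer-link adjustments (an independent draw from
#' the marginal model). Useful for simulation studies — repeated enrichment
#' runs against a fixed genome and repeat annotation.
#'
#' @param ds A `synthetic_dataset`.
#' @param sample_id Identifier for the new sample.
#' @param group Sample group (default `"AML"`; `"differentiated"` uses the
#'   differentiated overlap probabilities).
#' @param seed Integer seed.
#' @param null If `TRUE`, ignore the planted probabilities and draw only
#'   background peaks placed uniformly in mappable space (a no-enrichment
#'   sample with the same peak count distribution contribution from
#'   background).
#' @return A [PeakSet].
#' @export
synthetic_dhs_sample <- function(ds, sample_id = "SIM", group = "AML",
                                 seed = NULL, null = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  config <- ds$config
  el_fam <- S4Vectors::mcols(ds$repeats)$family
  p <- stats::setNames(rep(0, nrow(config$families)), config$families$name)
  if (!null) for (j in seq_len(nrow(config$enriched_families))) {
    ef <- config$enriched_families[j, ]
    p[ef$name] <- if (group == "differentiated") ef$overlap_prob_diff
                  else ef$overlap_prob_aml
  }
  act <- which(stats::runif(length(ds$repeats)) < p[el_fam])
  peaks_el <- if (length(act)) GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ds$repeats)[act],
    ranges = element_peak(GenomicRanges::start(ds$repeats)[act],
                          GenomicRanges::end(ds$repeats)[act],
                          config$peak_width)) else GenomicRanges::GRanges()
  n_bg <- stats::rpois(1, config$background_peak_rate *
                         sum(GenomicRanges::width(ds$genome$mappable)))
  bg <- if (n_bg > 0) shuffle_intervals(GenomicRanges::GRanges(
    seqnames = names(ds$genome$chroms)[1],
    ranges = IRanges::IRanges(start = rep(1L, n_bg),
                              width = config$peak_width)), ds$genome)
    else GenomicRanges::GRanges()
  PeakSet(sample_id, "DNase", group, c(peaks_el, bg), ds$genome)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$repeats), "elements in",
      nrow(x$config$families), "families;", length(x$dhs), "DNase samples;",
      length(x$marks), "histone-mark peak sets;",
      if (is.null(x$expr)) 0L else nrow(x$expr), "genes\n")
  invisible(x)
}

#' Write a synthetic dataset as standard-format files
#'
#' Emits chrom.sizes, excluded.bed, repeats.bed (family-labelled BED),
#' consensus and element FASTA, per-sample peak BEDs, transcripts.gtf,
#' genes.bed, expression.tsv, mutations.tsv, guides.txt, coverage bedGraphs,
#' de_genes.tsv and the ground-truth manifest truth.json.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  utils::write.table(
    data.frame(names(ds$genome$chroms), unname(ds$genome$chroms)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_bed6(ds$genome$excluded, file.path(dir, "excluded.bed"))
  write_bed6(ds$repeats, file.path(dir, "repeats.bed"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ds$consensus),
    file.path(dir, "consensus.fa"))
  Biostrings::writeXStringSet(ds$element_seqs, file.path(dir, "elements.fa"))
  for (ps in c(ds$dhs, ds$marks,
               if (is.null(ds$dcas9)) list() else list(ds$dcas9))) {
    fn <- sprintf("%s_%s.bed", gsub("[^A-Za-z0-9]", "", ps$assay),
                  ps$sample_id)
    write_bed6(ps$peaks, file.path(dir, "peaks", fn))
  }
  if (!is.null(ds$transcripts)) {
  gtf <- ds$transcripts
  lines <- sprintf(
    '%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; sample_id "%s";',
    gtf$chrom, gtf$start, gtf$end, gtf$strand,
    gtf$transcript_id, gtf$transcript_id, gtf$sample_id)
  writeLines(lines, file.path(dir, "transcripts.gtf"))
  }
  genes_bed <- ds$genes
  S4Vectors::mcols(genes_bed)$name <- S4Vectors::mcols(genes_bed)$gene_id
  write_bed6(genes_bed, file.path(dir, "genes.bed"))
  if (!is.null(ds$expr)) utils::write.table(
    data.frame(gene_id = rownames(ds$expr), ds$expr, check.names = FALSE),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(ds$samples, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$guides))
    writeLines(ds$guides, file.path(dir, "guides.txt"))
  for (nm in names(ds$tracks)) {
    tr <- ds$tracks[[nm]]
    utils::write.table(
      data.frame(as.character(GenomicRanges::seqnames(tr)),
                 GenomicRanges::start(tr) - 1L, GenomicRanges::end(tr),
                 S4Vectors::mcols(tr)$score),
      file.path(dir, "coverage", paste0(nm, ".bedGraph")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(ds$de_table))
    utils::write.table(ds$de_table, file.path(dir, "de_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth$dhs_active <- NULL  # large matrix: keep manifest compact; the
  truth$link_active <- NULL # activity is re-derivable from the peak files
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Self-audit a synthetic dataset against its own manifest
#'
#' Re-derives planted truths from the emitted objects by brute force: planted
#' active elements really overlap a DNase peak in the stated samples, planted
#' motifs occur at their stated consensus offsets, guide-recognised elements
#' match by Hamming distance, and link expression shifts are present.
#'
#' @param ds A `synthetic_dataset`.
#' @return `TRUE` (invisibly) if all checks pass; otherwise stops.
#' @export
audit_synthetic <- function(ds) {
  el_id <- S4Vectors::mcols(ds$repeats)$element_id
  # planted DHS activity implies a peak overlap in that sample
  for (sid in sample(colnames(ds$truth$dhs_active), 5)) {
    act <- ds$truth$dhs_active[, sid]
    ovl <- GenomicRanges::countOverlaps(ds$repeats, ds$dhs[[sid]]$peaks,
                                        ignore.strand = TRUE) > 0L
    if (!all(ovl[act]))
      stop("audit: active element lacks a peak in ", sid)
  }
  # planted motifs present in consensus at the stated offset
  for (j in seq_len(nrow(ds$truth$planted_motifs))) {
    pm <- ds$truth$planted_motifs[j, ]
    found <- substr(ds$consensus[[pm$family]], pm$offset + 1L,
                    pm$offset + nchar(pm$consensus))
    if (found != pm$consensus)
      stop("audit: motif not at stated offset in ", pm$family)
  }
  # guide recognition recomputes identically
  if (!is.null(ds$guides)) {
  fam_map <- stats::setNames(S4Vectors::mcols(ds$repeats)$family, el_id)
  gt <- predict_guide_targets(ds$guides, ds$element_seqs, fam_map,
                              max_mismatches = 2)
  if (!setequal(names(gt$recognised)[gt$recognised],
                ds$truth$guide_recognised))
    stop("audit: guide target list mismatch")
  }
  # link shift visible in expression
  if (!is.null(ds$expr))
  for (r in seq_len(nrow(ds$truth$links))) {
    g <- ds$truth$links$gene_id[r]
    on <- colnames(ds$truth$link_active)[ds$truth$link_active[r, ]]
    off <- setdiff(colnames(ds$truth$link_active), on)
    if (mean(ds$expr[g, on]) - mean(ds$expr[g, off]) < 1)
      stop("audit: link shift not visible for ", g)
  }
  invisible(TRUE)
}
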