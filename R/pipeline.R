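#' Run the analysis stages end-to-end on a dataset
#'
#' Orchestrates the analysis in dependency order — family enrichment,
#' family selection, heterogeneity, chromatin states, promoter discovery,
#' gene association, TF/motif analysis, CRISPRi evaluation — writing each
#' stage's TSV/JSON outputs plus a provenance block (config digest, seed,
#' package version) to a run directory. Rerunning with an identical config
#' reproduces identical outputs.
#'
#' @param config Either a [synthetic_config] (the dataset is generated), a
#'   `synthetic_dataset`, or a path to a YAML file with a `synthetic:`
#'   section of [synthetic_config] overrides and optional `params:`
#'   (n_shuffles, seed, k, thresholds) and `stages:` entries.
#' @param outdir Output directory.
#' @param stages Character vector of stages to run (default all):
#'   `"enrich", "select", "heterogeneity", "states", "promoters", "assoc",
#'   "tf", "motif", "crispri"`.
#' @param n_shuffles Shuffles for the enrichment null (default 200 at toy
#'   scale).
#' @param seed Seed for the stochastic stages (shuffles, permutation tests,
#'   k-means); defaults to the dataset's own seed.
#' @param k Cluster count for the chromatin-state stage (default: number of
#'   planted states when known, else 6).
#' @return Invisibly, a named list with each stage's main result object.
#' @export
run_pipeline <- function(config = synthetic_config(), outdir,
                         stages = c("enrich", "select", "heterogeneity",
                                    "states", "promoters", "assoc", "tf",
                                    "motif", "crispri"),
                         n_shuffles = 200, seed = NULL, k = NULL) {
  all_stages <- c("enrich", "select", "heterogeneity", "states", "promoters",
                  "assoc", "tf", "motif", "crispri")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (is.character(config) && length(config) == 1L) {
    yml <- yaml::read_yaml(config)
    cfg_args <- yml$synthetic
    if (!is.null(cfg_args$families)) cfg_args$families <-
      do.call(rbind.data.frame, cfg_args$families)
    config <- do.call(synthetic_config, cfg_args)
    if (!is.null(yml$params$n_shuffles)) n_shuffles <- yml$params$n_shuffles
    if (!is.null(yml$params$seed)) seed <- yml$params$seed
    if (!is.null(yml$params$k)) k <- yml$params$k
    if (!is.null(yml$stages)) stages <- yml$stages
  }
  ds <- if (inherits(config, "synthetic_dataset")) config
        else generate_synthetic(config)
  if (is.null(seed)) seed <- ds$config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  t0 <- Sys.time()
  log_stage <- function(name, n_records) {
    message(sprintf("[%s] %s: %d record(s), %.1fs elapsed", "INFO", name,
                    n_records, as.numeric(Sys.time() - t0, units = "secs")))
  }
  tsv <- function(d, name) utils::write.table(
    d, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  need <- function(stage, dep) {
    if (is.null(out[[dep]]))
      stop("stage '", stage, "' needs output of stage '", dep,
           "' which was not run")
  }

  if ("enrich" %in% stages) {
    dnase <- Filter(function(p) p$assay == "DNase", ds$dhs)
    res <- lapply(seq_along(dnase), function(i)
      family_dhs_enrichment(dnase[[i]], ds$repeats, ds$genome,
                            n_shuffles = n_shuffles, seed = seed + i))
    names(res) <- vapply(dnase, function(p) p$sample_id, character(1))
    out$enrich <- do.call(rbind, res)
    tsv(out$enrich, "enrichment.tsv")
    log_stage("enrich", nrow(out$enrich))
  }
  if ("select" %in% stages) {
    need("select", "enrich")
    sel <- select_families(out$enrich, ds$groups)
    out$select <- sel
    jsonlite::write_json(
      list(selected = sel$selected,
           aml_pass_frac = as.list(sel$aml_pass_frac)),
      file.path(outdir, "selected_families.json"), auto_unbox = TRUE,
      digits = NA)
    log_stage("select", length(sel$selected))
  }
  if ("heterogeneity" %in% stages) {
    m <- build_overlap_matrix(ds$repeats,
                              Filter(function(p) p$group == "AML", ds$dhs))
    cc <- sample_correlation(m)
    mut <- stats::setNames(ds$samples[[ds$truth$mutation_label]],
                           ds$samples$sample_id)
    cmp <- mutation_correlation_test(cc, mut, n_perm = 2000, seed = seed)
    out$heterogeneity <- cmp
    tsv(data.frame(sample = rownames(cc), cc, check.names = FALSE),
        "sample_correlation.tsv")
    tsv(data.frame(mutation = ds$truth$mutation_label, n_mut = cmp$n_mut,
                   n_wt = cmp$n_wt, median_mut = cmp$median_mut,
                   median_wt = cmp$median_wt, p_perm = cmp$p_perm),
        "mutation_correlation.tsv")
    log_stage("heterogeneity", nrow(cc))
  }
  if ("states" %in% stages) {
    feats <- mark_overlap_fractions(ds$repeats, ds$marks)
    kk <- if (!is.null(k)) k else length(ds$config$state_probs)
    cl <- cluster_elements(feats, k = kk, seed = seed)
    st <- classify_state(feats)
    out$states <- list(features = feats, clusters = cl, states = st)
    tsv(data.frame(element_id = rownames(feats$fractions), feats$fractions,
                   cluster = cl[rownames(feats$fractions)],
                   state = st[rownames(feats$fractions)],
                   check.names = FALSE), "chromatin_states.tsv")
    tsv(cluster_elbow(feats, seed = seed), "state_cluster_elbow.tsv")
    log_stage("states", length(st))
  }
  if ("promoters" %in% stages) {
    tss <- transcript_tss(ds$transcripts)
    hits <- element_tss_hits(tss, ds$repeats)
    calls <- aml_specific_promoters(hits$hits, ds$groups)
    out$promoters <- list(per_sample = hits$per_sample, calls = calls)
    tsv(hits$per_sample, "tss_per_sample.tsv")
    tsv(calls, "element_promoters.tsv")
    log_stage("promoters", sum(calls$selected))
  }
  if ("assoc" %in% stages) {
    pairs <- genes_near_elements(ds$genes, ds$repeats)
    m <- build_overlap_matrix(
      ds$repeats, Filter(function(p) p$group %in% c("AML", "differentiated"),
                         ds$dhs))
    grpdist <- group_expression_by_dhs(pairs, ds$expr, m)
    contrasts <- dhs_contrast_table(pairs, ds$expr, m)
    out$assoc <- list(pairs = pairs, groups = grpdist, contrasts = contrasts)
    tsv(contrasts, "dhs_expression_contrasts.tsv")
    tsv(data.frame(class = rep(c("aml_and_diff", "aml_only", "no_dhs"),
                               grpdist$counts),
                   mean_expr = c(grpdist$aml_and_diff, grpdist$aml_only,
                                 grpdist$no_dhs)),
        "dhs_expression_groups.tsv")
    log_stage("assoc", nrow(contrasts))
  }
  if ("tf" %in% stages) {
    tf_sets <- Filter(function(p) grepl("^TF:", p$assay), ds$marks)
    if (length(tf_sets) == 0L) {
      # emulate a TF track with the H3K27ac peak sets of two AML samples
      k27 <- Filter(function(p) p$assay == "H3K27ac" && p$group == "AML",
                    ds$marks)[1:2]
      tf_sets <- lapply(k27, function(p)
        PeakSet(p$sample_id, "TF:K27ACLIKE", p$group, p$peaks))
    }
    reps <- lapply(seq_along(tf_sets), function(i)
      tf_family_enrichment(tf_sets[[i]], ds$repeats, ds$genome,
                           seed = seed + i))
    out$tf <- aggregate_tf_enrichment(reps)
    tsv(out$tf, "tf_enrichment.tsv")
    log_stage("tf", nrow(out$tf))
  }
  if ("motif" %in% stages) {
    pwms <- lapply(seq_len(nrow(ds$config$planted_motifs)), function(j)
      pwm_from_consensus(ds$config$planted_motifs$consensus[j],
                         motif_id = paste0("planted_",
                                           ds$config$planted_motifs$family[j])))
    cmap <- consensus_motif_map(ds$consensus, pwms, threshold = 6)
    fam_map <- stats::setNames(S4Vectors::mcols(ds$repeats)$family,
                               S4Vectors::mcols(ds$repeats)$element_id)
    seqs <- as.character(ds$element_seqs)
    freq_tabs <- lapply(pwms, function(p) {
      hits <- lapply(seqs, function(s) scan_pwm(s, p, threshold = 6))
      cbind(motif_id = p$motif_id, motif_family_frequency(hits, fam_map))
    })
    out$motif <- list(consensus_map = cmap,
                      family_frequency = do.call(rbind, freq_tabs))
    tsv(cmap, "consensus_motif_map.tsv")
    tsv(out$motif$family_frequency, "motif_family_frequency.tsv")
    log_stage("motif", nrow(cmap))
  }
  if ("crispri" %in% stages) {
    cls <- classify_dcas9_peaks(ds$dcas9, ds$repeats,
                                ds$config$crispri$target_families)
    k27 <- signal_log2_ratio(ds$tracks$H3K27ac_sg, ds$tracks$H3K27ac_ctrl,
                             ds$dcas9, genome = ds$genome)
    k9 <- signal_log2_ratio(ds$tracks$H3K9me3_sg, ds$tracks$H3K9me3_ctrl,
                            ds$dcas9, genome = ds$genome)
    prox <- proximal_genes(cls, ds$genes, de_table = ds$de_table)
    fam_map <- stats::setNames(S4Vectors::mcols(ds$repeats)$family,
                               S4Vectors::mcols(ds$repeats)$element_id)
    gt <- predict_guide_targets(ds$guides, ds$element_seqs, fam_map)
    out$crispri <- list(classification = cls, k27ac_ratio = k27,
                        k9me3_ratio = k9, proximal = prox,
                        guide_targets = gt)
    tsv(data.frame(class = names(cls$counts), n = unname(cls$counts)),
        "dcas9_classes.tsv")
    tsv(cbind(k27, mark = "H3K27ac", class = cls$class),
        "crispri_signal_ratios_k27ac.tsv")
    tsv(cbind(k9, mark = "H3K9me3", class = cls$class),
        "crispri_signal_ratios_k9me3.tsv")
    tsv(prox, "crispri_proximal_genes.tsv")
    tsv(gt$per_family, "guide_targets.tsv")
    log_stage("crispri", length(cls$class))
  }
  prov <- list(
    package = "ervchrom",
    version = as.character(utils::packageVersion("ervchrom")),
    seed = seed, n_shuffles = n_shuffles, stages = stages,
    config_digest = config_digest(ds$config),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# order-stable digest of a config (deparse + sum of char codes; enough to
# detect accidental config drift between runs)
config_digest <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "")]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97)) %%
            .Machine$integer.max)
}
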