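# Shared fixtures, built once per test run. Scaled-down configs keep the
# simulation studies quick while preserving the planted statistical
# structure.

# compact full-featured dataset for module-level tests
cfg_compact <- function(seed = 7, ...) {
  synthetic_config(
    seed = seed,
    chrom_length = 4e5,
    families = data.frame(
      name = c("LTR2B", "LTR2", "LTR5B", "LTR12C"),
      n_copies = c(150, 40, 50, 60),
      length = c(400, 400, 350, 500),
      divergence = c(0.10, 0.10, 0.12, 0.15),
      stringsAsFactors = FALSE),
    n_aml_samples = 10, n_diff_samples = 4, n_cell_lines = 2,
    n_genes = 30, n_links = 4, link_n_active = 4,
    mutation = list(label = "NPM1", n_members = 4,
                    correlation_strength = 0.6),
    crispri = list(target_families = c("LTR2B", "LTR2"),
                   k27ac_depletion = 0.5, k9me3_gain = 2.0,
                   n_offtarget_peaks = 10, guide_length = 20),
    ...)
}

ds_compact <- generate_synthetic(cfg_compact())

toy_genome <- GenomeLayout(c(chrA = 1000, chrB = 800))
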