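# Small scenario presets shared across tests. Sizes are chosen so a
# full generate -> simulate -> analyse loop stays in the seconds range.

tiny_scenario <- function(seed = 11L, ...) {
  args <- list(
    chrom_lengths = stats::setNames(c(40000L, 40000L), c("chr1", "chr2")),
    chloroplast_length = 10000L,
    n_genes = 8L, n_res = 6L, n_pseudo = 2L,
    gene_length = c(800L, 1600L), re_length = c(300L, 800L),
    pseudo_length = c(400L, 800L),
    peak_fixture = NULL,
    groups = "G1", n_replicates = 3L,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, args)
}

# flat landscape: no features, explicit base levels, no shifts
flat_scenario <- function(base = c(CGN = 0.5, CHG = 0.5, CHH = 0.5),
                          seed = 12L, ...) {
  args <- list(
    chrom_lengths = c(chr1 = 60000L), chloroplast_length = 10000L,
    n_genes = 0L, n_res = 0L, n_pseudo = 0L,
    base_levels = base,
    subcontext_multipliers = c(CCG = 1),
    treatment_shift = c(CGN = 0, CHG = 0, CHH = 0),
    peak_fixture = NULL, groups = "G1",
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, args)
}
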