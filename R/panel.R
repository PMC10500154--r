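#' Simulate a two-group site panel for test calibration
#'
#' A site-level simulation used to study the DMS caller's error rates:
#' `n_sites` independent cytosines of one context, two groups of
#' replicates, negative-binomial coverage, and a fraction of sites given
#' a true between-group methylation difference (added to the warm
#' group, clipped to `[0, 1]`). Sites are laid out on one synthetic
#' chromosome far enough apart that they never merge.
#'
#' @param n_sites number of sites.
#' @param n_per_group replicates per group (>= 2).
#' @param coverage_mean,coverage_size negative-binomial depth model.
#' @param base_level baseline methylation probability.
#' @param frac_diff fraction of truly differential sites.
#' @param delta true probability difference at differential sites.
#' @param context context label for the panel.
#' @param seed RNG seed.
#' @return list: `methylome` (long per-sample count table), `design`
#'   (sample_id, group, condition), `truth` (data.table pos, is_diff).
#' @export
simulate_site_panel <- function(n_sites = 20000L, n_per_group = 3L,
                                coverage_mean = 30, coverage_size = 10,
                                base_level = 0.30, frac_diff = 0.05,
                                delta = 0.3, context = "CHG", seed = 1L) {
  stopifnot(n_per_group >= 2L, frac_diff >= 0, frac_diff <= 1)
  set.seed(seed)
  pos <- (seq_len(n_sites) - 1L) * 1000L
  is_diff <- rep(FALSE, n_sites)
  n_diff <- round(frac_diff * n_sites)
  if (n_diff > 0) is_diff[sample.int(n_sites, n_diff)] <- TRUE
  p_cold <- rep(base_level, n_sites)
  p_warm <- pmin(pmax(p_cold + delta * is_diff, 0), 1)
  design <- CJ(condition = c("18C", "28C"),
               replicate = seq_len(n_per_group), sorted = FALSE)
  design[, `:=`(group = "panel",
                sample_id = paste0("panel_", condition, "_r", replicate))]
  tri <- if (context == "CHG") "CAG" else if (context == "CGN") "CGA"
    else "CAA"
  tabs <- lapply(seq_len(nrow(design)), function(j) {
    p <- if (design$condition[j] == "28C") p_warm else p_cold
    cv <- rnbinom(n_sites, mu = coverage_mean, size = coverage_size)
    data.table(sample_id = design$sample_id[j], chrom = "panel_chr",
               pos = pos, strand = "+", tri = tri, context = context,
               mc = rbinom(n_sites, cv, p), cov = cv)
  })
  list(methylome = rbindlist(tabs),
       design = design[, .(sample_id, group, condition, replicate)],
       truth = data.table(pos = pos, is_diff = is_diff))
}
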