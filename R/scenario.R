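#' Scenario configuration for the synthetic methylome world
#'
#' A `scenario_config` object parameterises every aspect of the synthetic
#' data generator: genome layout, per-context methylation levels,
#' trinucleotide (subcontext) multipliers, feature-shape modulation,
#' treatment effects (global shifts and planted DMR intervals, including
#' the shared 50-kb peak fixture), bisulfite sequencing depth and
#' non-conversion, the expression model, and the group design.
#'
#' Methylation context classes follow the plant convention: CGN, CHG and
#' CHH, where H is A, C or T. Default global levels target roughly 55%
#' (CGN), 30% (CHG) and 6% (CHH) weighted methylation, with CCG
#' suppressed relative to CAG/CTG within CHG. Warm-treatment global
#' shifts default to +4/+5/+1 percentage points per context.
#'
#' If `base_levels` is `NULL` (the default), per-context base
#' probabilities are calibrated at truth-simulation time so that the
#' genome-wide weighted mean of the modulated landscape equals
#' `target_levels` per context (anchored global levels). Supplying
#' `base_levels` disables the calibration and uses the values directly.
#'
#' @param chrom_lengths named integer vector of autosome lengths in bp.
#' @param chloroplast_length length of the unmethylated control contig (bp).
#' @param n_genes,n_res,n_pseudo features per autosome.
#' @param gene_length,re_length,pseudo_length length ranges (bp).
#' @param target_levels named per-context genome-wide weighted methylation
#'   targets used for base-level calibration.
#' @param base_levels optional named per-context base probabilities; when
#'   given, used as-is (no calibration).
#' @param subcontext_multipliers named multipliers applied per
#'   trinucleotide (default: CCG at 0.6, all others 1).
#' @param gene_body_level,gene_dip_depth,gene_dip_width gene-body
#'   multiplier and the depth/width (fraction of body length) of the
#'   smooth dips at TSS and TTS.
#' @param re_plateau RE-body multiplier (hypermethylation plateau).
#' @param pseudo_edge_peak,pseudo_edge_width pseudogene edge-bump height
#'   above 1 and width (fraction of body length).
#' @param treatment_shift named per-context global probability shift added
#'   in the warm condition.
#' @param planted_dmrs `data.frame` with columns chrom, start, end
#'   (0-based half-open), shift, context; intervals receive an extra
#'   warm-condition shift. `NULL` for none.
#' @param peak_fixture `data.frame` with columns chrom, window (0-based
#'   50-kb window index); each listed window is filled with
#'   `peak_dmrs_per_window` clustered planted CHG intervals. `NULL` for none.
#' @param peak_dmrs_per_window,peak_dmr_length,peak_dmr_shift geometry and
#'   effect of the clustered intervals planted in fixture windows.
#' @param coverage_mean,coverage_size negative-binomial read-depth model
#'   (mean and size/dispersion parameter).
#' @param epsilon bisulfite non-conversion (false-methylation) rate.
#' @param epsilon_under under-conversion rate of methylated cytosines.
#' @param expr_baseline_mean,expr_dispersion negative-binomial expression
#'   model for a typical gene.
#' @param repression_factor multiplier on the baseline mean for genes with
#'   an RE within `repression_range` bp.
#' @param repression_range distance (bp) within which an RE represses.
#' @param de_fraction fraction of genes truly differentially expressed
#'   between conditions.
#' @param de_log2fc absolute true log2 fold change of DE genes.
#' @param dedmg_coupling fraction of true-DE genes drawn preferentially
#'   from genes carrying a planted DMR in promoter/body.
#' @param groups character vector of group (ecotype) labels.
#' @param conditions character vector of the two temperature labels,
#'   control first.
#' @param n_replicates replicates per group x condition (>= 2).
#' @param seed master seed; all generator randomness derives from it.
#'
#' @return An object of class `scenario_config` (a validated list).
#' @seealso [scenario_baseline()], [scenario_warm_shift()],
#'   [scenario_peaks()], [generate_genome()], [simulate_truth()]
#' @export
scenario_config <- function(chrom_lengths = stats::setNames(rep(300000L, 7),
                                                            paste0("chr", 1:7)),
                            chloroplast_length = 30000L,
                            n_genes = 60L, n_res = 40L, n_pseudo = 10L,
                            gene_length = c(1000L, 3000L),
                            re_length = c(300L, 1500L),
                            pseudo_length = c(500L, 1500L),
                            target_levels = c(CGN = 0.55, CHG = 0.30, CHH = 0.06),
                            base_levels = NULL,
                            subcontext_multipliers = c(CCG = 0.6),
                            gene_body_level = 0.8,
                            gene_dip_depth = 0.5,
                            gene_dip_width = 0.12,
                            re_plateau = 1.5,
                            pseudo_edge_peak = 0.4,
                            pseudo_edge_width = 0.1,
                            treatment_shift = c(CGN = 0.04, CHG = 0.05, CHH = 0.01),
                            planted_dmrs = NULL,
                            peak_fixture = default_peak_fixture(),
                            peak_dmrs_per_window = 12L,
                            peak_dmr_length = 600L,
                            peak_dmr_shift = 0.4,
                            coverage_mean = 30,
                            coverage_size = 10,
                            epsilon = 0.005,
                            epsilon_under = 0,
                            expr_baseline_mean = 100,
                            expr_dispersion = 0.05,
                            repression_factor = 0.5,
                            repression_range = 2000L,
                            de_fraction = 0.1,
                            de_log2fc = 2,
                            dedmg_coupling = 0.5,
                            groups = c("ES12", "ICE2", "IT4", "NOR2"),
                            conditions = c("18C", "28C"),
                            n_replicates = 3L,
                            seed = 1L) {
  sc <- list(
    chrom_lengths = chrom_lengths,
    chloroplast = "chloroplast",
    chloroplast_length = as.integer(chloroplast_length),
    n_genes = as.integer(n_genes), n_res = as.integer(n_res),
    n_pseudo = as.integer(n_pseudo),
    gene_length = as.integer(gene_length), re_length = as.integer(re_length),
    pseudo_length = as.integer(pseudo_length),
    target_levels = target_levels, base_levels = base_levels,
    subcontext_multipliers = subcontext_multipliers,
    gene_body_level = gene_body_level, gene_dip_depth = gene_dip_depth,
    gene_dip_width = gene_dip_width, re_plateau = re_plateau,
    pseudo_edge_peak = pseudo_edge_peak, pseudo_edge_width = pseudo_edge_width,
    treatment_shift = treatment_shift,
    planted_dmrs = planted_dmrs,
    peak_fixture = peak_fixture,
    peak_dmrs_per_window = as.integer(peak_dmrs_per_window),
    peak_dmr_length = as.integer(peak_dmr_length),
    peak_dmr_shift = peak_dmr_shift,
    coverage_mean = coverage_mean, coverage_size = coverage_size,
    epsilon = epsilon, epsilon_under = epsilon_under,
    expr_baseline_mean = expr_baseline_mean,
    expr_dispersion = expr_dispersion,
    repression_factor = repression_factor,
    repression_range = as.integer(repression_range),
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    dedmg_coupling = dedmg_coupling,
    groups = groups, conditions = conditions,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  class(sc) <- "scenario_config"
  validate_scenario(sc)
  sc
}

#' Default shared-peak fixture
#'
#' Eight 50-kb windows, two on each of synthetic chromosomes 2, 3, 5 and
#' 6, that receive clustered planted hyper-CHG intervals in every group.
#'
#' @return data.frame with columns `chrom` and `window` (0-based index).
#' @export
default_peak_fixture <- function() {
  data.frame(
    chrom = rep(c("chr2", "chr3", "chr5", "chr6"), each = 2L),
    window = rep(c(0L, 2L), 4L),
    stringsAsFactors = FALSE
  )
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario_config"))
  if (is.null(names(sc$chrom_lengths)) || any(!nzchar(names(sc$chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(sc$chrom_lengths <= 0L)) stop("chromosome lengths must be positive")
  prob_ok <- function(p) all(p >= 0 & p <= 1)
  if (!prob_ok(sc$target_levels)) stop("target_levels must lie in [0,1]")
  if (!is.null(sc$base_levels) && !prob_ok(sc$base_levels))
    stop("base_levels must lie in [0,1]")
  if (!all(c("CGN", "CHG", "CHH") %in% names(sc$target_levels)))
    stop("target_levels needs CGN, CHG and CHH entries")
  if (any(sc$subcontext_multipliers < 0))
    stop("subcontext multipliers must be non-negative")
  if (sc$epsilon < 0 || sc$epsilon > 0.05)
    stop("epsilon must lie in [0, 0.05]")
  if (sc$coverage_mean <= 0) stop("coverage_mean must be positive")
  if (sc$n_replicates < 2L)
    stop("at least 2 replicates per group x condition are required")
  if (length(sc$conditions) != 2L) stop("exactly two conditions are required")
  if (!is.null(sc$planted_dmrs)) {
    pd <- sc$planted_dmrs
    need <- c("chrom", "start", "end", "shift", "context")
    if (!all(need %in% names(pd)))
      stop("planted_dmrs needs columns: ", paste(need, collapse = ", "))
    bad <- !(pd$chrom %in% names(sc$chrom_lengths)) |
      pd$start < 0 | pd$end > sc$chrom_lengths[pd$chrom] | pd$end <= pd$start
    if (any(bad))
      stop("planted DMR interval outside chromosome bounds (rows ",
           paste(which(bad), collapse = ","), ")")
  }
  if (!is.null(sc$peak_fixture)) {
    pf <- sc$peak_fixture
    if (!all(c("chrom", "window") %in% names(pf)))
      stop("peak_fixture needs columns chrom and window")
    if (anyDuplicated(pf)) stop("peak_fixture windows must be distinct")
    lim <- (pf$window + 1L) * 50000L - sc$peak_dmrs_per_window *
      (sc$peak_dmr_length + 300L)
    if (any(pf$window * 50000L > sc$chrom_lengths[pf$chrom]))
      stop("peak_fixture window outside chromosome bounds")
    if (any(lim < pf$window * 50000L))
      stop("peak fixture windows too small for the requested cluster count")
  }
  invisible(sc)
}

#' Baseline (18C-only) scenario preset
#'
#' The default synthetic world with no treatment applied: used for
#' global-level recovery and profile-shape checks.
#'
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_baseline <- function(seed = 1L, ...) {
  scenario_config(treatment_shift = c(CGN = 0, CHG = 0, CHH = 0),
                  planted_dmrs = NULL, peak_fixture = NULL,
                  seed = seed, ...)
}

#' Warm-shift scenario preset
#'
#' Global per-context warm-condition shifts of +4/+5/+1 percentage points
#' with no planted intervals, so the genome-wide level difference is
#' attributable to the configured shifts alone.
#'
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_warm_shift <- function(seed = 2L, ...) {
  scenario_config(planted_dmrs = NULL, peak_fixture = NULL, seed = seed, ...)
}

#' Shared-peaks scenario preset
#'
#' Clustered hyper-CHG intervals planted in the eight fixture windows
#' (two each on chromosomes 2, 3, 5 and 6) in every group, on a reduced
#' 7 x 150 kb genome so a four-group genome-wide permutation analysis
#' stays desk-scale. 150-kb chromosomes hold three 50-kb windows each.
#'
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_peaks <- function(seed = 3L, ...) {
  scenario_config(
    chrom_lengths = stats::setNames(rep(150000L, 7), paste0("chr", 1:7)),
    n_genes = 30L, n_res = 20L, n_pseudo = 5L,
    peak_fixture = default_peak_fixture(),
    seed = seed, ...
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  genome:", length(x$chrom_lengths), "autosomes,",
      sum(x$chrom_lengths), "bp + chloroplast", x$chloroplast_length, "bp\n")
  cat("  targets: CGN", x$target_levels["CGN"], "CHG", x$target_levels["CHG"],
      "CHH", x$target_levels["CHH"], "\n")
  cat("  warm shift:", paste(sprintf("%s %+0.2f", names(x$treatment_shift),
                                     x$treatment_shift), collapse = ", "), "\n")
  cat("  design:", length(x$groups), "groups x", length(x$conditions),
      "conditions x", x$n_replicates, "replicates\n")
  cat("  coverage:", x$coverage_mean, "x, epsilon", x$epsilon, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Stable per-stream seed derivation: polynomial byte hash of the stream
# label folded into the master seed, kept below 2^31.
derive_seed <- function(master_seed, label) {
  bytes <- as.integer(charToRaw(as.character(label)))
  h <- as.numeric(master_seed) %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}
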