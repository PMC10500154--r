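#' Run the full synthetic analysis pipeline
#'
#' End-to-end flow on a synthetic scenario: genome generation,
#' per-sample bisulfite counts, non-conversion estimation from the
#' chloroplast control, window profiles, per-group DMS/DMR calling per
#' context, DMR annotation and DMG calling, expression simulation with
#' TMM + NB/Wald DE and DEDMG intersection, DMR-density peaks with
#' cross-group sharing, feature-density regression and RE-proximity
#' analysis. Any stage failure halts with the stage name; a manifest
#' records the configuration hash, seed and per-stage tallies.
#'
#' @param scenario a [scenario_config()].
#' @param out_dir optional directory; when given, principal outputs
#'   (FASTA, GFF3, per-sample allc, DMR BED, manifest JSON) are written.
#' @param contexts contexts to test for differential methylation.
#' @param design optional subset of [scenario_design()] rows.
#' @param fdr,min_pooled_cov,B,gap,promoter_len stage parameters (defaults:
#'   empirical FDR 0.003, pooled coverage 30, 1000
#'   permutations, 250 bp merge gap, 2 kb promoters).
#' @param peak_floor minimum DMR count for a density peak.
#' @return (invisibly) a list bundle: genome, design, epsilon, profiles,
#'   dms, dmrs, annotations, dmgs, expression, gene_stats, dedmg, peaks,
#'   regression, proximity, manifest.
#' @export
run_pipeline <- function(scenario, out_dir = NULL,
                         contexts = c("CGN", "CHG", "CHH"),
                         design = NULL, fdr = 0.003, min_pooled_cov = 30L,
                         B = 1000L, gap = 250L, promoter_len = 2000L,
                         peak_floor = 10L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts_log <- list()

  genome <- stage("genome", generate_genome(scenario))
  if (is.null(design)) design <- scenario_design(scenario)
  meth <- stage("simulate", simulate_methylomes(genome, scenario, design))
  counts_log$samples <- nrow(design)

  eps <- stage("nonconversion",
               estimate_nonconversion(meth, genome$control))
  auto <- meth[chrom != genome$control]
  profiles <- stage("profile", {
    per_sample <- auto[, window_profile(.SD, genome$chrom_lengths),
                       by = sample_id]
    per_sample
  })

  dms <- list(); dmrs <- list()
  stage("dmr", {
    for (g in unique(design$group)) {
      dsub <- design[group == g]
      for (cc in contexts) {
        key <- paste(g, cc, sep = ".")
        sites <- call_dms(auto[group == g], dsub, cc, fdr = fdr,
                          min_pooled_cov = min_pooled_cov, B = B,
                          seed = derive_seed(scenario$seed, key),
                          conditions = scenario$conditions)
        dms[[key]] <- sites
        dmrs[[key]] <- merge_dms(sites, gap = gap)
      }
    }
  })
  counts_log$dms <- sum(vapply(dms, nrow, integer(1)))
  counts_log$dmrs <- sum(vapply(dmrs, nrow, integer(1)))

  genes <- genome$features[type == "gene"]
  annotations <- list(); dmgs <- list()
  stage("annotate", {
    for (g in unique(design$group)) {
      keys <- paste(g, contexts, sep = ".")
      all_dmrs <- rbindlist(dmrs[keys], use.names = TRUE)
      ann <- annotate_dmrs(all_dmrs, genes, promoter_len = promoter_len)
      annotations[[g]] <- ann
      dmgs[[g]] <- call_dmgs(ann)
    }
  })

  expression <- stage("expression",
                      simulate_expression(genome, scenario, design,
                                          promoter_len = promoter_len))
  gene_stats <- list(); dedmg <- list()
  stage("de", {
    for (g in unique(design$group)) {
      dsub <- design[group == g]
      cnt <- expression$counts[, dsub$sample_id, drop = FALSE]
      gs <- de_test(cnt, dsub, conditions = scenario$conditions)
      gene_stats[[g]] <- gs
      dedmg[[g]] <- intersect_dedmg(dmgs[[g]]$any, gs[deg == TRUE, gene_id],
                                     gs$gene_id)
    }
  })
  counts_log$degs <- sum(vapply(gene_stats, function(x) sum(x$deg),
                                integer(1)))

  peaks <- stage("peaks", {
    by_group <- lapply(stats::setNames(nm = unique(design$group)),
                       function(g) rbindlist(
                         dmrs[paste(g, contexts, sep = ".")],
                         use.names = TRUE))
    call_peaks(dmr_density(by_group), floor = peak_floor)
  })

  landscape <- stage("landscape", {
    dens <- feature_density(genome$features, genome$chrom_lengths)
    pooled <- window_profile(auto, genome$chrom_lengths)
    list(densities = dens,
         regression = methylation_regression(
           pooled[chrom != genome$control], dens))
  })

  proximity <- stage("proximity", {
    cats <- proximity_categories(genes, genome$features[type == "RE"])
    lapply(gene_stats, function(gs)
      tryCatch(proximity_effect(gs, cats), warning = function(w) NULL,
               error = function(e) NULL))
  })

  cfg <- scenario
  cfg$planted_dmrs <- NULL
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  manifest <- list(config_hash = unname(tools::md5sum(tf)),
                   seed = scenario$seed,
                   epsilon_estimate = eps,
                   stage_counts = counts_log,
                   outputs = character(0))
  unlink(tf)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outs <- c(fasta = file.path(out_dir, "genome.fa"),
              gff3 = file.path(out_dir, "annotation.gff3"),
              dmr_bed = file.path(out_dir, "dmrs.bed"),
              manifest = file.path(out_dir, "manifest.json"))
    write_genome_fasta(genome, outs["fasta"])
    write_genome_gff3(genome, outs["gff3"])
    write_dmr_bed(rbindlist(dmrs, use.names = TRUE), outs["dmr_bed"])
    for (sid in design$sample_id) {
      p <- file.path(out_dir, paste0("allc_", sid, ".tsv"))
      write_allc(meth[sample_id == sid], p)
      outs <- c(outs, p)
    }
    manifest$outputs <- unname(outs)
    jsonlite::write_json(manifest, outs["manifest"], auto_unbox = TRUE,
                         digits = NA)
  }

  invisible(list(genome = genome, design = design, epsilon = eps,
                 profiles = profiles, dms = dms, dmrs = dmrs,
                 annotations = annotations, dmgs = dmgs,
                 expression = expression, gene_stats = gene_stats,
                 dedmg = dedmg, peaks = peaks, landscape = landscape,
                 proximity = proximity, manifest = manifest))
}
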