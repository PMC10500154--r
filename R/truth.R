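#' Simulate the ground-truth methylation landscape (baseline condition)
#'
#' Assigns every cytosine a true methylation probability:
#' per-context base level x subcontext (trinucleotide) multiplier x a
#' smooth feature-shape multiplier. Shapes follow the canonical plant
#' profiles: gene bodies are relatively hypomethylated with smooth dips
#' at TSS and TTS, RE bodies carry a hypermethylation plateau, and
#' pseudogenes peak at their edges. The chloroplast control contig has
#' probability exactly 0.
#'
#' When the scenario leaves `base_levels` unset, base levels are
#' calibrated so the mean probability over autosomal sites of each
#' context equals the scenario `target_levels` (anchored global levels);
#' explicit `base_levels` are applied without calibration, so that e.g.
#' a flat landscape with CGN base 0.55 gives every CGN site exactly 0.55.
#'
#' @param genome a `genome_model` from [generate_genome()].
#' @param scenario the [scenario_config()] used to build it.
#' @return data.table (one row per cytosine, both strands): chrom, pos
#'   (0-based), strand, tri, context, truncated, p_true. Sites whose
#'   context is undeterminable (contig-end truncation) get `NA`
#'   probability and are skipped by the count simulator.
#' @export
simulate_truth <- function(genome, scenario) {
  sites <- find_cytosines(genome)
  feats <- genome$features
  sites[, mult := 1.0]
  ctx_mult <- rep(1.0, nrow(sites))
  sm <- scenario$subcontext_multipliers
  if (length(sm)) {
    idx <- match(sites$tri, names(sm))
    ctx_mult[!is.na(idx)] <- sm[idx[!is.na(idx)]]
  }
  shape <- rep(1.0, nrow(sites))
  if (nrow(feats)) {
    f <- feats[, .(chrom, start, end, strand, type)]
    setkey(f, chrom, start, end)
    pts <- sites[, .(chrom, start = pos, end = pos + 1L)]
    ov <- foverlaps(pts, f, type = "within", which = TRUE, mult = "first")
    hit <- which(!is.na(ov))
    if (length(hit)) {
      fi <- ov[hit]
      p <- sites$pos[hit]
      fs <- f$start[fi]; fe <- f$end[fi]
      u <- (p - fs) / pmax(fe - fs, 1L)
      u[f$strand[fi] == "-"] <- 1 - u[f$strand[fi] == "-"]
      ty <- f$type[fi]
      m <- rep(1.0, length(hit))
      edge <- function(u, w) exp(-(u / w)^2) + exp(-((1 - u) / w)^2)
      g <- ty == "gene"
      m[g] <- scenario$gene_body_level *
        (1 - scenario$gene_dip_depth * edge(u[g], scenario$gene_dip_width))
      m[ty == "RE"] <- scenario$re_plateau
      ps <- ty == "pseudogene"
      m[ps] <- 1 + scenario$pseudo_edge_peak *
        edge(u[ps], scenario$pseudo_edge_width)
      shape[hit] <- m
    }
  }
  sites[, mult := ctx_mult * shape]
  auto <- sites$chrom != genome$control & !is.na(sites$context)
  base <- scenario$base_levels
  if (is.null(base)) {
    base <- scenario$target_levels
    for (cc in c("CGN", "CHG", "CHH")) {
      sel <- auto & sites$context == cc
      mbar <- mean(sites$mult[sel])
      if (is.finite(mbar) && mbar > 0) base[cc] <- base[cc] / mbar
    }
  }
  sites[, p_true := pmin(pmax(base[context] * mult, 0), 1)]
  sites[is.na(context), p_true := NA_real_]
  sites[chrom == genome$control, p_true := 0]
  sites[, mult := NULL]
  sites[]
}

#' Apply the warm-treatment effect to a baseline truth table
#'
#' Adds the scenario's per-context global probability shift plus any
#' planted interval shifts (explicit planted DMRs and the shared-peak
#' fixture clusters), clipping probabilities to `[0, 1]`. The
#' chloroplast control stays exactly 0.
#'
#' @param truth baseline truth table from [simulate_truth()].
#' @param scenario the [scenario_config()].
#' @param control name of the control contig.
#' @return a new truth table for the warm condition.
#' @export
apply_treatment <- function(truth, scenario, control = "chloroplast") {
  out <- copy(truth)
  shift <- scenario$treatment_shift
  out[!is.na(context) & chrom != control,
      p_true := p_true + shift[context]]
  pl <- planted_intervals(scenario)
  if (nrow(pl)) {
    bad <- !(pl$chrom %in% names(scenario$chrom_lengths)) |
      pl$end > scenario$chrom_lengths[pl$chrom] | pl$start < 0
    if (any(bad))
      stop("planted interval outside genome bounds (rows ",
           paste(which(bad), collapse = ","), ")")
    setkey(pl, chrom, start, end)
    pts <- out[, .(chrom, start = pos, end = pos + 1L)]
    ov <- foverlaps(pts, pl, type = "within", nomatch = NULL, which = TRUE)
    if (nrow(ov)) {
      add <- data.table(row = ov$xid, shift = pl$shift[ov$yid],
                        pctx = pl$context[ov$yid])
      add <- add[out$context[row] == pctx | is.na(pctx)]
      out[add$row, p_true := p_true + add$shift]
    }
  }
  out[, p_true := pmin(pmax(p_true, 0), 1)]
  out[chrom == control, p_true := 0]
  out[]
}

#' Simulate bisulfite counts for one sample
#'
#' Draws per-site coverage from a negative-binomial depth model and
#' methylated counts from Binomial(cov, p_obs) where
#' `p_obs = p_true * (1 - epsilon_under) + (1 - p_true) * epsilon`:
#' epsilon is the non-conversion (false-methylation) rate, so control
#' sites have expectation epsilon. Deterministic per (master seed,
#' sample_id).
#'
#' @param truth a truth table (baseline or treated).
#' @param scenario the [scenario_config()].
#' @param sample_id sample label; seeds the sample's random stream.
#' @param contexts optional context filter (e.g. "CHG") to restrict the
#'   simulated site set.
#' @param seed optional explicit seed overriding the derived stream.
#' @return data.table: chrom, pos, strand, tri, context, mc, cov.
#' @export
simulate_counts <- function(truth, scenario, sample_id, contexts = NULL,
                            seed = NULL) {
  stopifnot(scenario$epsilon >= 0, scenario$epsilon <= 0.05,
            scenario$coverage_mean > 0)
  tab <- truth[!is.na(p_true)]
  if (!is.null(contexts)) tab <- tab[context %in% contexts]
  if (is.null(seed)) seed <- derive_seed(scenario$seed, sample_id)
  set.seed(seed)
  n <- nrow(tab)
  cv <- rnbinom(n, mu = scenario$coverage_mean, size = scenario$coverage_size)
  p_obs <- tab$p_true * (1 - scenario$epsilon_under) +
    (1 - tab$p_true) * scenario$epsilon
  m <- rbinom(n, cv, p_obs)
  out <- tab[, .(chrom, pos, strand, tri, context)]
  out[, `:=`(mc = m, cov = cv)]
  out[]
}

#' Full sample design implied by a scenario
#'
#' @param scenario the [scenario_config()].
#' @return data.table: sample_id, group, condition, replicate.
#' @export
scenario_design <- function(scenario) {
  d <- CJ(group = scenario$groups, condition = scenario$conditions,
          replicate = seq_len(scenario$n_replicates), sorted = FALSE)
  d[, sample_id := paste(group, condition, paste0("r", replicate), sep = "_")]
  setcolorder(d, c("sample_id", "group", "condition", "replicate"))
  d[]
}

#' Simulate methylomes for a set of samples
#'
#' Generates a long per-cytosine count table for every sample in the
#' design: baseline truth for the control condition, treated truth for
#' the warm condition. Sample streams are independent and reproducible.
#'
#' @param genome a `genome_model`.
#' @param scenario the [scenario_config()].
#' @param design optional subset of [scenario_design()] rows.
#' @param contexts optional context filter passed to [simulate_counts()].
#' @return data.table with sample metadata columns plus chrom, pos,
#'   strand, tri, context, mc, cov.
#' @export
simulate_methylomes <- function(genome, scenario, design = NULL,
                                contexts = NULL) {
  if (is.null(design)) design <- scenario_design(scenario)
  base <- simulate_truth(genome, scenario)
  warm <- apply_treatment(base, scenario, control = genome$control)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    truth <- if (design$condition[i] == scenario$conditions[1]) base else warm
    tab <- simulate_counts(truth, scenario, design$sample_id[i],
                           contexts = contexts)
    tab[, `:=`(sample_id = design$sample_id[i], group = design$group[i],
               condition = design$condition[i],
               replicate = design$replicate[i])]
    out[[i]] <- tab
  }
  rbindlist(out)
}

#' Simulate an expression count matrix with planted structure
#'
#' Per gene and sample, negative-binomial counts around a baseline mean.
#' Genes with an RE within `repression_range` bp (boundary-to-boundary,
#' 0 if overlapping) have their mean multiplied by the repression
#' factor. A `de_fraction` of genes are true DEs between conditions with
#' log2 fold change of +/- `de_log2fc`; a `dedmg_coupling` share of the
#' DE slots is drawn preferentially from genes carrying a planted
#' differential interval in their promoter or body (DEDMG coupling).
#'
#' @param genome a `genome_model`.
#' @param scenario the [scenario_config()].
#' @param design optional subset of [scenario_design()] rows.
#' @param promoter_len promoter width used for the planted-DMG overlap.
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   and `truth` (data.table: gene_id, re_within, is_planted_dmg, is_de,
#'   true_lfc).
#' @export
simulate_expression <- function(genome, scenario, design = NULL,
                                promoter_len = 2000L) {
  if (is.null(design)) design <- scenario_design(scenario)
  genes <- genome$features[type == "gene"]
  if (nrow(genes) == 0L) stop("genome has no genes")
  res <- genome$features[type == "RE"]
  set.seed(derive_seed(scenario$seed, "expression"))
  nd <- if (nrow(res)) {
    nearest_feature_distance(genes, res)
  } else rep(Inf, nrow(genes))
  re_within <- nd <= scenario$repression_range

  pl <- planted_intervals(scenario)
  planted_dmg <- rep(FALSE, nrow(genes))
  if (nrow(pl)) {
    reg <- gene_regulatory_spans(genes, promoter_len)
    setkey(pl, chrom, start, end)
    ov <- foverlaps(reg, pl, type = "any", which = TRUE, nomatch = NULL)
    planted_dmg[unique(ov$xid)] <- TRUE
  }

  G <- nrow(genes)
  n_de <- round(scenario$de_fraction * G)
  is_de <- rep(FALSE, G)
  if (n_de > 0) {
    from_dmg <- which(planted_dmg)
    k <- min(length(from_dmg), round(scenario$dedmg_coupling * n_de))
    pick <- if (k > 0) sample(from_dmg, k) else integer(0)
    rest <- setdiff(seq_len(G), pick)
    pick <- c(pick, sample(rest, n_de - k))
    is_de[pick] <- TRUE
  }
  true_lfc <- numeric(G)
  true_lfc[is_de] <- scenario$de_log2fc * sample(c(-1, 1), sum(is_de),
                                                 replace = TRUE)
  mu0 <- rep(scenario$expr_baseline_mean, G)
  mu0[re_within] <- mu0[re_within] * scenario$repression_factor

  counts <- matrix(0L, nrow = G, ncol = nrow(design),
                   dimnames = list(genes$feature_id, design$sample_id))
  warm <- design$condition == scenario$conditions[2]
  for (j in seq_len(nrow(design))) {
    set.seed(derive_seed(scenario$seed,
                         paste0("expr_", design$sample_id[j])))
    mu <- if (warm[j]) mu0 * 2^true_lfc else mu0
    counts[, j] <- rnbinom(G, mu = mu, size = 1 / scenario$expr_dispersion)
  }
  truth <- data.table(gene_id = genes$feature_id, re_within = re_within,
                      is_planted_dmg = planted_dmg, is_de = is_de,
                      true_lfc = true_lfc)
  list(counts = counts, design = design, truth = truth)
}

# boundary-to-boundary distance from each gene to its nearest RE
nearest_feature_distance <- function(genes, others) {
  ga <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  ra <- GenomicRanges::GRanges(others$chrom,
                               IRanges::IRanges(others$start + 1L, others$end))
  hit <- GenomicRanges::distanceToNearest(ga, ra)
  d <- rep(Inf, length(ga))
  d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  d
}

# strand-aware promoter + body span per gene (0-based half-open), keyed
gene_regulatory_spans <- function(genes, promoter_len) {
  reg <- genes[, .(chrom,
                   start = fifelse(strand == "+", start - promoter_len, start),
                   end = fifelse(strand == "+", end, end + promoter_len),
                   gene_id = feature_id)]
  reg[, start := pmax(start, 0L)]
  setkey(reg, chrom, start, end)
  reg
}
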