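#' Annotate DMRs to genomic features
#'
#' Assigns each DMR, by its midpoint, to exactly one category in
#' precedence order: promoter (`[TSS - promoter_len, TSS)` strand-aware),
#' gene body (`[TSS, TTS]`), downstream (`(TTS, TTS + promoter_len]`),
#' else intergenic. When the midpoint sits in the same category of
#' several genes, the lexicographically smallest gene id wins and the
#' tie is reported via a message. The signed distance from the nearest
#' TSS to the DMR midpoint (negative upstream, positive downstream, in
#' the gene's 5'->3' orientation) is always reported.
#'
#' @param dmrs DMR table ([merge_dms()] output; 0-based half-open).
#' @param genes data.table of gene models: chrom, start, end, strand,
#'   feature_id (e.g. `genome_model$features[type == "gene"]`).
#' @param promoter_len promoter/downstream width in bp (default 2000).
#' @return the DMR table with added `midpoint`, `category`,
#'   `target_gene` (NA when intergenic) and `distance` columns.
#' @export
annotate_dmrs <- function(dmrs, genes, promoter_len = 2000L) {
  if (any(is.na(genes$strand)) || !all(genes$strand %in% c("+", "-")))
    stop("all gene models must be stranded")
  out <- copy(dmrs)
  out[, midpoint := as.integer((start + end) %/% 2L)]
  if (nrow(out) == 0L) {
    out[, `:=`(category = character(), target_gene = character(),
               distance = integer())]
    return(out[])
  }
  plus <- genes$strand == "+"
  zones <- rbindlist(list(
    data.table(chrom = genes$chrom,
               start = fifelse(plus, genes$start - promoter_len, genes$end),
               end = fifelse(plus, genes$start, genes$end + promoter_len),
               gene_id = genes$feature_id, category = "promoter",
               priority = 1L),
    data.table(chrom = genes$chrom, start = genes$start, end = genes$end,
               gene_id = genes$feature_id, category = "gene body",
               priority = 2L),
    data.table(chrom = genes$chrom,
               start = fifelse(plus, genes$end, genes$start - promoter_len),
               end = fifelse(plus, genes$end + promoter_len, genes$start),
               gene_id = genes$feature_id, category = "downstream",
               priority = 3L)
  ))
  zones <- zones[end > start]
  setkey(zones, chrom, start, end)
  pts <- out[, .(chrom, start = midpoint, end = midpoint + 1L,
                 row = .I)]
  ov <- foverlaps(pts, zones, type = "within", nomatch = NULL)
  out[, `:=`(category = "intergenic", target_gene = NA_character_)]
  if (nrow(ov)) {
    setorder(ov, row, priority, gene_id)
    ties <- ov[, .N, by = .(row, priority)][N > 1L]
    best <- ov[, .SD[1], by = row]
    if (best[ties, on = .(row, priority), nomatch = NULL][, .N] > 0L)
      message("annotate_dmrs: ", nrow(ties),
              " midpoint(s) equidistant between genes; ",
              "assigned to the lexicographically smaller gene id")
    out[best$row, `:=`(category = best$category, target_gene = best$gene_id)]
  }
  # signed distance to the nearest TSS, in each gene's orientation
  tss <- data.table(chrom = genes$chrom,
                    tss = fifelse(plus, genes$start, genes$end - 1L),
                    sgn = fifelse(plus, 1L, -1L))
  out[, distance := {
    d <- vapply(seq_len(.N), function(i) {
      cand <- tss[chrom == out$chrom[i]]
      if (nrow(cand) == 0L) return(NA_integer_)
      dd <- (out$midpoint[i] - cand$tss) * cand$sgn
      dd[which.min(abs(dd))]
    }, integer(1))
    d
  }]
  out[]
}

#' Call differentially methylated genes (DMGs)
#'
#' A gene is a DMG for context c iff at least one DMR of context c is
#' annotated to its promoter or gene body (downstream-only annotations
#' do not qualify). The any-context set is the union across contexts.
#'
#' @param annotations output of [annotate_dmrs()] (must retain the
#'   `context` column).
#' @return list with one character vector of gene ids per context plus
#'   `any` (the union).
#' @export
call_dmgs <- function(annotations) {
  hits <- annotations[category %in% c("promoter", "gene body") &
                        !is.na(target_gene)]
  out <- lapply(c(CGN = "CGN", CHG = "CHG", CHH = "CHH"), function(cc)
    sort(unique(hits[context == cc, target_gene])))
  out$any <- sort(unique(hits$target_gene))
  out
}

#' TMM library-size scaling factors
#'
#' Trimmed-mean-of-M-values normalization: the reference sample is the
#' one whose upper quartile is closest to the mean upper quartile;
#' per-sample log ratios (M) and log abundances (A) over genes positive
#' in both are trimmed (30% of M, 5% of A) and the factor is the
#' precision-weighted mean of the retained M values, with factors
#' renormalized to geometric mean 1. Computed via
#' [edgeR::calcNormFactors()].
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return named numeric vector of scaling factors.
#' @export
tmm_factors <- function(counts) {
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Negative-binomial Wald test for differential expression
#'
#' A compact GLM/Wald engine: counts are modelled per gene as negative
#' binomial with a condition effect and TMM-scaled library-size offsets.
#' Per-gene dispersions are method-of-moments estimates (floored at
#' 1e-8), shrunk 50/50 toward the trimmed mean dispersion of
#' similar-abundance genes. The Wald statistic on the condition
#' log2-fold-change is referred to a t distribution with the residual
#' degrees of freedom (a small-sample correction appropriate for
#' triplicate designs); p-values are BH-adjusted. The DEG flag uses raw
#' p <= `p_threshold` and |FC| >= `fc_threshold` by default; set
#' `use_padj = TRUE` for the adjusted-p variant.
#'
#' @param counts genes x samples integer matrix.
#' @param design data.table with `sample_id` and `condition` matching
#'   the matrix columns.
#' @param factors optional TMM factors (computed when `NULL`).
#' @param conditions length-2 character, control label first; defaults
#'   to sorted unique conditions.
#' @param p_threshold,fc_threshold DEG thresholds (defaults 0.05, 1.5).
#' @param use_padj flag DEGs on BH-adjusted instead of raw p.
#' @return data.table: gene_id, mean_expr (mean normalized abundance),
#'   log2fc (warm vs control), pvalue, padj, deg.
#' @export
de_test <- function(counts, design, factors = NULL, conditions = NULL,
                    p_threshold = 0.05, fc_threshold = 1.5,
                    use_padj = FALSE) {
  if (is.null(conditions)) conditions <- sort(unique(design$condition))
  stopifnot(length(conditions) == 2L)
  design <- design[match(colnames(counts), design$sample_id)]
  if (any(is.na(design$sample_id)))
    stop("design does not describe every count column")
  for (cond in conditions)
    if (sum(design$condition == cond) < 2L)
      stop("condition '", cond, "' has fewer than 2 replicates: ",
           "degenerate design")
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff_lib <- colSums(counts) * factors
  sf <- eff_lib / mean(eff_lib)
  norm <- sweep(counts, 2, sf, "/")
  cond <- factor(design$condition, levels = conditions)
  warm <- cond == conditions[2]

  # method-of-moments dispersion per gene, pooled across conditions
  mom_disp <- function(y) {
    ests <- vapply(list(y[!warm], y[warm]), function(v) {
      m <- mean(v); s2 <- var(v)
      if (m <= 0) return(NA_real_)
      (s2 - m) / m^2
    }, numeric(1))
    if (all(is.na(ests))) return(1e-8)
    max(mean(ests, na.rm = TRUE), 1e-8)
  }
  disp_raw <- apply(norm, 1, mom_disp)
  mean_expr <- rowMeans(norm)
  nb <- max(2L, min(20L, nrow(counts) %/% 25L))
  bin <- cut(rank(mean_expr, ties.method = "first"), breaks = nb,
             labels = FALSE)
  trend <- vapply(split(disp_raw, bin), mean, numeric(1), trim = 0.25,
                  na.rm = TRUE)
  disp <- pmax(0.5 * disp_raw + 0.5 * trend[bin], 1e-8)

  off <- log(eff_lib)
  df_resid <- length(cond) - 2L
  fit_one <- function(i) {
    y <- counts[i, ]
    if (all(y == y[1])) return(c(0, 1))  # identical counts: no effect
    fam <- MASS::negative.binomial(theta = 1 / disp[i])
    fit <- tryCatch(
      suppressWarnings(glm(y ~ cond + offset(off), family = fam)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(coef(fit)[2])) return(c(NA_real_, NA_real_))
    sm <- suppressWarnings(summary(fit)$coefficients)
    z <- sm[2, 1] / sm[2, 2]
    c(sm[2, 1] / log(2), 2 * pt(-abs(z), df = df_resid))
  }
  res <- vapply(seq_len(nrow(counts)), fit_one, numeric(2))
  out <- data.table(gene_id = rownames(counts), mean_expr = mean_expr,
                    log2fc = res[1, ], pvalue = res[2, ])
  out[, padj := p.adjust(pvalue, method = "BH")]
  pcol <- if (use_padj) out$padj else out$pvalue
  out[, deg := !is.na(pvalue) & pcol <= p_threshold &
        abs(log2fc) >= log2(fc_threshold)]
  out[]
}

#' DEDMG intersection with overlap-enrichment statistics
#'
#' DEDMGs are genes that are simultaneously differentially methylated
#' (any context) and differentially expressed. Enrichment of the overlap
#' is the hypergeometric upper tail (equivalently the one-sided Fisher
#' exact test) of observing at least `O` shared genes when drawing
#' `nB` from a universe of `N` containing `nA` marked genes, with
#' representation factor `RF = O / (nA * nB / N)`.
#'
#' @param dmg_genes character vector of DMG ids (any context).
#' @param deg_genes character vector of DEG ids.
#' @param universe character vector of tested genes (the DE universe).
#' @return list: `dedmg` (sorted ids), `n_dmg`, `n_deg`, `overlap`,
#'   `universe_size`, `rf`, `p_value`, and `dedmg_fraction`
#'   (overlap / n_dmg, the share of DMGs that are also DEGs).
#' @export
intersect_dedmg <- function(dmg_genes, deg_genes, universe) {
  N <- length(unique(universe))
  if (N < length(unique(dmg_genes)) || N < length(unique(deg_genes)))
    stop("universe smaller than one of the gene sets")
  dmg_genes <- intersect(unique(dmg_genes), universe)
  deg_genes <- intersect(unique(deg_genes), universe)
  nA <- length(dmg_genes); nB <- length(deg_genes)
  O <- length(intersect(dmg_genes, deg_genes))
  rf <- if (nA == 0 || nB == 0) 0 else O / (nA * nB / N)
  p <- if (nA == 0 || nB == 0) 1 else
    phyper(O - 1L, nA, N - nA, nB, lower.tail = FALSE)
  list(dedmg = sort(intersect(dmg_genes, deg_genes)),
       n_dmg = nA, n_deg = nB, overlap = O, universe_size = N,
       rf = rf, p_value = p,
       dedmg_fraction = if (nA > 0) O / nA else NA_real_)
}

#' Venn-style sharing counts across groups
#'
#' For k named gene sets, counts every one of the 2^k - 1 membership
#' patterns; pattern counts sum to the union size. Also reports the
#' fraction of each group's set unique to that group.
#'
#' @param sets named list of character vectors.
#' @return list with `patterns` (data.table: one logical column per
#'   group, `pattern` label, `n`) and `unique_fraction` (named numeric).
#' @export
shared_sets <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  univ <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 0L)
    memb <- matrix(logical(0), ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(univ))
  colnames(memb) <- names(sets)
  key <- apply(memb, 1, function(r)
    paste(names(sets)[r], collapse = "+"))
  pats <- do.call(CJ, c(stats::setNames(
    rep(list(c(FALSE, TRUE)), length(sets)), names(sets)), sorted = FALSE))
  pats <- pats[rowSums(pats) > 0]
  pats[, pattern := apply(.SD, 1, function(r)
    paste(names(sets)[as.logical(r)], collapse = "+")),
    .SDcols = names(sets)]
  cnt <- table(key)
  pats[, n := as.integer(ifelse(pattern %in% names(cnt),
                                cnt[pattern], 0L))]
  only <- vapply(names(sets), function(g) {
    tot <- length(sets[[g]])
    if (tot == 0) return(NA_real_)
    sum(memb[, g] & rowSums(memb) == 1L) / tot
  }, numeric(1))
  list(patterns = pats[], unique_fraction = only)
}
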