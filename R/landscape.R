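#' Windowed DMR density
#'
#' Assigns each DMR to the 50-kb window containing its midpoint
#' (half-open rule: a midpoint at `i*w` belongs to window i) and counts
#' DMRs per (group, context, chromosome, window).
#'
#' @param dmrs a DMR table, or a named list of DMR tables (names become
#'   group labels).
#' @param w window size in bp (default 50000).
#' @return data.table: group, context, chrom, window, count.
#' @export
dmr_density <- function(dmrs, w = 50000L) {
  if (is.data.frame(dmrs)) dmrs <- list(all = dmrs)
  out <- rbindlist(lapply(names(dmrs), function(g) {
    x <- dmrs[[g]]
    if (nrow(x) == 0L) return(NULL)
    x[, .(group = g, context, chrom,
          window = as.integer(((start + end) %/% 2L) %/% w))]
  }))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.table(group = character(), context = character(),
                      chrom = character(), window = integer(),
                      count = integer()))
  }
  out[, .(count = .N), by = .(group, context, chrom, window)]
}

#' Call DMR-density peaks and cross-group shared peaks
#'
#' A window is a peak for a (group, context) iff its DMR count reaches
#' `max(floor, q)` where `q` is the `quantile` of that group/context's
#' nonzero window counts; with fewer than 10 nonzero windows the
#' quantile is skipped and only the floor applies (reported via a
#' message). A shared peak is a window that is a peak in every group.
#'
#' @param density output of [dmr_density()].
#' @param floor minimum DMR count (default 10).
#' @param quantile empirical quantile of nonzero counts (default 0.99);
#'   `NULL` disables the quantile component (floor-only rule, the
#'   reproducible choice for planted fixtures).
#' @return list: `peaks` (data.table group, context, chrom, window,
#'   count, threshold, peak) and `shared` (data.table context, chrom,
#'   window with peaks present in all groups).
#' @export
call_peaks <- function(density, floor = 10L, quantile = 0.99) {
  if (nrow(density) == 0L) {
    return(list(peaks = data.table(group = character(), context = character(),
                                   chrom = character(), window = integer(),
                                   count = integer(), threshold = numeric(),
                                   peak = logical()),
                shared = data.table(context = character(), chrom = character(),
                                    window = integer())))
  }
  qv <- quantile
  pk <- copy(density)
  pk[, threshold := {
    nz <- count[count > 0]
    if (is.null(qv)) {
      as.numeric(floor)
    } else if (length(nz) < 10L) {
      message("call_peaks: fewer than 10 nonzero windows for ",
              group[1], "/", context[1], "; floor-only threshold")
      as.numeric(floor)
    } else max(as.numeric(floor), stats::quantile(nz, qv))
  }, by = .(group, context)]
  pk[, peak := count >= threshold]
  groups <- unique(pk$group)
  shared <- pk[peak == TRUE, .(n_groups = uniqueN(group)),
               by = .(context, chrom, window)][n_groups == length(groups),
                                               .(context, chrom, window)]
  setorder(shared, context, chrom, window)
  list(peaks = pk[], shared = shared[])
}

#' Windowed feature density
#'
#' Per window and feature type, the fraction of window bases covered by
#' the union of that type's intervals.
#'
#' @param features feature table (chrom, start, end, type; 0-based
#'   half-open), e.g. `genome_model$features`.
#' @param chrom_lengths named contig lengths or a `genome_model`.
#' @param w window size in bp (default 50000).
#' @return data.table: chrom, window, gene_density, re_density,
#'   pseudo_density.
#' @export
feature_density <- function(features, chrom_lengths, w = 50000L) {
  if (inherits(chrom_lengths, "genome_model"))
    chrom_lengths <- chrom_lengths$chrom_lengths
  grid <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    nw <- ceiling(chrom_lengths[[cn]] / w)
    data.table(chrom = cn, window = seq_len(nw) - 1L)
  }))
  win <- GenomicRanges::GRanges(
    grid$chrom, IRanges::IRanges(grid$window * w + 1L,
                                 pmin((grid$window + 1L) * w,
                                      chrom_lengths[grid$chrom])))
  for (ty in c("gene", "RE", "pseudogene")) {
    colnm <- c(gene = "gene_density", RE = "re_density",
               pseudogene = "pseudo_density")[[ty]]
    ff <- features[type == ty]
    val <- numeric(nrow(grid))
    if (nrow(ff)) {
      red <- GenomicRanges::reduce(GenomicRanges::GRanges(
        ff$chrom, IRanges::IRanges(ff$start + 1L, ff$end)))
      hits <- GenomicRanges::findOverlaps(win, red)
      if (length(hits)) {
        ints <- GenomicRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                          red[S4Vectors::subjectHits(hits)])
        bp <- tapply(GenomicRanges::width(ints), S4Vectors::queryHits(hits),
                     sum)
        val[as.integer(names(bp))] <- bp / w
      }
    }
    grid[, (colnm) := val]
  }
  grid[]
}

#' Regress window methylation on feature densities
#'
#' Ordinary least squares of the window weighted methylation level on
#' gene, RE and pseudogene density, fitted per context over windows
#' with defined methylation. Collinear predictors are reported with a
#' condition-number warning and fitted with aliased terms dropped.
#'
#' @param profiles output of [window_profile()].
#' @param densities output of [feature_density()].
#' @return named list per context: coefficients (intercept,
#'   gene_density, re_density, pseudo_density), r_squared, n.
#' @export
methylation_regression <- function(profiles, densities) {
  dat <- densities[profiles, on = .(chrom, window)]
  out <- list()
  for (cc in c("CGN", "CHG", "CHH")) {
    d <- dat[context == cc & !is.na(level)]
    if (nrow(d) < 5L) { out[[cc]] <- NULL; next }
    X <- as.matrix(d[, .(gene_density, re_density, pseudo_density)])
    kappa_val <- tryCatch(kappa(cbind(1, X)), error = function(e) Inf)
    if (!is.finite(kappa_val) || kappa_val > 1e8)
      warning("near-collinear predictors for context ", cc,
              " (condition number ", format(kappa_val, digits = 3), ")")
    fit <- lm(level ~ gene_density + re_density + pseudo_density, data = d)
    out[[cc]] <- list(coefficients = coef(fit),
                      r_squared = suppressWarnings(summary(fit)$r.squared),
                      n = nrow(d))
  }
  out
}

#' RE-proximity categories for genes
#'
#' Classifies genes by the boundary-to-boundary distance to the closest
#' repetitive element: within 2 kb (including overlap, distance 0),
#' 2-5 kb, 5-10 kb, or no RE within 10 kb. Category edges are closed on
#' the right (a distance of exactly 2000 bp is "within 2 kb").
#'
#' @param genes gene table (chrom, start, end, feature_id).
#' @param res RE table (chrom, start, end).
#' @param edges category boundaries in bp (default 2000, 5000, 10000).
#' @return data.table: gene_id, distance (bp; Inf when no RE on the
#'   chromosome), category (ordered factor).
#' @export
proximity_categories <- function(genes, res,
                                 edges = c(2000L, 5000L, 10000L)) {
  labs <- c("RE_within_2kb", "RE_2_5kb", "RE_5_10kb", "no_RE_within_10kb")
  d <- if (nrow(res)) nearest_feature_distance(genes, res) else
    rep(Inf, nrow(genes))
  cat <- cut(d, breaks = c(-1, edges, Inf), labels = labs, right = TRUE)
  data.table(gene_id = genes$feature_id, distance = d,
             category = factor(as.character(cat), levels = labs))
}

#' Games-Howell pairwise comparisons
#'
#' Post-hoc pairwise tests that assume neither equal variances nor equal
#' group sizes: for groups i, j the statistic is
#' `t = (mean_i - mean_j) / sqrt(s2_i/n_i + s2_j/n_j)` with
#' Welch-Satterthwaite degrees of freedom, and the p-value comes from
#' the studentized-range distribution with k groups evaluated at
#' `q = |t| * sqrt(2)`.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (>= 2 groups, each n >= 3).
#' @return data.table: group1, group2, diff, t, df, p_value.
#' @export
games_howell <- function(values, groups) {
  groups <- as.character(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  gl <- sort(unique(groups))
  k <- length(gl)
  if (k < 2L) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)[gl]
  if (any(ns < 3L)) stop("every group needs n >= 3")
  ms <- tapply(values, groups, mean)[gl]
  vs <- tapply(values, groups, var)[gl]
  pairs <- utils::combn(gl, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    dd <- ms[i] - ms[j]
    if (se2 == 0) {
      p <- if (dd == 0) 1 else {
        warning("zero variance with unequal means for pair ", i, "-", j)
        0
      }
      return(c(dd, if (dd == 0) 0 else Inf, Inf, p))
    }
    tt <- dd / sqrt(se2)
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) +
                     (vs[j] / ns[j])^2 / (ns[j] - 1))
    p <- ptukey(abs(tt) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    c(dd, tt, df, p)
  })
  data.table(group1 = pairs[1, ], group2 = pairs[2, ],
             diff = res[1, ], t = res[2, ], df = res[3, ],
             p_value = res[4, ])
}

#' RE-proximity effect on expression
#'
#' Two analyses over the proximity categories: (a) normalized abundance
#' per gene by category, and (b) absolute log2 fold change (warm vs
#' control) by category, each summarized and compared pairwise with
#' Games-Howell. Categories with fewer than 3 genes are excluded with a
#' warning.
#'
#' @param gene_stats [de_test()] output (gene_id, mean_expr, log2fc).
#' @param categories [proximity_categories()] output.
#' @return list of two elements (`abundance`, `abs_log2fc`), each with
#'   `summary` (per-category n, mean, sd) and `pairwise` (Games-Howell
#'   table).
#' @export
proximity_effect <- function(gene_stats, categories) {
  dat <- categories[gene_stats, on = "gene_id", nomatch = NULL]
  run <- function(vals) {
    d <- data.table(category = as.character(dat$category), value = vals)
    d <- d[is.finite(value)]
    sizes <- d[, .N, by = category]
    drop <- sizes[N < 3L, category]
    if (length(drop))
      warning("excluding categor", if (length(drop) > 1) "ies" else "y",
              " with < 3 genes: ", paste(drop, collapse = ", "))
    d <- d[!category %in% drop]
    list(summary = d[, .(n = .N, mean = mean(value), sd = sd(value)),
                     by = category],
         pairwise = if (uniqueN(d$category) >= 2L)
           games_howell(d$value, d$category) else NULL)
  }
  list(abundance = run(dat$mean_expr),
       abs_log2fc = run(abs(dat$log2fc)))
}

#' PCA of sample-level window methylation profiles
#'
#' Centered singular value decomposition of the samples x windows level
#' matrix (windows with undefined levels in any sample are dropped).
#'
#' @param profiles long table with columns sample_id, chrom, window,
#'   context, level (e.g. [window_profile()] computed per sample and
#'   stacked).
#' @param context optional single context to use; `NULL` uses all.
#' @return list: `scores` (samples x PCs), `variance_fraction`.
#' @export
pca_windows <- function(profiles, context = NULL) {
  tab <- profiles
  if (!is.null(context)) {
    cc <- context
    tab <- tab[context == cc]
  }
  wide <- dcast(tab, sample_id ~ chrom + window + context,
                value.var = "level")
  if (nrow(wide) < 2L) stop("need at least 2 samples for PCA")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = pc$x,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2))
}

utils::globalVariables(c("value", "n_groups", "threshold", "sgn", "row",
                         "priority", "pattern"))
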