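#' Root-mean-square heterogeneity statistic for one site
#'
#' For per-sample methylated counts `m` and coverages `n`, with
#' per-sample frequencies `f_i = m_i / n_i` and pooled frequency
#' `p = sum(m) / sum(n)`, the statistic is the root mean square of the
#' standardized (Pearson) deviations of the s x 2 count table:
#' `d = sqrt(mean(n_i * (f_i - p)^2 / (p * (1 - p))))`, i.e.
#' `sqrt(X^2 / s)` with `X^2` the Pearson chi-square statistic.
#' Standardizing by the per-sample binomial variance makes the null
#' distribution of `d` comparable across sites of different coverage,
#' which is what lets null statistics be pooled genome-wide for
#' empirical-FDR control. `d` is zero iff all sample frequencies are
#' equal (including the degenerate pooled levels 0 and 1) and is
#' invariant to sample order.
#'
#' @param m integer vector of methylated counts.
#' @param n integer vector of coverages (all > 0).
#' @return non-negative scalar d.
#' @export
rms_statistic <- function(m, n) {
  stopifnot(length(m) == length(n), all(n > 0), all(m >= 0), all(m <= n))
  f <- m / n
  p <- sum(m) / sum(n)
  if (p <= 0 || p >= 1) return(0)
  sqrt(mean(n * (f - p)^2 / (p * (1 - p))))
}

#' Parametric-bootstrap null distribution of the RMS statistic
#'
#' Draws `B` replicate tables `m_i* ~ Binomial(n_i, p)` with `p` the
#' pooled frequency, recomputing the statistic each time. The
#' permutation p-value is `(1 + #(d* >= d)) / (B + 1)`.
#'
#' @param m,n observed counts and coverages for one site.
#' @param B number of replicates (>= 100).
#' @param seed RNG seed.
#' @return list with `d` (observed), `null` (B replicate statistics) and
#'   `p_value`.
#' @export
permutation_null <- function(m, n, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L)
  d <- rms_statistic(m, n)
  p <- sum(m) / sum(n)
  set.seed(seed)
  s <- length(n)
  draws <- matrix(rbinom(s * B, size = n, prob = p), nrow = s)
  fstar <- draws / n
  pstar <- colSums(draws) / sum(n)
  qstar <- pstar * (1 - pstar)
  null <- colMeans(n * (fstar - rep(pstar, each = s))^2)
  null <- sqrt(ifelse(qstar > 0, null / qstar, 0))
  list(d = d, null = null, p_value = (1 + sum(null >= d)) / (B + 1))
}

#' Filter candidate sites by coverage
#'
#' Retains sites of the requested context where the pooled coverage over
#' all samples is at least `min_pooled_cov` (default 30) and every
#' sample covers the site at least once, and assembles the per-site
#' count matrices used by the test.
#'
#' @param methylome long per-sample count table (columns sample_id,
#'   chrom, pos, strand, context, mc, cov).
#' @param design data.table with sample_id and condition (two levels).
#' @param context context class to test.
#' @param min_pooled_cov pooled coverage floor (inclusive).
#' @return list with `sites` (data.table chrom, pos, strand), `m` and
#'   `n` (site x sample matrices, columns ordered as `design$sample_id`).
#' @export
filter_sites <- function(methylome, design, context, min_pooled_cov = 30L) {
  ctx <- context
  tab <- methylome[context == ctx & sample_id %in% design$sample_id]
  wide_n <- dcast(tab, chrom + pos + strand ~ sample_id, value.var = "cov",
                  fill = 0L)
  wide_m <- dcast(tab, chrom + pos + strand ~ sample_id, value.var = "mc",
                  fill = 0L)
  cols <- design$sample_id
  n <- as.matrix(wide_n[, ..cols])
  m <- as.matrix(wide_m[, ..cols])
  keep_rows <- rowSums(n) >= min_pooled_cov & rowSums(n > 0) == ncol(n)
  list(sites = wide_n[keep_rows, .(chrom, pos, strand)],
       m = m[keep_rows, , drop = FALSE],
       n = n[keep_rows, , drop = FALSE])
}

# Vectorised permutation engine over all sites at once.
# Returns per-site observed d, permutation p-values, and the pooled
# empirical-FDR curve evaluated at every observed d.
rms_perm_engine <- function(m, n, B = 1000L, seed = 1L, chunk = 25L) {
  S <- nrow(m); s <- ncol(m)
  nsum <- rowSums(n)
  pbar <- rowSums(m) / nsum
  qbar <- pbar * (1 - pbar)
  std_rms <- function(M, pb) {
    qq <- pb * (1 - pb)
    v <- rowMeans(n * (M / n - pb)^2)
    sqrt(ifelse(qq > 0, v / qq, 0))
  }
  d <- std_rms(m, pbar)
  ord <- order(d)
  dsorted <- d[ord]
  exceed <- integer(S)
  null_ge <- numeric(S)       # pooled #(d* >= t) accumulated at t = dsorted
  set.seed(seed)
  done <- 0L
  nvec <- as.vector(n)
  while (done < B) {
    k <- min(chunk, B - done)
    draws <- matrix(rbinom(S * s * k, size = rep(nvec, k),
                           prob = rep(pbar, s * k)),
                    nrow = S)
    for (j in seq_len(k)) {
      idx <- ((j - 1L) * s + 1L):(j * s)
      Mj <- draws[, idx, drop = FALSE]
      pbj <- rowSums(Mj) / nsum
      dstar <- std_rms(Mj, pbj)
      exceed <- exceed + (dstar >= d)
      ds <- sort(dstar)
      null_ge <- null_ge + (S - findInterval(dsorted, ds, left.open = TRUE))
    }
    done <- done + k
  }
  obs_ge <- S - findInterval(dsorted, dsorted, left.open = TRUE)
  list(d = d, p_value = (1 + exceed) / (B + 1),
       thresholds = dsorted, mean_null_ge = null_ge / B, obs_ge = obs_ge)
}

#' Call differentially methylated sites (DMSs)
#'
#' The site-level engine: per filtered site, the RMS heterogeneity
#' statistic across all samples of the two-group contrast, a
#' parametric-bootstrap (binomial) null with `B` permutations, and
#' empirical-FDR thresholding pooled across sites. For a candidate
#' threshold `t` over the observed statistics,
#' `eFDR(t) = mean_B #(d_null >= t) / #(d_obs >= t)`; the call threshold
#' `t*` is the smallest observed `t` with `eFDR(t) <= fdr`, and sites
#' with `d >= t*` (ties included) are called. Direction is hyper when
#' the warm-group pooled level exceeds the control-group pooled level.
#'
#' @param methylome long per-sample count table.
#' @param design data.table with sample_id and condition; the first
#'   level of `condition` (in `conditions` order) is the control.
#' @param context context class to test.
#' @param fdr nominal empirical FDR (default 0.003).
#' @param min_pooled_cov pooled coverage floor (default 30).
#' @param B permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @param conditions optional length-2 character giving control and warm
#'   labels; defaults to sorted unique conditions in the design.
#' @return data.table of called sites: chrom, pos, strand, context, d,
#'   p_value, level_a (control), level_b (warm), direction; empty (with
#'   a `threshold` attribute carrying diagnostics) when nothing passes.
#' @export
call_dms <- function(methylome, design, context, fdr = 0.003,
                     min_pooled_cov = 30L, B = 1000L, seed = 1L,
                     conditions = NULL) {
  if (is.null(conditions)) conditions <- sort(unique(design$condition))
  stopifnot(length(conditions) == 2L)
  for (cond in conditions) {
    if (sum(design$condition == cond) < 2L)
      stop("condition '", cond, "' has fewer than 2 replicates")
  }
  fs <- filter_sites(methylome, design, context, min_pooled_cov)
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      d = numeric(), p_value = numeric(),
                      level_a = numeric(), level_b = numeric(),
                      direction = character())
  if (nrow(fs$sites) == 0L) return(empty)
  eng <- rms_perm_engine(fs$m, fs$n, B = B, seed = seed)
  efdr <- eng$mean_null_ge / eng$obs_ge
  ok <- which(efdr <= fdr & eng$thresholds > 0)
  if (!length(ok)) {
    attr(empty, "threshold") <- list(t_star = NA_real_,
                                     min_efdr = suppressWarnings(min(efdr)))
    return(empty)
  }
  t_star <- min(eng$thresholds[ok])
  called <- which(eng$d >= t_star)
  a <- design$sample_id[design$condition == conditions[1]]
  b <- design$sample_id[design$condition == conditions[2]]
  lev_a <- rowSums(fs$m[called, a, drop = FALSE]) /
    rowSums(fs$n[called, a, drop = FALSE])
  lev_b <- rowSums(fs$m[called, b, drop = FALSE]) /
    rowSums(fs$n[called, b, drop = FALSE])
  out <- fs$sites[called]
  out[, `:=`(context = context, d = eng$d[called],
             p_value = eng$p_value[called],
             level_a = lev_a, level_b = lev_b,
             direction = fifelse(lev_b > lev_a, "hyper",
                                 fifelse(lev_b < lev_a, "hypo",
                                         NA_character_)))]
  setorder(out, chrom, pos)
  attr(out, "threshold") <- list(t_star = t_star, n_tested = nrow(fs$sites))
  out[]
}

#' Merge DMSs into differentially methylated regions (DMRs)
#'
#' Greedy left-to-right merge per chromosome: consecutive DMSs of the
#' same context and direction with inter-site distance <= `gap` bp
#' (inclusive boundary) join one region. The region interval spans the
#' first to the last member cytosine (half-open end includes the last
#' base). A direction change always splits, so DMRs are
#' direction-homogeneous.
#'
#' @param dms data.table from [call_dms()] (must be position-sorted
#'   within chromosome).
#' @param gap maximum merge distance in bp (default 250).
#' @return data.table: chrom, start, end (0-based half-open), context,
#'   direction, n_dms, level_a, level_b (pooled means over member
#'   sites), diff_level.
#' @export
merge_dms <- function(dms, gap = 250L) {
  if (nrow(dms) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), n_dms = integer(),
                      level_a = numeric(), level_b = numeric(),
                      diff_level = numeric()))
  }
  if (dms[, any(diff(pos) < 0), by = .(chrom, context)][, any(V1)])
    stop("DMS input must be sorted by position within chromosome")
  work <- copy(dms)
  work[, dmr_id := {
    brk <- c(TRUE, diff(pos) > gap | direction[-1] != direction[-.N])
    cumsum(brk)
  }, by = .(chrom, context)]
  out <- work[, .(start = min(pos), end = max(pos) + 1L,
                  direction = direction[1], n_dms = .N,
                  level_a = mean(level_a), level_b = mean(level_b)),
              by = .(chrom, context, dmr_id)]
  out[, diff_level := level_b - level_a]
  out[, dmr_id := NULL]
  setcolorder(out, c("chrom", "start", "end", "context", "direction",
                     "n_dms", "level_a", "level_b", "diff_level"))
  setorder(out, chrom, start)
  out[]
}

#' Tabulate DMR counts by context and direction
#'
#' @param dmr_sets named list of DMR tables (one per comparison or
#'   group), or a single DMR table.
#' @return data.table: comparison, context, direction, n.
#' @export
dmr_summary <- function(dmr_sets) {
  if (is.data.frame(dmr_sets)) dmr_sets <- list(all = dmr_sets)
  grid <- CJ(comparison = names(dmr_sets), context = c("CGN", "CHG", "CHH"),
             direction = c("hyper", "hypo"))
  obs <- rbindlist(lapply(names(dmr_sets), function(nm) {
    x <- dmr_sets[[nm]]
    if (nrow(x) == 0L) return(NULL)
    x[!is.na(direction), .(n = .N), by = .(context, direction)][,
      comparison := nm]
  }), use.names = TRUE)
  if (is.null(obs) || nrow(obs) == 0L) {
    grid[, n := 0L]
    return(grid[])
  }
  out <- obs[grid, on = .(comparison, context, direction)]
  out[is.na(n), n := 0L]
  setcolorder(out, c("comparison", "context", "direction", "n"))
  out[]
}
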