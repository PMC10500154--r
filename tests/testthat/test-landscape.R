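mk_dmrs <- function(mids, context = "CHG", chrom = "chr1") {
  data.table::data.table(chrom = chrom, start = mids - 5L, end = mids + 5L,
                         context = context, direction = "hyper",
                         n_dms = 2L, level_a = 0.3, level_b = 0.6,
                         diff_level = 0.3)
}

test_that("DMR density counts midpoints with the half-open window rule", {
  empty <- dmr_density(mk_dmrs(integer(0)))
  expect_equal(nrow(empty), 0L)
  # midpoint exactly at i*w belongs to window i
  d <- dmr_density(data.table::data.table(
    chrom = "chr1", start = 49995L, end = 50005L, context = "CHG",
    direction = "hyper", n_dms = 1L, level_a = 0.3, level_b = 0.6,
    diff_level = 0.3))
  expect_equal(d$window, 1L)
  set.seed(3)
  mids <- sample.int(500000L, 200L)
  dd <- dmr_density(mk_dmrs(sort(mids)))
  expect_equal(dd[, sum(count)], 200L)
})

test_that("peak calling applies the floor and the all-groups sharing rule", {
  dens <- data.table::CJ(group = c("g1", "g2"), context = "CHG",
                         chrom = "chr1", window = 0:5)
  dens[, count := 3L]
  res <- call_peaks(dens, floor = 10L, quantile = NULL)
  expect_equal(sum(res$peaks$peak), 0L)
  expect_equal(nrow(res$shared), 0L)
  # both groups peak in window 2; only g1 in window 4
  dens[group == "g1" & window %in% c(2L, 4L), count := 15L]
  dens[group == "g2" & window == 2L, count := 12L]
  res2 <- call_peaks(dens, floor = 10L, quantile = NULL)
  expect_equal(res2$shared$window, 2L)
  # peak sharing is monotone: adding a group can only shrink the set
  dens3 <- rbind(dens, data.table::data.table(
    group = "g3", context = "CHG", chrom = "chr1", window = 0:5,
    count = 3L))
  res3 <- call_peaks(dens3, floor = 10L, quantile = NULL)
  expect_true(all(res3$shared$window %in% res2$shared$window))
  expect_equal(nrow(res3$shared), 0L)
})

test_that("feature density equals brute-force base enumeration", {
  feats <- data.table::data.table(
    chrom = "chr1",
    start = c(0L, 100L, 150L, 900L), end = c(50L, 200L, 250L, 1100L),
    strand = "+", type = c("gene", "RE", "RE", "RE"),
    feature_id = paste0("f", 1:4))
  dens <- feature_density(feats, c(chr1 = 2000L), w = 1000L)
  # brute force: mark covered bases of the RE union per window
  covered <- logical(2000L)
  for (i in which(feats$type == "RE"))
    covered[(feats$start[i] + 1L):feats$end[i]] <- TRUE
  expect_equal(dens[window == 0L, re_density], sum(covered[1:1000]) / 1000)
  expect_equal(dens[window == 1L, re_density],
               sum(covered[1001:2000]) / 1000)
  expect_equal(dens[window == 0L, gene_density], 50 / 1000)
  expect_equal(dens[window == 1L, pseudo_density], 0)
  # fully covered window
  full <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                                 strand = "+", type = "gene",
                                 feature_id = "g")
  expect_equal(feature_density(full, c(chr1 = 1000L),
                               w = 1000L)$gene_density, 1)
})

test_that("regression recovers exact fits, null fits and planted signs", {
  dens <- data.table::CJ(chrom = "chr1", window = 0:199)
  set.seed(13)
  dens[, `:=`(gene_density = runif(200), re_density = runif(200),
              pseudo_density = runif(200))]
  # exact linear response: R^2 = 1
  prof <- data.table::copy(dens)
  prof[, `:=`(context = "CHG",
              level = 0.4 - 0.2 * gene_density + 0.3 * re_density +
                0.1 * pseudo_density)]
  fit <- methylation_regression(prof, dens)
  expect_equal(fit$CHG$r_squared, 1)
  expect_equal(unname(fit$CHG$coefficients),
               c(0.4, -0.2, 0.3, 0.1), tolerance = 1e-10)
  # independent noise: R^2 ~ 0
  prof2 <- data.table::copy(dens)
  prof2[, `:=`(context = "CHG", level = runif(200))]
  expect_lt(methylation_regression(prof2, dens)$CHG$r_squared, 0.1)
  # default scenario: gene coefficient negative, RE/pseudo positive
  sc <- tiny_scenario(chrom_lengths = stats::setNames(rep(100000L, 3),
                                                      paste0("chr", 1:3)),
                      n_genes = 15L, n_res = 12L, n_pseudo = 4L)
  g <- generate_genome(sc)
  m <- simulate_counts(simulate_truth(g, sc), sc, "s1")
  wp <- window_profile(m[chrom != g$control], g, w = 5000L)
  fd <- feature_density(g$features, g$chrom_lengths, w = 5000L)
  fit3 <- methylation_regression(wp[chrom != g$control], fd)
  for (cc in c("CGN", "CHG")) {
    co <- fit3[[cc]]$coefficients
    expect_lt(co["gene_density"], 0)
    expect_gt(co["re_density"], 0)
    expect_gt(co["pseudo_density"], 0)
  }
})

test_that("proximity categories match a brute-force distance scan", {
  genes <- data.table::data.table(
    chrom = "chr1", start = c(0L, 10000L, 30000L, 60000L),
    end = c(1000L, 11000L, 31000L, 61000L), strand = "+", type = "gene",
    feature_id = paste0("g", 1:4))
  res <- data.table::data.table(
    chrom = "chr1", start = c(500L, 13000L, 37500L), strand = "+",
    end = c(1500L, 13500L, 38000L), type = "RE",
    feature_id = paste0("r", 1:3))
  pc <- proximity_categories(genes, res)
  # g1 overlaps r1: distance 0 -> within 2 kb
  expect_equal(pc[gene_id == "g1", distance], 0)
  expect_equal(as.character(pc[gene_id == "g1", category]), "RE_within_2kb")
  # g2 to r2: gap = 13000 - 11000 = 2000 exactly -> closed right edge
  expect_equal(pc[gene_id == "g2", distance], 2000)
  expect_equal(as.character(pc[gene_id == "g2", category]), "RE_within_2kb")
  expect_equal(as.character(pc[gene_id == "g3", category]), "RE_5_10kb")
  expect_equal(as.character(pc[gene_id == "g4", category]),
               "no_RE_within_10kb")
  # brute force over random layouts
  set.seed(37)
  for (rep in 1:3) {
    gs <- sort(sample.int(200000L, 30L))
    rs <- sort(sample.int(200000L, 20L))
    genes2 <- data.table::data.table(chrom = "chr1", start = gs,
                                     end = gs + 500L, strand = "+",
                                     type = "gene",
                                     feature_id = paste0("g", seq_along(gs)))
    res2 <- data.table::data.table(chrom = "chr1", start = rs,
                                   end = rs + 300L, strand = "+",
                                   type = "RE",
                                   feature_id = paste0("r", seq_along(rs)))
    pc2 <- proximity_categories(genes2, res2)
    for (i in seq_along(gs)) {
      dd <- pmax(0L, pmax(rs - (gs[i] + 500L), gs[i] - (rs + 300L)))
      expect_equal(pc2$distance[i], min(dd))
    }
  }
})

test_that("Games-Howell matches an independent formula implementation", {
  gh_ref <- function(vals, grp) {
    gl <- sort(unique(grp)); k <- length(gl)
    out <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      x <- vals[grp == gl[a]]; y <- vals[grp == gl[b]]
      se2 <- var(x) / length(x) + var(y) / length(y)
      tt <- (mean(x) - mean(y)) / sqrt(se2)
      df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                       (var(y) / length(y))^2 / (length(y) - 1))
      p <- ptukey(abs(tt) * sqrt(2), k, df, lower.tail = FALSE)
      out <- rbind(out, data.frame(g1 = gl[a], g2 = gl[b], t = tt,
                                   df = df, p = p))
    }
    out
  }
  set.seed(41)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    grp <- rep(paste0("G", seq_len(k)), each = sample(5:20, 1))
    vals <- rnorm(length(grp), sd = runif(1, 0.5, 3))
    got <- games_howell(vals, grp)
    ref <- gh_ref(vals, grp)
    expect_equal(got$t, ref$t, tolerance = 1e-6)
    expect_equal(got$df, ref$df, tolerance = 1e-6)
    expect_equal(got$p_value, ref$p, tolerance = 1e-6)
  }
  # identical groups: p ~ 1
  x <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  expect_gt(games_howell(x, g)$p_value, 0.99)
  # separated third group at n = 50
  set.seed(43)
  vals <- c(rnorm(50), rnorm(50), rnorm(50, mean = 5))
  grp <- rep(c("a", "b", "c"), each = 50)
  gh <- games_howell(vals, grp)
  expect_gt(gh[group1 == "a" & group2 == "b", p_value], 0.05)
  expect_lt(gh[group1 == "a" & group2 == "c", p_value], 1e-6)
  expect_lt(gh[group1 == "b" & group2 == "c", p_value], 1e-6)
  expect_error(games_howell(1:4, c("a", "a", "b", "b")), "n >= 3")
})

test_that("RE proximity represses expression only within 2 kb", {
  sc <- tiny_scenario(
    chrom_lengths = stats::setNames(rep(300000L, 3), paste0("chr", 1:3)),
    n_genes = 60L, n_res = 8L, n_pseudo = 2L,
    gene_length = c(500L, 900L), re_length = c(200L, 400L), seed = 97L)
  g <- generate_genome(sc)
  ex <- simulate_expression(g, sc)
  gs <- de_test(ex$counts, ex$design, conditions = sc$conditions)
  cats <- proximity_categories(g$features[type == "gene"],
                               g$features[type == "RE"])
  eff <- suppressWarnings(proximity_effect(gs, cats))
  pw <- eff$abundance$pairwise
  p_close <- pw[(group1 == "RE_within_2kb" & group2 == "no_RE_within_10kb") |
                  (group2 == "RE_within_2kb" & group1 == "no_RE_within_10kb"),
                p_value]
  expect_lt(p_close, 0.05)
  far <- pw[(group1 == "no_RE_within_10kb" & group2 %in%
               c("RE_2_5kb", "RE_5_10kb")) |
              (group2 == "no_RE_within_10kb" & group1 %in%
                 c("RE_2_5kb", "RE_5_10kb")), p_value]
  expect_true(all(far > 0.05))
  # null world: repression off, no DE
  sc0 <- sc; sc0$repression_factor <- 1; sc0$de_fraction <- 0
  ex0 <- simulate_expression(g, sc0)
  gs0 <- de_test(ex0$counts, ex0$design, conditions = sc$conditions)
  eff0 <- suppressWarnings(proximity_effect(gs0, cats))
  expect_true(all(eff0$abundance$pairwise$p_value > 0.05))
})

test_that("window PCA separates conditions and satisfies its invariants", {
  sc <- tiny_scenario(treatment_shift = c(CGN = 0.1, CHG = 0.1, CHH = 0.1),
                      seed = 53L)
  g <- generate_genome(sc)
  design <- scenario_design(sc)
  meth <- simulate_methylomes(g, sc, design)
  prof <- meth[chrom != g$control,
               window_profile(.SD, g$chrom_lengths["chr1"], w = 10000L),
               by = sample_id]
  pca <- pca_windows(prof, context = "CHG")
  expect_true(all(pca$variance_fraction >= 0))
  expect_lte(sum(pca$variance_fraction), 1 + 1e-8)
  warm <- grepl("28C", rownames(pca$scores))
  expect_gt(abs(mean(pca$scores[warm, 1]) - mean(pca$scores[!warm, 1])),
            2 * (sd(pca$scores[warm, 1]) + sd(pca$scores[!warm, 1])) / 2)
  # duplicated sample gets identical scores
  prof2 <- rbind(prof, data.table::copy(prof[sample_id ==
    prof$sample_id[1]])[, sample_id := "dup"])
  pca2 <- pca_windows(prof2, context = "CHG")
  expect_equal(unname(pca2$scores["dup", ]),
               unname(pca2$scores[prof$sample_id[1], ]))
  expect_error(pca_windows(prof[sample_id == prof$sample_id[1]]),
               "at least 2 samples")
})
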