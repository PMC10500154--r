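mk_genes <- function() data.table::data.table(
  chrom = c("chr1", "chr1", "chr2"),
  start = c(10000L, 30000L, 5000L),
  end = c(12000L, 33000L, 8000L),
  strand = c("+", "-", "+"),
  type = "gene",
  feature_id = c("geneA", "geneB", "geneC"))

mk_dmr <- function(chrom, start, end, context = "CHG") {
  data.table::data.table(chrom = chrom, start = start, end = end,
                         context = context, direction = "hyper",
                         n_dms = 3L, level_a = 0.3, level_b = 0.6,
                         diff_level = 0.3)
}

test_that("DMR annotation assigns strand-aware categories with precedence", {
  genes <- mk_genes()
  # midpoint 500 bp upstream of geneA TSS (plus strand)
  ann <- annotate_dmrs(mk_dmr("chr1", 9400L, 9600L), genes)
  expect_equal(ann$category, "promoter")
  expect_equal(ann$target_gene, "geneA")
  expect_equal(ann$distance, -500L)
  # inside a minus-strand gene: body, positive distance from its TSS
  ann2 <- annotate_dmrs(mk_dmr("chr1", 31000L, 31002L), genes)
  expect_equal(ann2$category, "gene body")
  expect_equal(ann2$target_gene, "geneB")
  expect_gt(ann2$distance, 0)
  # downstream of geneA (plus strand, past TTS)
  ann3 <- annotate_dmrs(mk_dmr("chr1", 12400L, 12600L), genes)
  expect_equal(ann3$category, "downstream")
  # far from everything: intergenic, but distance still reported
  ann4 <- annotate_dmrs(mk_dmr("chr1", 20000L, 20002L), genes)
  expect_equal(ann4$category, "intergenic")
  expect_true(is.na(ann4$target_gene))
  expect_false(is.na(ann4$distance))
  # unstranded genes are rejected
  g2 <- data.table::copy(genes)[1, strand := "."]
  expect_error(annotate_dmrs(mk_dmr("chr1", 9400L, 9600L), g2), "strand")
})

test_that("equidistant promoter midpoints break ties lexicographically", {
  genes <- data.table::data.table(
    chrom = "chr1", start = c(10000L, 6000L), end = c(11000L, 7000L),
    strand = c("+", "-"), type = "gene",
    feature_id = c("geneZ", "geneA"))
  # midpoint 8500 is in geneZ's promoter [8000,10000) and geneA's
  # promoter [7000,9000)
  expect_message(
    ann <- annotate_dmrs(mk_dmr("chr1", 8499L, 8502L), genes),
    "lexicographically")
  expect_equal(ann$target_gene, "geneA")
})

test_that("annotation partitions DMRs: every DMR gets exactly one category", {
  sc <- tiny_scenario()
  g <- generate_genome(sc)
  set.seed(9)
  dmrs <- data.table::rbindlist(lapply(1:60, function(i) {
    s <- sample.int(39000L, 1)
    mk_dmr(sample(c("chr1", "chr2"), 1), s, s + 200L)
  }))
  ann <- annotate_dmrs(dmrs, g$features[type == "gene"])
  expect_equal(nrow(ann), 60L)
  expect_false(anyNA(ann$category))
  tab <- table(ann$category)
  expect_equal(sum(tab), 60L)
})

test_that("DMG calls require promoter or gene-body DMRs", {
  genes <- mk_genes()
  ann <- annotate_dmrs(data.table::rbindlist(list(
    mk_dmr("chr1", 12400L, 12600L, "CHG"),   # downstream only: not a DMG
    mk_dmr("chr1", 9400L, 9600L, "CHG"),     # geneA promoter, CHG
    mk_dmr("chr1", 10500L, 10700L, "CHH")    # geneA body, CHH
  )), genes)
  dmgs <- call_dmgs(ann)
  expect_equal(dmgs$CHG, "geneA")
  expect_equal(dmgs$CHH, "geneA")
  expect_equal(dmgs$CGN, character(0))
  expect_equal(dmgs$any, "geneA")  # counted once in the union
})

test_that("TMM factors satisfy identity, doubling and permutation checks", {
  set.seed(5)
  cnt <- matrix(rnbinom(500 * 4, mu = 200, size = 10), ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  same <- cbind(a = cnt[, 1], b = cnt[, 1], c = cnt[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3))
  # pure depth doubling: M == 0 for every gene, factors stay 1:1
  dbl <- cbind(a = cnt[, 1], b = 2L * cnt[, 1])
  f <- tmm_factors(dbl)
  expect_equal(unname(f["b"] / f["a"]), 1, tolerance = 1e-8)
  # gene order is irrelevant
  f1 <- tmm_factors(cnt)
  f2 <- tmm_factors(cnt[sample(nrow(cnt)), ])
  expect_equal(f1, f2)
  zero <- cbind(a = cnt[, 1], b = 0L * cnt[, 1])
  expect_error(tmm_factors(zero), "all-zero")
})

test_that("DE test is calibrated under the null and finds planted effects", {
  set.seed(17)
  G <- 1500L
  design <- data.table::data.table(sample_id = paste0("s", 1:6),
                                   condition = rep(c("18C", "28C"),
                                                   each = 3))
  cnt <- matrix(rnbinom(G * 6, mu = 100, size = 20), nrow = G,
                dimnames = list(paste0("g", 1:G), design$sample_id))
  gs <- de_test(cnt, design)
  tI <- mean(gs$pvalue <= 0.05, na.rm = TRUE)
  expect_lt(abs(tI - 0.05), 3 * sqrt(0.05 * 0.95 / G))
  # identical counts in all samples: log2FC 0, not a DEG
  cnt2 <- cnt; cnt2[1, ] <- 50L
  gs2 <- de_test(cnt2, design)
  expect_equal(gs2$log2fc[1], 0)
  expect_false(gs2$deg[1])
  # planted log2FC = 2 at mean 100, dispersion 0.05: recall >= 0.8
  mu <- rep(100, G); mu[1:150] <- 400
  cnt3 <- cnt
  for (j in 4:6) cnt3[, j] <- rnbinom(G, mu = mu, size = 20)
  gs3 <- de_test(cnt3, design)
  expect_gte(mean(gs3$deg[1:150]), 0.8)
  expect_gt(mean(gs3$log2fc[1:150]), 1.5)
  # degenerate design
  expect_error(de_test(cnt[, 1:4], design[c(1, 2, 3, 4)][
    , condition := c("18C", "18C", "18C", "28C")]), "replicates")
})

test_that("DEDMG overlap statistics match the exact hypergeometric sum", {
  universe <- paste0("g", 1:100)
  A <- paste0("g", 1:10)
  B <- paste0("g", c(1:5, 51:55))
  res <- intersect_dedmg(A, B, universe)
  expect_equal(res$overlap, 5L)
  expect_equal(res$rf, 5 / (10 * 10 / 100))
  p_exact <- sum(sapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res$dedmg_fraction, 0.5)
  # no overlap: RF 0, p ~ 1
  res0 <- intersect_dedmg(paste0("g", 1:10), paste0("g", 51:60), universe)
  expect_equal(res0$rf, 0)
  expect_gt(res0$p_value, 0.3)
  # saturation: A = universe forces O = nB, RF = 1, p = 1
  resS <- intersect_dedmg(universe, B, universe)
  expect_equal(resS$overlap, 10L)
  expect_equal(resS$rf, 1)
  expect_equal(resS$p_value, 1)
  expect_error(intersect_dedmg(universe, B, universe[1:5]), "universe")
})

test_that("hypergeometric upper tail equals one-sided Fisher on 2x2 tables", {
  set.seed(23)
  for (i in 1:20) {
    N <- sample(50:200, 1)
    nA <- sample(5:30, 1); nB <- sample(5:30, 1)
    O <- sample(0:min(nA, nB), 1)
    p_h <- phyper(O - 1, nA, N - nA, nB, lower.tail = FALSE)
    tab <- matrix(c(O, nA - O, nB - O, N - nA - nB + O), 2)
    p_f <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_h, p_f, tolerance = 1e-10)
  }
})

test_that("sharing counts reproduce brute-force membership enumeration", {
  sets <- list(g1 = c("a", "b", "c"), g2 = c("a", "b", "c"),
               g3 = c("a", "b", "c"), g4 = c("a", "b", "c"))
  res <- shared_sets(sets)
  expect_equal(res$patterns[pattern == "g1+g2+g3+g4", n], 3L)
  expect_equal(res$patterns[, sum(n)], 3L)
  disj <- list(g1 = c("a", "b"), g2 = c("c"), g3 = c("d", "e"))
  res2 <- shared_sets(disj)
  expect_equal(res2$patterns[pattern %in% c("g1", "g2", "g3"), sum(n)], 5L)
  expect_equal(res2$patterns[!pattern %in% c("g1", "g2", "g3"), sum(n)], 0L)
  expect_equal(unname(res2$unique_fraction), c(1, 1, 1))
  # random sets vs brute force
  set.seed(29)
  pool <- paste0("x", 1:40)
  rnd <- lapply(stats::setNames(nm = c("A", "B", "C")), function(i)
    sample(pool, sample(5:20, 1)))
  res3 <- shared_sets(rnd)
  univ <- unique(unlist(rnd))
  brute <- table(vapply(univ, function(g)
    paste(names(rnd)[vapply(rnd, function(s) g %in% s, logical(1))],
          collapse = "+"), character(1)))
  for (pat in names(brute))
    expect_equal(res3$patterns[pattern == pat, n],
                 as.integer(brute[[pat]]))
  expect_equal(res3$patterns[, sum(n)], length(univ))
})

test_that("planted DMGs are recovered end-to-end with high Jaccard", {
  sc <- tiny_scenario(
    chrom_lengths = stats::setNames(rep(120000L, 2), c("chr1", "chr2")),
    n_genes = 25L, n_res = 10L, n_pseudo = 3L, seed = 83L,
    treatment_shift = c(CGN = 0, CHG = 0, CHH = 0))
  g <- generate_genome(sc)
  genes <- g$features[type == "gene"]
  # plant CHG intervals inside the bodies of 8 genes
  set.seed(7)
  # avoid genes whose body centre sits inside another gene's promoter:
  # promoter precedence would (correctly) hand the DMR to the neighbour
  proms <- data.table::data.table(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$start - 2000L, genes$end),
    end = ifelse(genes$strand == "+", genes$start, genes$end + 2000L),
    owner = genes$feature_id)
  eligible <- vapply(seq_len(nrow(genes)), function(i) {
    ctr <- (genes$start[i] + genes$end[i]) %/% 2L
    !any(proms$chrom == genes$chrom[i] & proms$start <= ctr &
           proms$end > ctr & proms$owner != genes$feature_id[i])
  }, logical(1))
  pick <- genes[eligible][sample(sum(eligible), 8)]
  centre <- (pick$start + pick$end) %/% 2L
  sc$planted_dmrs <- data.frame(
    chrom = pick$chrom, start = centre - 300L, end = centre + 300L,
    shift = 0.4, context = "CHG")
  design <- scenario_design(sc)
  meth <- simulate_methylomes(g, sc, design, contexts = "CHG")
  dms <- call_dms(meth[chrom != g$control], design, "CHG", B = 1000L,
                  seed = 19L, conditions = sc$conditions)
  dmrs <- merge_dms(dms)
  ann <- annotate_dmrs(dmrs, genes)
  found <- call_dmgs(ann)$CHG
  jac <- length(intersect(found, pick$feature_id)) /
    length(union(found, pick$feature_id))
  expect_gte(jac, 0.8)
})
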