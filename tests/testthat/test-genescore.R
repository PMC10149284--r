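# Gene windows, fusion, LD-aware scores, enrichment

test_that("SNP-to-gene assignment respects the 50-kb window edges and
           multi-assignment", {
  ann <- data.table::data.table(
    gene = c("g1", "g2"), chr = 1L, start = c(100000L, 110000L),
    end = c(120000L, 190000L), strand = c("+", "-"),
    tss = c(100000L, 190000L), tes = c(120000L, 110000L),
    biotype = "protein_coding")
  snps <- data.table::data.table(
    snp = c("edge_in", "edge_out", "inside", "far"),
    chr = 1L, pos = c(50000L, 49999L, 115000L, 500000L))
  mp <- assign_snps_to_genes(ann, snps)
  expect_true("edge_in" %in% mp[gene == "g1", snp])
  expect_false("edge_out" %in% mp[gene == "g1", snp])
  expect_identical(mp[snp == "inside", gene], c("g1", "g2"))  # overlap
  expect_false("far" %in% mp$snp)
  # non-protein-coding/lincRNA genes are dropped
  ann2 <- data.table::copy(ann)[1, biotype := "pseudogene"]
  expect_false("g1" %in% assign_snps_to_genes(ann2, snps)$gene)
  expect_warning(
    assign_snps_to_genes(ann, data.table::data.table(snp = "x", chr = 9L,
                                                     pos = 1L)),
    "chromosome")
})

test_that("gene fusion respects the 100-kb boundary and is transitive", {
  mk <- function(gene, start, end) data.table::data.table(
    gene = gene, chr = 1L, start = start, end = end, strand = "+",
    tss = start, tes = end, biotype = "protein_coding")
  # gap of 99,999 intervening bases -> fused
  close_pair <- rbind(mk("a", 1e6, 1e6 + 1e4),
                      mk("b", 1e6 + 1e4 + 1e5, 2e6))
  expect_identical(nrow(fuse_genes(close_pair)), 1L)
  # gap of 100,001 -> separate
  far_pair <- rbind(mk("a", 1e6, 1e6 + 1e4),
                    mk("b", 1e6 + 1e4 + 1e5 + 2, 2e6))
  expect_identical(nrow(fuse_genes(far_pair)), 2L)
  # exact 100,000 gap -> separate (strictly-less rule)
  at_pair <- rbind(mk("a", 1e6, 1e6 + 1e4),
                   mk("b", 1e6 + 1e4 + 1e5 + 1, 2e6))
  expect_identical(nrow(fuse_genes(at_pair)), 2L)
  # chain a-b close, b-c close, a-c far -> one fusion of all three
  chain <- rbind(mk("a", 1e6, 1.01e6), mk("b", 1.06e6, 1.07e6),
                 mk("c", 1.12e6, 1.13e6))
  f <- fuse_genes(chain)
  expect_identical(nrow(f), 1L)
  expect_setequal(f$members[[1]], c("a", "b", "c"))
  expect_identical(f$gene, "a_b_c")
  expect_equal(f$start, 1000000)
  expect_equal(f$end, 1130000)
})

test_that("gene scores reduce to closed forms in degenerate LD", {
  # single SNP: gene p equals the SNP p
  for (p in c(0.2, 1e-4, 1e-30)) {
    s <- score_gene(p, 1)
    # |delta log10| < 1e-11 is sub-1e-10 relative error on p itself
    expect_lt(abs(s$neg_log10_p_raw + log10(p)), 1e-11)
  }
  # independent SNPs: chi-squared with n df
  set.seed(61)
  ps <- runif(6, 0.001, 0.9)
  s <- score_gene(ps, diag(6), ridge = 0)
  expect_equal(s$p, pchisq(s$statistic, df = 6, lower.tail = FALSE),
               tolerance = 1e-8)
  # two perfectly correlated SNPs with p = 0.05 each
  s2 <- score_gene(c(0.05, 0.05), matrix(c(1, 1, 1, 1), 2), ridge = 0)
  expect_equal(s2$p, 0.05, tolerance = 1e-8)
})

test_that("spectrum trace equals the SNP count and scores are invariant
           to SNP order", {
  set.seed(62)
  C <- cov2cor(crossprod(matrix(rnorm(200), 20, 10)))
  ps <- runif(10, 1e-6, 0.9)
  s <- score_gene(ps, C)
  expect_equal(sum(s$spectrum), 10, tolerance = 1e-6)
  perm <- sample(10)
  s2 <- score_gene(ps[perm], C[perm, perm])
  expect_equal(s$neg_log10_p_raw, s2$neg_log10_p_raw, tolerance = 1e-10)
  expect_error(score_gene(c(0.5, 0.5), matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("scores are capped at -log10 p = 100 with the flag set", {
  s <- score_gene(c(1e-300, 1e-280), diag(2))
  expect_true(s$capped)
  expect_equal(s$neg_log10_p, 100)
  expect_gt(s$neg_log10_p_raw, 100)
})

test_that("rank enrichment: extreme sets, null uniformity, rank
           invariance and the full-set case", {
  G <- 1000
  scores <- data.table::data.table(gene = sprintf("g%04d", 1:G),
                                   neg_log10_p_raw = sort(rexp(G, 0.5),
                                                          decreasing = TRUE))
  # set = the top 10 genes
  top <- rank_enrichment(scores, scores$gene[1:10])
  # direct evaluation of the formula at the extreme ranks:
  # T = sum qchisq(1 - (k - 0.5)/G, 1), k = 1..10, vs chi-squared(10)
  t_direct <- sum(qchisq((1:10 - 0.5) / G, 1, lower.tail = FALSE))
  expect_equal(top$statistic, t_direct)
  expect_equal(top$p, pchisq(t_direct, 10, lower.tail = FALSE))
  expect_lt(top$p, 1e-12)
  # depends on ranks only: squashing the scores changes nothing
  squashed <- data.table::copy(scores)[, neg_log10_p_raw :=
                                         rank(neg_log10_p_raw) / G]
  expect_equal(rank_enrichment(squashed, scores$gene[1:10])$p, top$p)
  # null calibration: random sets give uniform p
  set.seed(63)
  pnull <- replicate(400, {
    rank_enrichment(scores, sample(scores$gene, 15))$p
  })
  ks <- suppressWarnings(ks.test(pnull, "punif"))
  expect_gt(ks$p.value, 0.001)
  # the whole-genome set concentrates near its chi-squared mean
  allset <- rank_enrichment(scores, scores$gene)
  expect_gt(allset$p, 0.2)
  expect_lt(allset$p, 0.8)
  expect_message(rank_enrichment(scores, c(scores$gene[1:3], "absent")),
                 "unscored")
  expect_error(rank_enrichment(scores, "absent"), "no scored member")
})

test_that("tissue enrichment flags a planted upregulated set under the
           Bonferroni-over-tissues threshold", {
  hits <- 0; false_flags <- 0
  for (s in 1:20) {
    ann <- gen_annotations_and_sets(300, 5, 54, seed = 100 + s,
                                    planted_fold = 3)
    te <- tissue_enrichment(ann$expression, ann$sets[[ann$planted$set]])
    expect_equal(attr(te, "threshold"), 0.05 / 54)
    if (te[tissue == ann$planted$tissue, significant]) hits <- hits + 1
    false_flags <- false_flags +
      nrow(te[tissue != ann$planted$tissue & significant == TRUE])
  }
  expect_gte(hits, 19)        # planted tissue recovered in >= 95% of seeds
  expect_lte(false_flags, 3)  # other tissues essentially clean
  expect_error(tissue_enrichment(matrix(1, 2, 2,
                                        dimnames = list(c("a", "b"),
                                                        NULL)), "zz"),
               "no set member")
})

test_that("fusion expression pools member genes", {
  expr <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"),
                                            c("t1", "t2")))
  fusion <- data.table::data.table(gene = c("a_b", "c"),
                                   members = list(c("a", "b"), "c"),
                                   n_members = c(2L, 1L), chr = 1L,
                                   start = 1L, end = 2L)
  fe <- fusion_expression(expr, fusion)
  expect_equal(fe["a_b", "t1"], 3)
  expect_equal(fe["c", "t2"], 6)
})
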