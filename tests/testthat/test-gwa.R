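test_that("MAF filtering is inclusive at the threshold and idempotent", {
  n_lines <- 200
  mk_row <- function(k) c(rep(2L, k), rep(0L, n_lines - k))
  calls <- rbind(mk_row(0),    # monomorphic
                 mk_row(9),    # MAF 0.045
                 mk_row(10),   # MAF 0.050 (boundary, kept)
                 mk_row(100))  # MAF 0.5
  g <- toy_geno(calls)
  f <- suppressMessages(maf_filter(g, 0.05))
  expect_equal(f$variants$id, c("v003", "v004"))
  expect_equal(attr(f, "maf_filter")$n_dropped, 2)

  f2 <- suppressMessages(maf_filter(f, 0.05))
  expect_identical(f2$calls, f$calls)

  f0 <- suppressMessages(maf_filter(g, 0))
  expect_equal(nrow(f0$variants), 4)  # identity at threshold 0

  fa <- suppressMessages(maf_filter(g, 0.01))
  expect_false("v001" %in% fa$variants$id)  # monomorphic always dropped
})

test_that("association equals the closed-form simple-regression oracle", {
  g_vec <- c(0, 0, 0, 0, 2, 2, 2, 2)
  y <- c(1, 1.2, 0.9, 1.1, 2.0, 2.1, 1.9, 2.2)
  geno <- toy_geno(matrix(g_vec, nrow = 1))
  means <- data.frame(line = geno$lines, sensitivity = y)
  rec <- associate(geno, means, "sensitivity", min_class = 4, min_lines = 8)
  oracle <- ols_oracle(g_vec, y)
  expect_equal(rec$effect, oracle$slope, tolerance = 1e-10)
  expect_equal(rec$se, oracle$se, tolerance = 1e-10)
  expect_equal(rec$p, oracle$p, tolerance = 1e-10)
  expect_equal(rec$n, 8)
  expect_false(rec$degenerate)
})

test_that("association matches the oracle across many simulated variants", {
  cfg <- sim_config(n_lines = 60, n_variants = 300, seed = 17)
  geno <- simulate_genotypes(cfg)
  set.seed(18)
  means <- data.frame(line = geno$lines, sensitivity = rnorm(60))
  rec <- associate(geno, means, min_class = 1, min_lines = 10)
  for (i in which(!rec$degenerate)) {
    oracle <- ols_oracle(geno$calls[i, ], means$sensitivity)
    expect_equal(rec$effect[i], oracle$slope, tolerance = 1e-10)
    expect_equal(rec$se[i], oracle$se, tolerance = 1e-10)
    expect_equal(rec$p[i], oracle$p, tolerance = 1e-10)
  }
})

test_that("degenerate and underpowered variants are flagged, not dropped", {
  calls <- rbind(rep(0L, 20),                 # constant
                 c(rep(2L, 2), rep(0L, 18)),  # minor class of 2 < min_class 4
                 c(rep(2L, 10), rep(0L, 10)))
  geno <- toy_geno(calls)
  set.seed(1)
  means <- data.frame(line = geno$lines, sensitivity = rnorm(20))
  rec <- associate(geno, means, min_class = 4, min_lines = 10)
  expect_equal(rec$degenerate, c(TRUE, TRUE, FALSE))
  expect_equal(rec$p[1:2], c(1, 1))
  expect_error(associate(geno, means[1:5, ], min_lines = 10), "lines shared")
})

test_that("covariates are projected out and rank deficiency is an error", {
  set.seed(2)
  n <- 40
  g_vec <- rep(c(0, 2), each = n / 2)
  covar <- rnorm(n)
  y <- 1 + 0.5 * g_vec + 2 * covar + rnorm(n, sd = 0.1)
  geno <- toy_geno(matrix(as.integer(g_vec), nrow = 1))
  geno <- genotype_matrix(geno$calls, geno$variants, sprintf("L%02d", 1:n))
  means <- data.frame(line = geno$lines, sensitivity = y)
  cov_df <- data.frame(line = geno$lines, c1 = covar)
  rec <- associate(geno, means, covariates = cov_df, min_lines = 10)
  # oracle: multiple regression via lm
  fit <- lm(y ~ g_vec + covar)
  expect_equal(rec$effect, unname(coef(fit)["g_vec"]), tolerance = 1e-10)
  expect_equal(rec$se, unname(sqrt(diag(vcov(fit)))["g_vec"]),
               tolerance = 1e-10)
  expect_equal(rec$p, summary(fit)$coefficients["g_vec", 4], tolerance = 1e-10)

  bad <- data.frame(line = geno$lines, c1 = covar, c2 = 2 * covar)
  expect_error(associate(geno, means, covariates = bad, min_lines = 10),
               "rank-deficient")
})

test_that("a perfectly predictive variant gives slope 1 and vanishing p", {
  g_vec <- rep(c(0L, 2L), 10)
  geno <- toy_geno(matrix(g_vec, nrow = 1))
  means <- data.frame(line = geno$lines, sensitivity = as.numeric(g_vec))
  rec <- associate(geno, means, min_class = 4, min_lines = 10)
  expect_equal(rec$effect, 1, tolerance = 1e-12)
  expect_lt(rec$p, 1e-200)
})

test_that("threshold filtering is strict and monotone in alpha", {
  rec <- data.frame(variant_id = paste0("v", 1:6), chrom = "chr1", pos = 1:6,
                    maf = 0.2, n = 100,
                    effect = 1, se = 1, statistic = 1,
                    p = c(1e-6, 1e-5, 2e-5, 5e-5, 1e-3, 1),
                    degenerate = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  class(rec) <- c("association_table", "data.frame")
  hits <- threshold_hits(rec, 1e-5)
  expect_equal(hits$variant_id, "v1")  # p == alpha excluded, strict "<"
  relaxed <- threshold_hits(rec, 5e-5)
  expect_true(all(hits$variant_id %in% relaxed$variant_id))
  expect_equal(relaxed$variant_id, c("v1", "v2", "v3"))  # sorted by p
  expect_equal(relaxed$variant_id,
               rec$variant_id[order(rec$p)][rec$p[order(rec$p)] < 5e-5 &
                                              !rec$degenerate[order(rec$p)]])
  expect_equal(nrow(threshold_hits(rec[0, ], 1e-5)), 0)
})

test_that("threshold filtering restricts gene annotations to surviving hits", {
  genes <- gene_model_set(data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                                     start = c(0, 1000), end = c(500, 1500)))
  rec <- data.frame(variant_id = c("v1", "v2"), chrom = "chr1",
                    pos = c(100, 1200), maf = 0.2, n = 100, effect = 1,
                    se = 1, statistic = 1, p = c(1e-8, 1e-3),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  class(rec) <- c("association_table", "data.frame")
  ann <- annotate_variants(rec, genes, window = 10)
  hits <- threshold_hits(ann, 1e-5)
  expect_equal(hit_genes(hits), "gA")
  expect_equal(attr(hits, "n_distinct_genes"), 1)
  expect_equal(hit_genes(ann), c("gA", "gB"))
})

test_that("variants are annotated to genes in or near them", {
  genes <- gene_model_set(data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    start = c(1000, 5000, 20000), end = c(2000, 6000, 21000),
    strand = "+"))
  # 0-based half-open [1000, 2000) = 1-based body [1001, 2000]
  rec <- data.frame(
    variant_id = paste0("v", 1:5), chrom = "chr1",
    pos = c(1500,          # inside gA
            2999,          # 999 bp downstream of gA body end -> near
            3001,          # 1001 bp -> intergenic (gB is 2000 away)
            5500,          # inside gB
            30000),        # far from everything
    stringsAsFactors = FALSE)
  ann <- annotate_variants(rec, genes, window = 1000)
  long <- attr(ann, "annotation")
  expect_equal(ann$genes, c("gA", "gA", "", "gB", ""))
  expect_equal(long$relation[long$variant_id == "v1"], "inside")
  expect_equal(long$distance[long$variant_id == "v2"], 999)
  expect_equal(long$relation[long$variant_id == "v2"], "near")
  expect_true(ann$intergenic[3] && ann$intergenic[5])
  expect_equal(attr(ann, "n_distinct_genes"), 2)

  # upstream boundary: 1000 bp away kept, window boundary inclusive
  rec2 <- data.frame(variant_id = "u", chrom = "chr1", pos = 1,
                     stringsAsFactors = FALSE)
  ann2 <- annotate_variants(rec2, genes, window = 1000)
  expect_equal(ann2$genes, "gA")
  expect_equal(attr(ann2, "annotation")$distance, 1000)

  expect_warning(
    annotate_variants(data.frame(variant_id = "w", chrom = "chrX", pos = 5),
                      genes, window = 1000),
    "absent from gene models")
})

test_that("toy variant/gene layout matches manual interval arithmetic", {
  genes <- gene_model_set(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = c("chr1", "chr1", "chr2"),
    start = c(100, 220, 50), end = c(200, 320, 150)))
  rec <- data.frame(variant_id = paste0("m", 1:5),
                    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                    pos = c(150, 210, 215, 100, 300),
                    stringsAsFactors = FALSE)
  ann <- annotate_variants(rec, genes, window = 10)
  # 1-based bodies: g1 [101,200], g2 [221,320], g3 [51,150]
  # m1 inside g1; m2 10 bp past g1 (g2 still 11 away); m3 6 bp before g2
  # (g1 already 15 away); m4 inside g3; m5 far from everything
  expect_equal(ann$genes, c("g1", "g1", "g2", "g3", ""))
  long <- attr(ann, "annotation")
  expect_equal(long$distance[long$variant_id == "m2"], 10)
  expect_equal(long$distance[long$variant_id == "m3"], 6)
  expect_equal(hit_genes(ann), c("g1", "g2", "g3"))
})

test_that("null p-values are uniform", {
  cfg <- sim_config(n_lines = 100, n_variants = 2000,
                    maf_range = c(0.1, 0.5), seed = 23)
  geno <- simulate_genotypes(cfg)
  set.seed(24)
  means <- data.frame(line = geno$lines, sensitivity = rnorm(100))
  rec <- associate(geno, means, min_class = 4, min_lines = 50)
  p <- rec$p[!rec$degenerate]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
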