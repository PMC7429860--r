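test_that("overlap_bp obeys half-open boundaries and flattens the second set", {
  a <- data.table(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(overlap_bp(a, data.table(chrom = "chr1", start = 50L, end = 150L)), 50)
  expect_equal(overlap_bp(a, data.table(chrom = "chr1", start = 100L, end = 200L)), 0)
  b <- data.table(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L))
  expect_equal(overlap_bp(a, b), 20)  # flattened to [10,30)
  expect_equal(overlap_bp(a[0], b), 0)
})

test_that("DMR bp is assigned to one category with TE > gene precedence", {
  genes <- make_features("chr1", 40L, 2000L, kind = "gene")
  tes_nogene <- make_features("chr1", 400L, 700L)
  # DMR inside an intergenic TE
  d1 <- data.table(chrom = "chr1", start = 500L, end = 600L)
  cat1 <- categorize_dmrs(d1, genes[0], tes_nogene)
  expect_equal(cat1[category == "TE_intergenic", bp], 100)
  # same TE but overlapping a gene: its bp becomes TE_genic
  cat2 <- categorize_dmrs(d1, genes, tes_nogene)
  expect_equal(cat2[category == "TE_genic", bp], 100)
  # DMR inside a gene with no TE
  cat3 <- categorize_dmrs(d1, genes, tes_nogene[0])
  expect_equal(cat3[category == "gene_body", bp], 100)
  # bp-resolution split: TE on [0,40), gene on [40,100)
  d4 <- data.table(chrom = "chr1", start = 0L, end = 100L)
  cat4 <- categorize_dmrs(d4, make_features("chr1", 40L, 100L, kind = "gene"),
                          make_features("chr1", 0L, 40L))
  expect_equal(cat4[category == "TE_intergenic", bp], 40)
  expect_equal(cat4[category == "gene_body", bp], 60)
  expect_equal(sum(cat4$bp), 100)
  expect_equal(sum(cat4$fraction), 1, tolerance = 1e-9)
})

test_that("category bp conservation holds on random inputs", {
  set.seed(13)
  rnd_iv <- function(n, L = 10000L) {
    st <- sort(sample.int(L - 200L, n))
    data.table(chrom = "chr1", start = st, end = st + sample(50:200, n, TRUE))
  }
  for (i in 1:5) {
    d <- rnd_iv(20); g <- rnd_iv(8); te <- rnd_iv(12)
    g[, `:=`(strand = "+", kind = "gene", family = "", id = paste0("g", .I))]
    te[, `:=`(strand = "+", kind = "TE", family = "MITE", id = paste0("t", .I))]
    ct <- categorize_dmrs(d, g, te)
    flat_d <- flatten_intervals(d)
    expect_equal(sum(ct$bp), sum(flat_d$end - flat_d$start))
    expect_equal(sum(ct$fraction), 1, tolerance = 1e-9)
  }
})

test_that("family breakdown recomputes percentages and flags enrichment", {
  tes <- rbind(make_features("chr1", 0L, 100L, family = "MITE"),
               make_features("chr1", c(1000L, 3000L), c(1900L, 3900L),
                             family = "Gypsy"))
  # all DMR overlap on the MITE, which is 100/1900 of TE bp
  d <- data.table(chrom = "chr1", start = 0L, end = 100L)
  fb <- family_breakdown(d, tes)
  expect_equal(fb[family == "MITE", overlap_pct], 100)
  expect_equal(fb[family == "MITE", enrichment], 1900 / 100, tolerance = 1e-9)
  expect_equal(fb$overlap_pct, 100 * fb$overlap_bp / sum(fb$overlap_bp),
               tolerance = 1e-9)
  expect_equal(fb$genome_pct, 100 * fb$genome_bp / sum(fb$genome_bp),
               tolerance = 1e-9)
  # zero DMRs: all-zero table, no division error
  fb0 <- family_breakdown(d[0], tes)
  expect_true(all(fb0$overlap_bp == 0))
  expect_true(all(fb0$overlap_pct == 0))
  # unknown family label buckets into Others with a warning
  expect_warning(fb2 <- family_breakdown(d, tes, families = "MITE"), "Others")
  expect_true("Others" %in% fb2$family)
})

test_that("uniform DMR placement over TE bp gives enrichment near 1", {
  set.seed(17)
  tes <- rbind(make_features("chr1", seq(0L, 90000L, 10000L) ,
                             seq(0L, 90000L, 10000L) + 400L, family = "MITE"),
               make_features("chr1", seq(5000L, 95000L, 10000L),
                             seq(5000L, 95000L, 10000L) + 1600L, family = "Gypsy"))
  # drop uniform 50-bp DMRs over the flattened TE bp
  flat <- flatten_intervals(tes)
  widths <- flat$end - flat$start
  reps <- 400
  picks <- sample.int(nrow(flat), reps, TRUE, prob = widths)
  st <- flat$start[picks] + floor(runif(reps) * pmax(1, widths[picks] - 50))
  d <- data.table(chrom = "chr1", start = as.integer(st),
                  end = as.integer(st + 50))
  fb <- family_breakdown(d, tes)
  expect_true(all(abs(fb$enrichment - 1) < 0.2))
})

test_that("feature body levels pool reads and stay undefined without sites", {
  te <- make_features("chr1", 0L, 100L)
  s <- make_sites("chr1", c(10, 50), m = c(8L, 2L), u = c(2L, 8L))
  lv <- feature_body_levels(te, s, "CHH")
  expect_equal(lv$level, 0.5)
  expect_true(is.na(feature_body_levels(te, s, "CG")$level))
})

test_that("MITE proximity classes follow the flank rule", {
  genes <- make_features("chr1", 5000L, 7000L, kind = "gene")
  near <- make_features("chr1", 4600L, 4800L)    # 200 bp upstream
  far <- make_features("chr1", 2000L, 2200L)     # ~2.8 kb away
  expect_equal(classify_genes_by_mite_proximity(genes, near, 1000L)$mite_class,
               "with_MITE")
  expect_equal(classify_genes_by_mite_proximity(genes, far, 1000L)$mite_class,
               "without_MITE")
  expect_equal(classify_genes_by_mite_proximity(genes, near[0], 1000L)$mite_class,
               "without_MITE")
})

test_that("TE methylation-change groups follow the epsilon/floor rules", {
  g <- classify_te_methylation_change(c(0.005, 0.05, 0.10, 0.30, NA),
                                      c(0.004, 0.20, 0.10, 0.10, 0.2))
  expect_equal(g$group, c("unmethylated", "gained", "similar", "lost"))
  expect_equal(attr(g, "n_excluded"), 1L)
})

test_that("hypermethylation overlap test matches the hypergeometric oracle", {
  universe <- paste0("te", 1:100)
  germ <- universe[1:40]
  sam <- universe[11:60]                     # intersection 30
  r <- hypermethylation_overlap_test(universe, germ, sam)
  expect_equal(r$ratio, 0.75)
  expect_equal(r$table[1, 1], 30)
  expect_equal(r$p_value, oracle_fisher(30, 10, 20, 40), tolerance = 1e-12)
  # germ subset of sam
  expect_equal(hypermethylation_overlap_test(universe, universe[1:20],
                                             universe[1:50])$ratio, 1.0)
  expect_error(hypermethylation_overlap_test(universe, character(), sam),
               "empty germ set")
})

test_that("hypermethylated TE sets support both membership criteria", {
  tes <- make_features("chr1", c(0L, 1000L, 2000L), c(400L, 1400L, 2400L))
  dmrs <- data.table(chrom = "chr1", start = c(100L, 2300L), end = c(200L, 2500L),
                     context = "CHH", direction = c("hyper_in_B", "hyper_in_B"),
                     n_windows = 1L, delta = 0.2, q = 1e-4)
  expect_setequal(hypermethylated_te_set(tes, dmrs), tes$id[c(1, 3)])
  lv <- hypermethylated_te_set(tes, criterion = "level_difference",
                               levels_A = c(0.05, 0.05, 0.5),
                               levels_B = c(0.30, 0.06, 0.55), min_delta = 0.1)
  expect_equal(lv, tes$id[1])
})
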