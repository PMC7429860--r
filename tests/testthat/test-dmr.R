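test_that("two-sided Fisher p matches closed forms and the enumeration oracle", {
  expect_equal(fisher_test_2x2(5, 5, 5, 5), 1.0)
  # only the two extreme tables are as unlikely as [10,0;0,10]
  expect_equal(fisher_test_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_test_2x2(3, 1, 1, 3), oracle_fisher(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_error(fisher_test_2x2(0, 0, 3, 1), "empty sample margin")
  expect_error(fisher_test_2x2(-1, 2, 3, 1), "non-negative")
  # vectorised path agrees with stats::fisher.test
  set.seed(7)
  for (i in 1:50) {
    t <- as.vector(stats::rmultinom(1, sample(4:150, 1), runif(4) + 0.05))
    if (t[1] + t[2] == 0 || t[3] + t[4] == 0) next
    expect_equal(fisher_test_2x2(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the literal step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(11)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("interval merging is inclusive at the gap boundary and idempotent", {
  iv <- data.table(chrom = "chr1", start = c(0L, 300L), end = c(100L, 400L))
  m <- merge_intervals(iv, 200)
  expect_equal(m, data.table(chrom = "chr1", start = 0L, end = 400L))
  iv2 <- data.table(chrom = "chr1", start = c(0L, 301L), end = c(100L, 400L))
  expect_equal(merge_intervals(iv2, 200), iv2)
  single <- data.table(chrom = "chr1", start = 5L, end = 10L)
  expect_equal(merge_intervals(single, 200), single)
  expect_equal(merge_intervals(m, 200), m)
})

test_that("identical samples yield zero DMRs at any setting", {
  set.seed(5)
  pos <- sort(sample(0:19999, 800))
  s <- make_sites("chr1", pos, m = rbinom(800, 8, 0.3), u = rbinom(800, 8, 0.7))
  w <- aggregate_windows(s, c(chr1 = 20000), 100, "CHH")
  expect_equal(nrow(call_dmrs(w, w)), 0L)
  expect_equal(nrow(call_dmrs(w, w, context_thresholds(CHH = 0.01, fdr = 0.5))), 0L)
})

test_that("qualifying windows within the merge gap form one DMR", {
  # two strong hyper windows at [100,200) and [350,450): gap 150 <= 200
  mk <- function(start, m, u) make_window(start = start, width = 50L,
                                          sum_meth = m, sum_total = m + u)
  starts <- seq(0L, 950L, by = 50L)
  wA <- rbindlist(lapply(starts, function(st) mk(st, 10L, 90L)))
  wB <- copy(wA)
  hot <- wB$start %in% c(100L, 150L, 350L, 400L)
  wB[hot == TRUE, `:=`(sum_meth = 60L, sum_total = 100L, level = 0.6)]
  d <- call_dmrs(wA, wB, context_thresholds(CHH = 0.1, merge_gap = 200L))
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 100L)
  expect_equal(d$end, 450L)
  expect_equal(d$direction, "hyper_in_B")
  expect_equal(d$n_windows, 4L)
  # with a merge gap below the separation they stay apart
  d2 <- call_dmrs(wA, wB, context_thresholds(CHH = 0.1, merge_gap = 100L))
  expect_equal(nrow(d2), 2L)
})

test_that("opposite-direction windows never merge", {
  starts <- seq(0L, 450L, by = 50L)
  wA <- rbindlist(lapply(starts, function(st)
    make_window(start = st, width = 50L, sum_meth = 30L, sum_total = 100L)))
  wB <- copy(wA)
  wB[start == 100L, `:=`(sum_meth = 80L, level = 0.8)]
  wB[start == 150L, `:=`(sum_meth = 0L, level = 0.0)]
  d <- call_dmrs(wA, wB, context_thresholds(CHH = 0.1))
  expect_equal(nrow(d), 2L)
  expect_setequal(d$direction, c("hyper_in_B", "hypo_in_B"))
})

test_that("a planted CHH block is recovered as one DMR within a window", {
  pl <- data.table(chrom = "chr1", start = 20000L, end = 20300L,
                   context = "CHH", delta = 0.3)
  spec <- tiny_spec(seed = 21, bb_rho = 0, coverage_mean = 25,
                    chh_edge_amp = c(vegetative = 0.1, reproductive = 0.1),
                    planted = pl)
  g <- generate_genome(spec)
  A <- generate_methylome(g, spec, "vegetative")
  B <- generate_methylome(g, spec, "reproductive")
  wA <- aggregate_windows(A$sites, g$chrom_sizes, 100, "CHH")
  wB <- aggregate_windows(B$sites, g$chrom_sizes, 100, "CHH")
  d <- call_dmrs(wA, wB)
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hyper_in_B")
  expect_lte(abs(d$start - 20000L), 100L)
  expect_lte(abs(d$end - 20300L), 100L)
})

test_that("stricter thresholds and wider gaps act monotonically", {
  spec <- tiny_spec(seed = 31, bb_rho = 0, coverage_mean = 15)
  g <- generate_genome(spec)
  A <- generate_methylome(g, spec, "vegetative")
  B <- generate_methylome(g, spec, "reproductive")
  wA <- aggregate_windows(A$sites, g$chrom_sizes, 100, "CHH")
  wB <- aggregate_windows(B$sites, g$chrom_sizes, 100, "CHH")
  counts <- sapply(c(0.05, 0.1, 0.2, 0.4), function(thr)
    nrow(call_dmrs(wA, wB, context_thresholds(CHH = thr))))
  expect_true(all(diff(counts) <= 0))
  gaps <- c(0L, 100L, 200L, 500L)
  res <- lapply(gaps, function(g_) call_dmrs(wA, wB, context_thresholds(merge_gap = g_)))
  n <- sapply(res, nrow)
  bp <- sapply(res, function(d) sum(d$end - d$start))
  expect_true(all(diff(n) <= 0))
  expect_true(all(diff(bp) >= 0))
})

test_that("DMR set overlap counts shared regions from both perspectives", {
  a <- data.table(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L))
  b <- data.table(chrom = "chr1", start = 99L, end = 200L)
  ov <- dmr_set_overlap(a, b)
  expect_equal(ov$shared_A, 1L)   # 1-bp overlap counts
  expect_equal(ov$only_A, 1L)
  expect_equal(ov$shared_B, 1L)
  # disjoint and identical sets
  expect_equal(dmr_set_overlap(a, data.table(chrom = "chr2", start = 0L, end = 10L))$shared_A, 0L)
  ident <- dmr_set_overlap(a, a)
  expect_equal(ident$shared_A, 2L)
  expect_equal(ident$shared_B, 2L)
})

test_that("per-DMR levels reflect the call and flag missing contexts", {
  pl <- data.table(chrom = "chr1", start = 10000L, end = 10300L,
                   context = "CHH", delta = 0.3)
  spec <- tiny_spec(seed = 41, bb_rho = 0, coverage_mean = 25,
                    chh_edge_amp = c(vegetative = 0.1, reproductive = 0.1),
                    planted = pl)
  g <- generate_genome(spec)
  A <- generate_methylome(g, spec, "vegetative")
  B <- generate_methylome(g, spec, "reproductive")
  wA <- aggregate_windows(A$sites, g$chrom_sizes, 100, "CHH")
  wB <- aggregate_windows(B$sites, g$chrom_sizes, 100, "CHH")
  d <- call_dmrs(wA, wB)
  lv <- dmr_levels(d, list(veg = A$sites, rep = B$sites), c("CG", "CHH"))
  chh <- dcast(lv[context == "CHH"], chrom + start + end ~ sample_id,
               value.var = "level")
  expect_true(all(chh$rep - chh$veg >= 0.1))
  # independent contexts: CG shows no systematic shift over CHH DMRs
  cg <- dcast(lv[context == "CG"], chrom + start + end ~ sample_id,
              value.var = "level")
  expect_true(all(abs(cg$rep - cg$veg) < 0.1, na.rm = TRUE))
  # DMR with no CG sites -> undefined cell
  fake <- data.table(chrom = "chr1", start = 0L, end = 1L, context = "CHH",
                     direction = "hyper_in_B", n_windows = 1L, delta = 0.2,
                     q = 1e-5)
  lv2 <- dmr_levels(fake, list(veg = A$sites[context == "CHH" & pos > 10]), "CG")
  expect_true(is.na(lv2$level))
})
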