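test_that("a constant methylation field gives flat profiles", {
  pos <- seq(0L, 9999L, by = 10L)
  s <- make_sites("chr1", pos, m = 3L, u = 7L)
  feats <- make_features("chr1", c(3000L, 6000L), c(5000L, 8000L))
  p <- anchored_profile(s, feats, "CHH", "five_prime",
                        upstream = 1000L, into = 2000L, bin = 100L)
  expect_true(all(abs(p$value - 0.3) < 1e-9))
  expect_equal(nrow(p), 30L)  # (1000 + 2000) / 100 bins
})

test_that("positions beyond the feature's far end are excluded from body bins", {
  s <- make_sites("chr1", c(3100L, 4500L), m = 5L, u = 5L)
  feat <- make_features("chr1", 3000L, 4000L)  # 1-kb TE
  p <- anchored_profile(s, feat, "CHH", "five_prime",
                        upstream = 1000L, into = 4000L, bin = 100L)
  expect_equal(p[bin_start == 100L, value], 0.5)
  expect_true(is.na(p[bin_start == 1500L, value]))  # past the far end
  expect_equal(p[bin_start == 1500L, n_features], 0L)
  expect_equal(p[bin_start == 500L, n_features], 1L)
  # the same position is counted for the downstream flank of nothing: bins
  # with zero denominator stay NA, never 0
  expect_true(all(is.na(p$value) | p$denominator > 0))
})

test_that("strand flipping makes mirror-image features identical", {
  # plus-strand feature with a site 150 bp into the body and one 250 bp
  # upstream; minus-strand mirror at the other end of the chromosome
  sp <- make_sites("chr1", c(1150L, 750L), m = c(9L, 1L), u = c(1L, 9L))
  sm <- make_sites("chr1", c(8849L, 9249L), m = c(9L, 1L), u = c(1L, 9L))
  fp <- make_features("chr1", 1000L, 2000L, strand = "+")
  fm <- make_features("chr1", 8000L, 9000L, strand = "-")
  pp <- anchored_profile(sp, fp, "CHH", "five_prime", 1000L, 2000L, 100L)
  pm <- anchored_profile(sm, fm, "CHH", "five_prime", 1000L, 2000L, 100L)
  expect_identical(pp$value, pm$value)
  # and for the 3' anchor
  p3p <- anchored_profile(sp, fp, "CHH", "three_prime", 1000L, 2000L, 100L)
  p3m <- anchored_profile(sm, fm, "CHH", "three_prime", 1000L, 2000L, 100L)
  expect_identical(p3p$value, p3m$value)
  expect_warning(anchored_profile(sp, make_features("chr1", 1000L, 2000L,
                                                    strand = "."),
                                  "CHH", "five_prime", 1000L, 1000L, 100L),
                 "unstranded")
})

test_that("pooled-bin numerators conserve the profiled signal", {
  set.seed(23)
  pos <- sort(sample(0:19999, 600))
  s <- make_sites("chr1", pos, m = rbinom(600, 10, 0.4),
                  u = rbinom(600, 10, 0.6))
  feats <- make_features("chr1", c(5000L, 12000L), c(7000L, 13000L))
  p <- anchored_profile(s, feats, "CHH", "five_prime", 2000L, 3000L, 100L)
  in_range <- s[(pos >= 3000 & pos < 7000) | (pos >= 10000 & pos < 13000)]
  expect_equal(sum(p$numerator), sum(in_range$count_meth))
  expect_equal(sum(p$denominator),
               sum(in_range$count_meth + in_range$count_unmeth))
})

test_that("a feature without covered sites changes no bin value", {
  pos <- seq(0L, 9999L, by = 10L)
  s <- make_sites("chr1", pos, m = 3L, u = 7L)
  f1 <- make_features("chr1", 3000L, 5000L)
  f2 <- rbind(f1, make_features("chr2", 100L, 2100L, id = "MITE_x"))
  p1 <- anchored_profile(s, f1, "CHH", "five_prime", 1000L, 2000L, 100L)
  p2 <- anchored_profile(s, f2, "CHH", "five_prime", 1000L, 2000L, 100L)
  expect_equal(p2$value, p1$value)
  expect_equal(p2$n_features, p1$n_features + 1L)
})

test_that("smRNA metaprofile normalises to average RPM per contributing feature", {
  reads <- data.table(chrom = "chr1", start = seq(1000L, 1023L),
                      end = seq(1024L, 1047L), strand = "+", length_nt = 24L)
  feat <- make_features("chr1", 1000L, 3000L)
  p <- smrna_metaprofile(reads, feat, 24L, total_mapped = 12e6,
                         upstream = 1000L, into = 2000L, bin = 100L)
  expect_equal(p[bin_start == 0L, value], 2.0)  # 24 reads / 12 M * 1e6 / 1 feature
  # a different length class leaves the 24-nt profile empty
  p21 <- smrna_metaprofile(reads, feat, 21L, total_mapped = 12e6,
                           upstream = 1000L, into = 2000L, bin = 100L)
  expect_equal(sum(p21$numerator), 0)
  expect_error(smrna_metaprofile(reads, feat, 24L, total_mapped = 0), "positive")
})

test_that("edge-concentrated 24-nt reads produce an edge peak over TEs", {
  spec <- tiny_spec(seed = 51, smrna_n_reads = 30000L)
  g <- generate_genome(spec)
  reads <- generate_smrna(g, spec, "reproductive")
  p <- smrna_metaprofile(reads, g$tes, 24L, attr(reads, "total_mapped"),
                         "five_prime", 1000L, 1000L, 100L)
  edge <- mean(p[bin_start %in% c(-100L, 0L), value], na.rm = TRUE)
  body <- mean(p[bin_start >= 400L, value], na.rm = TRUE)
  expect_gt(edge, 2 * body)
})

test_that("feature subsets profile independently and cover the whole set", {
  pos <- seq(0L, 9999L, by = 10L)
  s <- make_sites("chr1", pos, m = 3L, u = 7L)
  feats <- make_features("chr1", c(2000L, 6000L), c(4000L, 8000L))
  whole <- anchored_profile(s, feats, "CHH", "five_prime", 1000L, 1000L, 100L)
  subs <- profile_feature_subsets(s, feats, c("x", "x"), "CHH", "five_prime",
                                  1000L, 1000L, 100L)
  expect_equal(subs$x$value, whole$value)
  # NA labels fall into "other"
  subs2 <- profile_feature_subsets(s, feats, c("a", NA), "CHH", "five_prime",
                                   1000L, 1000L, 100L)
  expect_setequal(names(subs2), c("a", "other"))
})
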