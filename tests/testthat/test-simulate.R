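test_that("context scanning agrees with an IUPAC pattern-match oracle", {
  spec <- tiny_spec(seed = 71, chrom_length = 20000L, n_genes = 2L, n_tes = 3L)
  g <- generate_genome(spec)
  seq <- Biostrings::DNAString(g$seqs[["chr1"]])
  count_ctx <- function(subject, pat)
    length(Biostrings::matchPattern(pat, subject, fixed = FALSE))
  plus <- g$sites[strand == "+"]
  minus <- g$sites[strand == "-"]
  # plus strand: matches of CGN / CHG / CHH anchored at the C
  expect_equal(sum(plus$context == "CG"), count_ctx(seq, "CGN"))
  expect_equal(sum(plus$context == "CHG"), count_ctx(seq, "CHG"))
  expect_equal(sum(plus$context == "CHH"), count_ctx(seq, "CHH"))
  # plus-strand CG positions match the oracle exactly
  m <- Biostrings::matchPattern("CGN", seq, fixed = FALSE)
  expect_equal(plus[context == "CG", pos], Biostrings::start(m) - 1L)
  # minus strand: same patterns on the reverse complement
  rc <- Biostrings::reverseComplement(seq)
  expect_equal(sum(minus$context == "CG"), count_ctx(rc, "CGN"))
  expect_equal(sum(minus$context == "CHG"), count_ctx(rc, "CHG"))
  expect_equal(sum(minus$context == "CHH"), count_ctx(rc, "CHH"))
  # at balanced GC, asymmetric CHH sites dominate symmetric CG sites
  expect_gt(sum(g$sites$context == "CHH"), sum(g$sites$context == "CG"))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- tiny_spec(seed = 72, chrom_length = 20000L, n_genes = 2L, n_tes = 4L,
                    smrna_n_reads = 2000L)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(g1$tes, g2$tes)
  expect_identical(generate_methylome(g1, spec, "vegetative")$sites,
                   generate_methylome(g2, spec, "vegetative")$sites)
  expect_identical(generate_smrna(g1, spec, "leaf"),
                   generate_smrna(g2, spec, "leaf"))
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("infeasible feature packing is rejected", {
  expect_error(generate_genome(sim_spec(seed = 1, n_chroms = 1,
                                        chrom_length = 10000L,
                                        n_genes = 40L, n_tes = 60L)),
               "infeasible packing")
})

test_that("zero condition effect gives identical truth fields", {
  spec <- tiny_spec(seed = 73, chrom_length = 20000L, n_genes = 2L, n_tes = 4L,
                    chh_edge_amp = c(vegetative = 0.1, reproductive = 0.1))
  g <- generate_genome(spec)
  expect_identical(methylome_truth(g, spec, "vegetative"),
                   methylome_truth(g, spec, "reproductive"))
})

test_that("binomial counts at fixed coverage recover compartment truth", {
  spec <- tiny_spec(seed = 74, bb_rho = 0, coverage_mean = 10,
                    coverage_size = Inf)
  g <- generate_genome(spec)
  mm <- generate_methylome(g, spec, "vegetative")
  joined <- cbind(mm$sites, rate = mm$truth$rate)
  # group sites by their exact true rate (pure compartments, no edge decay)
  for (r in c(0.02, 0.05, 0.55, 0.85)) {
    grp <- joined[abs(rate - r) < 1e-12]
    if (nrow(grp) < 100) next
    tot <- sum(grp$count_meth + grp$count_unmeth)
    obs <- sum(grp$count_meth) / tot
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / tot))
  }
  # beta-binomial counts at rho > 0 show inflated variance relative to binomial
  spec2 <- tiny_spec(seed = 74, bb_rho = 0.2, coverage_mean = 10,
                     coverage_size = Inf)
  m2 <- generate_methylome(g, spec2, "vegetative")
  j2 <- cbind(m2$sites, rate = mm$truth$rate)
  v_bb <- j2[abs(rate - 0.55) < 1e-12 & count_meth + count_unmeth == 10,
             var(count_meth)]
  v_b <- joined[abs(rate - 0.55) < 1e-12 & count_meth + count_unmeth == 10,
                var(count_meth)]
  expect_gt(v_bb, 1.5 * v_b)
})

test_that("the CHH edge bump decays into TE bodies with the stated amplitude", {
  spec <- tiny_spec(seed = 75, chrom_length = 100000L, n_genes = 8L,
                    n_tes = 12L)
  g <- generate_genome(spec)
  tr <- methylome_truth(g, spec, "reproductive")
  amp <- spec$chh_edge_amp[["reproductive"]]
  # for each non-MITE TE longer than 1.2 kb, truth at the 5' edge is near
  # base + amp (both-end sum adds little) and decays toward the body
  long <- g$tes[family != "MITE" & end - start > 1200]
  for (k in seq_len(nrow(long))) {
    e5 <- tr[chrom == long$chrom[k] & context == "CHH" &
               pos >= long$start[k] & pos < long$start[k] + 50]
    mid <- tr[chrom == long$chrom[k] & context == "CHH" &
                pos >= long$start[k] + 500 & pos < long$end[k] - 500]
    if (nrow(e5) < 3 || nrow(mid) < 3) next
    expect_gt(mean(e5$rate), 0.05 + amp * exp(-50 / spec$edge_decay) * 0.8)
    expect_lt(mean(mid$rate), mean(e5$rate))
  }
})

test_that("smRNA generation honours the size mix and edge enrichment", {
  # point mass at 24 nt
  mix <- setNames(as.numeric(18:26 == 24), 18:26)
  spec <- tiny_spec(seed = 76, smrna_n_reads = 2000L,
                    smrna_size_mix = list(vegetative = mix, reproductive = mix,
                                          leaf = mix))
  g <- generate_genome(spec)
  reads <- generate_smrna(g, spec, "vegetative")
  expect_true(all(reads$length_nt == 24L))
  expect_equal(attr(reads, "total_mapped"), 2000L)
  # enrichment 1 means uniform: edge and body bins carry similar RPM
  spec_u <- tiny_spec(seed = 77, smrna_n_reads = 50000L,
                      smrna_edge_enrichment = 1)
  gu <- generate_genome(spec_u)
  ru <- generate_smrna(gu, spec_u, "reproductive")
  p <- smrna_metaprofile(ru, gu$tes, 24L, attr(ru, "total_mapped"),
                         "five_prime", 1000L, 1000L, 100L)
  # compare the near-edge flank bin with distant flank bins (both are
  # always fully covered, unlike body bins of short TEs)
  edge <- p[bin_start == -100L, value]
  far <- mean(p[bin_start <= -600L, value], na.rm = TRUE)
  expect_lt(abs(edge / far - 1), 0.5)
})
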