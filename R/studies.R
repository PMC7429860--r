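# Reusable simulation studies over the pipeline. These power the analysis
# drivers and the acceptance checks, so their conditions (sample sizes,
# coverages, planted effect sizes) are fixed here in one place.

#' False-positive study: two libraries from one truth field
#'
#' Draws pairs of methylomes from the same (vegetative) truth field —
#' no condition effect — and measures the fraction of testable CHH windows
#' reaching `q < fdr` across replicates.
#'
#' @param seed master seed.
#' @param n_seeds number of replicate pairs (default 20).
#' @param chrom_length toy chromosome length (one chromosome; default
#'   250 kb, about 2,500 CHH windows).
#' @param fdr FDR cutoff being audited (default 0.01).
#' @return list with `fraction` (pooled over replicates), `n_windows`
#'   (total testable windows), `per_seed` table.
#' @export
type1_study <- function(seed = 1L, n_seeds = 20L, chrom_length = 250000L,
                        fdr = 0.01) {
  spec <- sim_spec(seed = seed, n_chroms = 1L, chrom_length = chrom_length,
                   n_genes = 25L, n_tes = 38L)
  g <- generate_genome(spec)
  thr <- context_thresholds(fdr = fdr)
  per <- rbindlist(lapply(seq_len(n_seeds), function(s) {
    A <- generate_methylome(g, spec, "vegetative", seed = seed + 2L * s)
    B <- generate_methylome(g, spec, "vegetative", seed = seed + 2L * s + 1L)
    wA <- aggregate_windows(A$sites, g$chrom_sizes, 100L, "CHH")
    wB <- aggregate_windows(B$sites, g$chrom_sizes, 100L, "CHH")
    wt <- window_tests(wA, wB, thr)
    data.table(seed = s, n_testable = sum(wt$testable),
               n_sig = sum(wt$q_value < fdr, na.rm = TRUE))
  }))
  list(fraction = sum(per$n_sig) / sum(per$n_testable),
       n_windows = sum(per$n_testable), per_seed = per)
}

#' Planted-DMR recovery study
#'
#' Plants differential blocks at 1.5x the context delta thresholds
#' (CG +0.6, CHG +0.3, CHH +0.15) on low-methylation background away from
#' genes and TEs, simulates both conditions with binomial counts at 15x
#' mean coverage (pooled window depth >= 120 reads), calls windows, and
#' scores window-level sensitivity and precision against the planted truth.
#' Sensitivity is evaluated over planted windows whose pooled depth reaches
#' 120 reads in both samples; precision over all called windows.
#'
#' @param seed master seed.
#' @param n_seeds replicate count (default 20).
#' @param chrom_length toy chromosome length (default 50 kb).
#' @param block_bp planted block width (default 300, three windows).
#' @param min_pool minimum pooled reads per window for the sensitivity
#'   denominator (default 120).
#' @return list with `sensitivity`, `precision`, `n_planted_windows`,
#'   `n_called_windows`, `per_seed` table.
#' @export
recovery_study <- function(seed = 1L, n_seeds = 20L, chrom_length = 50000L,
                           block_bp = 300L, min_pool = 120L) {
  thr <- context_thresholds()
  deltas <- c(CG = 0.6, CHG = 0.3, CHH = 0.15)  # 1.5x each threshold
  per <- rbindlist(lapply(seq_len(n_seeds), function(s) {
    spec0 <- sim_spec(seed = seed + 1000L * s, n_chroms = 1L,
                      chrom_length = chrom_length, n_genes = 4L, n_tes = 6L,
                      bb_rho = 0, coverage_mean = 15,
                      chh_edge_amp = c(vegetative = 0.15, reproductive = 0.15))
    g <- generate_genome(spec0)
    # candidate blocks on a 2-kb grid, kept clear of features and bump reach
    cand <- data.table(chrom = "chr1",
                       start = seq(2000L, chrom_length - 3000L, by = 2000L))
    cand[, end := start + block_bp]
    buffer <- 800L
    feats <- rbind(g$genes[, .(chrom, start, end)], g$tes[, .(chrom, start, end)])
    feats[, `:=`(start = pmax(0L, start - buffer), end = end + buffer)]
    keep <- !.overlaps_any(cand, feats)
    blocks <- head(cand[keep], 8L)
    planted <- rbindlist(lapply(names(deltas), function(ctx)
      data.table(chrom = blocks$chrom, start = blocks$start, end = blocks$end,
                 context = ctx, delta = deltas[[ctx]])))
    spec <- do.call(sim_spec, c(list(
      seed = spec0$seed, n_chroms = 1L, chrom_length = chrom_length,
      n_genes = 4L, n_tes = 6L, bb_rho = 0, coverage_mean = 15,
      chh_edge_amp = c(vegetative = 0.15, reproductive = 0.15),
      planted = planted)))
    g2 <- generate_genome(spec)   # same seed: identical genome
    A <- generate_methylome(g2, spec, "vegetative")
    B <- generate_methylome(g2, spec, "reproductive")
    res <- rbindlist(lapply(names(deltas), function(ctx) {
      wA <- aggregate_windows(A$sites, g2$chrom_sizes, 100L, ctx)
      wB <- aggregate_windows(B$sites, g2$chrom_sizes, 100L, ctx)
      wt <- window_tests(wA, wB, thr)
      called <- wt$testable & !is.na(wt$q_value) & wt$q_value < thr$fdr &
        abs(wt$delta) >= thr$delta[[ctx]]
      in_block <- .overlaps_any(wt, blocks)
      deep <- wA$sum_total >= min_pool & wB$sum_total >= min_pool
      data.table(context = ctx,
                 tp = sum(called & in_block & deep),
                 planted_deep = sum(in_block & deep),
                 called = sum(called),
                 called_in_block = sum(called & in_block))
    }))
    res[, seed := s]
    res
  }))
  list(sensitivity = sum(per$tp) / sum(per$planted_deep),
       precision = sum(per$called_in_block) / sum(per$called),
       n_planted_windows = sum(per$planted_deep),
       n_called_windows = sum(per$called), per_seed = per)
}

#' Structural study on the default study conditions
#'
#' Runs the default simulated comparison (vegetative vs reproductive
#' meristem) through the full pipeline and extracts the structural
#' signatures: where CHH hyper-DMR bp falls (TEs vs gene bodies), the MITE
#' family enrichment, the TE-edge peak of the CHH metagene profile with a
#' truth-referenced amplitude check, the difference-density modes at TE
#' edges (CHH vs CG), and the 24-nt small-RNA fractions per condition.
#'
#' @param seed master seed.
#' @return list of summaries (see source for fields).
#' @export
structural_study <- function(seed = 1L) {
  spec <- sim_spec(seed = seed)
  g <- generate_genome(spec)
  A <- generate_methylome(g, spec, "vegetative")
  B <- generate_methylome(g, spec, "reproductive")
  thr <- context_thresholds()
  wA_chh <- aggregate_windows(A$sites, g$chrom_sizes, 100L, "CHH")
  wB_chh <- aggregate_windows(B$sites, g$chrom_sizes, 100L, "CHH")
  dmrs <- call_dmrs(wA_chh, wB_chh, thr)
  hyper <- dmrs[direction == "hyper_in_B"]
  cats <- categorize_dmrs(hyper, g$genes, g$tes)
  fams <- family_breakdown(hyper, g$tes)
  # metagene: observed vs truth-expected profile with matched weights
  prof_obs <- anchored_profile(B$sites, g$tes, "CHH", "five_prime")
  expected_sites <- copy(B$sites)
  tot <- expected_sites$count_meth + expected_sites$count_unmeth
  expected_sites[, count_meth := B$truth$rate * tot]
  expected_sites[, count_unmeth := tot - count_meth]
  prof_exp <- anchored_profile(expected_sites, g$tes, "CHH", "five_prime")
  deff <- 1 + (spec$coverage_mean - 1) * spec$bb_rho
  se_bin <- function(p, n) sqrt(pmax(p * (1 - p), 1e-6) * deff / n)
  peak_bin <- prof_obs$bin_start[which.max(prof_obs$value)]
  body_bins <- prof_obs$bin_start >= 600L & prof_obs$bin_start < 1000L
  edge_bin <- prof_obs$bin_start == 0L
  amp_obs <- prof_obs$value[edge_bin] - mean(prof_obs$value[body_bins], na.rm = TRUE)
  amp_exp <- prof_exp$value[edge_bin] - mean(prof_exp$value[body_bins], na.rm = TRUE)
  se_amp <- sqrt(se_bin(prof_exp$value[edge_bin], prof_obs$denominator[edge_bin])^2 +
                   sum(se_bin(prof_exp$value[body_bins],
                              prof_obs$denominator[body_bins])^2) /
                   sum(body_bins)^2)
  # difference densities restricted to TE edge zones
  zone <- 200L
  edges <- rbind(g$tes[, .(chrom, start = pmax(0L, start - zone), end = start + zone)],
                 g$tes[, .(chrom, start = pmax(0L, end - zone), end = end + zone)])
  dd_chh <- difference_density(wA_chh, wB_chh, region_set = edges)
  wA_cg <- aggregate_windows(A$sites, g$chrom_sizes, 100L, "CG")
  wB_cg <- aggregate_windows(B$sites, g$chrom_sizes, 100L, "CG")
  dd_cg <- difference_density(wA_cg, wB_cg, region_set = edges)
  # small-RNA size classes per condition
  f24 <- sapply(c("leaf", "vegetative", "reproductive"), function(cond) {
    r <- generate_smrna(g, spec, cond)
    size_class_fractions(r)[size_class == 24, fraction]
  })
  list(dmrs = dmrs, categories = cats, families = fams,
       te_fraction = cats[category %in% c("TE_intergenic", "TE_genic"), sum(fraction)],
       gene_fraction = cats[category == "gene_body", fraction],
       mite_enrichment = fams[family == "MITE", enrichment],
       profile = prof_obs, profile_expected = prof_exp,
       peak_offset_bp = peak_bin,
       amplitude_obs = amp_obs, amplitude_expected = amp_exp,
       amplitude_z = (amp_obs - amp_exp) / se_amp,
       diff_mode_chh_edges = dd_chh$mode, diff_mode_cg_edges = dd_cg$mode,
       n_density_windows = dd_chh$n_windows,
       smrna24_fractions = f24)
}

#' Null study for the hypermethylation set statistic
#'
#' Draws independent random germ/meristem membership sets over a TE
#' universe and summarises the overlap ratio relative to its independence
#' expectation (`|sam| / |universe|`) and the Fisher p-values.
#'
#' @param seed master seed.
#' @param n_seeds replicates (default 20).
#' @param n_universe universe size (default 2000).
#' @param n_germ,n_sam set sizes.
#' @return list with `mean_relative_enrichment` (≈ 1 under independence),
#'   `median_p`, `per_seed`.
#' @export
random_set_study <- function(seed = 1L, n_seeds = 20L, n_universe = 2000L,
                             n_germ = 400L, n_sam = 500L) {
  universe <- paste0("te", seq_len(n_universe))
  per <- rbindlist(lapply(seq_len(n_seeds), function(s) {
    set.seed(seed + s)
    germ <- sample(universe, n_germ)
    sam <- sample(universe, n_sam)
    r <- hypermethylation_overlap_test(universe, germ, sam)
    data.table(seed = s, ratio = r$ratio, p = r$p_value)
  }))
  list(mean_relative_enrichment = mean(per$ratio) / (n_sam / n_universe),
       median_p = stats::median(per$p), per_seed = per)
}
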