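#!/usr/bin/env Rscript
# Germ-cell/SAM hypermethylation set statistics: simulate a germ-cell-like
# condition (strongest CHH edge gain), define TEs hypermethylated in germ
# vs leaf and in the SAM comparisons, and test whether germ-hypermethylated
# TEs were already hypermethylated in the SAM.

source("analysis/common.R")

out <- res_dir("germ")
sim <- "results/sim"
spec <- study_spec()
genome <- generate_genome(spec)
tes <- genome$tes
chrom_sizes <- genome$chrom_sizes
thr <- context_thresholds()

leaf <- read_cytosine_report(file.path(sim, "report_leaf.tsv.gz"))
veg <- read_cytosine_report(file.path(sim, "report_vegetative.tsv.gz"))
rep_ <- read_cytosine_report(file.path(sim, "report_reproductive.tsv.gz"))
germ <- generate_methylome(genome, spec, "germ")$sites
write_cytosine_report(germ, file.path(out, "report_germ.tsv.gz"))

call_pair <- function(a, b) {
  wA <- aggregate_windows(a, chrom_sizes, 100L, "CHH")
  wB <- aggregate_windows(b, chrom_sizes, 100L, "CHH")
  suppressWarnings(call_dmrs(wA, wB, thr))
}
sets <- list(veg_vs_leaf = call_pair(leaf, veg),
             rep_vs_veg = call_pair(veg, rep_))
# "highly methylated in germ cells": pooled CHH body level gain over the
# leaf of at least 0.15 (the SAM sets use the DMR-overlap criterion)
lv_leaf <- feature_body_levels(tes, leaf, "CHH")
lv_germ <- feature_body_levels(tes, germ, "CHH")
te_sets <- lapply(sets, function(d) hypermethylated_te_set(tes, d))
te_sets$germ_vs_leaf <- hypermethylated_te_set(
  tes, criterion = "level_difference", levels_A = lv_leaf$level,
  levels_B = lv_germ$level, min_delta = 0.15)
sam_any <- union(te_sets$veg_vs_leaf, te_sets$rep_vs_veg)

# germ metaprofile alongside the organs (edge + body gain)
p_germ <- anchored_profile(germ, tes, "CHH", "five_prime")
fwrite(p_germ, file.path(out, "meth_germ_TEs_CHH_five_prime.tsv"), sep = "\t")

res <- rbindlist(lapply(c(veg = "veg_vs_leaf", rep = "rep_vs_veg"), function(nm) {
  r <- hypermethylation_overlap_test(tes$id, te_sets$germ_vs_leaf, te_sets[[nm]])
  data.table(sam_set = nm, ratio = r$ratio, odds_ratio = r$odds_ratio,
             p = r$p_value)
}))
r_any <- hypermethylation_overlap_test(tes$id, te_sets$germ_vs_leaf, sam_any)
res <- rbind(res, data.table(sam_set = "either_sam", ratio = r_any$ratio,
                             odds_ratio = r_any$odds_ratio, p = r_any$p))
fwrite(res, file.path(out, "germ_sam_overlap.tsv"), sep = "\t")
say("germ-hyper TEs: %d of %d; SAM-hyper (either comparison): %d",
    length(te_sets$germ_vs_leaf), nrow(tes), length(sam_any))
say("share of germ-hyper TEs already CHH-hypermethylated in the SAM: %.1f%% (p = %.3g)",
    100 * r_any$ratio, r_any$p)
print(res)
say("wrote %s", out)
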