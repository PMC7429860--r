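#!/usr/bin/env Rscript
# Windowed DMR calling for both organ comparisons (vegetative SAM vs leaf,
# reproductive vs vegetative SAM) in all three contexts, plus the CHH
# DMR-set overlap and per-DMR level matrix.

source("analysis/common.R")

out <- res_dir("dmrs")
sim <- "results/sim"
conds <- c("leaf", "vegetative", "reproductive")
reports <- lapply(setNames(conds, conds), function(cond)
  read_cytosine_report(file.path(sim, paste0("report_", cond, ".tsv.gz"))))
chrom_sizes <- setNames(rep(study_spec()$chrom_length, 2), c("chr1", "chr2"))
thr <- context_thresholds()

pairs <- list(veg_vs_leaf = c("leaf", "vegetative"),
              rep_vs_veg = c("vegetative", "reproductive"))
all_dmrs <- list()
for (nm in names(pairs)) {
  a <- pairs[[nm]][1]; b <- pairs[[nm]][2]
  per_ctx <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    wA <- aggregate_windows(reports[[a]], chrom_sizes, 100L, ctx)
    wB <- aggregate_windows(reports[[b]], chrom_sizes, 100L, ctx)
    wt <- window_tests(wA, wB, thr)
    fwrite(wt, file.path(out, sprintf("window_tests_%s_%s.tsv.gz", nm, ctx)),
           sep = "\t")
    d <- suppressWarnings(call_dmrs(wA, wB, thr))
    per_ctx[[ctx]] <- d
    say("%s %s: %d/%d windows testable, %d DMRs (%d hyper, %d hypo)",
        nm, ctx, sum(wt$testable), nrow(wt), nrow(d),
        sum(d$direction == "hyper_in_B"), sum(d$direction == "hypo_in_B"))
  }
  dmrs <- rbindlist(per_ctx)
  all_dmrs[[nm]] <- dmrs
  write_dmr_bed(dmrs, file.path(out, paste0("dmrs_", nm, ".bed")))
}

# counts table (hyper = higher in the second-named organ)
cmp <- dmr_comparison_table(all_dmrs)
fwrite(cmp, file.path(out, "dmr_counts.tsv"), sep = "\t")
print(cmp)

# CHH DMR set overlap between the two comparisons (Venn input)
ov <- dmr_set_overlap(all_dmrs$veg_vs_leaf[context == "CHH"],
                      all_dmrs$rep_vs_veg[context == "CHH"])
fwrite(as.data.table(ov), file.path(out, "chh_dmr_set_overlap.tsv"), sep = "\t")
say("CHH DMR overlap: only veg_vs_leaf %d, only rep_vs_veg %d, shared %d/%d",
    ov$only_A, ov$only_B, ov$shared_A, ov$shared_B)

# per-DMR methylation levels for all contexts in all organs (heat-map input)
hyper <- all_dmrs$rep_vs_veg[context == "CHH" & direction == "hyper_in_B"]
lv <- dmr_levels(hyper, reports)
fwrite(lv, file.path(out, "rep_hyper_chh_dmr_levels.tsv"), sep = "\t")
wide <- dcast(lv, chrom + start + end + context ~ sample_id, value.var = "level")
say("rep-hyper CHH DMRs: %d; mean level leaf/veg/rep in CHH: %.3f/%.3f/%.3f",
    nrow(hyper),
    wide[context == "CHH", mean(leaf, na.rm = TRUE)],
    wide[context == "CHH", mean(vegetative, na.rm = TRUE)],
    wide[context == "CHH", mean(reproductive, na.rm = TRUE)])
say("wrote %s", out)
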