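#!/usr/bin/env Rscript
# Chromosome-scale methylation levels (heat-map input) and genome-wide
# per-window difference distributions between organs, per context.

source("analysis/common.R")

out <- res_dir("global")
sim <- "results/sim"
conds <- c("leaf", "vegetative", "reproductive")
reports <- lapply(setNames(conds, conds), function(cond)
  read_cytosine_report(file.path(sim, paste0("report_", cond, ".tsv.gz"))))
chrom_sizes <- setNames(rep(study_spec()$chrom_length, 2), c("chr1", "chr2"))

# 100-kb tiles play the role of the chromosome-scale windows on this toy
# genome; levels are scaled to the per-context maximum across organs.
for (ctx in c("CG", "CHG", "CHH")) {
  levs <- lapply(reports, chromosome_levels, chrom_sizes = chrom_sizes,
                 window = 100000L, context = ctx)
  levs <- scale_to_context_max(levs)
  tab <- rbindlist(lapply(names(levs), function(cond)
    cbind(organ = cond, levs[[cond]])))
  fwrite(tab, file.path(out, paste0("chromosome_levels_", ctx, ".tsv")),
         sep = "\t")
  say("%s: global levels %s", ctx,
      paste(sprintf("%s %.3f", names(levs),
                    sapply(levs, function(l) mean(l$level, na.rm = TRUE))),
            collapse = ", "))
}

# difference densities in 50-bp windows for the two organ comparisons
pairs <- list(veg_vs_leaf = c("leaf", "vegetative"),
              rep_vs_veg = c("vegetative", "reproductive"))
for (ctx in c("CG", "CHG", "CHH")) {
  for (nm in names(pairs)) {
    a <- pairs[[nm]][1]; b <- pairs[[nm]][2]
    wA <- aggregate_windows(reports[[a]], chrom_sizes, 50L, ctx)
    wB <- aggregate_windows(reports[[b]], chrom_sizes, 50L, ctx)
    dd <- difference_density(wA, wB)
    fwrite(dd$histogram, file.path(out, sprintf("diffdensity_%s_%s.tsv", nm, ctx)),
           sep = "\t")
    say("%s %s: %d windows, mode %+0.2f, mean diff %+0.4f", nm, ctx,
        dd$n_windows, dd$mode, mean(dd$differences))
  }
}
say("wrote %s", out)
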