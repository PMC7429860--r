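#!/usr/bin/env Rscript
# Attribute DMR base pairs to genomic features and TE families, group TEs by
# CHH methylation change, and relate gene-flank methylation to MITE
# proximity.

source("analysis/common.R")

out <- res_dir("overlap")
sim <- "results/sim"
genes <- read_features(file.path(sim, "genes.bed"), "BED6", "gene")
tes <- read_features(file.path(sim, "tes.bed"), "BED6", "TE")
dmrs <- read_dmr_bed("results/dmrs/dmrs_rep_vs_veg.bed")
hyper <- dmrs[context == "CHH" & direction == "hyper_in_B"]
reports <- lapply(c(vegetative = "vegetative", reproductive = "reproductive"),
                  function(cond) read_cytosine_report(
                    file.path(sim, paste0("report_", cond, ".tsv.gz"))))

cats <- categorize_dmrs(hyper, genes, tes)
fwrite(cats, file.path(out, "rep_hyper_chh_categories.tsv"), sep = "\t")
say("rep-hyper CHH DMR bp: %.1f%% on TEs (%.1f%% intergenic), %.1f%% on gene bodies",
    100 * cats[category %in% c("TE_intergenic", "TE_genic"), sum(fraction)],
    100 * cats[category == "TE_intergenic", fraction],
    100 * cats[category == "gene_body", fraction])

fams <- family_breakdown(hyper, tes)
fwrite(fams, file.path(out, "rep_hyper_chh_families.tsv"), sep = "\t")
say("MITE share of TE-overlapping DMR bp: %.1f%% vs %.1f%% of TE bp (enrichment %.1fx)",
    fams[family == "MITE", overlap_pct], fams[family == "MITE", genome_pct],
    fams[family == "MITE", enrichment])

# TE groups by CHH body-methylation change between the two SAM stages
lvA <- feature_body_levels(tes, reports$vegetative, "CHH")
lvB <- feature_body_levels(tes, reports$reproductive, "CHH")
groups <- classify_te_methylation_change(lvA$level, lvB$level, ids = tes$id)
fwrite(groups, file.path(out, "te_chh_change_groups.tsv"), sep = "\t")
say("TE CHH groups: %s",
    paste(sprintf("%s %d", names(table(groups$group)), table(groups$group)),
          collapse = ", "))

# gene classes by MITE proximity, with flanking CHH levels per class
mites <- tes[family == "MITE"]
gcls <- classify_genes_by_mite_proximity(genes, mites, flank = 1000L)
flanks <- rbind(genes[, .(chrom, start = pmax(0L, start - 500L), end = start,
                          strand, kind, family, id)],
                genes[, .(chrom, start = end, end = end + 500L,
                          strand, kind, family, id)])
fl <- feature_body_levels(flanks, reports$reproductive, "CHH")
fl <- merge(fl[, .(id, level)], gcls[, .(id, mite_class)], by = "id")
cls_means <- fl[, .(mean_flank_chh = mean(level, na.rm = TRUE), n = .N),
                by = mite_class]
fwrite(cls_means, file.path(out, "gene_flank_chh_by_mite_class.tsv"), sep = "\t")
print(cls_means)
say("wrote %s", out)
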