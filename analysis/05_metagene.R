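#!/usr/bin/env Rscript
# Edge-anchored metagene profiles: methylation per context around genes and
# TEs for each organ, 24-nt small-RNA RPM profiles, and TE subsets split by
# overlap with reproductive-hypermethylation DMRs.

source("analysis/common.R")

out <- res_dir("metagene")
sim <- "results/sim"
genes <- read_features(file.path(sim, "genes.bed"), "BED6", "gene")
tes <- read_features(file.path(sim, "tes.bed"), "BED6", "TE")
conds <- c("leaf", "vegetative", "reproductive")

for (cond in conds) {
  sites <- read_cytosine_report(file.path(sim, paste0("report_", cond, ".tsv.gz")))
  for (featset in c("genes", "TEs")) {
    feats <- if (featset == "genes") genes else tes
    for (ctx in c("CG", "CHG", "CHH")) {
      for (anch in c("five_prime", "three_prime")) {
        p <- anchored_profile(sites, feats, ctx, anch)
        fwrite(p, file.path(out, sprintf("meth_%s_%s_%s_%s.tsv", cond, featset,
                                         ctx, anch)), sep = "\t")
      }
    }
  }
  p_edge <- fread(file.path(out, sprintf("meth_%s_TEs_CHH_five_prime.tsv", cond)))
  say("%-12s CHH at TE 5' edge bin: %.3f (body 600-1000 bp: %.3f)", cond,
      p_edge[bin_start == 0, value],
      p_edge[bin_start >= 600 & bin_start < 1000, mean(value, na.rm = TRUE)])
}

# 24-nt small-RNA profiles around TEs and genes
for (cond in conds) {
  reads <- read_smrna_bed(file.path(sim, paste0("smrna_", cond, ".bed.gz")))
  for (featset in c("genes", "TEs")) {
    feats <- if (featset == "genes") genes else tes
    p <- smrna_metaprofile(reads, feats, 24L, total_mapped = nrow(reads),
                           anchor = "five_prime")
    fwrite(p, file.path(out, sprintf("smrna24_%s_%s_five_prime.tsv", cond,
                                     featset)), sep = "\t")
  }
  pt <- fread(file.path(out, sprintf("smrna24_%s_TEs_five_prime.tsv", cond)))
  say("%-12s 24-nt RPM at TE 5' edge bin: %.2f", cond, pt[bin_start == 0, value])
}

# TEs overlapping rep-hyper CHH DMRs vs the rest
dmrs <- read_dmr_bed("results/dmrs/dmrs_rep_vs_veg.bed")
hyper_ids <- hypermethylated_te_set(tes, dmrs[context == "CHH"])
labels <- ifelse(tes$id %in% hyper_ids, "dmr_te", "other_te")
sites_rep <- read_cytosine_report(file.path(sim, "report_reproductive.tsv.gz"))
subs <- profile_feature_subsets(sites_rep, tes, labels, "CHH", "five_prime")
for (lab in names(subs))
  fwrite(subs[[lab]], file.path(out, sprintf("meth_reproductive_TEs_CHH_%s.tsv",
                                             lab)), sep = "\t")
say("TE subsets: %d DMR-overlapping, %d other; edge bins %.3f vs %.3f",
    sum(labels == "dmr_te"), sum(labels == "other_te"),
    subs$dmr_te[bin_start == 0, value], subs$other_te[bin_start == 0, value])
say("wrote %s", out)
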