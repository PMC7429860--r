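#!/usr/bin/env Rscript
# Small-RNA size-class composition per organ and normalised emPAI protein
# abundances from the bundled synthetic proteomics table.

source("analysis/common.R")

out <- res_dir("abundance")
sim <- "results/sim"

sizes <- rbindlist(lapply(c("leaf", "vegetative", "reproductive"), function(cond) {
  reads <- read_smrna_bed(file.path(sim, paste0("smrna_", cond, ".bed.gz")))
  cbind(organ = cond, size_class_fractions(reads))
}))
fwrite(sizes, file.path(out, "smrna_size_classes.tsv"), sep = "\t")
f24 <- sizes[size_class == 24]
say("24-nt fraction: %s",
    paste(sprintf("%s %.1f%%", f24$organ, 100 * f24$fraction), collapse = ", "))

# synthetic emPAI table (stand-in for a proteomics search output)
empai <- fread(system.file("extdata", "synthetic_empai.tsv",
                           package = "meristemethyl"))
norm <- normalize_empai(empai)
fwrite(norm, file.path(out, "normalized_empai.tsv"), sep = "\t")
ago <- norm[protein_id %in% c("AGO4a", "AGO4b")]
say("normalised emPAI of AGO4a/AGO4b per sample:")
print(dcast(ago, sample_id ~ protein_id, value.var = "normalized_empai"))
say("wrote %s", out)
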