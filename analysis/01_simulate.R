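#!/usr/bin/env Rscript
# Simulate the toy study: an 0.8-Mb two-chromosome genome with genes and a
# rice-like TE landscape, cytosine reports for three organs, and small-RNA
# libraries. All downstream drivers read these files from results/sim/.

source("analysis/common.R")

spec <- study_spec()
out <- res_dir("sim")

genome <- generate_genome(spec)
write_genome_fasta(genome, file.path(out, "genome.fa"))
fwrite(genome$genes[, .(chrom, start, end, id, 0L, strand)],
       file.path(out, "genes.bed"), sep = "\t", col.names = FALSE)
fwrite(genome$tes[, .(chrom, start, end, id, 0L, strand)],
       file.path(out, "tes.bed"), sep = "\t", col.names = FALSE)

say("genome: %d chromosomes x %d bp, GC %.3f", spec$n_chroms,
    spec$chrom_length, spec$gc)
say("annotation: %d genes, %d TEs (%d MITEs)", nrow(genome$genes),
    nrow(genome$tes), sum(genome$tes$family == "MITE"))
say("cytosine skeleton: %d sites (%s)", nrow(genome$sites),
    paste(sprintf("%s %d", names(table(genome$sites$context)),
                  table(genome$sites$context)), collapse = ", "))

for (cond in c("leaf", "vegetative", "reproductive")) {
  mm <- generate_methylome(genome, spec, cond)
  write_cytosine_report(mm$sites, file.path(out, paste0("report_", cond, ".tsv.gz")))
  fwrite(mm$truth, file.path(out, paste0("truth_", cond, ".tsv.gz")), sep = "\t")
  reads <- generate_smrna(genome, spec, cond)
  write_smrna_bed(reads, file.path(out, paste0("smrna_", cond, ".bed.gz")))
  say("%-12s mean coverage %.1f, global CHH level %.4f, %d smRNA reads",
      cond, mean(mm$sites$count_meth + mm$sites$count_unmeth),
      mm$sites[context == "CHH", sum(count_meth) / sum(count_meth + count_unmeth)],
      nrow(reads))
}
say("wrote %s", out)
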