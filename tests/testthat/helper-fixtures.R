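library(data.table)

# one-liner site builder (pos is 0-based)
make_sites <- function(chrom, pos, strand = "+", m = 1L, u = 1L,
                       context = "CHH", tri = "CAT") {
  data.table(chrom = chrom, pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             count_meth = as.integer(rep_len(m, length(pos))),
             count_unmeth = as.integer(rep_len(u, length(pos))),
             context = rep_len(context, length(pos)),
             tri = rep_len(tri, length(pos)))
}

make_features <- function(chrom, start, end, strand = "+", kind = "TE",
                          family = "MITE", id = NULL) {
  n <- length(start)
  if (is.null(id)) id <- paste0(rep_len(family, n), "_", seq_len(n))
  data.table(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), strand = rep_len(strand, n),
             kind = rep_len(kind, n),
             family = if (identical(kind, "gene")) "" else rep_len(family, n),
             id = id)
}

# a window row with the fields aggregate_windows() produces
make_window <- function(chrom = "chr1", start = 0L, width = 100L,
                        context = "CHH", n_sites = 5L, n_sites_cov_k = 5L,
                        sum_meth = 10L, sum_total = 100L) {
  data.table(chrom = chrom, start = as.integer(start),
             end = as.integer(start + width), context = context,
             n_sites = as.integer(n_sites),
             n_sites_cov_k = as.integer(n_sites_cov_k),
             sum_meth = as.integer(sum_meth), sum_total = as.integer(sum_total),
             level = ifelse(sum_total > 0, sum_meth / sum_total, NA_real_))
}

# small simulation spec for fast tests
tiny_spec <- function(seed = 1L, chrom_length = 50000L, n_genes = 5L,
                      n_tes = 8L, ...) {
  sim_spec(seed = seed, n_chroms = 1L, chrom_length = chrom_length,
           n_genes = n_genes, n_tes = n_tes, ...)
}
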