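#' Default TE family mix for the toy genome
#'
#' Family weights and log-normal length parameters loosely shaped after a
#' rice-like repeat landscape: abundant short MITEs, long LTR
#' retrotransposons (Ty3-gypsy), mid-sized CACTA and LINE elements, and a
#' remainder bucket.
#'
#' @return `data.table` with `family`, `weight`, `meanlog`, `sdlog`.
#' @export
default_te_families <- function() {
  data.table(
    family  = c("MITE", "Gypsy", "CACTA", "LINE", "Other"),
    weight  = c(0.35, 0.15, 0.15, 0.10, 0.25),
    meanlog = log(c(300, 4000, 2000, 1500, 700)),
    sdlog   = c(0.25, 0.35, 0.35, 0.35, 0.45))
}

#' Simulation specification for the synthetic methylome
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' study conditions at desk scale: a GC-realistic toy genome with genes and
#' a TE landscape (MITEs biased toward gene flanks), context-specific
#' baseline methylation (high CG/CHG in TE bodies, low CHH everywhere),
#' an exponential CHH bump at TE edges whose amplitude differs between
#' conditions (leaf < vegetative < reproductive), beta-binomially dispersed
#' counts under negative-binomial coverage, and condition-specific
#' small-RNA size mixtures with 24-nt reads concentrated at TE edges.
#'
#' @param seed integer master seed; identical seed + spec gives
#'   byte-identical outputs.
#' @param n_chroms,chrom_length toy genome shape.
#' @param gc genome GC fraction.
#' @param n_genes,gene_meanlog,gene_sdlog gene count per chromosome and
#'   log-normal length parameters.
#' @param n_tes TE count per chromosome.
#' @param te_families family mix table ([default_te_families()]).
#' @param mite_near_gene_prob probability a MITE is placed within
#'   `mite_gene_flank` bp of a gene.
#' @param mite_gene_flank flank width for MITE placement bias.
#' @param te_in_gene_prob acceptance probability for a TE overlapping a
#'   gene (otherwise resampled).
#' @param coverage_mean,coverage_size negative-binomial per-site coverage.
#' @param bb_rho beta-binomial overdispersion (0 = binomial counts).
#' @param baseline 3x3 matrix of per-compartment (rows `background`,
#'   `gene_body`, `te_body`) per-context (columns `CG`, `CHG`, `CHH`)
#'   methylation rates.
#' @param chh_edge_amp named vector of CHH edge-bump amplitudes per
#'   condition.
#' @param edge_decay exponential decay length of the edge bump (bp).
#' @param mite_edge_boost multiplicative boost of the edge-bump amplitude
#'   at MITE edges.
#' @param gene_flank_chh flat CHH elevation within `gene_flank_bp` of a
#'   gene (outside TEs).
#' @param gene_flank_bp gene flank width for the CHH elevation.
#' @param smrna_size_mix named list (per condition) of weights over
#'   `smrna_classes`.
#' @param smrna_classes small-RNA size classes (nt).
#' @param smrna_n_reads reads per simulated library.
#' @param smrna_edge_enrichment fold concentration of 24-nt read 5' ends
#'   within `smrna_edge_zone` bp of TE edges (1 = uniform).
#' @param smrna_edge_zone TE edge-zone half-width (bp).
#' @param planted optional `data.table` of explicit differential blocks
#'   (`chrom`, `start`, `end`, `context`, `delta`) added to the
#'   reproductive condition's truth field.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(seed = 1L,
                     n_chroms = 2L, chrom_length = 400000L, gc = 0.43,
                     n_genes = 40L, gene_meanlog = log(2000), gene_sdlog = 0.4,
                     n_tes = 60L, te_families = default_te_families(),
                     mite_near_gene_prob = 0.7, mite_gene_flank = 1000L,
                     te_in_gene_prob = 0.1,
                     coverage_mean = 8, coverage_size = 10,
                     bb_rho = 0.05,
                     baseline = NULL,
                     chh_edge_amp = c(leaf = 0.04, vegetative = 0.15,
                                      reproductive = 0.30),
                     edge_decay = 200,
                     mite_edge_boost = 1.5,
                     gene_flank_chh = 0.05, gene_flank_bp = 500L,
                     smrna_size_mix = NULL,
                     smrna_classes = 18:26,
                     smrna_n_reads = 100000L,
                     smrna_edge_enrichment = 8, smrna_edge_zone = 200L,
                     planted = NULL) {
  if (is.null(baseline)) {
    baseline <- matrix(c(0.10, 0.05, 0.02,
                         0.55, 0.05, 0.02,
                         0.85, 0.55, 0.05),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(c("background", "gene_body", "te_body"),
                                       c("CG", "CHG", "CHH")))
  }
  if (is.null(smrna_size_mix)) {
    # 24-nt shares mirror the meristem (~0.50/0.53) vs leaf (~0.09)
    # contrast; the remainder is spread with a 21-nt secondary class
    rest <- c(`18` = 0.04, `19` = 0.05, `20` = 0.08, `21` = 0.35, `22` = 0.18,
              `23` = 0.12, `25` = 0.10, `26` = 0.08)
    mk <- function(w24) {
      w <- c(rest * (1 - w24) / sum(rest), `24` = w24)
      w[order(as.integer(names(w)))]
    }
    smrna_size_mix <- list(leaf = mk(0.090), vegetative = mk(0.504),
                           reproductive = mk(0.527))
  }
  if (any(baseline < 0 | baseline > 1)) stop("baseline rates must be in [0, 1]")
  if (any(chh_edge_amp < 0 | chh_edge_amp > 1)) stop("edge amplitudes must be in [0, 1]")
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), gc = gc,
    n_genes = as.integer(n_genes), gene_meanlog = gene_meanlog,
    gene_sdlog = gene_sdlog, n_tes = as.integer(n_tes),
    te_families = as.data.table(te_families),
    mite_near_gene_prob = mite_near_gene_prob,
    mite_gene_flank = as.integer(mite_gene_flank),
    te_in_gene_prob = te_in_gene_prob,
    coverage_mean = coverage_mean, coverage_size = coverage_size,
    bb_rho = bb_rho, baseline = baseline, chh_edge_amp = chh_edge_amp,
    edge_decay = edge_decay, mite_edge_boost = mite_edge_boost,
    gene_flank_chh = gene_flank_chh, gene_flank_bp = as.integer(gene_flank_bp),
    smrna_size_mix = smrna_size_mix, smrna_classes = as.integer(smrna_classes),
    smrna_n_reads = as.integer(smrna_n_reads),
    smrna_edge_enrichment = smrna_edge_enrichment,
    smrna_edge_zone = as.integer(smrna_edge_zone),
    planted = if (is.null(planted)) NULL else as.data.table(planted)),
    class = "sim_spec")
}

# non-overlapping interval placement by rejection sampling
.place_intervals <- function(lens, L, occupied, max_tries = 200L,
                             candidate_starts = NULL) {
  placed <- data.table(start = integer(), end = integer())
  occ <- copy(occupied)
  for (len in lens) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      st <- if (!is.null(candidate_starts)) sample(candidate_starts, 1L)
            else sample.int(L - len, 1L) - 1L
      st <- max(0L, min(st, L - len))
      en <- st + len
      if (nrow(occ) == 0L || !any(st < occ$end & en > occ$start)) { ok <- TRUE; break }
    }
    if (!ok) next
    placed <- rbind(placed, data.table(start = st, end = en))
    occ <- rbind(occ, data.table(start = st, end = en))
  }
  placed
}

#' Generate the toy genome and annotations
#'
#' Random sequence at the specified GC, non-overlapping genes, and TEs
#' drawn from the family mix; MITEs are preferentially placed within
#' `mite_gene_flank` bp of a gene and TEs overlap genes only with the
#' configured probability. Cytosine positions on both strands are scanned
#' and classified into CG/CHG/CHH once here, so every downstream module
#' shares one site skeleton.
#'
#' @param spec a [sim_spec()].
#' @return list with `seqs` (named character vector of chromosome
#'   sequences), `chrom_sizes`, `genes`, `tes` (feature tables), `sites`
#'   (site skeleton: `chrom`, `pos`, `strand`, `context`, `tri`), `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  L <- spec$chrom_length
  req_gene <- spec$n_genes * exp(spec$gene_meanlog + spec$gene_sdlog^2 / 2)
  req_te <- spec$n_tes * sum(spec$te_families$weight *
                               exp(spec$te_families$meanlog + spec$te_families$sdlog^2 / 2))
  if (req_gene + req_te > 0.85 * L)
    stop("infeasible packing: requested feature bp exceeds genome capacity")
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  seqs <- character(0)
  genes_all <- list(); tes_all <- list(); sites_all <- list()
  p_base <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
              T = (1 - spec$gc) / 2)
  for (cn in chroms) {
    bases <- sample(names(p_base), L, replace = TRUE, prob = p_base)
    seqs[cn] <- paste(bases, collapse = "")
    # genes
    glens <- pmax(200L, as.integer(round(rlnorm(spec$n_genes, spec$gene_meanlog,
                                                spec$gene_sdlog))))
    g <- .place_intervals(glens, L, data.table(start = integer(), end = integer()))
    genes <- data.table(chrom = cn, start = g$start, end = g$end,
                        strand = sample(c("+", "-"), nrow(g), replace = TRUE),
                        kind = "gene", family = "",
                        id = sprintf("gene_%s_%03d", cn, seq_len(nrow(g))))
    # TEs: family mix, MITE near-gene bias, limited gene overlap
    fam_idx <- sample.int(nrow(spec$te_families), spec$n_tes, replace = TRUE,
                          prob = spec$te_families$weight)
    tes <- data.table(start = integer(), end = integer(), family = character())
    occ_te <- data.table(start = integer(), end = integer())
    for (i in seq_len(spec$n_tes)) {
      fam <- spec$te_families[fam_idx[i]]
      len <- pmax(80L, as.integer(round(rlnorm(1, fam$meanlog, fam$sdlog))))
      if (len >= L) next
      placedok <- FALSE
      for (t in 1:200) {
        near_gene <- fam$family == "MITE" && nrow(genes) > 0 &&
          runif(1) < spec$mite_near_gene_prob
        if (near_gene) {
          gi <- sample.int(nrow(genes), 1L)
          side <- sample(c(-1L, 1L), 1L)
          if (side < 0)
            st <- genes$start[gi] - len - sample.int(spec$mite_gene_flank, 1L)
          else
            st <- genes$end[gi] + sample.int(spec$mite_gene_flank, 1L)
        } else {
          st <- sample.int(max(1L, L - len), 1L) - 1L
        }
        st <- max(0L, min(st, L - len)); en <- st + len
        if (nrow(occ_te) && any(st < occ_te$end & en > occ_te$start)) next
        ov_gene <- nrow(genes) && any(st < genes$end & en > genes$start)
        if (ov_gene && runif(1) >= spec$te_in_gene_prob) next
        placedok <- TRUE; break
      }
      if (!placedok) next
      tes <- rbind(tes, data.table(start = st, end = en, family = fam$family))
      occ_te <- rbind(occ_te, data.table(start = st, end = en))
    }
    setorder(tes, start)
    te_dt <- data.table(chrom = cn, start = tes$start, end = tes$end,
                        strand = sample(c("+", "-"), nrow(tes), replace = TRUE),
                        kind = "TE", family = tes$family,
                        id = sprintf("%s_%s_%03d", tes$family, cn,
                                     seq_len(nrow(tes))))
    genes_all[[cn]] <- genes
    tes_all[[cn]] <- te_dt
    sites_all[[cn]] <- .scan_contexts(bases, cn)
  }
  list(seqs = seqs, chrom_sizes = setNames(rep(L, length(chroms)), chroms),
       genes = rbindlist(genes_all), tes = rbindlist(tes_all),
       sites = rbindlist(sites_all), spec = spec)
}

# classify every cytosine on both strands; positions 0-based.
# plus strand: C at i with next bases i+1, i+2; minus strand: G at i is a
# cytosine whose downstream (5'->3') bases are the complements of i-1, i-2.
.scan_contexts <- function(bases, chrom) {
  L <- length(bases)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n1 <- c(bases[-1], "N"); n2 <- c(bases[-(1:2)], "N", "N")
  ip <- which(bases == "C" & seq_len(L) <= L - 2L)
  ctx_p <- ifelse(n1[ip] == "G", "CG", ifelse(n2[ip] == "G", "CHG", "CHH"))
  plus <- data.table(chrom = chrom, pos = ip - 1L, strand = "+",
                     context = ctx_p,
                     tri = paste0("C", n1[ip], n2[ip]))
  im <- which(bases == "G" & seq_len(L) >= 3L)
  b1 <- bases[im - 1L]; b2 <- bases[im - 2L]
  ctx_m <- ifelse(b1 == "C", "CG", ifelse(b2 == "C", "CHG", "CHH"))
  minus <- data.table(chrom = chrom, pos = im - 1L, strand = "-",
                      context = ctx_m,
                      tri = paste0("C", comp[b1], comp[b2]))
  out <- rbind(plus, minus)
  setorder(out, pos)
  out
}

# deterministic per-condition seed offset
.condition_seed <- function(spec, condition) {
  idx <- match(condition, names(spec$chh_edge_amp))
  if (is.na(idx)) stop("unknown condition '", condition, "'")
  (spec$seed + 7919L * idx) %% .Machine$integer.max
}

#' True per-site methylation rates for one condition
#'
#' Deterministic truth field: compartment baseline (TE body > gene body >
#' background), a CHH edge bump `a * exp(-d / lambda)` applied from both TE
#' ends (inside and outside the element, MITE edges boosted), a flat CHH
#' elevation in gene flanks outside TEs, and any planted differential
#' blocks (reproductive condition only), all capped at 1.
#'
#' @param genome a [generate_genome()] result.
#' @param spec the [sim_spec()].
#' @param condition a name of `spec$chh_edge_amp`.
#' @return `data.table`: site skeleton plus `rate`.
#' @export
methylome_truth <- function(genome, spec, condition) {
  amp <- spec$chh_edge_amp[[condition]]
  if (is.null(amp)) stop("unknown condition '", condition, "'")
  s <- copy(genome$sites)
  tes <- genome$tes; genes <- genome$genes
  in_te <- .positions_in(s, tes)
  in_gene <- .positions_in(s, genes)
  compartment <- ifelse(in_te, "te_body", ifelse(in_gene, "gene_body", "background"))
  s[, rate := spec$baseline[cbind(compartment, context)]]
  # CHH edge bump, max over nearby TEs of the two-end exponential sum
  is_chh <- s$context == "CHH"
  if (amp > 0 && nrow(tes) && any(is_chh)) {
    reach <- as.integer(ceiling(6 * spec$edge_decay))
    sc <- s[is_chh, .(chrom, ps = pos, pe = pos, sid = .I)]
    tq <- data.table(chrom = tes$chrom, qs = tes$start - reach,
                     qe = tes$end - 1L + reach, ts = tes$start,
                     te_ = tes$end, mite = tes$family == "MITE")
    setkey(tq, chrom, qs, qe)
    ovp <- foverlaps(sc, tq, by.x = c("chrom", "ps", "pe"),
                     by.y = c("chrom", "qs", "qe"), nomatch = NULL)
    if (nrow(ovp)) {
      a_te <- amp * ifelse(ovp$mite, spec$mite_edge_boost, 1)
      bump <- a_te * (exp(-abs(ovp$ps - ovp$ts) / spec$edge_decay) +
                        exp(-abs(ovp$ps - (ovp$te_ - 1L)) / spec$edge_decay))
      mx <- data.table(sid = ovp$sid, bump = bump)[, .(b = max(bump)), keyby = sid]
      chh_idx <- which(is_chh)
      s[chh_idx[mx$sid], rate := rate + mx$b]
    }
  }
  # gene-flank CHH elevation outside TEs
  if (spec$gene_flank_chh > 0 && nrow(genes)) {
    flanks <- rbind(
      genes[, .(chrom, start = pmax(0L, start - spec$gene_flank_bp), end = start)],
      genes[, .(chrom, start = end, end = end + spec$gene_flank_bp)])
    in_flank <- .positions_in(s, flanks)
    s[is_chh & in_flank & !in_te & !in_gene, rate := rate + spec$gene_flank_chh]
  }
  if (!is.null(spec$planted) && condition == "reproductive") {
    for (j in seq_len(nrow(spec$planted))) {
      b <- spec$planted[j]
      s[chrom == b$chrom & pos >= b$start & pos < b$end & context == b$context,
        rate := rate + b$delta]
    }
  }
  s[, rate := pmin(pmax(rate, 0), 1)]
  s[]
}

# logical: is each site position inside any interval of the set
.positions_in <- function(sites, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, nrow(sites)))
  x <- data.table(chrom = sites$chrom, start = sites$pos,
                  end = sites$pos + 1L)
  .overlaps_any(x, as.data.table(intervals))
}

#' Simulate a cytosine report for one condition
#'
#' Coverage is negative-binomial per site; methylated counts are
#' beta-binomial around the truth rate (binomial when `bb_rho = 0`).
#' Identical `spec` + `seed` give byte-identical output. The truth field is
#' returned alongside so planted effects can be checked downstream.
#'
#' @param genome a [generate_genome()] result.
#' @param spec the [sim_spec()].
#' @param condition condition name (see [sim_spec()]).
#' @param seed RNG seed for coverage/counts; defaults to a deterministic
#'   per-condition offset of `spec$seed`.
#' @return list with `sites` (cytosine-report table) and `truth`.
#' @export
generate_methylome <- function(genome, spec, condition, seed = NULL) {
  truth <- methylome_truth(genome, spec, condition)
  if (is.null(seed)) seed <- .condition_seed(spec, condition)
  set.seed(seed)
  n <- nrow(truth)
  cov <- if (is.infinite(spec$coverage_size))
    rep(as.integer(round(spec$coverage_mean)), n)  # fixed coverage
  else rnbinom(n, mu = spec$coverage_mean, size = spec$coverage_size)
  rate <- truth$rate
  if (spec$bb_rho > 0) {
    nu <- 1 / spec$bb_rho - 1
    p <- rate
    mid <- rate > 0 & rate < 1
    p[mid] <- rbeta(sum(mid), rate[mid] * nu, (1 - rate[mid]) * nu)
  } else {
    p <- rate
  }
  m <- rbinom(n, cov, p)
  sites <- data.table(chrom = truth$chrom, pos = truth$pos,
                      strand = truth$strand, count_meth = m,
                      count_unmeth = cov - m, context = truth$context,
                      tri = truth$tri)
  list(sites = sites, truth = truth[, .(chrom, pos, strand, context, rate)])
}

#' Simulate a small-RNA library for one condition
#'
#' Read lengths follow the condition's size mixture; 5' ends of 24-nt
#' reads are concentrated within `smrna_edge_zone` bp of TE edges with the
#' configured fold enrichment, other reads land uniformly. The total
#' mapped count is attached as the `total_mapped` attribute.
#'
#' @inheritParams generate_methylome
#' @return read `data.table` (`chrom`, `start`, `end`, `strand`,
#'   `length_nt`) with attribute `total_mapped`.
#' @export
generate_smrna <- function(genome, spec, condition, seed = NULL) {
  mix <- spec$smrna_size_mix[[condition]]
  if (is.null(mix)) stop("unknown condition '", condition, "'")
  if (is.null(seed)) seed <- (.condition_seed(spec, condition) + 17L) %% .Machine$integer.max
  set.seed(seed)
  n <- spec$smrna_n_reads
  lens <- sample(spec$smrna_classes, n, replace = TRUE, prob = mix)
  chroms <- names(genome$chrom_sizes)
  G <- sum(genome$chrom_sizes)
  # flattened TE edge zones
  zones <- if (nrow(genome$tes)) flatten_intervals(rbind(
    genome$tes[, .(chrom, start = pmax(0L, start - spec$smrna_edge_zone),
                   end = pmin(start + spec$smrna_edge_zone,
                              genome$chrom_sizes[chrom]))],
    genome$tes[, .(chrom, start = pmax(0L, end - spec$smrna_edge_zone),
                   end = pmin(end + spec$smrna_edge_zone,
                              genome$chrom_sizes[chrom]))]))
  else data.table(chrom = character(), start = integer(), end = integer())
  zone_bp <- sum(as.numeric(zones$end - zones$start))
  e <- spec$smrna_edge_enrichment
  p_edge <- if (zone_bp > 0) e * zone_bp / (e * zone_bp + (G - zone_bp)) else 0
  # complement of the edge zones, for non-edge placement
  comp <- rbindlist(lapply(chroms, function(cn) {
    z <- zones[chrom == cn]
    bounds <- c(0L, as.vector(rbind(z$start, z$end)), genome$chrom_sizes[[cn]])
    st <- bounds[seq(1, length(bounds), by = 2)]
    en <- bounds[seq(2, length(bounds), by = 2)]
    data.table(chrom = cn, start = st, end = en)[end > start]
  }))
  sample_from <- function(iv, k) {
    ii <- sample.int(nrow(iv), k, replace = TRUE, prob = iv$end - iv$start)
    data.table(chrom = iv$chrom[ii],
               pos = iv$start[ii] +
                 as.integer(floor(runif(k) * (iv$end[ii] - iv$start[ii]))))
  }
  genome_iv <- data.table(chrom = chroms, start = 0L,
                          end = as.integer(genome$chrom_sizes))
  is24 <- lens == 24L
  pos <- sample_from(genome_iv, n)
  if (any(is24) && zone_bp > 0) {
    edge <- is24 & runif(n) < p_edge
    for (grp in list(list(which(edge), zones), list(which(is24 & !edge), comp))) {
      idx <- grp[[1]]
      if (length(idx)) {
        drawn <- sample_from(grp[[2]], length(idx))
        pos$chrom[idx] <- drawn$chrom
        pos$pos[idx] <- drawn$pos
      }
    }
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # pos is the 5' end: start on +, end-1 on -
  start <- ifelse(strand == "+", pos$pos, pos$pos - lens + 1L)
  start <- pmax(0L, pmin(start, genome$chrom_sizes[pos$chrom] - lens))
  reads <- data.table(chrom = pos$chrom, start = as.integer(start),
                      end = as.integer(start + lens), strand = strand,
                      length_nt = as.integer(lens))
  setorder(reads, chrom, start)
  setattr(reads, "total_mapped", n)
  reads[]
}

#' Write the toy genome as FASTA
#' @param genome a [generate_genome()] result.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
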