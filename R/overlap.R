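# interval helpers: package-internal coordinates are 0-based half-open;
# GRanges is 1-based closed, so convert at the boundary.
.to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

.from_gr <- function(gr) {
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Flatten (union) a set of intervals
#' @param intervals `data.table` with `chrom`, `start`, `end`.
#' @return non-overlapping sorted intervals covering the same bp.
#' @export
flatten_intervals <- function(intervals) {
  intervals <- as.data.table(intervals)
  if (nrow(intervals) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  out <- .from_gr(GenomicRanges::reduce(.to_gr(intervals)))
  setorder(out, chrom, start)
  out[]
}

#' Total base pairs of overlap between two interval sets
#'
#' Set B is flattened first so a base of A never counts twice within one
#' pairing; the total is the sum over A intervals of their overlap with the
#' flattened B.
#'
#' @param intervalsA,intervalsB interval `data.table`s (0-based half-open).
#' @param per_pair if `TRUE`, also return the per-(A, flattened-B) overlap
#'   table.
#' @return total overlapping bp (numeric), or a list
#'   `(total_bp, pairs)` when `per_pair = TRUE`.
#' @export
overlap_bp <- function(intervalsA, intervalsB, per_pair = FALSE) {
  A <- as.data.table(intervalsA); B <- flatten_intervals(intervalsB)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    if (per_pair) return(list(total_bp = 0,
                              pairs = data.table(a = integer(), b = integer(),
                                                 bp = integer())))
    return(0)
  }
  grA <- .to_gr(A); grB <- .to_gr(B)
  hits <- GenomicRanges::findOverlaps(grA, grB)
  ov <- IRanges::pintersect(grA[S4Vectors::queryHits(hits)],
                            grB[S4Vectors::subjectHits(hits)])
  bp <- sum(as.numeric(GenomicRanges::width(ov)))
  if (per_pair) {
    return(list(total_bp = bp,
                pairs = data.table(a = S4Vectors::queryHits(hits),
                                   b = S4Vectors::subjectHits(hits),
                                   bp = GenomicRanges::width(ov))))
  }
  bp
}

#' Attribute DMR base pairs to genomic feature categories
#'
#' Every DMR base pair is assigned to exactly one of four categories with
#' precedence TE > gene body > other intergenic; TE bp is split into
#' `TE_genic` / `TE_intergenic` by whether the overlapping TE itself
#' overlaps any gene. Base pairs are conserved exactly: the category totals
#' sum to the total DMR length.
#'
#' @param dmrs DMR table (`chrom`, `start`, `end`).
#' @param genes,tes feature tables from [read_features()] or
#'   [generate_genome()].
#' @return `data.table` with `category`, `bp`, `fraction`.
#' @export
categorize_dmrs <- function(dmrs, genes, tes) {
  dmrs <- as.data.table(dmrs); genes <- as.data.table(genes); tes <- as.data.table(tes)
  cats <- c("TE_intergenic", "TE_genic", "gene_body", "intergenic_other")
  if (nrow(dmrs) == 0L)
    return(data.table(category = cats, bp = 0, fraction = NA_real_))
  gr_d <- GenomicRanges::reduce(.to_gr(dmrs))
  # conservation is over unique DMR bp (same-context DMRs never overlap)
  total <- sum(as.numeric(GenomicRanges::width(gr_d)))
  gr_g <- if (nrow(genes)) GenomicRanges::reduce(.to_gr(genes)) else GenomicRanges::GRanges()
  te_genic_flag <- if (nrow(tes)) .overlaps_any(tes, genes) else logical()
  gr_te_genic <- if (any(te_genic_flag))
    GenomicRanges::reduce(.to_gr(tes[te_genic_flag])) else GenomicRanges::GRanges()
  gr_te_inter <- if (any(!te_genic_flag))
    GenomicRanges::reduce(.to_gr(tes[!te_genic_flag])) else GenomicRanges::GRanges()
  bp_of <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))
  d_te_genic <- GenomicRanges::intersect(gr_d, gr_te_genic)
  d_te_inter <- GenomicRanges::setdiff(GenomicRanges::intersect(gr_d, gr_te_inter),
                                       gr_te_genic)
  d_te_all <- GenomicRanges::union(d_te_genic, d_te_inter)
  d_gene <- GenomicRanges::setdiff(GenomicRanges::intersect(gr_d, gr_g), d_te_all)
  bp <- c(TE_intergenic = bp_of(d_te_inter), TE_genic = bp_of(d_te_genic),
          gene_body = bp_of(d_gene))
  bp <- c(bp, intergenic_other = total - sum(bp))
  data.table(category = cats, bp = as.numeric(bp[cats]),
             fraction = if (total > 0) as.numeric(bp[cats]) / total else NA_real_)
}

#' Per-TE-family DMR overlap accounting
#'
#' For every TE family: base pairs overlapping the DMR set, the share of
#' the total family-attributed overlap, the family's flattened genomic bp,
#' its share of total TE bp, the number of family members hit by at least
#' one DMR, and the enrichment (overlap share / genome share). TEs whose
#' family is not in `families` are bucketed as `"Others"` with a warning.
#'
#' @param dmrs DMR table.
#' @param tes TE feature table (must carry `family`).
#' @param families optional character vector fixing the family order;
#'   defaults to all families present.
#' @return `data.table` with one row per family plus totals implied by the
#'   bp columns.
#' @export
family_breakdown <- function(dmrs, tes, families = NULL) {
  dmrs <- as.data.table(dmrs); tes <- copy(as.data.table(tes))
  if (any(tes$family == "")) stop("every TE must carry a family")
  if (is.null(families)) families <- sort(unique(tes$family))
  unknown <- setdiff(unique(tes$family), families)
  if (length(unknown)) {
    warning("unknown TE families bucketed as 'Others': ",
            paste(unknown, collapse = ", "))
    tes[family %in% unknown, family := "Others"]
    families <- c(families, "Others")
  }
  res <- rbindlist(lapply(families, function(fam) {
    ft <- tes[family == fam]
    flat <- flatten_intervals(ft)
    ov <- overlap_bp(flat, dmrs)
    hit <- if (nrow(ft) && nrow(dmrs)) sum(.overlaps_any(ft, dmrs)) else 0L
    data.table(family = fam, overlap_bp_ = ov,
               genome_bp = sum(as.numeric(flat$end - flat$start)),
               n_tes_hit = hit)
  }))
  tot_ov <- sum(res$overlap_bp_); tot_gen <- sum(res$genome_bp)
  res[, overlap_pct := if (tot_ov > 0) 100 * overlap_bp_ / tot_ov else 0]
  res[, genome_pct := if (tot_gen > 0) 100 * genome_bp / tot_gen else 0]
  res[, enrichment := ifelse(genome_pct > 0 & tot_ov > 0,
                             overlap_pct / genome_pct, NA_real_)]
  setnames(res, "overlap_bp_", "overlap_bp")
  setcolorder(res, c("family", "overlap_bp", "overlap_pct", "genome_bp",
                     "genome_pct", "n_tes_hit", "enrichment"))
  res[]
}

#' Pooled methylation level over each feature body
#'
#' Read-weighted pooled ratio of context-matched sites within
#' `[start, end)` per feature; `NA` when no covered context site falls in
#' the feature.
#'
#' @param features feature table.
#' @param sites site table (cytosine report).
#' @param context one context label.
#' @return the feature table with added `level`, `n_sites`, `sum_total`.
#' @export
feature_body_levels <- function(features, sites, context) {
  features <- copy(as.data.table(features))
  ctx <- context
  s <- as.data.table(sites)[context == ctx & count_meth + count_unmeth > 0]
  features[, `:=`(level = NA_real_, n_sites = 0L, sum_total = 0L)]
  if (nrow(s) == 0L || nrow(features) == 0L) return(features[])
  gr_f <- .to_gr(features)
  gr_s <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos + 1L, s$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr_f, gr_s)
  hdt <- data.table(f = S4Vectors::queryHits(hits), i = S4Vectors::subjectHits(hits))
  if (nrow(hdt)) {
    agg <- hdt[, .(sm = sum(s$count_meth[i]),
                   st = sum(s$count_meth[i] + s$count_unmeth[i]),
                   ns = .N), keyby = f]
    features[agg$f, `:=`(level = agg$sm / agg$st, n_sites = agg$ns,
                         sum_total = agg$st)]
  }
  features[]
}

#' Classify genes by MITE proximity
#'
#' A gene is `with_MITE` when any MITE overlaps its body extended by
#' `flank` bp on both sides.
#'
#' @param genes gene feature table.
#' @param mites MITE feature table.
#' @param flank flank width in bp (default 1000).
#' @return the gene table with an added `mite_class` column
#'   (`"with_MITE"` / `"without_MITE"`).
#' @export
classify_genes_by_mite_proximity <- function(genes, mites, flank = 1000L) {
  if (flank < 0) stop("flank must be >= 0")
  genes <- copy(as.data.table(genes))
  ext <- genes[, .(chrom, start = pmax(0L, start - as.integer(flank)),
                   end = end + as.integer(flank))]
  hit <- if (nrow(as.data.table(mites))) .overlaps_any(ext, as.data.table(mites))
         else rep(FALSE, nrow(genes))
  genes[, mite_class := ifelse(hit, "with_MITE", "without_MITE")]
  genes[]
}

#' Group TEs by methylation change between two samples
#'
#' Groups: `unmethylated` when both levels are below `floor`; otherwise
#' `gained` when `level_B - level_A > epsilon`, `lost` when
#' `< -epsilon`, else `similar`. TEs with an undefined level in either
#' sample are excluded and counted in the `n_excluded` attribute.
#'
#' @param te_levels_A,te_levels_B numeric vectors of per-TE body levels
#'   (aligned; `NA` = undefined).
#' @param ids optional TE ids.
#' @param epsilon minimum change treated as gain/loss (default 0.01).
#' @param floor detection floor below which a TE counts as unmethylated
#'   (default 0.01).
#' @return `data.table` with `id`, `level_A`, `level_B`, `group`; attribute
#'   `n_excluded`.
#' @export
classify_te_methylation_change <- function(te_levels_A, te_levels_B, ids = NULL,
                                           epsilon = 0.01, floor = 0.01) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (floor < 0) stop("floor must be >= 0")
  stopifnot(length(te_levels_A) == length(te_levels_B))
  if (is.null(ids)) ids <- as.character(seq_along(te_levels_A))
  ok <- !is.na(te_levels_A) & !is.na(te_levels_B)
  d <- te_levels_B - te_levels_A
  group <- ifelse(te_levels_A < floor & te_levels_B < floor, "unmethylated",
                  ifelse(d > epsilon, "gained",
                         ifelse(d < -epsilon, "lost", "similar")))
  out <- data.table(id = ids[ok], level_A = te_levels_A[ok],
                    level_B = te_levels_B[ok], group = group[ok])
  setattr(out, "n_excluded", sum(!ok))
  out[]
}

#' Overlap statistics for two hypermethylated-TE sets
#'
#' Given a universe of TEs and two member sets (e.g. TEs hypermethylated in
#' germ cells and TEs hypermethylated in the meristem), reports the ratio
#' of germ-set members already in the meristem set, the odds ratio of the
#' 2x2 membership table over the universe, and a two-sided Fisher's exact
#' p-value.
#'
#' @param universe_ids character vector of all TE ids considered.
#' @param set_germ,set_sam character vectors of member ids (subsets of the
#'   universe).
#' @return list with `ratio`, `odds_ratio`, `p_value`, `table` (2x2 counts).
#' @export
hypermethylation_overlap_test <- function(universe_ids, set_germ, set_sam) {
  universe_ids <- unique(universe_ids)
  set_germ <- intersect(unique(set_germ), universe_ids)
  set_sam <- intersect(unique(set_sam), universe_ids)
  if (length(set_germ) == 0L) stop("empty germ set")
  in_g <- universe_ids %in% set_germ
  in_s <- universe_ids %in% set_sam
  a <- sum(in_g & in_s); b <- sum(in_g & !in_s)
  c_ <- sum(!in_g & in_s); d <- sum(!in_g & !in_s)
  p <- fisher_test_2x2(a, b, c_, d)
  list(ratio = a / length(set_germ),
       odds_ratio = (a * d) / (b * c_),
       p_value = p,
       table = matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                      dimnames = list(c("germ", "not_germ"),
                                      c("sam", "not_sam"))))
}

#' TE ids overlapping at least one hyper DMR
#'
#' Default membership criterion for [hypermethylation_overlap_test()]:
#' a TE belongs to a hypermethylated set when it overlaps (>= 1 bp) any
#' hyper-direction DMR of the relevant comparison. Alternatively a
#' body-level difference criterion can be used via `levels_A`/`levels_B`.
#'
#' @param tes TE feature table (with `id`).
#' @param dmrs DMR table; only rows with `direction == "hyper_in_B"` are
#'   used.
#' @param criterion `"dmr_overlap"` (default) or `"level_difference"`.
#' @param levels_A,levels_B per-TE body levels (aligned with `tes`),
#'   required for the level-difference criterion.
#' @param min_delta minimum `level_B - level_A` for the level criterion.
#' @return character vector of member TE ids.
#' @export
hypermethylated_te_set <- function(tes, dmrs = NULL,
                                   criterion = c("dmr_overlap", "level_difference"),
                                   levels_A = NULL, levels_B = NULL,
                                   min_delta = 0.1) {
  criterion <- match.arg(criterion)
  tes <- as.data.table(tes)
  if (criterion == "dmr_overlap") {
    dmrs <- as.data.table(dmrs)[direction == "hyper_in_B"]
    if (nrow(dmrs) == 0L) return(character())
    tes$id[.overlaps_any(tes, dmrs)]
  } else {
    stopifnot(!is.null(levels_A), !is.null(levels_B))
    ok <- !is.na(levels_A) & !is.na(levels_B)
    tes$id[ok & (levels_B - levels_A) >= min_delta]
  }
}
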