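#' Two-sided Fisher's exact test for 2x2 count tables (vectorised)
#'
#' Computes the conventional two-sided p-value: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table, using the standard relative
#' tolerance of 1e-7 when comparing probabilities. One p-value per input
#' table; tables are `[m_a, u_a; m_b, u_b]`.
#'
#' A window whose column margin is empty (no methylated call, or no
#' unmethylated call, in either sample) admits a single table and yields
#' p = 1. An empty row margin (a sample with zero reads) is an error; the
#' testability filter removes such windows upstream.
#'
#' @param m_a,u_a methylated/unmethylated counts in sample A.
#' @param m_b,u_b methylated/unmethylated counts in sample B.
#' @return numeric vector of p-values.
#' @export
fisher_test_2x2 <- function(m_a, u_a, m_b, u_b) {
  k <- length(m_a)
  if (length(u_a) != k || length(m_b) != k || length(u_b) != k)
    stop("count vectors must have equal length")
  all_counts <- c(m_a, u_a, m_b, u_b)
  if (anyNA(all_counts) || any(all_counts < 0) || any(all_counts != floor(all_counts)))
    stop("counts must be non-negative integers")
  rowA <- m_a + u_a
  rowB <- m_b + u_b
  if (any(rowA == 0 | rowB == 0))
    stop("empty sample margin (zero reads in one sample)")
  vapply(seq_len(k), function(i) {
    N <- rowA[i] + rowB[i]
    K <- m_a[i] + m_b[i]
    n1 <- rowA[i]
    lo <- max(0, n1 - (N - K))
    hi <- min(K, n1)
    dd <- stats::dhyper(lo:hi, K, N - K, n1)
    dobs <- dd[m_a[i] - lo + 1]
    min(1, sum(dd[dd <= dobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as an explicit
#' pipeline step so the correction scope (per context, genome-wide) is
#' visible in the caller.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Context-specific DMR calling thresholds
#'
#' Defaults follow the windowed DMR criteria of Stroud-style calling:
#' minimum absolute methylation difference 0.4 (CG), 0.2 (CHG), 0.1 (CHH),
#' BH FDR < 0.01, and merging of qualifying windows within 200 bp.
#'
#' @param CG,CHG,CHH minimum absolute pooled-level difference per context.
#' @param fdr BH FDR cutoff.
#' @param merge_gap maximum gap (bp, inclusive) merged between
#'   same-direction qualifying windows.
#' @param min_sites,min_cov testability filter (see
#'   [filter_testable_windows()]).
#' @return a named list of thresholds.
#' @export
context_thresholds <- function(CG = 0.4, CHG = 0.2, CHH = 0.1, fdr = 0.01,
                               merge_gap = 200L, min_sites = 4L, min_cov = 4L) {
  delta <- c(CG = CG, CHG = CHG, CHH = CHH)
  if (any(delta <= 0 | delta > 1)) stop("delta thresholds must be in (0, 1]")
  list(delta = delta, fdr = fdr, merge_gap = as.integer(merge_gap),
       min_sites = as.integer(min_sites), min_cov = as.integer(min_cov))
}

#' Per-window differential tests between two samples
#'
#' Applies the testability filter, runs Fisher's exact test on the pooled
#' 2x2 counts of every testable window, and BH-adjusts the p-values across
#' all tested windows of the context (genome-wide).
#'
#' @param winA,winB aligned window tables from [aggregate_windows()] (same
#'   tiling, same context).
#' @param thresholds a [context_thresholds()] list.
#' @return `data.table`: tiling columns, 2x2 counts, `delta`
#'   (`level_B - level_A`), `testable`, `p_value`, `q_value` (`NA` for
#'   untested windows).
#' @export
window_tests <- function(winA, winB, thresholds = context_thresholds()) {
  winA <- as.data.table(winA); winB <- as.data.table(winB)
  testable <- filter_testable_windows(winA, winB, thresholds$min_sites,
                                      thresholds$min_cov)
  out <- data.table(chrom = winA$chrom, start = winA$start, end = winA$end,
                    context = winA$context,
                    sum_meth_A = winA$sum_meth,
                    sum_unmeth_A = winA$sum_total - winA$sum_meth,
                    sum_meth_B = winB$sum_meth,
                    sum_unmeth_B = winB$sum_total - winB$sum_meth,
                    delta = winB$level - winA$level,
                    testable = testable,
                    p_value = NA_real_, q_value = NA_real_)
  if (any(testable)) {
    p <- fisher_test_2x2(out$sum_meth_A[testable], out$sum_unmeth_A[testable],
                         out$sum_meth_B[testable], out$sum_unmeth_B[testable])
    out[testable == TRUE, p_value := p]
    out[testable == TRUE, q_value := bh_fdr(p_value)]
  }
  out[]
}

#' Merge intervals separated by at most a given gap
#'
#' Transitive closure of "separated by <= gap" (the boundary is inclusive:
#' a 200-bp gap merges at `gap = 200`). Idempotent.
#'
#' @param intervals `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param gap maximum separating distance in bp.
#' @return merged intervals, sorted.
#' @export
merge_intervals <- function(intervals, gap = 200L) {
  intervals <- as.data.table(intervals)
  if (nrow(intervals) == 0L) return(intervals)
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L, intervals$end))
  m <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(gap) + 1L)
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(m)),
                    start = GenomicRanges::start(m) - 1L,
                    end = GenomicRanges::end(m))
  setorder(out, chrom, start)
  out[]
}

#' Call differentially methylated regions between two samples
#'
#' Full windowed pipeline for one context: testability filter, Fisher's
#' exact test on pooled window counts, BH FDR across all tested windows,
#' selection of windows with `q < fdr` and an absolute pooled-level
#' difference at least the context threshold, then merging of qualifying
#' same-direction windows separated by at most `merge_gap` bp. Hyper and
#' hypo windows never merge with each other.
#'
#' @param winA,winB aligned window tables ([aggregate_windows()], same
#'   tiling and context). Sample A is the reference; direction is reported
#'   relative to sample B.
#' @param thresholds a [context_thresholds()] list.
#' @return `data.table` of DMRs: `chrom`, `start`, `end`, `context`,
#'   `direction` (`hyper_in_B`/`hypo_in_B`), `n_windows`, `delta` (pooled
#'   level difference over the merged span), `q` (minimum member-window q).
#'   Zero testable windows yield an empty table with a warning.
#' @export
call_dmrs <- function(winA, winB, thresholds = context_thresholds()) {
  winA <- as.data.table(winA); winB <- as.data.table(winB)
  ctx <- unique(winA$context)
  stopifnot(length(ctx) == 1L)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      n_windows = integer(), delta = numeric(), q = numeric())
  wt <- window_tests(winA, winB, thresholds)
  if (!any(wt$testable)) {
    warning("no testable windows for context ", ctx)
    return(empty)
  }
  thr <- thresholds$delta[[ctx]]
  sel <- wt[testable == TRUE & q_value < thresholds$fdr & abs(delta) >= thr &
              delta != 0]
  if (nrow(sel) == 0L) return(empty)
  sel[, direction := ifelse(delta > 0, "hyper_in_B", "hypo_in_B")]
  res <- lapply(split(sel, by = "direction"), function(s) {
    m <- merge_intervals(s[, .(chrom, start, end)], thresholds$merge_gap)
    m[, direction := s$direction[1]]
    # member windows and pooled counts over each merged span
    gr_m <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start + 1L, m$end))
    gr_s <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start + 1L, s$end))
    hit_members <- GenomicRanges::findOverlaps(gr_m, gr_s)
    memb <- data.table(dmr = S4Vectors::queryHits(hit_members),
                       win = S4Vectors::subjectHits(hit_members))
    m[, n_windows := memb[, .N, keyby = dmr]$N]
    m[, q := memb[, min(s$q_value[win]), keyby = dmr]$V1]
    gr_all <- GenomicRanges::GRanges(winA$chrom,
                                     IRanges::IRanges(winA$start + 1L, winA$end))
    hit_all <- GenomicRanges::findOverlaps(gr_m, gr_all)
    pool <- data.table(dmr = S4Vectors::queryHits(hit_all),
                       win = S4Vectors::subjectHits(hit_all))
    pl <- pool[, .(
      lA = sum(winA$sum_meth[win]) / sum(winA$sum_total[win]),
      lB = sum(winB$sum_meth[win]) / sum(winB$sum_total[win])), keyby = dmr]
    m[, delta := pl$lB - pl$lA]
    m
  })
  out <- rbindlist(res)
  out[, context := ctx]
  setorder(out, chrom, start)
  setcolorder(out, c("chrom", "start", "end", "context", "direction",
                     "n_windows", "delta", "q"))
  out[]
}

#' Overlap accounting between two DMR sets
#'
#' A DMR counts as shared when it overlaps any DMR of the other set by at
#' least 1 bp; counts are reported from each set's perspective (Venn-style).
#'
#' @param setA,setB DMR tables (need `chrom`, `start`, `end`).
#' @return list with `only_A`, `only_B`, `shared_A`, `shared_B`.
#' @export
dmr_set_overlap <- function(setA, setB) {
  setA <- as.data.table(setA); setB <- as.data.table(setB)
  shared_A <- if (nrow(setA)) sum(.overlaps_any(setA, setB)) else 0L
  shared_B <- if (nrow(setB)) sum(.overlaps_any(setB, setA)) else 0L
  list(only_A = nrow(setA) - shared_A, only_B = nrow(setB) - shared_B,
       shared_A = shared_A, shared_B = shared_B)
}

#' Pooled methylation levels over DMR spans, per sample and context
#'
#' For every DMR span the read-weighted pooled level of each requested
#' context is computed in each sample (heat-map input). Cells without
#' covered context sites are `NA`.
#'
#' @param dmrs DMR table.
#' @param samples named list of site tables (cytosine reports).
#' @param contexts contexts to evaluate (default all three).
#' @return long-format `data.table`: DMR coordinates, `sample_id`,
#'   `context`, `level`.
#' @export
dmr_levels <- function(dmrs, samples, contexts = c("CG", "CHG", "CHH")) {
  dmrs <- as.data.table(dmrs)
  stopifnot(!is.null(names(samples)))
  gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  res <- list()
  for (sid in names(samples)) {
    s <- as.data.table(samples[[sid]])
    for (ctx in contexts) {
      sc <- s[context == ctx & count_meth + count_unmeth > 0]
      lev <- rep(NA_real_, nrow(dmrs))
      if (nrow(sc)) {
        gr_s <- GenomicRanges::GRanges(sc$chrom,
                                       IRanges::IRanges(sc$pos + 1L, sc$pos + 1L))
        hits <- GenomicRanges::findOverlaps(gr_d, gr_s)
        hdt <- data.table(dmr = S4Vectors::queryHits(hits),
                          site = S4Vectors::subjectHits(hits))
        if (nrow(hdt)) {
          pl <- hdt[, .(lev = sum(sc$count_meth[site]) /
                          sum(sc$count_meth[site] + sc$count_unmeth[site])),
                    keyby = dmr]
          lev[pl$dmr] <- pl$lev
        }
      }
      res[[length(res) + 1L]] <- data.table(
        chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
        dmr_context = dmrs$context, direction = dmrs$direction,
        sample_id = sid, context = ctx, level = lev)
    }
  }
  rbindlist(res)
}

#' Per-context, per-direction DMR counts and total bp
#'
#' @param dmrs DMR table (possibly from several contexts bound together).
#' @return `data.table` with `context`, `direction`, `n`, `bp`.
#' @export
dmr_count_summary <- function(dmrs) {
  dmrs <- as.data.table(dmrs)
  if (nrow(dmrs) == 0L)
    return(data.table(context = character(), direction = character(),
                      n = integer(), bp = integer()))
  dmrs[, .(n = .N, bp = sum(end - start)), keyby = .(context, direction)]
}
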