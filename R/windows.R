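#' Tile a genome into fixed-width windows
#'
#' Consecutive non-overlapping tiles cover each chromosome; the final
#' partial tile is retained.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param window tile width in bp (default 100).
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_genome <- function(chrom_sizes, window = 100L) {
  if (window <= 0) stop("window must be positive")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  window <- as.integer(window)
  tiles <- lapply(names(chrom_sizes), function(cn) {
    L <- as.integer(chrom_sizes[[cn]])
    starts <- seq.int(0L, L - 1L, by = window)
    data.table(chrom = cn, start = starts, end = pmin(starts + window, L))
  })
  rbindlist(tiles)
}

#' Aggregate cytosine sites into per-context methylation windows
#'
#' Pools methylated/unmethylated read counts of all context-matched
#' cytosines (both strands) within each tile. The window level is the
#' read-weighted pooled ratio `sum_meth / sum_total`, `NA` when the window
#' has no reads. `n_sites` counts covered sites (at least one read);
#' `n_sites_cov_k` counts sites with coverage at least `min_cov`.
#'
#' @param sites site table (0-based `pos`), e.g. from
#'   [read_cytosine_report()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window tile width in bp.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_cov site coverage threshold for `n_sites_cov_k` (default 4).
#' @return `data.table` of windows: `chrom`, `start`, `end`, `context`,
#'   `n_sites`, `n_sites_cov_k`, `sum_meth`, `sum_total`, `level`, ordered by
#'   chromosome (input order of `chrom_sizes`) then start.
#' @export
aggregate_windows <- function(sites, chrom_sizes, window = 100L, context,
                              min_cov = 4L) {
  stopifnot(length(context) == 1L, context %in% c("CG", "CHG", "CHH"))
  window <- as.integer(window)
  tiles <- tile_genome(chrom_sizes, window)
  ctx <- context
  s <- as.data.table(sites)[context == ctx]
  bad <- s[!chrom %in% names(chrom_sizes)]
  if (nrow(bad)) stop("site on unknown chromosome '", bad$chrom[1], "'")
  over <- s[pos >= chrom_sizes[chrom]]
  if (nrow(over))
    stop("site at ", over$chrom[1], ":", over$pos[1] + 1,
         " beyond chromosome length")
  s[, total := count_meth + count_unmeth]
  s[, start := (pos %/% window) * window]
  agg <- s[, .(n_sites = sum(total >= 1L),
               n_sites_cov_k = sum(total >= min_cov),
               sum_meth = sum(count_meth),
               sum_total = sum(total)), by = .(chrom, start)]
  out <- merge(tiles, agg, by = c("chrom", "start"), all.x = TRUE, sort = FALSE)
  for (cn in c("n_sites", "n_sites_cov_k", "sum_meth", "sum_total"))
    set(out, which(is.na(out[[cn]])), cn, 0L)
  out[, context := ctx]
  out[, level := ifelse(sum_total > 0, sum_meth / sum_total, NA_real_)]
  out[, chrom := factor(chrom, levels = names(chrom_sizes))]
  setorder(out, chrom, start)
  out[, chrom := as.character(chrom)]
  setcolorder(out, c("chrom", "start", "end", "context", "n_sites",
                     "n_sites_cov_k", "sum_meth", "sum_total", "level"))
  out[]
}

#' Site/coverage testability filter for a pair of aligned windows
#'
#' A window pair is testable when at least one of the two samples has at
#' least `min_sites` context cytosines each covered by at least `min_cov`
#' reads, and both samples have at least one read in the window (so a 2x2
#' count table exists).
#'
#' @param winA,winB window tables from [aggregate_windows()] on the same
#'   tiling and context (aligned row by row, or single rows).
#' @param min_sites minimum qualifying sites (default 4).
#' @param min_cov minimum per-site coverage (default 4); must equal the
#'   `min_cov` used during aggregation.
#' @return logical vector, one entry per window pair.
#' @export
filter_testable_windows <- function(winA, winB, min_sites = 4L, min_cov = 4L) {
  winA <- as.data.table(winA); winB <- as.data.table(winB)
  if (nrow(winA) != nrow(winB) ||
      !all(winA$chrom == winB$chrom & winA$start == winB$start &
           winA$context == winB$context))
    stop("window tables are not aligned on the same tiling/context")
  (winA$n_sites_cov_k >= min_sites | winB$n_sites_cov_k >= min_sites) &
    winA$sum_total >= 1L & winB$sum_total >= 1L
}

#' Chromosome-scale methylation levels (heat-map input)
#'
#' Convenience wrapper around [aggregate_windows()] with megabase tiles.
#'
#' @inheritParams aggregate_windows
#' @param window tile width, default 1 Mb.
#' @export
chromosome_levels <- function(sites, chrom_sizes, window = 1000000L, context,
                              min_cov = 4L) {
  aggregate_windows(sites, chrom_sizes, window = window, context = context,
                    min_cov = min_cov)
}

#' Scale window levels to the per-context maximum across samples
#'
#' For heat-map rendering the maximum of each context is set to the highest
#' level observed in any sample; every level is divided by that maximum.
#'
#' @param level_tables named list of window tables for one context.
#' @return the list with an added `level_scaled` column in each table.
#' @export
scale_to_context_max <- function(level_tables) {
  mx <- max(unlist(lapply(level_tables, function(t) t$level)), na.rm = TRUE)
  lapply(level_tables, function(t) {
    t <- as.data.table(t)
    t[, level_scaled := level / mx]
    t[]
  })
}

#' Distribution of per-window methylation differences between two samples
#'
#' For every testable window pair (see [filter_testable_windows()]) the
#' signed difference `level_B - level_A` of pooled window levels is computed.
#' The normative output is a histogram with 0.01-wide bins on `[-1, 1]`; a
#' Gaussian kernel density estimate (Silverman's bandwidth) on a fixed grid
#' is attached for plotting.
#'
#' @param winA,winB aligned window tables (same tiling and context).
#' @param min_sites,min_cov testability filter settings.
#' @param region_set optional interval `data.table` (`chrom`, `start`,
#'   `end`); only windows overlapping the set by at least 1 bp are retained.
#' @return list with `differences` (numeric vector), `histogram`
#'   (`data.table`: `mid`, `count`), `mode` (midpoint of the fullest bin;
#'   ties resolved toward the smallest absolute midpoint), `kde`
#'   (`data.table`: `x`, `y`), `n_windows`, `window` (tile width),
#'   `region_restricted` (logical).
#' @export
difference_density <- function(winA, winB, min_sites = 4L, min_cov = 4L,
                               region_set = NULL) {
  winA <- as.data.table(winA); winB <- as.data.table(winB)
  keep <- filter_testable_windows(winA, winB, min_sites, min_cov)
  if (!is.null(region_set)) {
    keep <- keep & .overlaps_any(winA, as.data.table(region_set))
  }
  d <- winB$level[keep] - winA$level[keep]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no testable windows")
  breaks <- seq(-1.005, 1.005, by = 0.01)
  mids <- round(seq(-1, 1, by = 0.01), 3)
  idx <- findInterval(d, breaks, rightmost.closed = TRUE)
  hist_dt <- data.table(mid = mids, count = tabulate(idx, nbins = length(mids)))
  cand <- hist_dt[count == max(count)]
  mode <- cand$mid[which.min(abs(cand$mid))]
  kde <- if (length(d) > 1L && stats::sd(d) > 0) {
    k <- stats::density(d, bw = "nrd0", from = -1, to = 1, n = 512)
    data.table(x = k$x, y = k$y)
  } else {
    data.table(x = numeric(), y = numeric())
  }
  list(differences = d, histogram = hist_dt, mode = mode, kde = kde,
       n_windows = length(d),
       window = as.integer(winA$end[1] - winA$start[1]),
       region_restricted = !is.null(region_set))
}

# logical: does each interval in `x` overlap >= 1 bp of the flattened set `regions`
.overlaps_any <- function(x, regions) {
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(x)))
  gx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)))
  # disjoint chromosome sets are a legitimate (all-FALSE) query
  suppressWarnings(IRanges::overlapsAny(gx, gr))
}
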