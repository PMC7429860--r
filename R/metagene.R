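# Anchor position and direction for offset computation.
# Offsets run 5'->3' biologically for 5' anchors; for 3' anchors positive
# offsets point back into the feature, so in both cases positive = body.
.anchor_dir <- function(features, anchor) {
  strand <- ifelse(features$strand %in% c("+", "-"), features$strand, "+")
  if (anchor == "five_prime") {
    a <- ifelse(strand == "+", features$start, features$end - 1L)
    dir <- ifelse(strand == "+", 1L, -1L)
  } else {
    a <- ifelse(strand == "+", features$end - 1L, features$start)
    dir <- ifelse(strand == "+", -1L, 1L)
  }
  list(a = as.integer(a), dir = as.integer(dir),
       unstranded = !features$strand %in% c("+", "-"))
}

.profile_skeleton <- function(upstream, into, bin) {
  if (upstream %% bin != 0 || into %% bin != 0)
    stop("upstream and into must be multiples of the bin width")
  bin_start <- seq.int(-upstream, into - bin, by = bin)
  data.table(bin_start = as.integer(bin_start),
             bin_end = as.integer(bin_start + bin),
             numerator = 0, denominator = 0, n_features = 0L)
}

# (position, feature) pairs with signed offsets; positions beyond a
# feature's far end are excluded from body bins, flank positions kept.
.offset_pairs <- function(positions, features, anchor, upstream, into) {
  ad <- .anchor_dir(features, anchor)
  if (any(ad$unstranded))
    warning(sum(ad$unstranded), " unstranded features treated as plus strand")
  q <- data.table(chrom = features$chrom,
                  qs = ifelse(ad$dir == 1L, ad$a - upstream, ad$a - into + 1L),
                  qe = ifelse(ad$dir == 1L, ad$a + into - 1L, ad$a + upstream),
                  a = ad$a, dir = ad$dir,
                  len = features$end - features$start,
                  fid = seq_len(nrow(features)))
  setkey(q, chrom, qs, qe)
  p <- data.table(chrom = positions$chrom, ps = positions$pos,
                  pe = positions$pos, pid = seq_len(nrow(positions)))
  if (nrow(p) == 0L || nrow(q) == 0L)
    return(data.table(pid = integer(), fid = integer(), offset = integer()))
  ov <- foverlaps(p, q, by.x = c("chrom", "ps", "pe"),
                  by.y = c("chrom", "qs", "qe"), type = "within", nomatch = NULL)
  o <- ov$dir * (ov$ps - ov$a)
  keep <- (o >= 0L & o < pmin(into, ov$len)) | (o >= -upstream & o < 0L)
  data.table(pid = ov$pid[keep], fid = ov$fid[keep], offset = o[keep])
}

# number of features contributing to each bin: all features contribute to
# flank bins; a feature reaches a body bin only if its body covers the
# bin's first position
.bin_feature_counts <- function(prof, feature_lengths) {
  ifelse(prof$bin_start < 0L, length(feature_lengths),
         vapply(prof$bin_start, function(b) sum(feature_lengths > b), 0L))
}

#' Edge-anchored metagene profile of methylation
#'
#' Averages a per-cytosine methylation signal around the 5' or 3' ends of a
#' feature set. Minus-strand features are flipped so offsets run in the
#' biological direction; positive offsets point into the annotated body and
#' positions beyond a feature's far end are excluded (a 1-kb feature
#' contributes nothing past offset +1000). Bin values are pooled
#' (read-weighted) across features: sum of methylated over sum of total
#' reads per bin. Bins with zero denominator are `NA`, never zero.
#'
#' @param sites site table (cytosine report) — filtered to `context`.
#' @param features feature table with strand; unstranded features are
#'   treated as plus strand with a warning.
#' @param context one context label.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param upstream bp of flank before the anchor (default 3000).
#' @param into bp into the feature (default 4000).
#' @param bin bin width in bp (default 100).
#' @param per_feature_mean if `TRUE`, average per-feature rates per bin
#'   instead of pooling reads.
#' @return `data.table`: `bin_start`, `bin_end` (signed offsets), `value`,
#'   `numerator`, `denominator`, `n_features`.
#' @export
anchored_profile <- function(sites, features, context,
                             anchor = c("five_prime", "three_prime"),
                             upstream = 3000L, into = 4000L, bin = 100L,
                             per_feature_mean = FALSE) {
  anchor <- match.arg(anchor)
  features <- as.data.table(features)
  ctx <- context
  s <- as.data.table(sites)[context == ctx & count_meth + count_unmeth > 0]
  prof <- .profile_skeleton(upstream, into, bin)
  pairs <- .offset_pairs(s, features, anchor, upstream, into)
  if (nrow(pairs)) {
    pairs[, bidx := (offset + upstream) %/% bin + 1L]
    pairs[, `:=`(m = s$count_meth[pid],
                 t = s$count_meth[pid] + s$count_unmeth[pid])]
    if (per_feature_mean) {
      pf <- pairs[, .(r = sum(m) / sum(t)), by = .(fid, bidx)]
      agg <- pf[, .(num = sum(r), den = .N), keyby = bidx]
      prof[agg$bidx, `:=`(numerator = agg$num, denominator = agg$den)]
      prof[, value := ifelse(denominator > 0, numerator / denominator, NA_real_)]
    } else {
      agg <- pairs[, .(num = sum(m), den = sum(t)), keyby = bidx]
      prof[agg$bidx, `:=`(numerator = agg$num, denominator = agg$den)]
      prof[, value := ifelse(denominator > 0, numerator / denominator, NA_real_)]
    }
  } else {
    prof[, value := NA_real_]
  }
  prof[, n_features := .bin_feature_counts(prof, features$end - features$start)]
  prof[]
}

#' Edge-anchored small-RNA abundance profile (RPM)
#'
#' Reads (optionally restricted to one length class, default 24 nt) are
#' assigned to the bin containing their 5' end; offsets are computed as in
#' [anchored_profile()]. The bin value is the read count normalised to
#' reads per million mapped reads, divided by the number of features
#' contributing to the bin ("average RPM").
#'
#' @param reads read table (`chrom`, `start`, `end`, `strand`,
#'   `length_nt`).
#' @param features feature table with strand.
#' @param length_filter read length(s) to keep (default 24); `NULL` keeps
#'   all.
#' @param total_mapped total mapped reads of the library (normalisation
#'   denominator); must be positive.
#' @inheritParams anchored_profile
#' @return `data.table`: `bin_start`, `bin_end`, `value` (average RPM),
#'   `numerator` (read count), `n_features`.
#' @export
smrna_metaprofile <- function(reads, features, length_filter = 24L,
                              total_mapped,
                              anchor = c("five_prime", "three_prime"),
                              upstream = 3000L, into = 4000L, bin = 100L) {
  anchor <- match.arg(anchor)
  if (total_mapped <= 0) stop("total_mapped must be positive")
  reads <- as.data.table(reads)
  if (!is.null(length_filter)) reads <- reads[length_nt %in% length_filter]
  features <- as.data.table(features)
  prof <- .profile_skeleton(upstream, into, bin)
  # 5' end of a read: start on +, end-1 on -; unstranded reads use start
  p5 <- data.table(chrom = reads$chrom,
                   pos = as.integer(ifelse(reads$strand == "-",
                                           reads$end - 1L, reads$start)))
  pairs <- .offset_pairs(p5, features, anchor, upstream, into)
  if (nrow(pairs)) {
    bidx <- (pairs$offset + upstream) %/% bin + 1L
    prof[, numerator := as.numeric(tabulate(bidx, nbins = nrow(prof)))]
  }
  prof[, denominator := as.numeric(total_mapped)]
  prof[, n_features := .bin_feature_counts(prof, features$end - features$start)]
  prof[, value := ifelse(n_features > 0,
                         rpm(numerator, total_mapped) / n_features, NA_real_)]
  prof[]
}

#' Metagene profiles for labelled feature subsets
#'
#' Splits the feature set by a label vector and computes one profile per
#' label with identical binning. Unlabelled features (`NA`) fall into
#' `"other"`; empty subsets yield all-`NA` profiles with a warning.
#'
#' @param sites site table.
#' @param features feature table.
#' @param labels character vector aligned with `features`.
#' @inheritParams anchored_profile
#' @return named list of profile `data.table`s.
#' @export
profile_feature_subsets <- function(sites, features, labels, context,
                                    anchor = c("five_prime", "three_prime"),
                                    upstream = 3000L, into = 4000L, bin = 100L) {
  anchor <- match.arg(anchor)
  features <- as.data.table(features)
  stopifnot(length(labels) == nrow(features))
  labels <- ifelse(is.na(labels), "other", as.character(labels))
  out <- list()
  for (lab in unique(labels)) {
    sub <- features[labels == lab]
    if (nrow(sub) == 0L) {
      warning("empty subset '", lab, "'")
      p <- .profile_skeleton(upstream, into, bin)
      p[, value := NA_real_]
      out[[lab]] <- p[]
    } else {
      out[[lab]] <- anchored_profile(sites, sub, context, anchor,
                                     upstream, into, bin)
    }
  }
  out
}
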