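#' Small-RNA size-class composition
#'
#' Counts reads per size class (default nine one-nt classes, 18-26 nt) and
#' the fraction of each class among classified reads. Reads outside the
#' class range are counted separately as unclassified, not included in the
#' fractions.
#'
#' @param reads read table with `length_nt`, or a numeric vector of read
#'   lengths.
#' @param classes integer vector of class sizes in nt (default `18:26`).
#' @return `data.table` with `size_class`, `n_reads`, `fraction`; attribute
#'   `n_unclassified`.
#' @export
size_class_fractions <- function(reads, classes = 18:26) {
  lens <- if (is.numeric(reads)) as.integer(reads) else as.data.table(reads)$length_nt
  if (any(lens <= 0)) stop("read lengths must be positive")
  inclass <- lens %in% classes
  if (!any(inclass)) stop("zero classified reads")
  n <- vapply(classes, function(k) sum(lens == k), 0L)
  out <- data.table(size_class = as.integer(classes), n_reads = n,
                    fraction = n / sum(n))
  setattr(out, "n_unclassified", sum(!inclass))
  out[]
}

#' Reads per million mapped reads
#'
#' @param count read count (vectorised).
#' @param total_mapped total mapped reads; must be positive.
#' @return `count / total_mapped * 1e6`.
#' @export
rpm <- function(count, total_mapped) {
  if (length(total_mapped) != 1L || total_mapped <= 0)
    stop("total_mapped must be a single positive number")
  count / total_mapped * 1e6
}

#' Normalise emPAI protein abundances within a sample
#'
#' Each protein's emPAI is divided by the sum of emPAI values of all
#' proteins detected in the sample, so normalised values sum to 1 per
#' sample. Proteins missing in a sample (`NA`) are reported as not
#' detected and excluded from that sample's sum.
#'
#' @param empai_table `data.table`/data.frame with `protein_id`,
#'   `sample_id`, `emPAI` (long format). `NA` emPAI marks non-detection.
#' @return the table with added `normalized_empai` (`NA` for non-detected)
#'   and `detected` columns.
#' @export
normalize_empai <- function(empai_table) {
  dt <- copy(as.data.table(empai_table))
  stopifnot(all(c("protein_id", "sample_id", "emPAI") %in% names(dt)))
  if (any(dt$emPAI < 0, na.rm = TRUE)) stop("emPAI must be non-negative")
  dt[, detected := !is.na(emPAI)]
  sums <- dt[detected == TRUE, .(s = sum(emPAI)), keyby = sample_id]
  if (any(sums$s <= 0) || !all(unique(dt$sample_id) %in% sums$sample_id))
    stop("a sample has no positive emPAI values")
  dt[sums, s_total := i.s, on = "sample_id"]
  dt[, normalized_empai := ifelse(detected, emPAI / s_total, NA_real_)]
  dt[, s_total := NULL]
  dt[]
}
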