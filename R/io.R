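# gzip-transparent fread: base R connections auto-detect compression
.fread_auto <- function(path, ...) {
  if (endsWith(path, ".gz")) {
    lines <- readLines(path)
    if (!length(lines))
      return(suppressWarnings(data.table::fread(text = character(), ...)))
    data.table::fread(text = lines, ...)
  } else {
    suppressWarnings(data.table::fread(path, ...))
  }
}

#' Read a per-cytosine methylation report
#'
#' Parses a Bismark-style cytosine report: a tab-delimited file with seven
#' columns (chromosome, 1-based position, strand, methylated count,
#' unmethylated count, context, trinucleotide) sorted by chromosome then
#' position. Positions are converted to the package-internal 0-based
#' convention on read. Reading is gzip-transparent.
#'
#' @param path path to the report (`.gz` accepted).
#' @param context_filter optional character vector of contexts to keep
#'   (subset of `"CG"`, `"CHG"`, `"CHH"`); other sites are skipped.
#' @return a `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `count_meth`, `count_unmeth`, `context`, `tri`, in file order.
#' @export
read_cytosine_report <- function(path, context_filter = NULL) {
  cols <- c("chrom", "pos", "strand", "count_meth", "count_unmeth", "context", "tri")
  dt <- .fread_auto(path, header = FALSE, sep = "\t",
                    colClasses = list(character = c(1, 3, 6, 7)),
                    fill = FALSE)
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), pos = integer(), strand = character(),
                      count_meth = integer(), count_unmeth = integer(),
                      context = character(), tri = character()))
  }
  if (ncol(dt) != 7L)
    stop("cytosine report must have 7 tab-delimited columns, found ", ncol(dt))
  setnames(dt, cols)
  .check_report_fields(dt)
  .check_report_sorted(dt)
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) records in cytosine report")
  dt[, pos := as.integer(pos - 1L)]
  if (!is.null(context_filter)) {
    bad <- setdiff(context_filter, c("CG", "CHG", "CHH"))
    if (length(bad)) stop("unknown context in filter: ", paste(bad, collapse = ", "))
    dt <- dt[context %in% context_filter]
  }
  dt[]
}

.check_report_fields <- function(dt) {
  first_bad <- function(v) {
    num <- suppressWarnings(as.numeric(v))
    which(is.na(num))[1]
  }
  if (!is.numeric(dt$pos) || anyNA(dt$pos))
    stop("malformed position at line ", first_bad(dt$pos))
  for (cn in c("count_meth", "count_unmeth")) {
    v <- dt[[cn]]
    if (!is.numeric(v) || anyNA(v))
      stop("malformed ", cn, " at line ", first_bad(v))
    if (any(v < 0))
      stop("negative ", cn, " at line ", which(v < 0)[1])
  }
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad))
    stop("unknown context label '", dt$context[bad[1]], "' at line ", bad[1])
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand '", dt$strand[bad[1]], "' at line ", bad[1])
  invisible(TRUE)
}

.check_report_sorted <- function(dt) {
  r <- rle(dt$chrom)
  if (anyDuplicated(r$values)) {
    second <- which(duplicated(r$values))[1]
    line <- sum(r$lengths[seq_len(second - 1L)]) + 1L
    stop("input not sorted: chromosome '", r$values[second],
         "' reappears at line ", line)
  }
  dec <- dt[, .I[c(FALSE, diff(pos) < 0)], by = chrom]$V1
  if (length(dec))
    stop("input not sorted: position decreases at line ", dec[1])
  invisible(TRUE)
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]: positions are converted back to
#' 1-based on write. Writing to a `.gz` path compresses transparently.
#'
#' @param sites site table as returned by [read_cytosine_report()] or
#'   [generate_methylome()].
#' @param path output path.
#' @export
write_cytosine_report <- function(sites, path) {
  out <- data.table(sites$chrom, sites$pos + 1L, sites$strand,
                    sites$count_meth, sites$count_unmeth, sites$context, sites$tri)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Read gene or TE annotations
#'
#' Reads BED6 (0-based half-open, used directly) or GFF3 (1-based closed,
#' converted to 0-based half-open on read). For TEs, the family label is
#' taken from the record name: either its prefix before the first underscore
#' (`family_source = "name_prefix"`), a GFF3 attribute name, or an explicit
#' id-to-family mapping.
#'
#' @param path annotation file.
#' @param format `"BED6"` or `"GFF3"`.
#' @param kind `"gene"` or `"TE"`.
#' @param family_source for TEs: `"name_prefix"` or, for GFF3, the name of
#'   the attribute column carrying the family.
#' @param family_map optional named character vector mapping feature id to
#'   family; overrides `family_source`.
#' @return a `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `kind`, `family`, `id`.
#' @export
read_features <- function(path, format = c("BED6", "GFF3"),
                          kind = c("gene", "TE"),
                          family_source = "name_prefix", family_map = NULL) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (format == "BED6") {
    dt <- .fread_auto(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6L) stop("BED6 requires 6 columns, found ", ncol(dt))
    dt <- dt[, 1:6]
    setnames(dt, c("chrom", "start", "end", "name", "score", "strand"))
    feats <- data.table(chrom = as.character(dt$chrom),
                        start = as.integer(dt$start), end = as.integer(dt$end),
                        strand = as.character(dt$strand), kind = kind,
                        family = "", id = as.character(dt$name))
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
    feats <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        kind = kind, family = "", id = ids)
    feats[strand == "*", strand := "."]
    if (kind == "TE" && is.null(family_map) && family_source != "name_prefix") {
      att <- S4Vectors::mcols(gr)[[family_source]]
      if (is.null(att)) stop("GFF3 attribute '", family_source, "' not found")
      feats[, family := as.character(att)]
    }
  }
  bad <- which(!(feats$start < feats$end))
  if (length(bad))
    stop("invalid interval (start >= end) for record '", feats$id[bad[1]], "'")
  if (any(feats$start < 0)) stop("negative start coordinate")
  if (kind == "TE" && all(feats$family == "")) {
    if (!is.null(family_map)) {
      feats[, family := unname(family_map[id])]
      if (anyNA(feats$family)) stop("family_map misses ids: ",
                                    paste(head(feats$id[is.na(feats$family)], 3), collapse = ", "))
    } else if (family_source == "name_prefix") {
      feats[, family := sub("_.*$", "", id)]
    }
  }
  if (kind == "gene") feats[, family := ""]
  feats[]
}

#' Read mapped small-RNA reads from BED
#'
#' Reads BED intervals (0-based half-open); read length is `end - start`.
#' Reads outside the accepted length range are discarded and counted in the
#' `n_discarded` attribute of the result.
#'
#' @param path BED file (3 or 6 columns).
#' @param min_len,max_len accepted length range in nt (defaults 15-50).
#' @return `data.table` with `chrom`, `start`, `end`, `strand`, `length_nt`;
#'   attribute `n_discarded` counts rejected reads.
#' @export
read_smrna_bed <- function(path, min_len = 15L, max_len = 50L) {
  dt <- .fread_auto(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED requires at least 3 columns")
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6]]) else rep(".", nrow(dt))
  reads <- data.table(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                      end = as.integer(dt[[3]]), strand = strand)
  reads[, length_nt := end - start]
  if (any(reads$length_nt <= 0)) stop("read with non-positive length")
  ok <- reads$length_nt >= min_len & reads$length_nt <= max_len
  out <- reads[ok]
  setattr(out, "n_discarded", sum(!ok))
  out[]
}

#' Write small-RNA reads as BED6
#' @param reads read table as from [read_smrna_bed()] or [generate_smrna()].
#' @param path output path.
#' @export
write_smrna_bed <- function(reads, path) {
  out <- data.table(reads$chrom, reads$start, reads$end,
                    paste0("read_", seq_len(nrow(reads))), 0L, reads$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Write DMRs as BED6+3
#'
#' One line per DMR: name is `context_direction` (e.g. `CHH_hyper_in_B`),
#' score is `-10 log10(q)` capped at 1000, plus extra columns `delta`,
#' `n_windows` and `q`. Same-context DMRs must not overlap (the merge step
#' guarantees this for same-direction records; hyper and hypo records cannot
#' overlap because each window has one sign).
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dmrs <- as.data.table(dmrs)
  if (nrow(dmrs)) {
    setorder(dmrs, chrom, start, end)
    for (ctx in unique(dmrs$context)) {
      d <- dmrs[context == ctx]
      if (nrow(d) > 1L) {
        ov <- d[, any(start[-1] < head(end, -1)), by = chrom]$V1
        if (any(ov)) stop("overlapping same-context DMRs in one track (context ", ctx, ")")
      }
    }
    score <- pmin(1000, round(-10 * log10(pmax(dmrs$q, 1e-100)), 1))
    out <- data.table(dmrs$chrom, dmrs$start, dmrs$end,
                      paste0(dmrs$context, "_", dmrs$direction), score, ".",
                      sprintf("%.6f", dmrs$delta), dmrs$n_windows,
                      format(dmrs$q, digits = 15))
  } else {
    out <- data.table()
  }
  header <- "#chrom\tstart\tend\tname\tscore\tstrand\tdelta\tn_windows\tq"
  lines <- header
  if (nrow(out))
    lines <- c(header, do.call(paste, c(as.list(out), sep = "\t")))
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Read a DMR BED6+3 file written by [write_dmr_bed()]
#' @param path BED file.
#' @return DMR `data.table` (`chrom`, `start`, `end`, `context`, `direction`,
#'   `n_windows`, `delta`, `q`).
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  dt <- if (length(lines)) data.table::fread(text = lines, header = FALSE, sep = "\t")
        else data.table()
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      n_windows = integer(), delta = numeric(), q = numeric()))
  name <- as.character(dt[[4]])
  context <- sub("_.*$", "", name)
  direction <- sub("^[^_]+_", "", name)
  data.table(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]), context = context, direction = direction,
             n_windows = as.integer(dt[[8]]), delta = as.numeric(dt[[7]]),
             q = as.numeric(dt[[9]]))
}

#' Write window values as bedGraph
#'
#' Windows with an undefined value are skipped. Values are printed with six
#' decimal places; records are sorted by chromosome and start.
#'
#' @param windows window table (needs `chrom`, `start`, `end` and the value
#'   column).
#' @param value_field name of the value column (default `"level"`).
#' @param path output path.
#' @export
write_bedgraph <- function(windows, value_field = "level", path) {
  w <- as.data.table(windows)[!is.na(get(value_field))]
  setorder(w, chrom, start)
  out <- data.table(w$chrom, w$start, w$end, sprintf("%.6f", w[[value_field]]))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}
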