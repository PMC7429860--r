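#' Validate a pipeline run configuration
#'
#' A run config is a plain list (or a YAML file) with either a `simulate`
#' block (overrides for [sim_spec()], plus `conditions`, the two condition
#' names compared as A and B) or an `inputs` block (paths: `report_A`,
#' `report_B`, `genes`, `tes`). Common fields: `outdir`, `seed`,
#' `contexts`, `thresholds` (overrides for [context_thresholds()]),
#' `window` (analysis tiling, bp), `density_window`, `metagene`
#' (`upstream`, `into`, `bin`), `smrna_classes`.
#'
#' @param config list or path to a YAML file.
#' @return the completed config list (defaults filled in).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  defaults <- list(seed = 1L, contexts = c("CG", "CHG", "CHH"),
                   window = 100L, density_window = 100L,
                   thresholds = list(),
                   metagene = list(upstream = 3000L, into = 4000L, bin = 100L),
                   smrna_classes = 18:26)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$outdir)) stop("config$outdir is required")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("config needs exactly one of 'simulate' or 'inputs'")
  if (has_inp) {
    req <- c("report_A", "report_B", "genes", "tes")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
    for (p in unlist(config$inputs[req]))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  } else {
    if (is.null(config$simulate$conditions))
      config$simulate$conditions <- c("vegetative", "reproductive")
    if (length(config$simulate$conditions) != 2L)
      stop("simulate$conditions must name exactly two conditions")
  }
  config
}

#' Run the full windowed-methylome pipeline
#'
#' Stages, in dependency order: obtain inputs (simulate the toy study or
#' load cytosine reports and annotations), aggregate windows per context,
#' call DMRs (A vs B), compute per-window difference distributions,
#' attribute DMR bp to genomic features and TE families, compute
#' edge-anchored metagene and 24-nt small-RNA profiles over TEs, and
#' summarise small-RNA size classes. Every output file is recorded in a
#' JSON manifest with its md5 hash, alongside all parameters and stage
#' tallies, so a run is self-describing; identical config + inputs give
#' identical hashes.
#'
#' @param config run configuration (see [validate_run_config()]).
#' @return the manifest list, invisibly; also written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  thr <- do.call(context_thresholds, config$thresholds)
  log_counts <- list()
  outfiles <- character()
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    conds <- sim_args$conditions
    sim_args$conditions <- NULL
    spec <- do.call(sim_spec, c(list(seed = config$seed), sim_args))
    genome <- generate_genome(spec)
    sampleA <- generate_methylome(genome, spec, conds[1])
    sampleB <- generate_methylome(genome, spec, conds[2])
    sitesA <- sampleA$sites; sitesB <- sampleB$sites
    genes <- genome$genes; tes <- genome$tes
    chrom_sizes <- genome$chrom_sizes
    readsB <- generate_smrna(genome, spec, conds[2])
    total_mapped <- attr(readsB, "total_mapped")
    ann_path <- file.path(config$outdir, "tes.bed")
    fwrite(tes[, .(chrom, start, end, id, 0L, strand)], ann_path,
           sep = "\t", col.names = FALSE)
    outfiles <- c(outfiles, ann_path)
  } else {
    sitesA <- read_cytosine_report(config$inputs$report_A)
    sitesB <- read_cytosine_report(config$inputs$report_B)
    genes <- read_features(config$inputs$genes, "BED6", "gene")
    tes <- read_features(config$inputs$tes, "BED6", "TE")
    chrom_sizes <- .infer_chrom_sizes(sitesA, sitesB, genes, tes)
    readsB <- if (!is.null(config$inputs$smrna_B))
      read_smrna_bed(config$inputs$smrna_B) else NULL
    total_mapped <- if (!is.null(readsB)) nrow(readsB) else NULL
  }
  all_dmrs <- list()
  for (ctx in config$contexts) {
    wA <- aggregate_windows(sitesA, chrom_sizes, config$window, ctx, thr$min_cov)
    wB <- aggregate_windows(sitesB, chrom_sizes, config$window, ctx, thr$min_cov)
    wt <- window_tests(wA, wB, thr)
    dmrs <- call_dmrs(wA, wB, thr)
    all_dmrs[[ctx]] <- dmrs
    log_counts[[ctx]] <- list(windows = nrow(wt),
                              windows_testable = sum(wt$testable),
                              windows_significant = sum(
                                wt$q_value < thr$fdr & !is.na(wt$q_value) &
                                  abs(wt$delta) >= thr$delta[[ctx]], na.rm = TRUE),
                              dmrs = nrow(dmrs),
                              dmr_bp = sum(dmrs$end - dmrs$start))
    f_wt <- file.path(config$outdir, paste0("window_tests_", ctx, ".tsv"))
    fwrite(wt, f_wt, sep = "\t")
    f_bed <- file.path(config$outdir, paste0("dmrs_", ctx, ".bed"))
    write_dmr_bed(dmrs, f_bed)
    dd <- tryCatch(difference_density(wA, wB, thr$min_sites, thr$min_cov),
                   error = function(e) NULL)
    if (!is.null(dd)) {
      f_dd <- file.path(config$outdir, paste0("difference_density_", ctx, ".tsv"))
      fwrite(dd$histogram, f_dd, sep = "\t")
      outfiles <- c(outfiles, f_dd)
    }
    outfiles <- c(outfiles, f_wt, f_bed)
  }
  chh_hyper <- all_dmrs[["CHH"]]
  if (!is.null(chh_hyper)) chh_hyper <- chh_hyper[direction == "hyper_in_B"]
  if (!is.null(chh_hyper) && nrow(chh_hyper)) {
    cat_tab <- categorize_dmrs(chh_hyper, genes, tes)
    fam_tab <- family_breakdown(chh_hyper, tes)
    f_cat <- file.path(config$outdir, "dmr_categories_CHH_hyper.tsv")
    f_fam <- file.path(config$outdir, "dmr_families_CHH_hyper.tsv")
    fwrite(cat_tab, f_cat, sep = "\t")
    fwrite(fam_tab, f_fam, sep = "\t")
    outfiles <- c(outfiles, f_cat, f_fam)
  }
  if (nrow(tes)) {
    prof <- anchored_profile(sitesB, tes, "CHH", "five_prime",
                             config$metagene$upstream, config$metagene$into,
                             config$metagene$bin)
    f_mg <- file.path(config$outdir, "metagene_CHH_TE_5p_B.tsv")
    fwrite(prof, f_mg, sep = "\t")
    outfiles <- c(outfiles, f_mg)
    if (!is.null(readsB)) {
      sp <- smrna_metaprofile(readsB, tes, 24L, total_mapped, "five_prime",
                              config$metagene$upstream, config$metagene$into,
                              config$metagene$bin)
      f_sp <- file.path(config$outdir, "smrna24_metaprofile_TE_5p_B.tsv")
      fwrite(sp, f_sp, sep = "\t")
      outfiles <- c(outfiles, f_sp)
    }
  }
  if (!is.null(readsB)) {
    sizes <- size_class_fractions(readsB, config$smrna_classes)
    f_sz <- file.path(config$outdir, "smrna_size_classes_B.tsv")
    fwrite(sizes, f_sz, sep = "\t")
    outfiles <- c(outfiles, f_sz)
  }
  manifest <- list(
    params = list(seed = config$seed, contexts = config$contexts,
                  window = config$window,
                  thresholds = thr[c("delta", "fdr", "merge_gap", "min_sites",
                                     "min_cov")],
                  metagene = config$metagene,
                  mode = if (!is.null(config$simulate)) "simulate" else "inputs"),
    counts = log_counts,
    files = lapply(stats::setNames(outfiles, basename(outfiles)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.infer_chrom_sizes <- function(...) {
  tabs <- list(...)
  mx <- list()
  for (t in tabs) {
    if (is.null(t) || nrow(t) == 0L) next
    endcol <- if ("end" %in% names(t)) t$end else t$pos + 1L
    m <- tapply(endcol, t$chrom, max)
    for (cn in names(m)) mx[[cn]] <- max(mx[[cn]] %||% 0L, m[[cn]])
  }
  unlist(mx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare DMR tallies of two pipeline runs
#'
#' Side-by-side per-context hyper/hypo DMR counts and total bp for two
#' runs (e.g. vegetative-vs-leaf and vegetative-vs-reproductive). Both
#' runs must have used the same analysis tiling.
#'
#' @param runA,runB manifests returned by [run_pipeline()], or paths to
#'   `manifest.json` files.
#' @param labels names for the two comparisons.
#' @return `data.table`: `comparison`, `context`, `direction`, `n`, `bp`.
#' @export
compare_report <- function(runA, runB, labels = c("A", "B")) {
  load_m <- function(x) if (is.character(x)) jsonlite::read_json(x, simplifyVector = FALSE) else x
  mA <- load_m(runA); mB <- load_m(runB)
  if (!identical(mA$params$window, mB$params$window))
    stop("tiling mismatch: runs used different window sizes")
  grab <- function(m, lab) {
    rbindlist(lapply(names(m$counts), function(ctx) {
      data.table(comparison = lab, context = ctx,
                 n_dmrs = m$counts[[ctx]]$dmrs,
                 dmr_bp = m$counts[[ctx]]$dmr_bp)
    }))
  }
  rbind(grab(mA, labels[1]), grab(mB, labels[2]))
}

#' Per-direction DMR summary of two DMR-table sets
#'
#' Convenience for the comparison figure: binds named lists of DMR tables
#' and tabulates counts and bp per comparison, context and direction.
#'
#' @param dmr_sets named list of DMR tables (one per comparison), each as
#'   returned by [call_dmrs()] (possibly several contexts row-bound).
#' @return `data.table`: `comparison`, `context`, `direction`, `n`, `bp`.
#' @export
dmr_comparison_table <- function(dmr_sets) {
  rbindlist(lapply(names(dmr_sets), function(nm) {
    s <- dmr_count_summary(dmr_sets[[nm]])
    if (nrow(s)) s[, comparison := nm]
    s
  }), fill = TRUE)
}
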