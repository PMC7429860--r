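# Shared setup for the analysis drivers: the study-wide simulation spec and
# output locations. Source this from each numbered script.

suppressMessages({
  library(meristemethyl)
  library(data.table)
})

STUDY_SEED <- 20260901L

# The toy study: three organs (leaf, vegetative SAM, reproductive SAM) plus
# a germ-cell-like condition used only in 07. CHH edge-bump amplitudes rise
# leaf < vegetative < reproductive < germ; everything else is shared.
study_spec <- function(seed = STUDY_SEED) {
  sim_spec(seed = seed,
           chh_edge_amp = c(leaf = 0.04, vegetative = 0.15,
                            reproductive = 0.30, germ = 0.45))
}

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

say <- function(...) cat(sprintf(...), "\n")
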