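---
title: "Windowed DMR calling and TE-edge methylation profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed DMR calling and TE-edge methylation profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Plant genomes methylate cytosines in three sequence contexts — CG, CHG and
CHH (H = A, C or T). CG and CHG are symmetric and maintained through DNA
replication; CHH is asymmetric and must be re-established de novo after
every replication, largely by the RNA-directed DNA methylation (RdDM)
pathway, whose 24-nt small RNAs target chiefly the *edges* of transposable
elements (TEs). In the shoot apical meristem (SAM) — the stem-cell tissue
that ultimately gives rise to gametes — CHH methylation behaves very
differently from differentiated leaf tissue, and quantifying that
difference requires a chain of standard but fiddly computations: windowed
aggregation of per-cytosine bisulfite counts, Fisher-exact differential
testing with FDR control and context-specific effect thresholds,
distance-based region merging, base-pair accounting of region overlaps with
genes and TE families, and edge-anchored metagene averaging of methylation
and small-RNA signal.

`meristemethyl` implements that chain as composable, tested functions, and
pairs it with a synthetic-data generator so that every step can be
validated end to end without any sequencing data.

## The DMR model

The genome is tiled into fixed, non-overlapping windows (default 100 bp;
the terminal partial tile is retained — no trimming rule is defensible, and
retention is conservative). Within each window and context, methylated and
unmethylated read counts are pooled across sites and strands; the window
level is the read-weighted ratio
$\hat p = \sum m_i / \sum (m_i + u_i)$, not the mean of per-site rates.
Pooling matches the underlying count comparison, gives high-coverage sites
their proper weight, and makes the Fisher table below exact. Symmetric CG
pairs are *not* collapsed across strands; both strand reads enter the pool
independently.

A window pair (samples A, B) is *testable* when at least one sample has at
least 4 context cytosines each covered by at least 4 reads, and both
samples have at least one read. The second clause is ours: the literal
site/coverage criterion permits an empty count column, which makes the 2×2
table degenerate. Testable windows are tested two-sided with Fisher's exact
test on `[m_A, u_A; m_B, u_B]`; p-values are BH-adjusted per context across
all tested windows genome-wide (not per chromosome, and never jointly
across contexts — contexts are independent pathways and are called
independently throughout). Windows with `q < 0.01` and an absolute pooled
level difference of at least 0.4 (CG), 0.2 (CHG) or 0.1 (CHH) qualify;
same-direction qualifying windows separated by at most 200 bp (inclusive)
merge transitively into DMRs. Hyper- and hypo-methylated windows never
merge, whatever their distance. A merged DMR reports the pooled level
difference over its whole span and the minimum member-window q.

Two numerical points are fixed for reproducibility: the two-sided Fisher
p-value is the sum of hypergeometric probabilities not exceeding the
observed table's probability (with the conventional `1 + 1e-7` relative
tolerance), implemented as a vectorised `dhyper` sum and checked in the
test suite against both `stats::fisher.test` and a log-factorial
enumeration to 1e-12; and a window whose methylated (or unmethylated)
column is empty in both samples admits a single table and yields p = 1
rather than an error — such windows are routine in unmethylated genome and
their test is well-defined, so only an empty *sample* margin errors.

## Difference distributions

Per-window signed differences (`level_B − level_A` over testable windows,
optionally restricted to windows overlapping a region set by ≥ 1 bp) are
summarised two ways: a histogram with 0.01-wide bins on [−1, 1], which is
the normative output tests assert against, and a Gaussian KDE with
Silverman's bandwidth for plotting — the kernel is unspecified in the
windowed-DMR tradition, so the histogram is authoritative. The mode of a
0.01-binned histogram of a few thousand noisy windows is only resolved to
a couple of bins; checks against "the mode is at zero" therefore allow
±0.03. Both 100-bp (analysis) and 50-bp (figure-style) tilings share the
same code path.

## Feature and family accounting

Every DMR base pair is attributed to exactly one category with precedence
TE > gene body > other intergenic; TE base pairs split into genic and
intergenic TEs by whether the TE itself touches a gene. The accounting is
exact: category totals sum to the unique DMR bp. Family tables flatten
same-family TE annotations before measuring genomic bp (nested repeat
annotations otherwise double-count), and report per-family DMR-overlap bp,
its share of the family-attributed total, the family's share of TE bp, and
their ratio as enrichment. Under uniform placement of DMRs over TE bp the
enrichment is 1 within Monte-Carlo error — the test suite uses this as the
negative control.

## Metagene profiles

Profiles anchor features at the 5′ or 3′ end, flip minus-strand features so
offsets run in the biological direction, and bin offsets from −3 kb
(flank) to +4 kb (body) in 100-bp bins. Positive offsets past a feature's
far end are excluded: a 1-kb TE contributes nothing beyond +1000, so edge
peaks are not diluted with flanking sequence. Flank bins are not masked
for neighbouring annotation — near-gene CHH signal genuinely reflects
nearby MITEs and masking would hide exactly the biology of interest.
Methylation bins pool reads across features (read-weighted); small-RNA
bins count read 5′ ends, normalise to reads per million mapped, and divide
by the number of features contributing to the bin ("average RPM"). A
per-feature-averaged methylation variant is available behind a flag.
Because a feature "contributes" to a body bin whenever its body reaches the
bin's first position, body bins near the typical feature length mix fully
and partially covered features; comparisons in the tests therefore use
flank bins or truth-referenced expectations rather than raw body bins.

## The synthetic generator

The generator emulates the statistical structure of a rice-like SAM
methylome at desk scale, and its defaults are the package's study
conditions:

* genome: 2 chromosomes × 400 kb at GC 0.43 (rice-like); cytosines scanned
  on both strands, so a CG on the plus strand implies one on the minus,
  while CHH is strand-specific;
* annotation: 40 genes and 60 TEs per chromosome; TE families MITE (35 %,
  ~300 bp), Ty3-gypsy (15 %, ~4 kb), CACTA (15 %, ~2 kb), LINE (10 %,
  ~1.5 kb) and a remainder bucket, log-normal lengths; 70 % of MITEs are
  placed within 1 kb of a gene (the rice-specific near-gene MITE bias);
  TEs overlap genes with probability 0.1;
* baseline rates per compartment and context: gene body CG 0.55 /
  CHG 0.05 / CHH 0.02, TE body 0.85 / 0.55 / 0.05, background 0.10 /
  0.05 / 0.02 — high CG/CHG in TE bodies, low CHH everywhere;
* the CHH edge bump: `a · [exp(−d/λ) + exp(−(L−1−d)/λ)]` from both TE ends
  (inside and outside the element), λ = 200 bp, capped at 1, with
  amplitude per condition `a` = 0.04 (leaf), 0.15 (vegetative SAM), 0.30
  (reproductive SAM) and MITE edges boosted 1.5× — the leaf < vegetative <
  reproductive ordering and the MITE concentration are the structural
  signatures the acceptance checks recapitulate; a flat +0.05 CHH elevation
  marks 500-bp gene flanks outside TEs;
* counts: per-site coverage is negative-binomial (mean 8, size 10; the
  real libraries' 24–25× is scaled down for desk-scale runtimes — the
  tests state their own coverages); methylated counts are beta-binomial
  with ρ = 0.05 by default, or binomial at ρ = 0 for closed-form checks;
* small RNAs: nine size classes 18–26 nt with 24-nt weights 0.090 (leaf),
  0.504 (vegetative) and 0.527 (reproductive) — the meristem/leaf contrast
  in the published size distributions; 24-nt read 5′ ends are concentrated
  8-fold within 200 bp of TE edges, other reads land uniformly on the
  zone complement.

Every generator is byte-deterministic under a fixed seed. The truth field
(per-site true rate, per-condition) is emitted alongside the counts, so
downstream checks compare observed quantities to expectations computed
from the truth with matched weights.

What the generator does *not* model — and hence what green tests do not
show about real data: realistic repeat sequence content (the genome is
i.i.d. random), bisulfite conversion failure, mapping bias, biological
replicates (the method compares single pooled libraries, as the windowed
Fisher approach assumes), chromosome-scale methylation gradients such as
pericentromeric enrichment, and linkage between contexts at shared loci.
Fisher's exact test presumes binomial within-library sampling; the
generator's mild overdispersion (ρ = 0.05) leaves the genome-wide
false-discovery fraction far below the nominal 0.01 in the type-I study,
but stronger biological overdispersion in real comparisons would not be
controlled — that is a property of the windowed-Fisher method itself, not
of this implementation.

## Validation studies and their sizes

The acceptance machinery (tests and `scripts/acceptance.R`) runs four
simulation studies whose problem sizes are the package's own choices:

* *oracle equivalence*: on a 40-kb planted genome, the full caller
  (filter → Fisher → BH → threshold → merge) must match an independent
  brute-force implementation (naive loops, log-factorial Fisher, literal
  step-up BH, literal scan-merge) record for record, and the vectorised
  Fisher must match factorial enumeration to 1e-12 on exhaustive small
  tables and random tables with totals ≤ 200;
* *type-I*: 20 replicate pairs drawn from one vegetative truth field on a
  250-kb chromosome (~2,500 testable CHH windows each); the pooled
  fraction of `q < 0.01` windows must stay ≤ 0.02;
* *planted recovery*: 20 seeds of a 50-kb genome with eight 300-bp blocks
  per context planted at exactly 1.5× the context thresholds (CG +0.6,
  CHG +0.3, CHH +0.15) on clean background, binomial counts at 15× mean
  site coverage so pooled window depth clears 120 reads; window-level
  sensitivity and precision must both reach 0.9. Coverage 15× was chosen
  once so that the sparsest context (CG, ~9 sites per window) meets the
  120-read pooled floor;
* *structural recapitulation*: one default-spec run must place more CHH
  hyper-DMR bp on TEs than on gene bodies, enrich MITEs above 1, peak the
  CHH TE metagene within 200 bp of the edge with the observed edge
  amplitude within 3 SE of the truth-derived expectation (the SE uses the
  beta-binomial design effect `1 + (c̄ − 1)ρ`), and shift the TE-edge
  difference-density mode positive for CHH while the CG mode stays at
  zero (±0.03, the histogram's mode resolution).

## Known limitations

* The per-window Fisher test ignores biological replication and
  overdispersion by design; replicate-aware beta-binomial testing is out
  of scope.
* DMR boundaries are window-quantised; a planted block is recovered to
  ±1 window.
* `read_cytosine_report` materialises the table in memory; at toy scale
  (hundreds of thousands of sites) this is a few tens of MB. The strict
  sortedness check preserves the single-pass contract a streaming reader
  would need.
* The germ-cell analysis in `analysis/07` treats "highly methylated in
  germ cells" as a pooled body-level gain ≥ 0.15 over the leaf, because no
  published threshold exists for that set; the DMR-overlap criterion is
  available behind a flag and neither is claimed to reproduce the
  published overlap fraction.
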