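# meristemethyl

Windowed differential-methylation analysis and TE-edge profiling for plant
shoot-apical-meristem (SAM) bisulfite data, with a fully synthetic test
bench.

## What it does

Plant cytosine methylation falls into three sequence contexts (CG, CHG,
CHH; H = A/C/T). Asymmetric CHH methylation is re-deposited after every
replication, mostly by the 24-nt small-RNA-guided RdDM pathway at the
edges of transposable elements (TEs), and it reconfigures dramatically
between differentiated leaf tissue and the meristem. This package
implements the complete desk-side analysis chain for such comparisons:

* **Windows** — tile the genome (default 100 bp), pool per-cytosine
  methylated/unmethylated counts per context into window levels
  `p̂ = Σm / Σ(m+u)`, and compute per-window difference distributions
  between samples.
* **DMRs** — Stroud-style calling between two samples: windows with ≥ 4
  cytosines each covered ≥ 4× in at least one sample are tested with a
  two-sided Fisher's exact test on the pooled 2×2 counts; BH FDR < 0.01
  per context genome-wide; absolute difference ≥ 0.4 / 0.2 / 0.1 for
  CG / CHG / CHH; qualifying same-direction windows within 200 bp merge.
* **Overlap accounting** — DMR base pairs attributed to TEs (genic /
  intergenic), gene bodies and other intergenic space; per-TE-family
  overlap tables with genome-share enrichment (MITEs vs the rest); TE
  grouping by methylation change; germ-cell/SAM hypermethylated-set
  overlap with a hypergeometric test.
* **Metagene profiles** — 5′/3′-anchored pooled methylation and 24-nt
  small-RNA RPM profiles from −3 kb to +4 kb in 100-bp bins, with
  positions beyond a feature's far end excluded so TE-edge peaks stay
  sharp.
* **Abundance summaries** — nine small-RNA size classes (18–26 nt) and
  per-sample-normalised emPAI protein abundances.
* **Synthetic data** — a deterministic generator (toy genome, gene/TE
  annotation with near-gene MITE bias, compartment baselines, a
  condition-specific exponential CHH edge bump, beta-binomial counts,
  edge-enriched 24-nt reads) plus the ground truth behind every site.

Everything lives in `R/` as tested functions; the numbered scripts under
`analysis/` drive the full toy study and write tables under `results/`.

## Worked example

```r
library(meristemethyl)

spec   <- sim_spec(seed = 42, n_chroms = 1, chrom_length = 100000,
                   n_genes = 10, n_tes = 15)
genome <- generate_genome(spec)
veg    <- generate_methylome(genome, spec, "vegetative")
rep_   <- generate_methylome(genome, spec, "reproductive")

wV <- aggregate_windows(veg$sites,  genome$chrom_sizes, 100, "CHH")
wR <- aggregate_windows(rep_$sites, genome$chrom_sizes, 100, "CHH")
dmrs <- call_dmrs(wV, wR)           # vegetative = A, reproductive = B
dmr_count_summary(dmrs)
#>    context  direction     n    bp
#> 1:     CHH hyper_in_B    14  5700
```

Fourteen CHH regions gain methylation in the reproductive sample — they
sit at TE edges, where the generator raised the bump amplitude from 0.15
to 0.30. The edge-anchored profile makes that visible directly:

```r
p <- anchored_profile(rep_$sites, genome$tes, "CHH", "five_prime")
p[bin_start %in% c(-300, 0, 500), .(bin_start, value, n_features)]
#>    bin_start     value n_features
#> 1:      -300 0.2187675         15
#> 2:         0 0.3521170         15
#> 3:       500 0.1061485          9
```

The profile peaks in the first body bin (offset 0, the TE 5′ edge) and
decays into the body, the hallmark of RdDM-driven edge methylation.

Running the full toy study (`Rscript analysis/01_simulate.R` … `07`)
prints, among other things:

```
rep-hyper CHH DMR bp: 48.7% on TEs (45.2% intergenic), 4.3% on gene bodies
MITE share of TE-overlapping DMR bp: 59.2% vs 10.3% of TE bp (enrichment 5.7x)
24-nt fraction: leaf 8.8%, vegetative 50.3%, reproductive 52.6%
```

i.e. reproductive-stage CHH gains concentrate on intergenic TEs, MITEs are
strongly over-represented relative to their genomic share, and the
meristem small-RNA pool is dominated by the 24-nt class while the leaf's
is not — the qualitative structure the pipeline is designed to expose.

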