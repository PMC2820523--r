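# selfscape

Population structure, selfing and isolation by distance from sparse SNP
panels, for spatially referenced collections of highly selfing plants.

Large field collections of predominantly self-fertilizing plants (the
motivating case is *Arabidopsis thaliana*, sampled across field sites on
several continents and genotyped on ~139 intermediate-frequency SNPs) raise
a recurring set of questions: which plants carry haplotypes that are
*potentially identical* given marker resolution and genotyping error; how
often does each field site outcross; how diverse is a site; and how does
genetic similarity decay with geographic distance — smoothly, as classical
isolation by distance, or abruptly, when un-recombined haplotypes spread
clonally across a continent? `selfscape` implements that analysis chain as
a tested R package, together with synthetic genotype-landscape generators
so every estimator can be validated by parameter recovery.

## What it computes

* **Genotype QC** — sample filter on missing-call fraction (default the
  "more than 50 of 149 markers" rule as a fraction), marker filter on
  missingness or excess heterozygosity (default > 25% each, applied
  separately), and removal of whole haplogroups that contain blacklisted
  (lab-strain-like) samples.
* **Haplogroup clustering** — a modified QT clustering. The distance
  between two haplotypes is derived from the binomial probability of seeing
  the observed number or more of mismatches among the `n` markers
  informative in both, given a per-marker discrepancy rate ε:
  `q = P(X ≥ k), X ~ Bin(n, ε)`, used as `d = −log10(q)`. Clusters grow
  around candidate centers, admitting haplotypes in order of distance while
  `d < α·m` with `m` the current cluster size (α = 0.05); the largest
  formable cluster is extracted each round. Heterozygous calls are treated
  as missing.
* **Selfing rates** — per field site, multilocus
  `F_IS = 1 − ΣH_obs / ΣH_exp` (ratio of sums over polymorphic loci, with
  the `2n/(2n−1)` small-sample correction), converted by
  `s = 2/(1/F_IS + 1)`, with locus-bootstrap percentile confidence
  intervals and site-eligibility rules (field-collected tissue only, at
  least two haplogroups present).
* **Diversity** — per-site probability that two plants are of different
  haplogroups, `1 − Σcᵢ(cᵢ−1)/(n(n−1))`; dominance summaries; the pairwise
  mismatch distribution stratified by continent; and a panmixia null
  obtained by resampling each marker independently from a donor pool
  (optionally one representative per haplogroup), against which pairs are
  classified identical / intermediate / unrelated.
* **Spatial analysis** — haversine distances, binned same-haplogroup
  probability and mismatch quantiles at any scale (150 / 10 / 0.5 km
  presets), linear `y = mx + b` and exponential `y = C·e^{−λx}` /
  `y = K − C·e^{−λx}` fits, pairwise-site Weir–Cockerham F_ST, and the
  regression of F_ST on ln(distance) with sliding-window slopes.
* **Synthetic data** — a mixed-mating inbreeding-equilibrium genotype
  generator (each call is an inbred draw with probability F, a
  Hardy–Weinberg draw otherwise) and a two-scenario landscape generator:
  smooth spatially autocorrelated allele-frequency gradients
  ("eurasia") versus clonal founder spread over weak background structure
  ("north_america"), both with genotyping error and missingness.

## Worked example

The whole chain runs from one configuration; with no input files it
simulates a landscape first:

```r
library(selfscape)
run <- run_pipeline(list(
  seed = 7,
  simulate = list(scenario = "north_america", n_sites = 30, plants_per_site = 10),
  selfing = list(n_boot = 100),
  ibd = list(bin_widths_km = c(300)),
  fst = list(window = 50)
))
summarize_run(run)
```

```
selfscape run (seed 7, config e76ad445b7db2b273555314a07f3e7a7)
samples: 300, markers: 139 after QC
haplogroups: 35 (largest 72)
haplogroup size spectrum (size x n_groups):
  72x1  54x3  36x1  1x30
selfing: plant-weighted 98.8%, site-weighted 98.8% (site quartiles 98.4/98.9/99.4%)
sites dominated by one haplogroup: 100% of 30
pair classes: 4.5% identical, 12.2% intermediate, 83.3% unrelated
IBD 300km bins: p(same haplogroup) slope -9.12e-05 per km (n bins 11)
F_ST ~ ln(km): slope 0.0435 over 435 site pairs
```

The clone scenario produces what such collections look like in practice: a
few continent-spanning haplogroups (here 72, 54, 54, 54 and 36 copies)
over a background of singletons, every site dominated by one haplogroup,
and a tri-modal pair structure — a spike of genetically identical pairs, a
large unrelated mass, and an intermediate shoulder. The same run on
`scenario = "eurasia"` instead yields 300 singleton haplogroups, no
dominated sites and a clearly positive F_ST–ln(distance) slope (0.040
at seed 7): smooth isolation by distance without clonal sharing.

Individual stages are ordinary functions (`read_genotypes()`,
`qt_cluster()`, `selfing_by_site()`, `simulate_panmixia()`,
`pairwise_site_fst()`, …) and every tabular result is a plain data frame;
`run_pipeline(out_dir = …)` additionally writes each stage as TSV plus a
YAML manifest with counts, checksums and timings.

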