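---
title: "Methods: haplogroup clustering, selfing estimation and spatial structure in selfscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplogroup clustering, selfing estimation and spatial structure in selfscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`selfscape` analyses spatially referenced SNP genotype collections from
highly selfing plants. This vignette is the package's account of the
statistical machinery: the models and their assumptions, the tunable
parameters and why their defaults are what they are, what the synthetic
generators do and do not emulate, and the numerical choices made where the
underlying procedure left the design open.

## Data model

Genotypes are biallelic calls in {HOM_REF, HET, HOM_ALT, MISSING}, stored
as an integer matrix (samples × markers; 0/1/2/NA). Two conventions run
through everything:

* **Mismatch statistics treat heterozygous calls as missing.** A selfing
  plant's haplotype is essentially homozygous; residual heterozygous calls
  are a mix of genuine recent outcrossing and assay noise, and comparing
  them across plants is not informative about haplotype identity. So the
  mismatch kernel counts `n` = markers with informative (homozygous) calls
  in both plants and `k` = those at which the calls differ.
* **Heterozygosity-based statistics do not.** `F_IS` and the
  heterozygous-locus counts exist precisely to measure heterozygote
  deficit, so there the HET calls are the signal.

Pairs with `n = 0` comparable markers have an undefined mismatch fraction;
they are flagged, counted, and excluded from every downstream
distribution, and they can never be co-clustered.

## QC filters

Samples are dropped when their missing-call fraction exceeds a threshold
stored as a fraction (default 50/149 ≈ 0.336) so that the rule scales to
panels of any size. Markers are dropped when missingness *or*
heterozygosity exceeds 25% of samples — two separate symptoms of a failing
assay, tested separately rather than summed (summing would double-count a
marker failing both ways). Blacklist removal deletes entire haplogroups
containing named samples; since the blacklist is defined on haplogroups,
the pipeline clusters first, removes, then re-clusters the survivors.

## Haplogroup clustering

Two haplotypes are "potentially identical" when their `k` observed
mismatches among `n` informative markers are compatible with genotyping
error alone. Under that identity hypothesis, with a per-marker discrepancy
rate ε, the tail probability is `q = P(X ≥ k)` for `X ~ Binomial(n, ε)`
(evaluated via the survival function; `k = 0` gives `q = 1`).

The clustering is a QT-style greedy extraction: every remaining sample is
tried as a center; candidates are proposed in order of ascending distance
and admitted while `d < τ(m)`, where `m` is the current cluster size
(center included) and `τ(m) = α·m` by default; the largest formable
cluster wins each round and is removed.

**Distance transform.** The size-proportional threshold only behaves
sensibly if the distance is unbounded: a raw probability-valued distance
(`1 − q`) saturates at 1, so once a cluster reached `1/α = 20` members it
would admit *every* haplotype, collapsing the sample into one group. The
default distance is therefore `d = −log10(q)`, which is 0 for identical
haplotypes, grows smoothly with the mismatch count, and is unbounded —
large clonal groups tolerate a few genotyping errors while unrelated
haplotypes (mismatch fractions around 30–40% on this marker class) sit at
astronomically large distances and never merge. The bounded transform and
two alternative threshold rules (`α/m`, fixed `α`) are retained as
configuration for sensitivity analysis, not as defaults.

**ε (default 0.005).** The per-marker discrepancy rate between two reads
of the same haplotype. It is a property of the assay, not of the
population; 0.5% per marker is a conservative figure for array-style SNP
genotyping. Note the threshold ladder this implies: a single mismatch on
139 markers gives `d = −log10(1 − 0.995¹³⁹) ≈ 0.2995`, so a one-error copy
is only admitted once the cluster already holds ≥ 6 closer members. A
consequence worth knowing: clusters *seed* through exact matches. If every
copy of a clone carries at least one error, no pair is ever admissible at
`τ(1) = 0.05` and the clone fragments into singletons. Exact recovery of
clonal groups therefore requires errors to be rare per copy (most copies
exact), which is also the regime the recovery tests exercise; at per-call
error rates of 0.5–1% on 139 markers, fragmentation of small clonal groups
is expected behaviour, not a bug.

**Determinism and tie-breaks.** Candidates tie-break by ascending input
index; centers by largest cluster, then smallest sum of member distances,
then lowest input index. Identical observed haplotypes are collapsed to
one representative during the center search — a pure optimization verified
against an exhaustive re-evaluating implementation — and a round whose
best cluster is a singleton finishes the partition immediately (no later
round could do better), with singletons emitted in input order, exactly as
the naive tie-break would.

## Selfing rates from F_IS

Per field site, for each locus polymorphic within the site, with
within-site alternate-allele frequency `p̂` from the `n` plants with
non-missing calls:

* `H_obs = n_het / n`,
* `H_exp = 2p̂(1−p̂) · 2n/(2n−1)` (small-sample correction),

and the multilocus estimate combines loci as a **ratio of sums**,
`F_IS = 1 − ΣH_obs / ΣH_exp` — the standard multilocus combination, robust
to low-information loci in a way a mean of per-locus ratios is not.
Monomorphic loci carry no information and contribute nothing; a site with
no polymorphic locus is skipped. At inbreeding equilibrium under uniform
outcrossing within a site, `F = s/(2−s)`, inverted as
`s = 2/(1/F_IS + 1)`. Negative `F_IS` (heterozygote excess) is clamped to
`s = 0` with a note; the round-trip `s → F → s` is exact to 1e-12 on
(0, 1].

Eligibility mirrors the sampling design the estimator assumes: only sites
whose genotyped tissue is field-collected seed or mature field-grown
plants (stock-center material has a different ascertainment history), and
only sites with at least two haplogroups (a clonally uniform site carries
no outcrossing information). Confidence intervals resample **loci** with
replacement (the sampling unit for a multilocus estimate at a fixed set of
plants), with percentile bounds; replicates whose resampled loci are all
monomorphic are dropped and counted, and the interval is reported
undefined if more than half drop. Aggregates over sites are reported both
plant-weighted and site-weighted, since the collection's site sizes span
orders of magnitude and the two weightings answer different questions.

## Diversity, panmixia and pair classes

Site diversity is the probability that two plants drawn *without
replacement* are of different haplogroups, `1 − Σcᵢ(cᵢ−1)/(n(n−1))`
(a with-replacement Simpson variant is available by flag). The panmixia
null simulates haplotypes by copying, for each marker independently, the
call of a uniformly chosen donor — destroying linkage while preserving
marginal call frequencies; the `unique_only` variant draws from one
representative (the central haplotype) per haplogroup, removing the
weighting caused by clonal amplification. The closed-form companion
`Σ 2f₀f₂ / Σ g²` (donor call frequencies `f₀`, `f₂`, informative mass `g`)
is exact when all donor calls are informative and is used as the
simulation's cross-check.

Pairs are classified **identical** (`k = 0`), **unrelated** (mismatch
fraction at or above the 1st percentile of the simulated panmictic
distribution — i.e. indistinguishable from random re-assortment), else
**intermediate**. The three-way split is this package's operational
formalization of the tri-modal mismatch structure such collections show;
the quantile and the `k = 0` rule are configurable, and the fractions it
yields on synthetic data are descriptive, not calibrated to any published
percentages. Mismatch histograms default to bins of width `1/L` (one
marker).

## Spatial analysis

Distances are haversine great-circle km on the IUGG mean Earth radius
6371.0088 km; coordinates are decimal degrees, WGS84 assumed, no datum
conversion. Pairs enter half-open bins `[iw, (i+1)w)` by the floor rule at
any width (150 / 10 / 0.5 km presets); per bin the same-haplogroup
proportion, interpolated mismatch quantiles (9/25/50/75/91%) and pair
count are reported. Curve fits — linear, `C·e^{−λx}` and the saturating
`K − C·e^{−λx}` — are least squares on bin midpoints, weighted by per-bin
pair count by default (bins summarize wildly different numbers of pairs);
bins with fewer than 5 pairs are excluded by default (configurable,
logged). Nonlinear fits use Levenberg–Marquardt with data-driven starts
(`C₀` from the first bin, `λ₀` from a log-linear regression, `K₀` from the
last bin); a solver failure or a negative fitted rate returns
`converged = FALSE` rather than an error, because monotone rising data
genuinely cannot fit a decay and the caller should see that as a result,
not a crash.

Between-site differentiation is the two-population Weir–Cockerham θ,
computed per locus from the variance components (a, b, c) and combined
across loci as a ratio of summed components. Negative estimates are
retained — truncating at zero would bias the distance regressions the
estimator feeds. The F_ST–ln(distance) regression excludes zero-distance
pairs and reports, besides the global OLS slope, slopes over sliding
windows of consecutive distance-ordered pairs (step 1; the window size is
a dataset-scale constant — 500 pairs suits a continental collection,
and synthetic runs scale it down to ~50).

## Synthetic data: what it emulates, and what it does not

`generate_panel` draws marker frequencies uniformly on [0.25, 0.30],
matching a panel ascertained for intermediate minor allele frequencies.
`generate_equilibrium_site` draws each call independently: an inbred draw
(homozygous, alt with probability p) with probability F, a Hardy–Weinberg
draw otherwise — the stationary genotype distribution of partial selfing,
giving per-locus heterozygosity `(1−F)·2p(1−p)` exactly.

`generate_landscape` realizes two qualitative regimes:

* **eurasia** — sites uniform on a square (default 3000 km, anchored at
  45°N), per-site allele frequencies perturbed on the logit scale by a
  Gaussian field with correlation `exp(−d/scale)` (default scale 800 km,
  sd 1, truncated to frequencies in (0.02, 0.98)), genotypes at
  equilibrium (default F = 0.95). Expected pairwise mismatch then rises
  smoothly with distance — tunable isolation by distance without a
  forward simulator.
* **north_america** — a handful of fully homozygous founder haplotypes;
  each site draws `clone_fraction` (default 0.9) of its plants as copies
  of one founder plus equilibrium background. Founder choice decays with
  distance to the founder's origin over the *full landscape extent*, so it
  is only weakly spatial: clones span the continent, and the
  F_ST–distance relationship stays near flat while same-haplogroup sharing
  reaches across it. (An earlier calibration with a much shorter decay
  scale made founder choice strongly spatial and reproduced a
  Eurasia-like F_ST slope — the opposite of the regime this scenario
  exists to emulate.)

Both scenarios end with genotyping noise: each non-missing call flips to
the *opposite homozygote* with probability `error_rate` (heterozygote
errors would vanish downstream, where HET is treated as missing; a
HET-error mode exists by flag) and is then set missing with probability
`missing_rate`. All generators are bit-reproducible given their seed, and
a truth record (per-site F, per-site frequencies, founder assignments)
accompanies every landscape for recovery tests.

What the generators deliberately do **not** model: coalescent or
forward-time history, recombination and linkage (markers are independent,
matching the marker-level statistics computed from them), landmass
geometry, migration dynamics, or any quantitative dispersal parameters.
Passing recovery tests on these landscapes shows the estimators recover
the parameters of *this* generating process at desk scale; it does not
certify the published continental estimates, which depend on the original
collection.

## Problem sizes and runtime choices

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in well under a minute of compute per module: selfing
recovery at 50 sites × 30 plants and 8 × 25 (139 loci), clustering oracle
equivalence at N ≤ 12 against a literal exhaustive re-implementation,
clone recovery at 4 founders × 20 copies over 20 seeds, landscape
contrasts at 25–50 sites × 4–10 plants over 10 seeds, F_ST nulls at 2 × 40
plants over 50 replicates, and panmixia checks at a few hundred simulated
haplotypes (the simulator itself defaults to 10,000, with pair scoring
capped at 10⁵ randomly chosen pairs).

## Known limitations

* The size-adaptive threshold semantics reconstruct a procedure whose
  original description is under-specified (the probability-valued reading
  degenerates, and ε is unstated); the default is a behaviour-preserving
  interpretation, exposed as configuration, not a verified reconstruction
  of the original code.
* `F_IS` here is the ratio-of-sums multilocus form with the `2n/(2n−1)`
  correction; a Weir–Cockerham within-population `f` could be swapped in
  behind the same interface and will differ slightly at small `n`.
* The saturating exponential fit's parameters are only as identifiable as
  the binned data allow; with ~40 bins and noise of the order used in the
  recovery tests, the least-squares λ estimate itself strays beyond 10%
  of truth in a non-negligible fraction of realizations — a statistical
  limit of the fixture, not a solver failure (restarts at the true
  parameters land on the same optimum).
* Selfing estimates assume uniform outcrossing within a site and
  equilibrium heterozygosity; within-site spatial mating structure
  inflates them, and no effective-selfing correction for inbreeding
  depression is attempted.
* The package's interface is its exported functions plus
  `run_pipeline()`/YAML configs; there is no shell entry point, as the
  expected use is interactive or scripted R.
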