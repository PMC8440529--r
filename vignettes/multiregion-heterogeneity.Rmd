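---
title: "Quantifying intratumor heterogeneity from multi-region exome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity from multi-region exome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrith)
```

## The problem

Single-biopsy sequencing of a solid tumor sees one sample of a genetically
heterogeneous cell population. When several spatially separated regions of
the same tumor are exome-sequenced against a matched normal, the regional
distribution of somatic mutations and copy-number alterations becomes
observable, and with it the quantities this package computes: the fraction
of mutations confined to a subset of regions (SNV ITH), the divergence of
copy-number profiles between regions (CNV ITH), mutation clusters and their
cellular prevalence, whole-genome doubling, mutational signatures, and the
association of these features with disease-free and overall survival.
The package is organised around the design of surgically resected small
cell lung cancer cohorts — around 40 patients, three FFPE regions per
tumor, ~250x exome depth — but every cohort parameter is configurable.

Because real multi-region cohorts of this kind are controlled-access, the
package ships a synthetic cohort generator with full ground truth; every
downstream method is validated by parameter recovery against that truth.

## From read counts to cancer cell fractions

For a mutation observed at variant allele frequency $v$ in a region with
tumor purity $\rho$, local tumor total copy number $n_t$ and normal copy
number $n_n$ (2 on autosomes), the mutation copy number is

$$\mu = v \cdot \frac{\rho\, n_t + (1-\rho)\, n_n}{\rho}.$$

Multiplicity is $m = \mathrm{clamp}(\mathrm{round}(\mu),\, 1,\,
\max(\text{major CN}, 1))$ and the cancer cell fraction is
$\mathrm{CCF} = \mu / m$. Noise — FFPE artifacts in particular — can push
raw CCFs above 1; values are capped at 1.5 with a flag rather than
discarded, and the default cap is configurable.

## Clustering across regions

Mutations are clustered on their per-region CCF profiles by a
binomial-likelihood mixture fitted with EM, a deterministic stand-in for
sampling-based subclonal deconvolution. Each cluster carries a prevalence
per region (constrained to $[0,1]$ — a cellular prevalence is a fraction
of cells); a mutation absent from a region is an observation of prevalence
zero there. For each $k = 1..k_{max}$ (default 6) the model is fitted from
a k-means++-style seeded initialization, best of 4 restarts, and $k$ is
selected by BIC.

A subtlety worth recording: the CCF is a *linear transform* of the VAF, so
binomial read noise is inflated on the CCF scale by the squared inverse of
the transform coefficient (small at low purity). `ccf_matrix()` therefore
supplies the EM with *effective* depths chosen so the model's
$\mathrm{Binomial}(n_{\mathrm{eff}}, \pi/2)$ variance matches the actual
sampling variance of each CCF estimate. Without this correction the
clonal cluster of a low-purity region over-splits and SNV ITH is grossly
overestimated.

The cluster with the maximum mean prevalence across regions defines the
clonal mutations (ties to the larger cluster, then the lower id); all
others are subclonal, and

$$\text{SNV ITH} = \frac{\#\ \text{subclonal}}{\#\ \text{all mutations}}$$

over the patient-level union of nonsilent mutations. Silent mutations are
carried through but excluded from clustering and TMB, which uses the
cross-region union of nonsilent mutations divided by the callable coding
footprint (default 38 Mb, configurable — exome captures differ and the
denominator is a convention, not a measurement).

## Copy number: gains, losses, GII, WGD, CNV ITH

Gains and losses are called against regional ploidy:
$\log_2(n_t/\text{ploidy}) \ge \log_2(2.5/2)$ is a gain,
$< \log_2(1.5/2)$ a loss. The genome instability index is the
length fraction of the autosomal genome covered by either, averaged over
regions. Sex chromosomes are excluded from genome-wide denominators by
default (tumor CN on X/Y is confounded by sex).

Whole-genome doubling is detected from the length-weighted fraction of
the autosomal genome with major allele copy number $\ge 2$. The null
distribution re-pairs the segments' allele states with the segment
lengths at random ($10^4$ permutations by default), and the p-value is
compared with a ploidy-class threshold: $p \le 0.001$ up to triploid,
$\le 0.05$ tetraploid, $\le 0.5$ pentaploid, and always at hexaploid or
above. The permutation preserves the state multiset, so a fully doubled
genome — every segment's major CN $\ge 2$ — reproduces the observed
statistic in every permutation and the p-value degenerates to 1; that
case (statistic 1.0, rounded ploidy $\ge 4$) short-circuits to a WGD
call. On the generator's doubled genomes this combination yields
region-level sensitivity above 95% with false calls below 5% on diploid
genomes (checked in the test suite at $n_{sim} = 1000$).

Because regions are segmented independently, cross-region CNV comparison
happens on fixed 10 Mb bins (configurable); a bin takes the direction
covering the majority of its covered length. A gain is clonal iff every
region shows it; a loss is clonal iff every region shows loss *or LOH*.
CNV ITH is the mean pairwise Jaccard distance between the regions'
(bin, direction) event sets; pairs with an empty union contribute 0.

## Phylogenies and timing

Trees are built from the binary presence/absence matrix of nonsilent
mutations (mutations co-localized with LOH in any region are excluded as
unreliable characters). The root is the all-zero germline profile joined
by a trunk edge to the regions' most recent common ancestor; with at most
four regions the topology search is exhaustive, so the maximum-parsimony
tree is exact. Mutations are placed on edges by an exact unit-cost
small-parsimony pass; ambiguous placements resolve toward the trunk-most
edge, and branch lengths are mutation counts per edge. Trunk mutations —
present in every region — coincide with the trunk edge's mutation set
whenever the matrix is conflict-free.

Timing follows the copy-number logic: an SNV is *early* iff its mutation
copy number exceeds 1 (it predates a gain that amplified it); a CNV gain
is timed by the mean mutation copy number of at least five mutations
inside the segment (fewer gives NA); a CNV loss is *early* iff clonal and
coupled with WGD. Note the SNV rule is a hard threshold at 1: on noisy
diploid data roughly half of clonal single-copy mutations fall marginally
above it, so "early" fractions from this rule are only informative where
copy number actually departs from 1 — a property of the rule, not of the
implementation.

## Signatures and drivers

Spectra use the standard 96 trinucleotide classes in the pyrimidine
convention. Exposures are refit by non-negative least squares against a
catalog of signature profiles, renormalized, pruned below 0.06 (the usual
refitting convention) and renormalized again. The packaged catalog is
**synthetic**: a deterministic 30-column stand-in (sparse Dirichlet
profiles with an ageing-like and a tobacco-like column) generated by
`synthetic_signature_catalog()`, because the reference catalog cannot be
redistributed here. All operations are catalog-agnostic — pass any
96 x S matrix with unit column sums to use a real catalog.

Driver analysis uses a compact packaged gene list (also a synthetic
census subset). Occurrence is frequency over cohort size. The dominant
score of gene $g$ is

$$\mathrm{score}(g) = \Big[\sum_{t \ni g}\ \sum_{d \in t,\, d \ne g}
\frac{1}{\mathrm{freq}(d)}\Big] \cdot \frac{1}{\mathrm{freq}(g)},$$

summed over tumors by default (`mode = "per_tumor"` averages instead):
a gene that always occurs alone scores 0, and co-occurrence with rare
drivers counts for more than co-occurrence with ubiquitous ones.

## Survival

Heterogeneity metrics are dichotomized at the cutoff maximizing the
two-group log-rank statistic over observed values between the 20% and 80%
quantiles (maximally selected rank statistic; the resulting p-value is
optimistic and no selection-bias correction is applied, which is
documented rather than fixed). TMB alone uses the upper-quartile split
(type-7 quantiles, pinned so tests are deterministic). The log-rank
statistic is implemented directly — the cutoff scan needs it in a tight
loop — and its agreement with `survival::survdiff` to 1e-8 is enforced in
the test suite; Cox models delegate to `survival::coxph`, with adjusted
models using age, smoking, tumor size and stage.

## The synthetic cohort generator

`sim_config()` defaults describe the emulated study: 40 patients, 3
regions, mean depth 252x, purity 0.3–0.9, 0–4 subclones with target CCFs
0.25–0.8 present in random region subsets, clonal mutation counts 80–500
and 15–120 per subclone (~10% silent), WGD probability 0.4 (doubling is
frequent in SCLC), a four-signature mixture (0.4/0.3/0.2/0.1), and
exponential proportional-hazards survival with log-hazard +2.0 per unit
SNV ITH on OS and −0.25 per mut/Mb/cluster on DFS. Per-patient seeds
derive from the master seed, so any patient regenerates independently.

Design choices the data does not force, decided once:

* **Clone trees** are linear or branching with equal probability; both
  occur in real multi-region cohorts.
* **Subclone separation**: prevalence profiles of distinct subclones are
  kept at L-infinity distance $\ge 0.15$. Two populations with
  near-identical prevalence in every region are indistinguishable *in
  principle*, so generating them would make "true clone count"
  ill-defined rather than the recovery test harder. When a deep lineage
  runs out of CCF budget, the feasible prefix of the clone list is kept.
* **Copy number** is chromosome-scale (clonal arm events plus rare
  region-private ones, full doubling under WGD with occasional post-WGD
  losses). Real segment boundaries are finer; the binning step makes
  downstream behaviour insensitive to this simplification.
* **FFPE artifacts** are available as a rate knob (private low-VAF C>T
  calls), off by default.

What the generator does *not* emulate: indels, germline contamination,
mapping artifacts, subclonal copy number within a region, and kataegis-
like local hypermutation. Recovery results on synthetic cohorts therefore
validate the estimators under the stated noise model, not performance on
any real cohort.

## Numerical choices and problem sizes

EM convergence uses a relative log-likelihood tolerance of 1e-8 (max 200
iterations); BIC counts $kR + (k-1)$ parameters. The WGD permutation
p-value uses the add-one estimator $(1 + \#\{sim \ge obs\})/(n_{sim}+1)$.
Validation suites run the full 40-patient cohort for ITH/cluster
recovery, 100 simulated regions each for WGD operating characteristics
($n_{sim} = 1000$), $10^5$ sampled mutations for signature refitting, and
$n = 500$ for Cox hazard recovery; these sizes give comfortable
Monte-Carlo margins for the properties being checked while keeping the
whole suite fast.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_patients = 5, seed = 1)
cohort <- simulate_cohort(cfg)
ana <- analyze_cohort(cohort, seed = 1)
ana$report[, c("patient_id", "snv_ith", "cnv_ith", "tmb", "n_clusters",
               "wgd", "gii")]
```

The `analysis/` directory holds the same steps as a numbered script
workflow (simulate, filter+rescue, clonality/ITH, CNV/WGD, phylogeny,
signatures/drivers, survival), each writing its tables under `results/`.

## Known limitations

* The clustering stand-in is a point-estimate EM; it reports no
  uncertainty over assignments or cluster counts.
* The WGD permutation null tests association between segment length and
  allele state, not doubling per se; the definitive behaviour comes from
  the degenerate-case rule described above, faithful to the thresholds
  quoted for each ploidy class.
* Best-cutoff survival p-values are anti-conservative by construction.
* With three regions, topologies are few and parsimony is exact; the
  exhaustive search scales to ~6 regions at most.
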