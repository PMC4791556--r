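---
title: "Landrace diversity analysis and mixed-variable core selection with creolecore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landrace diversity analysis and mixed-variable core selection with creolecore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creolecore)
```

## The problem

Gene banks hold collections of crop landraces far too large to phenotype
exhaustively. A *core reference set* is a small subset chosen to represent
the collection's diversity — ideally retaining the rare alleles that natural,
non-elite populations carry at very low frequency, since those alleles are a
prime source of adaptive variation for breeding. `creolecore` implements a
complete workflow for collections genotyped with sparse biallelic SNP panels
(genotyping-by-sequencing style data, with heavy missingness), phenotyped for
a modest number of mixed ordinal/continuous traits, and georeferenced at
their collection sites:

1. diversity description of the collection (allele-frequency spectrum, Nei
   and Shannon indices, G~ST~ and gene flow, pairwise F~ST~, distance-based
   classification);
2. rare-allele characterization per group (counts, per-accession rates,
   unique and geographically fixed alleles);
3. core selection from genotype and phenotype *simultaneously*, and
   evaluation of the chosen core against the complete set.

Because collections of this kind are rarely deposited, the package ships a
calibrated population simulator so that every stage is testable end to end.

## Data model

Genotypes are stored as alternate-allele dosage (0/1/2) with `NA` a distinct
missing state — dosage is the minimal faithful encoding of biallelic SNPs in
largely inbred material, and missingness is never conflated with the
reference genotype. Marker filtering retains markers with missing fraction
*strictly below* the threshold (default 50%). Phenotypes carry a declared
kind per trait — ordinal traits are level-coded integers validated against a
finite level set, continuous traits plain numerics — and metadata carry
region, latitude, longitude and altitude per accession.

## Diversity statistics

Per-marker allele frequency is the dosage sum over twice the called
genotypes. With `p` the alternate-allele frequency and `q = 1 - p`:

* **Nei's index** is biallelic gene diversity `1 - (p^2 + q^2)`, averaged
  over markers with at least one call. The published formula names only the
  major allele; `1 - P_major^2` alone is not a diversity index, so the
  standard two-allele form is used (and documented here as a deliberate
  reading).
* **Shannon's index** is `-(p log p + q log q)` with `0 log 0 = 0`.
* **G~ST~** is `(H_T - H_S)/H_T` where `H_S` is the size-weighted mean
  within-group gene diversity and `H_T` the diversity at pooled frequencies,
  both averaged over markers; gene flow is `N_m = (1 - G_ST)/(4 G_ST)`,
  reported as infinite when `G_ST = 0`.
* **Pairwise F~ST~** defaults to the Weir–Cockerham variance-components
  estimator (ratio of summed per-locus components, so loci are weighted by
  information); a Nei G~ST~-based variant is available. Slightly negative
  estimates for undifferentiated pairs are clamped to 0 in the reported
  matrix with raw values kept as an attribute.

Classification uses the simple-matching distance `d = 1 - M/N` (`M` matching
genotype calls, `N` non-missing pairs; heterozygotes match only
heterozygotes, the plain reading of "simple matching" at the call level)
with complete-linkage agglomeration. The squared-Euclidean transform
`2 N d` is exposed as an explicit view, never applied silently. For
statistics on a thinned panel, `select_spaced_markers()` reproduces the
four-step per-chromosome procedure: largest-remainder quotas proportional to
each chromosome's marker share, a grid of quota points starting at the first
marker with step span/quota, and the nearest unused marker to each grid
point (ties to the lower position). The grid convention — quota points from
the first marker, end point excluded — is one of several readings of the
published steps and is the package's fixed choice.

## Rare-allele characterization

An allele is **rare** when its frequency in the reference population lies
strictly in (0, 0.05): frequency 0 is a *lost* allele and the bound itself
is excluded. Reports per group support two reference conventions: each group
as its own population (the convention behind per-group tables) or the
complete set. A rare allele is **unique** to a group when it is rare there
and carried by no accession outside the group; the carried-nowhere-else
clause is what makes the count invariant to group sizes (duplicating a
group's accessions changes nothing). The published definition is only
qualitative; this operationalization is the package's.

The `raf` column reports the mean frequency of the group's rare alleles
under the chosen reference convention. Published per-group tables show
`raf ~ 0.14` for every group, which cannot be the mean of frequencies below
0.05; the exact published definition is unrecoverable, so the package
documents its own and makes no attempt to match that column.

**Fixed alleles**: within a geographic cluster (k-means on standardized
latitude/longitude/altitude), a marker is fixed when its within-cluster call
rate is at least 60%, it does not segregate in the cluster (MAF = 0 by
default; a MAF < 0.05 variant is available), and it segregates in the
complete set. The 60% figure reads the ambiguous published "60% data points"
phrase as a call-rate gate — the only reading under which a per-marker data
fraction is meaningful; both the gate and the fixation rule are arguments.

## Core selection

The selection engine chains five stages, all reproducible from one seed:

1. **PCA reduction** of the marker matrix (per-marker mean imputation of
   missing calls — the field default, preserving column means — then a
   centered decomposition via the accession-side Gram matrix). Components
   are sign-fixed so the largest-magnitude score is positive.
2. **Two-block factor analysis.** The genotype-score block and the
   standardized phenotype block (ordinal traits as level codes, z-scored)
   are each divided by the square root of their first eigenvalue — the
   multiple-factor-analysis normalization that stops either block dominating
   a priori — and the phenotype block is rescaled by a scalar weight found
   by bisection so that cumulative genotype:phenotype contributions to the
   first six axes hit a target ratio (default 75:25) within tolerance. A
   block's contribution to an axis is the summed squared loading of its
   columns; cumulative contributions weight axes by eigenvalue.
   Contributions respond monotonically to the weight, which is what makes
   bisection valid; the search refuses targets outside the achievable range.
3. **Ward-MLM grouping.** Ward agglomeration on the axes initializes EM for
   a Gaussian mixture with shared full covariance (per-group diagonal
   optional); a near-singular covariance is ridge-regularized with a
   warning. The number of groups is chosen by BIC by default — raw
   log-likelihood is non-decreasing in the number of groups, so "maximum
   likelihood" selection is reproduced instead by a plateau rule (smallest
   G whose relative gain falls below 1%) under `criterion = "loglik"`.
4. **D-method allocation.** Group quotas are proportional to group
   diversity, the mean within-group pairwise distance (singletons
   contribute 0 and fall under a minimum-quota rule), rounded by largest
   remainder to conserve the core size exactly, clamped at group size with
   redistribution.
5. **Stratified Gower-max sampling.** Many candidate cores (default 1000)
   each draw every group's quota uniformly without replacement; the
   candidate with the maximum mean pairwise distance wins, ties to the
   lowest index.

The selection-stage distance is a Gower-type range-normalized distance *on
the factor axes*, each axis weighted by its eigenvalue
(`axis_gower_distance()`): computing a raw mixed-variable Gower distance
over tens of thousands of markers for a thousand candidate sets is
intractable, and the published account does not state which representation
fed the distance. The full mixed-variable `gower_distance()` (exact-match
similarity for markers, range-normalized for traits, missing-aware weighted
mean) is retained for small problems and for evaluation.

`simulate_core_size()` produces the Monte-Carlo genetic-variance curve:
for each sampling level (5–100%, step 5) it draws subsamples without
replacement and summarizes the across-replicate variance of per-marker
allele frequencies — `f_ST = var(p)/(p̄ q̄)` per marker and the genetic
variance `s²` as the across-marker mean of the chosen statistic. Under the
printed equations `var(p)` decreases monotonically with the sampling
fraction (hypergeometric sampling theory), so the curve peaks at the
smallest level; the alternative statistics (`"fst"`, `"het_var"`) are
exposed, but the package does not claim to reproduce a mid-range optimum,
and the default core fraction (14.18%) is taken as the published choice
rather than derived from this curve.

## The simulator

`simulate_population()` draws group allele frequencies from a
Balding–Nichols model: for ancestral frequency `p` and drift parameter `F`,
group frequencies are `Beta(p(1-F)/F, (1-p)(1-F)/F)`, giving expected
differentiation `F` — chosen because landrace groups are
drift-differentiated subpopulations, and any model reproducing a target
F~ST~ would serve. Defaults encode the regime the package was built around:
15 groups with the published size profile, per-group `F` evenly spaced on
[0.04, 0.28] (bracketing the published pairwise range), ~40% of ancestral
frequencies seeded at the rare edge, per-marker missingness uniform on
[0, 0.5], heterozygosity capped at 30.5% via an inbreeding coefficient
`1 - 2 het_max` (documenting that such lines are largely inbred), 23 traits
with the published means and variances (30% of each trait's variance
between groups — a regime where groups differ but overlap), and collection
sites jittered around region-typical centers. Ordinal traits are
discretized latent normals, which slightly shrinks their variance relative
to specification; the published ordinal level counts are not stated, so
3–5 levels were chosen from the trait ranges.

`inject_rare_alleles()` plants group-private ground truth: heterozygous
carriers are a random 2–9% of the designated group's members, capped so the
allele frequency stays below 0.05 both in the whole population and within
the group's called members. The within-group cap matters: per-group
rare-allele tables treat each group as its own reference population, so a
planted allele must be rare *there* to register. High published
per-accession rare-allele counts in small distinct groups are exactly this
pattern — alleles carried by a few members of one group and nobody else.

What the simulator does **not** emulate: linkage disequilibrium (markers are
independent), coalescent ancestry, selection, genotyping error, and the
real correlation structure among traits. Passing tests therefore show the
machinery is correct under drift-structured, LD-free data of the configured
regime — not that any particular real collection would yield the same
numbers.

## Numerical choices and problem sizes

Ties are broken toward the lowest index everywhere (grid nearest-marker,
allocation remainders, candidate argmax). All randomness in a pipeline run
flows from one integer seed. Degenerate cases are defined rather than left
to chance: zero-call markers are flagged and excluded from averages;
a pair of accessions with no shared called marker has a flagged-missing
distance (clustering refuses such matrices); `G_ST = 0` reports infinite
gene flow; an empty rare-allele set makes core recovery vacuously 100%;
and a zero-variance phenotype block is rejected by the factor analysis with
the achievable contribution range in the message.

The test suite exercises the full pipeline at 2,000 accessions x 5,000
markers with 10 groups (20 replicate seeds) for the core-versus-random
comparison, 500 x 2,000 and 200 x 1,000 for estimator calibration, and
small analytic fixtures elsewhere; the acceptance script uses a 1,200 x
6,000 collection with all 15 default groups. These sizes were chosen so the
whole suite runs on a laptop-class single core in minutes while keeping
every estimator in its well-behaved regime.

## Known limitations

* The factor analysis is strictly two-block; deeper block hierarchies are
  out of scope.
* The mixture stage uses hard Ward initialization only — no random-restart
  EM — trading global-optimum guarantees for determinism.
* Gower distances at collection scale are computed on factor axes, not raw
  markers (see above).
* The core-size curve cannot identify an interior optimum under its default
  statistic, by construction.
* Genome mapping of fixed-allele markers is out of scope; the scan emits
  marker IDs and positions for external tools.
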