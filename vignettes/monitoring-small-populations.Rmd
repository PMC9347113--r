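---
title: "Monitoring genetic diversity in small managed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring genetic diversity in small managed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockdiv)
```

flockdiv models the situation of a conservation or breeding program for a
small closed population: a nucleus flock founded from `Nm` sires and `Nf`
dams, bred in discrete generations under a hierarchical mating plan (one
sire per three to four hens), with pedigrees recorded and, at some point, a
medium-density SNP panel genotyped. This vignette explains the models behind
each statistic, the tunable parameters and their defaults, what the
simulator does and does not emulate, and the numerical conventions that make
results reproducible.

## Demographic model

**Founder effective size.** The classical sex-ratio formula
`Ne = 4 Nm Nf / (Nm + Nf)` summarizes the drift rate implied by the founder
group alone, assuming random union of gametes and Poisson-like variance in
family sizes. It is symmetric in the sexes and attains the census `Nm + Nf`
only at an even sex ratio; with one sire per several hens the male side
dominates (`Ne -> 4 Nm` as `Nf` grows), which is why sire numbers are the
binding constraint in hierarchical programs.

**Pedigree inbreeding.** `pedigree_inbreeding()` computes each individual's
F as the kinship of its parents by the exact tabular (recursive) method: the
kinship matrix is filled in topological order with
`K[i,i] = (1 + F_i) / 2` and `K[i,j] = (K[sire_i, j] + K[dam_i, j]) / 2`,
unknown parents contributing zero. The method is exact for arbitrary
pedigrees; the test suite checks it against an independent Wright
path-counting oracle. Founders and individuals with any unknown parent get
F = 0 — the program's convention that coancestry is zero at the pedigree
base. Unsorted pedigrees are resorted internally rather than miscomputed,
and cycles are reported with the offending chain of identifiers.

**Realized effective size.** `realized_effective_size()` uses individual
increases in inbreeding: for an individual with equivalent complete
generations `EqG > 1`, `dF = 1 - (1 - F)^(1 / (EqG - 1))`, and
`Ne = 1 / (2 mean(dF))` over a reference cohort. Individuals with
`EqG <= 1` fall outside the method's domain (the exponent is undefined) and
are excluded; a cohort with no eligible individuals or a non-positive mean
increase yields an `NA` flag rather than an error. The default cohort is the
latest birth cohort (maximum birth year when recorded, else the deepest
generation), because a monitoring report describes the current generation;
`cohort = "all"` or an explicit id vector are available since the published
single-number summaries of other programs do not state their cohort
convention.

**Inbreeding rate.** `ΔF = 1 - (1 - F̄)^(1/n)` inverts the compound-interest
accumulation of inbreeding over `n` generations from a base of zero. All
internal values are fractions; only the reporting layer multiplies by 100.

## SNP panel conventions

Genotypes are stored as 0/1/2 counts of allele 2, which `read_ped_map()`
fixes once, panel-wide, to the minor allele (ties at frequency 0.5 broken by
taking the alphabetically first symbol). Orientation is therefore global:
a per-population frequency of allele 2 may exceed 0.5, and per-population
MAF is reported as `min(p, 1 - p)` locally. Half-missing genotypes (one
missing allele) are treated as fully missing, the PLINK text convention.
Chromosome labels are opaque strings; sex chromosomes are removed by listing
their labels in `exclude_chrom`. Positions are 1-based and intervals closed.

**QC order.** `filter_panel()` applies individual missingness, then marker
missingness, then MAF — in that fixed, logged order, because the thresholds
interact (marker MAF is computed on retained individuals). The MAF filter is
strictly `>` at the boundary; the missingness thresholds default to 0.05,
i.e. call rates of at least 95% for both markers and individuals.

**LD pruning.** `prune_ld()` slides a 30-SNP window by 10 SNPs per
chromosome; within a window, while any pair of retained markers exceeds
r² = 0.8 (squared Pearson correlation of dosages over pairwise-complete
calls — composite LD, needing no phase), one member is removed. The removal
rule must be deterministic for reproducibility: the marker with the lower
panel-wide MAF loses, ties going to the later position. A marker pair with
zero variance on either side has undefined r² and is never pruned against.

## Diversity indices

`Fit` and `Fis` are the same method-of-moments coefficient
`F = (#Hom_obs − #Hom_exp) / (#loci − #Hom_exp)` evaluated against two
reference frequency sets: the whole panel (all populations pooled) for Fit,
the individual's own population for Fis. `#Hom_exp` sums
`1 − 2p(1−p)·N/(N−1)` over usable loci, where `N` is the number of allele
observations behind the frequency; the `N/(N−1)` correction (default on,
toggleable) removes the downward bias of plugging sample frequencies into
the expectation. Loci that are missing in the individual, have no frequency,
or are monomorphic in the reference scope are excluded. Under this
convention Fis ≈ 0 signals random mating within the population, Fis > 0 an
internal structure (Wahlund effect) or non-random mating, and Fit the total
deviation from panel-wide expectations.

**A calibration worth knowing.** Pooling `k` equally sized, equally
diverged demes produces a Wahlund heterozygote deficit of
`Fis = (k−1)/k × θ`, not θ itself, because the Weir–Cockerham estimator
scales the among-deme variance by `k/(k−1)`. With two pooled flocks the
pooled Fis is therefore about *half* the pairwise Fst; the factor approaches
1 only as many demes are pooled. The test suite asserts the exact
`(k−1)/k` relation at k = 2 and the near-equality at k = 8. Small-population
corrections (heterozygote excess of order `1/(2N)` within each deme, and
the one-generation lag between parental gamete frequencies and the current
sample) subtract a few hundredths more; they are negligible once flock
census reaches ~100.

**Fst.** `wc_fst()` implements the Weir–Cockerham (1984) variance
components for biallelic markers with unequal sample sizes. The global value
is the ratio of summed components `Σa / Σ(a+b+c)` — the weighted estimator —
not the mean of per-SNP ratios, which would be biased by low-information
markers; per-SNP components are returned for inspection and negative values
are kept in the sums. Markers monomorphic across the compared populations,
or observed in fewer than two of them, carry no information and are
excluded. Nei's D uses the standard 1972 form with identities averaged over
loci before the log; completely non-overlapping allele sets yield `Inf`.

## Runs of homozygosity

`detect_roh()` reproduces the classical two-phase scan. Phase 1 slides a
50-SNP window one marker at a time; a window *qualifies* if it has at most
one heterozygous and one missing call; each SNP's hit fraction is the share
of qualifying windows among those covering it, and SNPs at or above the 0.05
threshold (compared with `>=`) are eligible. Phase 2 takes maximal runs of
eligible SNPs, splits them at inter-marker gaps above 1 Mb, trims them to
start and end at homozygous calls, and keeps those at least 500 kb long,
with at least 30 SNPs, at a density of one SNP per 50 kb or better (checked
as `n_snps × 50000 ≥ length` in integer arithmetic). Chromosomes shorter
than the window use a single truncated window with the same absolute
allowances. Segment boundaries are the positions of the first and last
homozygous marker, not midpoints to flanking markers — a convention that
matters at low density and is therefore stated here. The window hit
threshold and the gap limit are scanner defaults rather than
panel-specific choices, and both are exposed in `roh_params()` and echoed in
report headers.

`F_ROH` divides summed segment length by the SNP-covered span (per
chromosome, last minus first position + 1). An exhaustive-enumeration oracle
re-derives segments by brute force in the tests, and the scanner must match
it exactly on randomized tracks; a monotonicity property (lowering the
minimum length never removes a segment) guards the filter logic.

The panel density matters: the default ROH parameters suit a ~50K chip
(≈ one marker per 50 kb). The simulator's default genome (10 chromosomes ×
10 Mb × 200 SNPs) reproduces exactly that spacing; a sparser simulated panel
would silently fail the density filter, which is the first thing to check
when a simulation yields no segments.

## Structure

`ibs_distance()` is `mean(|g_i − g_j| / 2)` over mutually called markers —
one minus the average shared-allele fraction. `neighbor_joining()`
re-implements Saitou–Nei agglomeration rather than delegating it, so that
two behaviors are pinned down: tied minimal-Q pairs are resolved toward the
lexicographically smallest label pair, and a negative branch estimate is
clamped to zero with the deficit moved to its sister branch, preserving the
path lengths the algorithm intended. On additive (tree-derived) matrices the
output reproduces the generating metric to 1e-9; trees are ape `phylo`
objects and serialize via `write_newick()`.

`dapc()` chains per-SNP mean imputation (after centering), PCA, K-means on
the retained axes (default: the smallest axis count explaining 80% of
variance; 20 restarts under a fixed seed), then linear discriminant analysis
of the clusters with posterior memberships from the discriminant-space
Gaussian model. K = 2 is the default, matching the common question "which of
two ancestral clusters does each breed align with"; component counts are
exposed because no universal rule fits panels from tens to thousands of
individuals.

`mantel_test()` correlates upper triangles after elementwise transforms —
defaulting to `1/(1−Fst)` against log great-circle km, the
isolation-by-distance convention — and permutes the second matrix's labels,
reporting the one-sided `p = (1 + #{r* ≥ r}) / (1 + n_perm)`. An exact mode
enumerates all label permutations for small matrices. The type-I error is
calibrated in the tests. `partial_correlation()` computes the
inverse-correlation-matrix coefficient in its numerically robust residual
form (regress both variables on the covariates, correlate residuals —
algebraically identical), with a two-sided t test on `n − 2 − k` degrees of
freedom; sidedness is stated because published reports often omit it.

For the packaged management table, `management_partial_correlations()`
corrects each feature pair for the remaining management features, except
that pairs involving the founder Ne are corrected for generation count only
(founder Ne being a function of the founder counts, correcting for them
would remove the signal). Complete-case rows are used; with 18 rows and
several missing entries the magnitudes are fragile, which is why the tests
assert only the signs of the two headline correlations (positive realized
Ne × generations, negative founder Ne × inbreeding rate).

## The simulator: what it emulates, what it does not

`build_pedigree()` + `simulate_founders()` + `gene_drop()` generate a closed
nucleus: founders carry haplotypes drawn independently per marker from a
configurable frequency distribution (default uniform on [0.05, 0.5],
mimicking an ascertained chip spectrum truncated at rare alleles), and each
meiosis places a Poisson number of crossovers (mean = map length in Morgans,
Haldane model, no interference) uniformly on the genetic map, starting
strand by fair coin. Offspring sex is a fair coin, with deterministic
repairs — under family conservation the first offspring of each sire family
is made male, and any shortfall in required sires or dams is filled by birth
order — so that the design stays feasible; the final generation is exempt.

Founders are in linkage equilibrium: all LD and all ROH in descendants are
created by the pedigree, which is precisely what makes the simulator a clean
truth source for ROH and inbreeding tests. Consequently it does *not*
emulate ancestral LD, chip ascertainment toward high-MAF markers, mutation,
selection, genotyping error, or a realistic karyotype; a real 50K dataset
has background ROH from old haplotype sharing that the simulator will not
produce. Passing tests therefore validate the statistical machinery, not
claims about any particular real breed.

Two design facts discovered during calibration are worth recording. First,
the sex-ratio formula assumes Poisson-like variance in the number of
offspring a breeder contributes to the next generation's breeders; a
strictly equalized scheme (exactly 3 dams per sire, exactly 4 offspring per
dam, breeders drawn from a pool not much larger than the breeding team)
has hypergeometrically *reduced* family-size variance and a realized Ne some
10–15% above `4NmNf/(Nm+Nf)`. The drift-calibration test therefore breeds a
generous offspring pool (10 per dam) so the idealized formula's assumptions
hold; the residual few-percent deviation sits well inside the 3-SE band at
30 replicates. Second, the per-individual correlation between F-ROH and
pedigree F is limited by Mendelian sampling noise around the pedigree
expectation; within a single cohort of one flock the between-individual
variance in pedigree F can be too small for a stable correlation. The
validation therefore samples 200 individuals across lines bred at different
intensities (a full-sib line and hierarchical flocks with 3–24 sires),
mirroring the across-breed spread of inbreeding that makes the comparison
meaningful in real surveys, and uses a 2 cM/Mb map so that each chromosome
carries more independent segments.

## Problem sizes and numerical choices

The test suite and validation run at desk scale by design: panels of
0.5–2 thousand markers over 3–10 chromosomes, populations of 20–200
individuals, pedigrees up to a few thousand records, 30-replicate
calibrations — the full suite completes in well under two minutes on one
core, and each property was sized to keep its Monte-Carlo error far from
its acceptance margin. Kinship uses a dense matrix (fine to a few thousand
individuals; quadratic memory beyond that). Determinism: every stochastic
function takes a `seed`; the pipeline derives per-stage substreams from one
top-level seed; K-means uses a fixed seed with multiple restarts. Ties are
broken by documented rules everywhere a choice exists (minor-allele
orientation, LD victim selection, NJ pair choice). Degenerate inputs return
flags (`NA`, `Inf`) where the quantity is undefined by the method's own
domain, and errors only where a contract is violated.

## Known limitations

- The exact set of markers behind a published Fst or diversity table depends
  on that study's pruning; both pruned and unpruned panels are supported,
  with pruning the default in `run_pipeline()`.
- `mom_inbreeding()`'s denominator is the expected heterozygote count; in
  tiny reference samples the estimate is noisy and can fall below −1 for an
  individual, though population means behave well.
- Realized-Ne cohort choice is a genuine degree of freedom; two programs can
  report different single numbers from the same pedigree.
- The NJ implementation is quadratic per join (cubic overall) — ample for
  population trees and a few hundred individuals, not for thousands of tips.
- `simulate_admixture()` draws parental gametes allele-wise (no linkage
  within the cross), which suffices for tree-position and heterozygosity
  properties but not for studying LD in hybrids.
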