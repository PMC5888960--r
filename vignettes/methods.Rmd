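---
title: "Models and methods behind namQxE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind namQxE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(namQxE)
```

`namQxE` is an analysis pipeline for QTL-by-environment (Q×E) genome
scans in nested association mapping (NAM) panels: many biparental
families sharing one elite recurrent parent, phenotyped under contrasting
environments (well-watered, WW, versus water-limited, WL). This vignette
is the package's own account of the models it fits, the defaults it
ships, the numerical choices it makes, and what its simulations do and do
not establish.

## The population simulator

`simulateFamily()` breeds lines gamete by gamete through an explicit
crossing scheme — by default BC1S3: an F1 between the recurrent parent
and a wild donor, one backcross to the recurrent parent, three selfings.
Recombination between adjacent map positions uses the Haldane map
function, $r = \tfrac12(1 - e^{-2d/100})$ for $d$ cM, with no crossover
interference; markers on different chromosomes assort independently. The
Haldane choice is the simplest self-consistent one and matters little at
the marker densities used here.

The single-locus genotype distribution implied by a scheme is computed
exactly by `expectedGenotypeFreqs()` as a three-state Markov chain over
{Hv/Hv, Hv/Hs, Hs/Hs}: a backcross maps the heterozygote to
$(\tfrac12,\tfrac12,0)$ and the donor homozygote to the heterozygote; a
selfing maps the heterozygote to $(\tfrac14,\tfrac12,\tfrac14)$. For
BC1S3 this gives $(0.71875,\,0.0625,\,0.21875)$ — heterozygosity
$\tfrac12(\tfrac12)^3$ — and the gamete-level simulator is required, in
tests and in the acceptance script, to reproduce it within binomial
error.

`simulatePopulation()` assembles 25 families of 57 lines by default (the
size and structure of the barley panel the pipeline emulates, 1420 lines
over 25 crosses). Each donor carries the wild allele at a random 75% of
markers (about the fraction of chip SNPs that were informative in that
panel); at the rest its family is monomorphic, giving the family-private
allele structure typical of NAM designs and giving the marker filters
something to do. Missing genotype calls are injected completely at
random at 2%, so the sub-10%-missing filter is exercised without being
binding. One master seed drives everything; per-family, per-trait and
per-replicate streams are derived from it deterministically, so output
is byte-identical across runs at a fixed seed.

`simulatePhenotypes()` generates, per trait,

$$y = \mu + F_i + \textstyle\sum_l a_l d_l + \mathbf{1}[\mathrm{WL}]\,(E + \sum_l q_l d_l) + g + \varepsilon$$

with allele dose $d_l \in \{0, \tfrac12, 1\}$ (heterozygotes of dominant
loci get the full effect), a line-level polygenic draw $g$ with
covariance proportional to a supplied kinship matrix, and i.i.d. Gaussian
residuals with per-environment SDs. The polygenic scale is set from the
heritability as $\sigma_g^2 = \frac{h^2}{1-h^2}\,\sigma_{e,\mathrm{WW}}^2$
with the kinship normalized to unit mean diagonal, so $h^2$ is the
genetic fraction of the WW phenotypic variance. The family, locus and
polygenic components are constant across environments and years;
residuals are drawn per record. An optional multiplicative per-year scale
(default 1) emulates between-season level shifts and is exactly what the
cross-year adjustment is designed to remove.

What the simulator does *not* emulate: genotyping error, selection during
line development, multi-allelic markers, spatial field trends,
non-Gaussian residuals, and environment-specific polygenic effects.
Passing tests therefore certify the pipeline's statistics under its own
model assumptions, not robustness to every feature of real field data.

## Genotype handling and kinship

`filterMarkers()` applies the informative-marker rules in a fixed order:
drop markers monomorphic within every family; drop markers with a
missing fraction of 10% or more (the kept set has strictly less than 10%
missing); deduplicate markers in complete linkage disequilibrium,
keeping the first in map order. Two markers count as complete-LD
duplicates only when identical at every jointly observed line *and*
jointly observed in at least half the lines — without the coverage
floor, two markers missing in complementary halves of the panel could be
merged on no evidence. Deduplication is global (not per family) and is
implemented with blocked cross-products, $O(m^2)$ in markers, which is
comfortable at the few-thousand-marker scales used here.

`computeKinship()` defaults to the allele-sharing proportion
$K_{ab} = \mathrm{mean}_m\!\left(1 - |g_{am} - g_{bm}|/2\right)$, which
is exact on hand examples (identical lines share 1, opposite homozygotes
0), scale-free, and has unit diagonal. A VanRaden-style centred
cross-product estimator is available as an option. Missing codes are
mean-imputed inside the kinship computation only; association tests drop
lines missing at the tested marker instead.

## The mixed-model engine

`fitNullREML()` estimates $\sigma_g^2$ and $\sigma_e^2$ in
$V = \sigma_g^2 K + \sigma_e^2 I$ by profiling the restricted likelihood
over $\lambda = \sigma_g^2/\sigma_e^2$ on the spectrum of $K$: one
symmetric eigendecomposition, then one-dimensional maximization of the
profiled REML objective over $\log\lambda \in [\log 10^{-5}, \log 10^5]$
(golden-section/parabolic search, tolerance $10^{-8}$, with the interval
endpoints also evaluated so boundary optima — no polygenic variance, or
all variance genetic — are admissible). Tests hold the optimum to within
$10^{-6}$ of a 10,000-point dense-matrix grid oracle. Eigenvalues are
clamped at zero; a kinship matrix with an eigenvalue below $-10^{-8}$
(relative) is rejected.

Marker tests are generalized least squares under the fitted covariance.
The marker enters as a 3-level genotype class with the recurrent-parent
homozygote as reference — effects are read directly as "wild allele
versus elite allele" — and the reported p-value is the joint F-test of
the marker contrasts (2 df when all classes are present; the df adapt
when a class is absent, and a marker monomorphic in the tested subset
gets a missing p). Additive dose coding is available as an option.

Variance components are estimated once on the no-marker null model and
reused across markers (P3D/EMMAX-style), which turns each marker test
into a weighted regression in the rotated basis. The approximation is
tight for markers that do not themselves carry genetic signal; at a
marker that absorbs polygenic variance — the causal QTL above all — the
exact refit lowers $\hat\lambda$ and strengthens the test, so P3D errs on
the conservative side there. The tests assert exactly this two-sided
characterization (90th percentile of $-\log_{10}p$ differences below 0.2
on a null architecture; conservative direction at a planted QTL), and
`exact = TRUE` provides the per-marker refit when the extra cost is
acceptable.

With $K = I$ the engine collapses to ordinary least squares, and the
marker test reproduces the plain linear-model F-test to $10^{-8}$ — the
analytic limit used as a cross-check.

## The Q×E scan and the acceptance rule

`scanQxE()` stacks each line's WW and WL records and adds environment
and genotype-by-environment terms to the fixed effects. The two records
of a line share a single polygenic effect: the stacked covariance is
$\sigma_g^2 (K \otimes J_2) + \sigma_e^2 I$, where $J_2$ is the all-ones
2×2 block. The Kronecker structure keeps the eigendecomposition at the
line level ($K \otimes J_2$ has eigenvalues $2d_i$ and 0), so the
stacked fit costs little more than the per-environment one. Residuals
are independent across a line's two records and homoskedastic; the
headline p-value is the joint 2-df F-test of the interaction contrasts,
and environment-specific wild-allele effects are reported for both
environments. Lines observed in only one environment are dropped (at
least 80% of phenotyped lines must have both records; a
single-environment table is redirected to `scanPerSe()`).

`crossval()` implements the resampling acceptance rule: per replicate,
draw $\lceil 0.70\, n_f \rceil$ lines within each family without
replacement (ceiling rounding never empties a small family), rerun the
scan — re-estimating variance components, since the subsample changes
the design, with P3D applied within the replicate — and record whether
each marker's p falls below 0.05. A marker is accepted as a putative QTL
when detected in at least 30% of replicates. The default is 200
replicates; the package's own acceptance runs use 100, which leaves the
detection-rate SE below 0.05 at the rates that matter while keeping the
run inside a desk-scale compute budget. `windowPeaks()` then tiles each
chromosome into half-open 5-cM windows anchored at 0 cM and reports the
smallest-p marker per window (ties broken by lower position, then marker
id — a deterministic, order-independent convention).

`reactionNorms()` gives family-adjusted least-squares means of the three
genotype classes in each environment (via `emmeans` on the fixed-effects
model), the standard display for a conditional QTL: parallel norms mean
no interaction, converging norms a buffering wild allele.

## Calibration scenarios

The null-calibration checks (empirical size of both tests at
$\alpha = 0.05$ within the exact binomial 99% band, Kolmogorov–Smirnov
uniformity of p-values) run on 2,000 *unlinked* null markers — one per
chromosome — in 500 lines from 25 families, with equal WW/WL residual
SDs, family effects and 40% polygenic heritability present. Unlinked
markers are essential: the binomial band and the KS test presume
independent tests, and packing 2,000 markers onto 7 chromosomes makes
neighbouring p-values strongly dependent, which invalidates both checks
without saying anything about the engine. Equal residual SDs match the
fitted models' homoskedasticity assumption; the generator's *defaults*
keep the WL-inflated variance seen in the field data (coefficients of
variation of roughly 28 versus 17 under WL versus WW), and the
descriptive summaries reproduce that contrast.

The discrimination scenario plants a WL-only effect of one residual SD
in a 1,000-line panel and requires the cross-validation rule to accept
the causal marker under the interaction model while the per-se WW scan
rejects it — the qualitative signature of a conditional drought QTL that
a single-environment scan cannot see.

## Trait preparation

`deriveTraits()` adds GFP = MAT − HEA, HI = PGY/TDM (missing, with a
warning, when TDM = 0) and VDW = TDM − PGY. `adjustAcrossYears()`
multiplies every value of a trait-year cell by (all-years mean)/(year
mean), equalizing per-year trait means exactly; it is idempotent, and
with equal year sample sizes it preserves the grand mean. Year means
pool both environments and all lines by default (environment-stratified
factors are a switch), since the adjustment targets season-level scale
shifts. The pipeline order is fixed as derive → adjust → average years:
for difference traits the first two steps commute whenever a season
shifts all traits by one common factor (the situation the adjustment
models), but for the ratio HI they do not, and computing ratios on raw
within-year values is the biologically meaningful choice.
`lineMeans()` then averages adjusted values over years to the per-line
responses used by the scans.

## Senescence scoring

`classifyPixels()` converts 8-bit RGB to YCbCr (ITU-R BT.601 full
range), forces pixels matching the white-background rule (Y ≥ 220,
|Cb−128| ≤ 12, |Cr−128| ≤ 12) to background, and assigns every other
pixel to the class — green or yellow/brown — of its nearest reference
shade in the (Cb, Cr) chroma plane, if within the tolerance (default 20
chroma units); otherwise background. Distances deliberately ignore luma,
which makes the classification robust to brightness differences between
photos; a 3-D distance is left as a possible extension. The reference
shades shipped in `shadePalette()` span typical leaf greens and
senescent yellows/browns; shades, tolerance and the white rule are all
configuration, because such values are camera- and scene-specific and no
published reference values exist for this procedure. `canopyScore()`
reports the yellow/brown percentage of the *leaf* area (background
excluded from the denominator), and `senescenceChange()` the
percent-point increase between two photo dates.

`generateCanopyImage()` builds ground-truth fixtures: a centred leaf
blob on white, outer ring painted senescent, exact pixel counts by
construction, optional Gaussian chroma noise. Noiseless fixtures must be
recovered at 100% pixel accuracy; at noise SD of a third of the
tolerance, accuracy stays above 99% — the single-shade Rayleigh
exceedance at that SD is about 1%, but within-class shade spacing in the
shipped palette catches most near-misses (verified by simulation).
Images are read and written as PNG.

## Pot-experiment statistics

`groupAlleles()` pools heterozygous and homozygous wild carriers
(`Hs/_`) against the cultivated class, the grouping used when validating
a locus in segregating material. `factorialAnova()` fits the two-way
fixed-effects model (drought treatment × allelic state) with Type-II
sums of squares, which are the appropriate main-effect tests under the
unbalanced carrier counts such experiments produce; an empty cell drops
the interaction with a warning, and an all-equal response returns a
zero-SS table rather than an error. `meanLetters()` produces compact
letter displays from either pairwise Student's t-tests (pooled variance
per pair, as used in figure annotations) or Tukey–Kramer comparisons,
via the insert-and-absorb construction; tests verify the letters against
brute-force enumeration of the pairwise tests. `percentReduction()`
reports $100\,(\bar x_{\mathrm{ref}} - \bar x_{\mathrm{stress}})/\bar
x_{\mathrm{ref}}$ to one decimal (round-half-even).

## Problem sizes and limitations

The shipped tests and the acceptance script run at desk scale: 500–1,000
lines, 120–2,000 markers, 100 cross-validation replicates — sizes chosen
so the full suite completes in minutes while leaving every statistical
check adequately powered (detection-rate SE < 0.05, binomial band width
about ±1.3 percentage points at 2,000 markers). The engine itself
handles the full panel scale (1,420 lines, 5,709 markers); the
$O(n^3)$ eigendecompositions and $O(m^2)$ LD deduplication are the
practical ceilings.

Known limitations: variance components are assumed shared across
environments in the Q×E model (no heteroskedastic extension); the
interaction test treats heterozygotes as their own class, which costs
power when they are rare; pedigree-based kinship is not derived from the
crossing scheme (marker-based kinship is used throughout); and the
senescence scorer performs no morphological cleanup or leaf segmentation
beyond the chroma rule.
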