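# namQxE

Mixed-model genome scans for QTL-by-environment interactions in
multi-parent nested association mapping (NAM) populations.

## The problem

NAM panels cross one elite recurrent parent to many wild donors (25
families of BC1S3 lines in the barley panel this package emulates) and map
trait variation jointly across families. When the same panel is phenotyped
under contrasting environments — here well-watered (WW) versus
water-limited (WL) field conditions — the interesting loci are often not
the ones that move a trait *per se*, but the ones whose effect depends on
the environment (Q×E): wild alleles that buffer grain number or yield
against drought. `namQxE` implements that analysis end to end for
researchers in quantitative genetics and crop stress physiology, with a
population simulator so every stage runs and is testable without any
external data.

## The models

Per-environment scan (trait per se), for line *j* in family *i*:

    y_ij = mu + F_i + G_j + u + e,     u ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I)

with family `F` as fixed dummies, the marker `G` as a 3-level genotype
class (Hv/Hv reference, Hv/Hs, Hs/Hs — a joint 2-df F-test), and a
polygenic random effect with covariance proportional to the kinship matrix
`K` (allele-sharing proportion by default). Variance components are
estimated once per trait/environment by REML on the spectrum of K (EMMA
profiling) and reused across markers (P3D, as TASSEL's MLM does); an exact
per-marker refit is available behind a flag.

Q×E scan: each line's WW and WL records are stacked,

    y_ijk = mu + F_i + G_j + E_k + (G x E)_jk + u + e

with one shared polygenic effect per line across its two records
(covariance `K ⊗ J2`) and the joint 2-df test of the interaction contrasts
as the headline p-value.

QTL acceptance follows the resampling rule: the scan is cross-validated
200 times on random subsamples of 70% of the lines drawn within each
family; markers detected at P<0.05 in at least 30% of subsamples are
accepted as putative QTLs. Peaks are summarized per 5-cM half-open map
window.

Around the scans the package provides: BC1S3 genotype simulation on a
genetic map (Haldane map function, exact Markov-chain genotype
frequencies), the marker quality filters (polymorphic in at least one
family, under 10% missing, complete-LD deduplication), derived traits
(GFP = MAT − HEA, HI = PGY/TDM, VDW = TDM − PGY), the multiplicative
cross-year adjustment, factorial pot-experiment ANOVA with compact letter
displays, and a YCbCr-chroma canopy classifier that scores leaf senescence
as the yellow/brown percentage of leaf area against a white photo
background.

## Worked example

Simulate a 25-family panel, plant a WL-only QTL of 40 grains at one
marker, run the interaction scan and the cross-validation rule:

```r
library(namQxE)
map <- generateMap(nChromosomes = 7, chromLength = 150, nMarkers = 350, seed = 1)
pop <- filterMarkers(simulatePopulation(map, nFamilies = 25,
                                        linesPerFamily = 20, seed = 1))$pop
K   <- computeKinship(pop)
causal <- markerIds(pop)[30]
arch <- architectureSpec("GN", mu = 334, familyEffects = rnorm(25, 0, 6),
                         loci = data.frame(marker = causal, effect = 0,
                                           dominant = FALSE, qxe = 40),
                         h2 = 0.4, envEffect = -103,
                         residSD = c(WW = 36, WL = 42))
ph  <- simulatePhenotypes(pop, arch, years = 2, kinship = K, seed = 2,
                          yearScale = c(1, 1.15))
adj <- adjustAcrossYears(ph)
qxe <- scanQxE(pop, adj, "GN", kinship = K)
head(scanTable(qxe)[order(scanTable(qxe)$p),
                    c("marker", "chrom", "pos", "effWW_HsHs", "effWL_HsHs", "p")], 3)
#>       marker chrom       pos effWW_HsHs effWL_HsHs            p
#> 30 M01_00030     1 100.29284  -3.490346   33.25389 4.687183e-14
#> 33 M01_00033     1 105.57850  -5.475226   19.71110 8.023932e-07
#> 29 M01_00029     1  98.08226   0.238310   26.18504 3.995539e-06
```

The planted marker is the genome-wide peak: its wild allele does nothing
under WW (−3.5 grains, relative to the Barke-type homozygote) but adds
~33 grains under WL — a protective Q×E effect, flanked by linked markers
echoing it. The cross-validation rule accepts it:

```r
cv <- crossval(pop, adj, "GN", model = "qxe", replicates = 50, seed = 3,
               markers = causal, kinship = K)
cv
#> DetectionProfile: 1 markers, 50 replicates, 1 accepted (rate >= 0.30)

reactionNorms(pop, adj, causal, "GN")
#>   genotype environment lsmean    se
#> 1     HvHv          WW  395.1 1.811
#> 2     HvHs          WW  394.5 7.746
#> 3     HsHs          WW  393.7 4.369
#> 4     HvHv          WL  285.1 1.811
#> 5     HvHs          WL  316.5 7.746
#> 6     HsHs          WL  320.4 4.369
```

The reaction norms show the signature the scan is built to find: all
genotype classes start level under WW, but wild-allele carriers lose ~73
grains under WL where the cultivated class loses ~110. The pot-experiment
helpers summarize such contrasts the way field reports print them:

```r
percentReduction(334, 221)   # drought-sensitive carriers: 33.8 (% reduction)
percentReduction(272, 252)   # drought-tolerant carriers:   7.4
```

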