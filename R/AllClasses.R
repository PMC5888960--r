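#' @import methods
#' @importFrom stats aggregate aov cor dist lm lm.fit lm.wfit model.matrix
#'   optimize pf rnorm runif sd setNames t.test var TukeyHSD
#' @importFrom utils head read.delim write.table
NULL

VALID_GENO_CODES <- c(0L, 1L, 2L)

#' NAM population: genotypes, families and a genetic map
#'
#' Container for a multi-parent nested association mapping (NAM) panel:
#' a lines-by-markers genotype matrix coded 0 (recurrent-parent homozygote,
#' Hv/Hv), 1 (heterozygote, Hv/Hs), 2 (donor homozygote, Hs/Hs) or `NA`;
#' a family (donor) assignment per line; and a genetic map giving each
#' marker's chromosome and position in centimorgans.
#'
#' @slot geno integer matrix, lines x markers, values in \{0, 1, 2, NA\};
#'   rownames are line identifiers, colnames marker identifiers.
#' @slot family factor of length `nrow(geno)`; the donor family of each line.
#' @slot map data.frame with columns `marker`, `chrom` (integer), `pos`
#'   (cM, non-decreasing within chromosome); one row per genotype column,
#'   same order.
#'
#' @seealso [simulatePopulation()], [readGenotypes()], [filterMarkers()]
#' @export
setClass("NamPopulation",
  representation(geno = "matrix", family = "factor", map = "data.frame"))

setValidity("NamPopulation", function(object) {
  g <- object@geno
  msg <- character()
  if (!is.numeric(g)) msg <- c(msg, "genotype matrix must be numeric")
  bad <- !(g %in% VALID_GENO_CODES | is.na(g))
  if (any(bad)) msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (length(object@family) != nrow(g))
    msg <- c(msg, "one family label required per line")
  if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
    msg <- c(msg, "line identifiers must be present and unique")
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msg <- c(msg, "marker identifiers must be present and unique")
  m <- object@map
  if (!all(c("marker", "chrom", "pos") %in% names(m))) {
    msg <- c(msg, "map needs columns marker, chrom, pos")
  } else {
    if (nrow(m) != ncol(g) || !identical(as.character(m$marker), colnames(g)))
      msg <- c(msg, "map rows must match genotype columns in order")
    if (any(m$pos < 0, na.rm = TRUE)) msg <- c(msg, "map positions must be >= 0")
    if (any(unlist(tapply(m$pos, m$chrom, function(p) diff(p) < 0))))
      msg <- c(msg, "map positions must be non-decreasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Trait architecture for phenotype simulation
#'
#' Specifies the generative model for one trait: population mean, family
#' effects, causal loci with per-se and environment-conditional (Q\eqn{\times}E)
#' effects, a polygenic component with covariance proportional to kinship at a
#' stated heritability, an environment main effect active under water
#' limitation (WL), and per-environment residual standard deviations.
#'
#' Locus effects are the expected difference between the donor homozygote
#' (code 2) and the recurrent-parent homozygote (code 0); heterozygotes get
#' half the effect unless the dominance flag is set, in which case they get
#' the full effect. Q\eqn{\times}E effects are added only under WL.
#'
#' @slot trait trait name.
#' @slot mu population mean (trait units).
#' @slot familyEffects numeric, one entry per family (trait units); recycled
#'   from 0 if empty.
#' @slot loci data.frame with columns `marker`, `effect`, `dominant`
#'   (logical), `qxe` (trait units, added under WL only). Zero rows allowed.
#' @slot h2 polygenic heritability in [0, 1] (fraction of the WW
#'   non-residual+residual variance attributed to the kinship component).
#' @slot envEffect environment main effect, added to every WL record.
#' @slot residSD named numeric `c(WW = ..., WL = ...)`, both > 0.
#' @export
setClass("ArchitectureSpec",
  representation(trait = "character", mu = "numeric", familyEffects = "numeric",
    loci = "data.frame", h2 = "numeric", envEffect = "numeric",
    residSD = "numeric"))

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (length(object@h2) != 1 || object@h2 < 0 || object@h2 > 1)
    msg <- c(msg, "h2 must be a single value in [0, 1]")
  if (!all(c("WW", "WL") %in% names(object@residSD)))
    msg <- c(msg, "residSD must be named with WW and WL")
  if (any(object@residSD <= 0)) msg <- c(msg, "residual SDs must be > 0")
  need <- c("marker", "effect", "dominant", "qxe")
  if (!all(need %in% names(object@loci)))
    msg <- c(msg, "loci needs columns marker, effect, dominant, qxe")
  if (length(msg)) msg else TRUE
})

#' Genome-scan result
#'
#' Per-marker statistics from a per-environment scan or a
#' marker-by-environment interaction scan: wild-homozygote and heterozygote
#' effects relative to the recurrent-parent class, the joint test statistic,
#' its p-value and the number of lines used.
#'
#' @slot table data.frame, one row per marker tested.
#' @slot trait trait name.
#' @slot environment "WW", "WL" or "both" (interaction scan).
#' @slot model "per-se" or "qxe".
#' @export
setClass("ScanResult",
  representation(table = "data.frame", trait = "character",
    environment = "character", model = "character"))

setValidity("ScanResult", function(object) {
  p <- object@table$p
  if (!is.null(p) && any(p <= 0 | p > 1, na.rm = TRUE))
    "p-values must lie in (0, 1]" else TRUE
})

#' Cross-validation detection profile
#'
#' Per-marker detection rates over repeated subsamples of the population and
#' the resulting acceptance calls (rate at least the threshold).
#'
#' @slot table data.frame with columns `marker`, `detections`, `replicates`,
#'   `rate`, `accepted`.
#' @slot params list of the resampling parameters used (replicates, fraction,
#'   alpha, rateThreshold, model, trait, environment, seed).
#' @export
setClass("DetectionProfile",
  representation(table = "data.frame", params = "list"))

setValidity("DetectionProfile", function(object) {
  t <- object@table
  msg <- character()
  if (!all(c("marker", "detections", "replicates", "rate", "accepted") %in% names(t)))
    msg <- c(msg, "table needs marker, detections, replicates, rate, accepted")
  else {
    if (any(abs(t$rate - t$detections / t$replicates) > 1e-12, na.rm = TRUE))
      msg <- c(msg, "rate must equal detections/replicates exactly")
    thr <- object@params$rateThreshold
    if (!is.null(thr) && any(t$accepted != (t$rate >= thr), na.rm = TRUE))
      msg <- c(msg, "accepted flag must equal rate >= threshold")
  }
  if (length(msg)) msg else TRUE
})

#' Marker filter report
#'
#' Records, per quality rule, how many markers were removed and which
#' markers survive. Rules are applied in a fixed order: monomorphic within
#' every family, then missingness, then complete-LD deduplication.
#'
#' @slot nInput number of markers before filtering.
#' @slot dropped named integer vector: markers dropped by `monomorphic`,
#'   `missing`, `duplicate`.
#' @slot surviving character vector of surviving marker identifiers.
#' @slot maxMissing missingness threshold used (markers with a missing
#'   fraction at or above it are dropped).
#' @export
setClass("FilterReport",
  representation(nInput = "integer", dropped = "integer",
    surviving = "character", maxMissing = "numeric"))

setValidity("FilterReport", function(object) {
  if (sum(object@dropped) + length(object@surviving) != object@nInput)
    "dropped + surviving must equal input markers" else TRUE
})

#' Canopy senescence score
#'
#' Pixel areas from classifying a canopy photograph against a white
#' background: total leaf area, its green and yellow/brown parts, and the
#' yellow/brown percentage of the leaf area.
#'
#' @slot totalArea leaf pixels (green + yellow/brown).
#' @slot greenArea green pixels.
#' @slot yellowArea yellow/brown pixels.
#' @slot yellowFraction 100 * yellow / (green + yellow); `NA` when no leaf
#'   pixels were found.
#' @export
setClass("CanopyScore",
  representation(totalArea = "numeric", greenArea = "numeric",
    yellowArea = "numeric", yellowFraction = "numeric"))

setValidity("CanopyScore", function(object) {
  if (object@greenArea + object@yellowArea != object@totalArea)
    "green + yellow must equal total leaf area" else TRUE
})
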