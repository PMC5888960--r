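#' Accessors for NamPopulation
#'
#' @param x a [NamPopulation-class].
#' @return `genotypes()` the integer genotype matrix; `families()` the factor
#'   of family labels; `linkageMap()` the map data.frame; `lineIds()` and
#'   `markerIds()` character vectors; `nLines()`/`nMarkers()` counts.
#' @name NamPopulation-accessors
#' @aliases genotypes families linkageMap lineIds markerIds nLines nMarkers
NULL

#' @rdname NamPopulation-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname NamPopulation-accessors
#' @export
setGeneric("families", function(x) standardGeneric("families"))
#' @rdname NamPopulation-accessors
#' @export
setGeneric("linkageMap", function(x) standardGeneric("linkageMap"))
#' @rdname NamPopulation-accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))
#' @rdname NamPopulation-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname NamPopulation-accessors
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))
#' @rdname NamPopulation-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' Extract the per-marker statistics table
#'
#' @param x a [ScanResult-class] or [DetectionProfile-class].
#' @return a data.frame, one row per marker.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname NamPopulation-accessors
#' @export
setMethod("genotypes", "NamPopulation", function(x) x@geno)
#' @rdname NamPopulation-accessors
#' @export
setMethod("families", "NamPopulation", function(x) x@family)
#' @rdname NamPopulation-accessors
#' @export
setMethod("linkageMap", "NamPopulation", function(x) x@map)
#' @rdname NamPopulation-accessors
#' @export
setMethod("lineIds", "NamPopulation", function(x) rownames(x@geno))
#' @rdname NamPopulation-accessors
#' @export
setMethod("markerIds", "NamPopulation", function(x) colnames(x@geno))
#' @rdname NamPopulation-accessors
#' @export
setMethod("nLines", "NamPopulation", function(x) nrow(x@geno))
#' @rdname NamPopulation-accessors
#' @export
setMethod("nMarkers", "NamPopulation", function(x) ncol(x@geno))

#' @describeIn ScanResult-class the per-marker table
#' @param x a ScanResult
#' @export
setMethod("scanTable", "ScanResult", function(x) x@table)

#' @describeIn DetectionProfile-class the per-marker detection table
#' @param x a DetectionProfile
#' @export
setMethod("scanTable", "DetectionProfile", function(x) x@table)

setMethod("show", "NamPopulation", function(object) {
  cat("NamPopulation:", nrow(object@geno), "lines x", ncol(object@geno),
      "markers,", nlevels(object@family), "families,",
      length(unique(object@map$chrom)), "chromosomes\n")
  miss <- mean(is.na(object@geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s, trait %s, environment %s): %d markers\n",
              object@model, object@trait, object@environment,
              nrow(object@table)))
  p <- object@table$p
  if (any(!is.na(p)))
    cat(sprintf("  min p = %.3g at %s\n", min(p, na.rm = TRUE),
                object@table$marker[which.min(p)]))
})

setMethod("show", "DetectionProfile", function(object) {
  cat(sprintf("DetectionProfile: %d markers, %d replicates, %d accepted (rate >= %.2f)\n",
              nrow(object@table), object@params$replicates,
              sum(object@table$accepted, na.rm = TRUE),
              object@params$rateThreshold))
})

setMethod("show", "CanopyScore", function(object) {
  cat(sprintf("CanopyScore: leaf %d px (green %d, yellow/brown %d), yellow fraction %s%%\n",
              as.integer(object@totalArea), as.integer(object@greenArea),
              as.integer(object@yellowArea),
              ifelse(is.na(object@yellowFraction), "NA",
                     sprintf("%.1f", object@yellowFraction))))
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@nInput, "markers in,",
      length(object@surviving), "surviving\n")
  cat(sprintf("  dropped: %d monomorphic, %d missing (>= %.0f%%), %d complete-LD duplicates\n",
              object@dropped["monomorphic"], object@dropped["missing"],
              100 * object@maxMissing, object@dropped["duplicate"]))
})
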