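#' Read and write the genotype, map and phenotype file dialects
#'
#' The on-disk dialects are plain tab-separated text. Genotype file: header
#' row `line<TAB>family<TAB><marker ids...>`, one row per line, genotype
#' cells in \{0, 1, 2, NA\}. Map file: columns `marker`, `chrom`, `pos`.
#' Phenotype file: long format with columns `line`, `family`, `year`,
#' `environment` (WW/WL), `trait`, `value`.
#'
#' `readGenotypes()` needs the map to order and validate markers; a
#' write/read round trip reproduces the population exactly.
#'
#' @param path file path.
#' @param map a map data.frame (as returned by [readMap()]).
#' @param pop a [NamPopulation-class].
#' @param tab a phenotype data.frame.
#' @return `readGenotypes` a [NamPopulation-class]; `readMap`/
#'   `readPhenotypes` data.frames; the writers return their input invisibly.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
writeGenotypes <- function(pop, path) {
  g <- genotypes(pop)
  out <- data.frame(line = rownames(g), family = as.character(families(pop)),
                    g, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pop)
}

#' @rdname genotype-io
#' @export
readGenotypes <- function(path, map) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot_arg(all(c("line", "family") %in% names(raw)[1:2]),
                "genotype file must start with columns line, family")
  if (anyDuplicated(raw$line))
    stop("duplicated line id in genotype file: ",
         raw$line[anyDuplicated(raw$line)], call. = FALSE)
  mk <- setdiff(names(raw), c("line", "family"))
  stopifnot_arg(setequal(mk, map$marker), "genotype columns must match the map")
  g <- as.matrix(raw[, as.character(map$marker), drop = FALSE])
  badm <- matrix(!(g %in% VALID_GENO_CODES | is.na(g)), nrow(g))
  if (any(badm)) {
    bad <- which(badm, arr.ind = TRUE)
    stop(sprintf("invalid genotype code '%s' at line '%s', marker '%s'",
                 g[bad[1, 1], bad[1, 2]], raw$line[bad[1, 1]],
                 colnames(g)[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(g) <- "integer"
  rownames(g) <- raw$line
  new("NamPopulation", geno = g, family = factor(raw$family),
      map = data.frame(map, stringsAsFactors = FALSE))
}

#' @rdname genotype-io
#' @export
writeMap <- function(map, path) {
  write.table(map[, c("marker", "chrom", "pos")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(map)
}

#' @rdname genotype-io
#' @export
readMap <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_arg(all(c("marker", "chrom", "pos") %in% names(m)),
                "map file needs columns marker, chrom, pos")
  m$marker <- as.character(m$marker)
  m$chrom <- as.integer(m$chrom)
  m
}

#' @rdname genotype-io
#' @export
writePhenotypes <- function(tab, path) {
  checkPhenotypeTable(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname genotype-io
#' @export
readPhenotypes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  checkPhenotypeTable(tab)
  tab
}

# Markers monomorphic within every family (ignoring NA). A marker counts as
# polymorphic if any family shows >= 2 distinct non-missing codes.
.polymorphicAnywhere <- function(g, fam) {
  res <- rep(FALSE, ncol(g))
  for (f in levels(fam)) {
    sub <- g[fam == f, , drop = FALSE]
    mn <- suppressWarnings(apply(sub, 2, min, na.rm = TRUE))
    mx <- suppressWarnings(apply(sub, 2, max, na.rm = TRUE))
    res <- res | (is.finite(mn) & is.finite(mx) & mn < mx)
  }
  res
}

# Complete-LD duplicate detection: markers i < j (map order) are duplicates
# when identical at every jointly non-missing line and jointly non-missing
# at >= minShared of lines. Blocked cross-products keep memory bounded.
.completeLDDuplicates <- function(g, minShared = 0.5, blockSize = 512L) {
  m <- ncol(g); n <- nrow(g)
  if (m < 2) return(logical(m))
  N <- !is.na(g); storage.mode(N) <- "double"
  A <- lapply(VALID_GENO_CODES, function(k) {
    a <- (g == k) & N; storage.mode(a) <- "double"; a[is.na(a)] <- 0; a
  })
  dup <- logical(m)
  for (start in seq(1, m, by = blockSize)) {
    idx <- start:min(start + blockSize - 1L, m)
    joint <- crossprod(N[, idx, drop = FALSE], N)           # |idx| x m
    match <- Reduce(`+`, lapply(A, function(a)
      crossprod(a[, idx, drop = FALSE], a)))
    isdup <- (match == joint) & (joint >= minShared * n)
    for (r in seq_along(idx)) {
      i <- idx[r]
      js <- which(isdup[r, ]) ; js <- js[js > i]
      if (!dup[i] && length(js)) dup[js] <- TRUE
    }
  }
  dup
}

#' Apply marker quality filters
#'
#' Reproduces the informative-marker filter of NAM genotype panels, in a
#' fixed order: (1) drop markers monomorphic within every family; (2) drop
#' markers whose missing fraction is `>= maxMissing` (so strictly less than
#' 10% missing survives at the default); (3) among markers in complete
#' linkage disequilibrium — identical at every jointly non-missing line,
#' with at least half the lines jointly observed — keep only the first in
#' map order. The filter is idempotent.
#'
#' @param pop a [NamPopulation-class] with family labels.
#' @param maxMissing drop markers with missing fraction at or above this.
#' @return list with `pop` (filtered [NamPopulation-class]) and `report`
#'   (a [FilterReport-class]).
#' @export
filterMarkers <- function(pop, maxMissing = 0.10) {
  g <- genotypes(pop)
  fam <- families(pop)
  keep1 <- .polymorphicAnywhere(g, fam)
  nMono <- sum(!keep1)
  g2 <- g[, keep1, drop = FALSE]
  missFrac <- colMeans(is.na(g2))
  keep2 <- missFrac < maxMissing
  nMiss <- sum(!keep2)
  g3 <- g2[, keep2, drop = FALSE]
  dup <- .completeLDDuplicates(g3)
  nDup <- sum(dup)
  keepIds <- colnames(g3)[!dup]
  sel <- match(keepIds, colnames(g))
  newpop <- new("NamPopulation", geno = g[, sel, drop = FALSE], family = fam,
                map = pop@map[sel, , drop = FALSE])
  report <- new("FilterReport", nInput = ncol(g),
                dropped = c(monomorphic = nMono, missing = nMiss,
                            duplicate = nDup),
                surviving = keepIds, maxMissing = maxMissing)
  list(pop = newpop, report = report)
}

#' Compute the relative kinship matrix
#'
#' Marker-based relatedness among lines, used as the covariance structure of
#' the polygenic random effect in the mixed-model scans.
#'
#' Methods: `"allele-sharing"` gives \eqn{K_{ab} = \mathrm{mean}_m (1 -
#' |g_{am} - g_{bm}|/2)}, the proportion of shared alleles (1 on the
#' diagonal); `"centered-cross-product"` is the cross-product of
#' column-centred genotypes rescaled to unit mean diagonal (VanRaden-style).
#' Missing codes are imputed by the marker mean for this computation only;
#' markers missing in all lines are excluded with a warning.
#'
#' @param pop a [NamPopulation-class] with at least 2 lines.
#' @param method kinship estimator.
#' @return symmetric positive-semidefinite numeric matrix with line ids as
#'   dimnames.
#' @examples
#' # two lines opposite homozygotes everywhere share no alleles: K[a,b] = 0
#' @export
computeKinship <- function(pop,
                           method = c("allele-sharing",
                                      "centered-cross-product")) {
  method <- match.arg(method)
  g <- genotypes(pop)
  stopifnot_arg(nrow(g) >= 2, "need at least 2 lines")
  allmiss <- colSums(!is.na(g)) == 0
  if (any(allmiss)) {
    warning(sum(allmiss), " all-missing marker(s) excluded from kinship")
    g <- g[, !allmiss, drop = FALSE]
  }
  G <- g
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mns <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mns[idx[, 2]]
  }
  K <- switch(method,
    "allele-sharing" = 1 - as.matrix(dist(G, method = "manhattan")) /
      (2 * ncol(G)),
    "centered-cross-product" = {
      W <- sweep(G, 2, colMeans(G))
      K0 <- tcrossprod(W) / ncol(W)
      K0 / mean(diag(K0))
    })
  dimnames(K) <- list(rownames(g), rownames(g))
  (K + t(K)) / 2
}
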