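# Marker-by-environment interaction scan and the subsample cross-validation
# acceptance rule.  The two environment records of a line share one
# polygenic effect: the stacked covariance is K (x) J2 (Kronecker with an
# all-ones 2x2 block), whose spectrum follows from the spectra of K and J2,
# so the per-trait eigendecomposition stays n x n.

# eigen pieces of K (x) J2 for records ordered line-major (WW, WL per line)
.qxeSpectral <- function(K) {
  ed <- .kinshipSpectral(K)
  VJ <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  list(U = kronecker(ed$vectors, VJ),
       d = as.vector(rbind(2 * ed$values, 0)))
}

# REML fit given a precomputed spectral decomposition of the covariance
.fitNullCore <- function(y, X0, U, d, lambdaRange = c(1e-5, 1e5),
                         tol = 1e-8) {
  if (var(y) == 0) stop("zero-variance response", call. = FALSE)
  n <- length(y)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X0)
  obj <- function(loglam) .remlObjective(exp(loglam), yt, Xt, d)
  opt <- optimize(obj, log(lambdaRange), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, log(lambdaRange))
  vals <- c(opt$objective, obj(log(lambdaRange[1])), obj(log(lambdaRange[2])))
  lambda <- exp(cand[which.max(vals)])
  w <- 1 / (lambda * d + 1)
  fit <- lm.wfit(Xt, yt, w)
  p <- fit$rank
  s2 <- sum(w * fit$residuals^2) / (n - p)
  list(vc = structure(list(lambda = lambda, sigmaG2 = lambda * s2,
                           sigmaE2 = s2, logREML = max(vals), n = n, p = p),
                      class = "VarianceComponents"),
       yt = yt, X0t = Xt, w = w, U = U, d = d)
}

#' Genome scan for marker-by-environment interaction
#'
#' Stacks each line's WW and WL records and fits, per marker, the
#' interaction model with fixed effects intercept, family, genotype class,
#' environment, and genotype-class-by-environment interaction, plus a
#' polygenic random effect shared by the two records of a line (covariance
#' \eqn{\sigma^2_g (K \otimes J_2)}) and i.i.d. residuals. The headline
#' p-value is the joint F-test of the interaction contrasts (2 df when all
#' three genotype classes are present); environment-specific marker effects
#' relative to the recurrent-parent class are reported for both
#' environments. Variance components are estimated once on the null model
#' (intercept + family + environment) and reused across markers (P3D).
#'
#' @inheritParams scanPerSe
#' @return a [ScanResult-class] with per-marker columns `effWW_HsHs`,
#'   `effWL_HsHs`, `effWW_HvHs`, `effWL_HvHs`, `Fstat`, `df1`, `df2`, `p`,
#'   `n` (lines).
#' @export
scanQxE <- function(pop, phenos, trait, kinship = NULL, markers = NULL,
                    coding = c("class", "additive")) {
  coding <- match.arg(coding)
  checkPhenotypeTable(phenos)
  present <- intersect(ENVS, unique(phenos$environment))
  if (length(present) < 2)
    stop("phenotypes cover a single environment; use scanPerSe()",
         call. = FALSE)
  if (is.null(kinship)) kinship <- computeKinship(pop)
  yWW <- .responseVector(phenos, trait, "WW")
  yWL <- .responseVector(phenos, trait, "WL")
  anyPheno <- union(names(yWW)[!is.na(yWW)], names(yWL)[!is.na(yWL)])
  both <- intersect(names(yWW)[!is.na(yWW)], names(yWL)[!is.na(yWL)])
  lines <- intersect(lineIds(pop), both)
  stopifnot_arg(length(lines) >= 0.8 * length(intersect(lineIds(pop), anyPheno)),
                "need both environments for at least 80% of phenotyped lines")
  stopifnot_arg(length(lines) >= 10, "too few lines with both environments")
  idx <- match(lines, lineIds(pop))
  fam <- droplevels(families(pop)[idx])
  n <- length(lines)
  # record order: line-major, WW then WL within line
  y <- as.vector(rbind(as.numeric(yWW[lines]), as.numeric(yWL[lines])))
  env <- factor(rep(ENVS, n), levels = ENVS)
  famR <- fam[rep(seq_len(n), each = 2)]
  X0 <- if (nlevels(fam) > 1) stats::model.matrix(~famR + env) else
    stats::model.matrix(~env)
  K <- kinship[lines, lines]
  sp <- .qxeSpectral(K)
  ns <- .fitNullCore(y, X0, sp$U, sp$d)
  G <- genotypes(pop)[idx, , drop = FALSE]
  if (!is.null(markers)) {
    stopifnot_arg(all(markers %in% colnames(G)), "unknown marker requested")
    G <- G[, markers, drop = FALSE]
  }
  sw <- sqrt(ns$w)
  X0w <- ns$X0t * sw
  yw <- ns$yt * sw
  isWL <- as.numeric(env == "WL")
  rows <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    if (anyNA(g)) {
      rows[[j]] <- .qxeMarkerSubset(y, X0, g, K, env, famR, ns$vc, coding,
                                    lines)
    } else {
      gr <- rep(g, each = 2)
      D <- .markerDesign(gr, coding)
      if (ncol(D) == 0) { rows[[j]] <- .qxeEmptyRow(n); next }
      DE <- D * isWL
      colnames(DE) <- paste0(colnames(D), ":WL")
      Dw <- crossprod(ns$U, D) * sw
      DEw <- crossprod(ns$U, DE) * sw
      fitRed <- lm.fit(cbind(X0w, Dw), yw)
      res <- .glsMarkerTest(cbind(X0w, Dw), DEw, yw,
                            sum(fitRed$residuals^2), fitRed$rank)
      full <- lm.fit(cbind(X0w, Dw, DEw), yw)
      rows[[j]] <- .qxeRow(full, ncol(X0w), D, res, coding, n)
    }
  }
  tab <- do.call(rbind, rows)
  mp <- pop@map[match(colnames(G), pop@map$marker), ]
  tab <- data.frame(marker = colnames(G), chrom = mp$chrom, pos = mp$pos,
                    tab, stringsAsFactors = FALSE, row.names = NULL)
  new("ScanResult", table = tab, trait = trait, environment = "both",
      model = "qxe")
}

.qxeEmptyRow <- function(n) {
  data.frame(effWW_HsHs = NA_real_, effWL_HsHs = NA_real_,
             effWW_HvHs = NA_real_, effWL_HvHs = NA_real_,
             Fstat = NA_real_, df1 = 0L, df2 = NA_integer_, p = NA_real_,
             n = n)
}

# environment-specific effects + interaction F-test from the full GLS fit
.qxeRow <- function(full, p0, D, res, coding, n) {
  cf <- full$coefficients
  getc <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else NA_real_
  if (coding == "additive") {
    ww <- getc("dose"); dd <- getc("dose:WL")
    out <- data.frame(effWW_HsHs = 2 * ww, effWL_HsHs = 2 * (ww + dd),
                      effWW_HvHs = ww, effWL_HvHs = ww + dd)
  } else {
    w2 <- getc("HsHs"); d2 <- getc("HsHs:WL")
    w1 <- getc("HvHs"); d1 <- getc("HvHs:WL")
    out <- data.frame(effWW_HsHs = w2, effWL_HsHs = w2 + d2,
                      effWW_HvHs = w1, effWL_HvHs = w1 + d1)
  }
  cbind(out, data.frame(Fstat = res$F, df1 = res$df1, df2 = res$df2,
                        p = res$p, n = n))
}

# Cholesky-path interaction test for markers with missing genotypes:
# lines missing at the marker contribute neither record
.qxeMarkerSubset <- function(y, X0, g, K, env, famR, vc, coding, lines) {
  keepL <- !is.na(g)
  n2 <- sum(keepL)
  if (n2 < 4 || length(unique(g[keepL])) < 2) return(.qxeEmptyRow(n2))
  keepR <- rep(keepL, each = 2)
  ys <- y[keepR]
  X0s <- X0[keepR, , drop = FALSE]
  Ks <- K[keepL, keepL, drop = FALSE]
  V <- vc$lambda * kronecker(Ks, matrix(1, 2, 2)) + diag(2 * n2)
  R <- chol(V)
  wh <- function(M) backsolve(R, M, transpose = TRUE)
  gr <- rep(g[keepL], each = 2)
  D <- .markerDesign(gr, coding)
  if (ncol(D) == 0) return(.qxeEmptyRow(n2))
  DE <- D * as.numeric(env[keepR] == "WL")
  colnames(DE) <- paste0(colnames(D), ":WL")
  yw <- wh(ys); X0w <- wh(X0s); Dw <- wh(D); DEw <- wh(DE)
  colnames(Dw) <- colnames(D); colnames(DEw) <- colnames(DE)
  fitRed <- lm.fit(cbind(X0w, Dw), yw)
  res <- .glsMarkerTest(cbind(X0w, Dw), DEw, yw, sum(fitRed$residuals^2),
                        fitRed$rank)
  full <- lm.fit(cbind(X0w, Dw, DEw), yw)
  .qxeRow(full, ncol(X0w), D, res, coding, n2)
}

# subset a population to a set of lines (markers untouched)
.subsetLines <- function(pop, lines) {
  idx <- match(lines, lineIds(pop))
  new("NamPopulation", geno = pop@geno[idx, , drop = FALSE],
      family = droplevels(pop@family[idx]), map = pop@map)
}

#' Cross-validated QTL detection rates
#'
#' The resampling acceptance rule: the scan is repeated on random
#' subsamples of the population — by default 200 replicates, each drawing
#' 70% of the lines within every family (ceiling rounding, without
#' replacement) — and a marker's detection rate is the fraction of
#' replicates in which its test gives `p < alpha`. Markers with a rate at
#' or above `rateThreshold` (default 30%) are accepted as putative QTLs.
#' Variance components are re-estimated in every replicate (the subsample
#' changes n); P3D applies within a replicate.
#'
#' @inheritParams scanPerSe
#' @param model `"per-se"` (needs `environment`) or `"qxe"`.
#' @param environment environment for the per-se model.
#' @param replicates number of subsamples.
#' @param fraction fraction of lines drawn per family, in (0, 1].
#' @param alpha per-replicate significance threshold.
#' @param rateThreshold acceptance threshold on the detection rate.
#' @param seed master seed; replicate streams are derived from it.
#' @param keepDraws logical; keep every replicate's drawn line ids in
#'   `params$draws` (for auditing the per-family stratification).
#' @return a [DetectionProfile-class].
#' @export
crossval <- function(pop, phenos, trait, model = c("per-se", "qxe"),
                     environment = NULL, replicates = 200L, fraction = 0.70,
                     alpha = 0.05, rateThreshold = 0.30, seed = 1L,
                     markers = NULL, kinship = NULL, keepDraws = FALSE) {
  model <- match.arg(model)
  stopifnot_arg(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  stopifnot_arg(replicates >= 1, "need at least one replicate")
  if (model == "per-se")
    stopifnot_arg(!is.null(environment) && environment %in% ENVS,
                  "per-se model needs environment WW or WL")
  famSplit <- split(lineIds(pop), families(pop))
  stopifnot_arg(all(lengths(famSplit) >= 2), "every family needs >= 2 lines")
  if (is.null(kinship)) kinship <- computeKinship(pop)
  if (is.null(markers)) markers <- markerIds(pop)
  det <- setNames(integer(length(markers)), markers)
  used <- setNames(integer(length(markers)), markers)
  draws <- if (keepDraws) vector("list", replicates) else NULL
  for (r in seq_len(replicates)) {
    set.seed(deriveSeed(seed, 701, r))
    sub <- unlist(lapply(famSplit, function(ls)
      sample(ls, ceiling(fraction * length(ls)))), use.names = FALSE)
    if (keepDraws) draws[[r]] <- sub
    spop <- .subsetLines(pop, sub)
    sphen <- phenos[phenos$line %in% sub, , drop = FALSE]
    Ksub <- kinship[sub, sub]
    sc <- if (model == "per-se")
      scanPerSe(spop, sphen, trait, environment, kinship = Ksub,
                markers = markers)
    else scanQxE(spop, sphen, trait, kinship = Ksub, markers = markers)
    p <- scanTable(sc)$p[match(markers, scanTable(sc)$marker)]
    hit <- !is.na(p) & p < alpha
    det[hit] <- det[hit] + 1L
    used <- used + 1L
  }
  tab <- data.frame(marker = markers, detections = as.integer(det),
                    replicates = as.integer(replicates),
                    rate = det / replicates,
                    accepted = det / replicates >= rateThreshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("DetectionProfile", table = tab,
      params = list(replicates = as.integer(replicates), fraction = fraction,
                    alpha = alpha, rateThreshold = rateThreshold,
                    model = model, trait = trait,
                    environment = if (is.null(environment)) "both" else environment,
                    seed = seed, draws = draws))
}

#' Window peak markers
#'
#' Tiles each chromosome into consecutive half-open `[start, start + window)`
#' windows anchored at 0 cM and reports, per window containing markers, the
#' marker with the smallest p-value. Ties are broken by lower cM position,
#' then lexically by marker id.
#'
#' @param scan a [ScanResult-class] (its table must carry `chrom`, `pos`,
#'   `p`) or a data.frame of the same shape.
#' @param windowCM window width in cM (default 5).
#' @return data.frame `chrom`, `windowStart`, `windowEnd`, `peakMarker`,
#'   `peakP`, `nMarkers`.
#' @export
windowPeaks <- function(scan, windowCM = 5) {
  tab <- if (is(scan, "ScanResult")) scanTable(scan) else scan
  stopifnot_arg(all(c("marker", "chrom", "pos", "p") %in% names(tab)),
                "scan table needs marker, chrom, pos, p")
  win <- floor(tab$pos / windowCM)
  keys <- split(seq_len(nrow(tab)), list(chrom = tab$chrom, win = win),
                drop = TRUE)
  rows <- lapply(keys, function(ii) {
    sub <- tab[ii, ]
    ord <- order(sub$p, sub$pos, sub$marker, na.last = TRUE)
    best <- sub[ord[1], ]
    data.frame(chrom = best$chrom, windowStart = floor(best$pos / windowCM) * windowCM,
               windowEnd = floor(best$pos / windowCM) * windowCM + windowCM,
               peakMarker = best$marker, peakP = best$p, nMarkers = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$windowStart), ]
  rownames(out) <- NULL
  out
}

#' Reaction norms at a marker
#'
#' Least-squares means of the three genotype classes in each environment,
#' adjusted for family (via `emmeans` on the fixed-effects model
#' `value ~ family + genotype * environment`). With balanced data and no
#' family effects these equal the raw class means. Empty classes get
#' missing means.
#'
#' @inheritParams scanPerSe
#' @param marker marker identifier.
#' @return data.frame `genotype` (HvHv/HvHs/HsHs), `environment`, `lsmean`,
#'   `se`.
#' @export
reactionNorms <- function(pop, phenos, marker, trait) {
  checkPhenotypeTable(phenos)
  stopifnot_arg(marker %in% markerIds(pop), "marker not in population")
  lm_ <- lineMeans(phenos)
  lm_ <- lm_[lm_$trait == trait & !is.na(lm_$value), ]
  idx <- match(lm_$line, lineIds(pop))
  ok <- !is.na(idx)
  lm_ <- lm_[ok, ]; idx <- idx[ok]
  g <- genotypes(pop)[idx, marker]
  dat <- data.frame(value = lm_$value,
                    genotype = factor(c("HvHv", "HvHs", "HsHs")[g + 1],
                                      levels = c("HvHv", "HvHs", "HsHs")),
                    environment = factor(lm_$environment, levels = ENVS),
                    family = factor(families(pop)[idx]))
  dat <- dat[!is.na(dat$genotype), ]
  fml <- if (nlevels(droplevels(dat$family)) > 1)
    value ~ family + genotype * environment else
    value ~ genotype * environment
  fit <- lm(fml, data = droplevels(dat))
  em <- as.data.frame(emmeans::emmeans(fit, ~ genotype * environment))
  grid <- expand.grid(genotype = c("HvHv", "HvHs", "HsHs"),
                      environment = ENVS, stringsAsFactors = FALSE)
  m <- match(paste(grid$genotype, grid$environment),
             paste(em$genotype, em$environment))
  data.frame(grid, lsmean = em$emmean[m], se = em$SE[m],
             stringsAsFactors = FALSE)
}
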