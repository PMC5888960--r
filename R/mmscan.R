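# Mixed-linear-model engine: y = X b + g + e, g ~ N(0, sigmaG2 K),
# e ~ N(0, sigmaE2 I).  REML over lambda = sigmaG2/sigmaE2 is profiled on
# the spectrum of K (one eigendecomposition, then 1-D optimization), the
# EMMA approach.  Per-marker tests are generalized least squares under the
# fitted covariance; P3D reuses the null-model variance components across
# markers, as TASSEL's MLM does by default.

# restricted log-likelihood at lambda, on rotated data (d = eigenvalues of K)
.remlObjective <- function(lambda, yt, Xt, d) {
  w <- 1 / (lambda * d + 1)
  fit <- lm.wfit(Xt, yt, w)
  p <- fit$rank
  n <- length(yt)
  rss <- sum(w * fit$residuals^2)
  s2 <- rss / (n - p)
  Xw <- Xt[, !is.na(fit$coefficients), drop = FALSE] * sqrt(w)
  ldXVX <- determinant(crossprod(Xw), logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(lambda * d + 1)) +
            as.numeric(ldXVX))
}

# eigendecomposition + PSD check of a kinship matrix
.kinshipSpectral <- function(K) {
  stopifnot_arg(is.matrix(K) && nrow(K) == ncol(K) &&
                  max(abs(K - t(K))) < 1e-8, "K must be a symmetric matrix")
  ed <- eigen(K, symmetric = TRUE)
  if (min(ed$values) < -1e-8 * max(abs(ed$values), 1))
    stop("kinship matrix is not positive semidefinite", call. = FALSE)
  ed$values <- pmax(ed$values, 0)
  ed
}

# full null fit keeping the spectral pieces for marker-test reuse
.fitNullSpectral <- function(y, X0, K, lambdaRange = c(1e-5, 1e5),
                             tol = 1e-8) {
  stopifnot_arg(is.numeric(y) && !anyNA(y), "y must be numeric without NA")
  if (var(y) == 0) stop("zero-variance response", call. = FALSE)
  n <- length(y)
  if (is.null(X0)) X0 <- matrix(1, n, 1)
  stopifnot_arg(nrow(X0) == n && nrow(K) == n, "dimensions must agree")
  ed <- .kinshipSpectral(K)
  U <- ed$vectors; d <- ed$values
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X0)
  obj <- function(loglam) .remlObjective(exp(loglam), yt, Xt, d)
  opt <- optimize(obj, log(lambdaRange), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, log(lambdaRange))
  vals <- c(opt$objective, obj(log(lambdaRange[1])), obj(log(lambdaRange[2])))
  loglam <- cand[which.max(vals)]
  lambda <- exp(loglam)
  w <- 1 / (lambda * d + 1)
  fit <- lm.wfit(Xt, yt, w)
  p <- fit$rank
  s2 <- sum(w * fit$residuals^2) / (n - p)
  vc <- structure(list(lambda = lambda, sigmaG2 = lambda * s2, sigmaE2 = s2,
                       logREML = max(vals), n = n, p = p),
                  class = "VarianceComponents")
  list(vc = vc, U = U, d = d, yt = yt, X0t = Xt, w = w,
       rss0 = sum(w * fit$residuals^2), rank0 = p)
}

#' Fit the null mixed model by REML
#'
#' Estimates the polygenic and residual variance components of the model
#' without any marker term, profiling the restricted likelihood over
#' \eqn{\lambda = \sigma^2_g/\sigma^2_e} on the spectrum of the kinship
#' matrix: one eigendecomposition of K followed by one-dimensional
#' maximization of the profiled REML objective on the log scale over
#' `lambdaRange` (boundary values are also checked, so \eqn{\hat\lambda}
#' can sit at the no-polygenic-variance edge).
#'
#' @param y numeric response (per-line trait means), no missing values.
#' @param X0 fixed-effect design matrix without the marker (default a
#'   column of ones); typically intercept + family dummies.
#' @param K kinship matrix, symmetric positive semidefinite.
#' @param lambdaRange search interval for \eqn{\lambda}.
#' @param tol convergence tolerance of the 1-D optimization (log scale).
#' @return a `VarianceComponents` list: `lambda`, `sigmaG2`, `sigmaE2`,
#'   `logREML`, `n`, `p`.
#' @export
fitNullREML <- function(y, X0 = NULL, K, lambdaRange = c(1e-5, 1e5),
                        tol = 1e-8) {
  .fitNullSpectral(y, X0, K, lambdaRange, tol)$vc
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat(sprintf("VarianceComponents: sigmaG2 = %.4g, sigmaE2 = %.4g, lambda = %.4g (n = %d)\n",
              x$sigmaG2, x$sigmaE2, x$lambda, x$n))
  invisible(x)
}

# marker design columns for one marker; class coding uses the
# recurrent-parent homozygote (code 0) as reference level
.markerDesign <- function(g, coding = "class") {
  if (coding == "additive") {
    m <- cbind(dose = g / 2)
  } else {
    m <- cbind(HvHs = as.numeric(g == 1), HsHs = as.numeric(g == 2))
    m <- m[, colSums(m) > 0, drop = FALSE]
  }
  m
}

# GLS F-test of the extra columns in Xadd given whitened (rotated+weighted)
# data; returns effects, F, dfs, p
.glsMarkerTest <- function(X0w, Xaddw, yw, rss0, rank0) {
  n <- length(yw)
  if (is.null(Xaddw) || ncol(Xaddw) == 0)
    return(list(coef = numeric(0), F = NA_real_, df1 = 0L,
                df2 = n - rank0, p = NA_real_))
  fit <- lm.fit(cbind(X0w, Xaddw), yw)
  rss1 <- sum(fit$residuals^2)
  df1 <- fit$rank - rank0
  df2 <- n - fit$rank
  if (df1 <= 0 || df2 <= 0)
    return(list(coef = fit$coefficients, F = NA_real_, df1 = df1,
                df2 = df2, p = NA_real_))
  Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
  Fst <- max(Fst, 0)
  p <- pf(Fst, df1, df2, lower.tail = FALSE)
  cf <- fit$coefficients[seq(ncol(X0w) + 1, length.out = ncol(Xaddw))]
  list(coef = cf, F = Fst, df1 = df1, df2 = df2, p = min(max(p, 1e-300), 1))
}

#' Test one marker under the fitted mixed model
#'
#' Generalized least squares under \eqn{V = \sigma^2_g K + \sigma^2_e I}
#' with the variance components taken from `vc` (P3D). The marker enters as
#' a genotype-class factor with the recurrent-parent homozygote as reference
#' level; the reported p-value is the joint F-test of the marker-class
#' contrasts (2 df when all three classes are present). Lines with a missing
#' genotype at the marker are dropped. Markers monomorphic in the tested
#' subset get a missing p-value.
#'
#' @param y numeric response, one value per line (NA allowed; dropped).
#' @param X0 fixed-effect design without the marker (rows = lines).
#' @param g genotype codes 0/1/2/NA at the marker.
#' @param K kinship matrix over the same lines.
#' @param vc `VarianceComponents` from [fitNullREML()].
#' @param coding `"class"` (3-level factor, joint 2-df test) or
#'   `"additive"` (allele dose, 1-df test).
#' @return one-row data.frame: `effectHsHs`, `effectHvHs`, `Fstat`, `df1`,
#'   `df2`, `p`, `n`.
#' @export
testMarker <- function(y, X0 = NULL, g, K, vc, coding = c("class", "additive")) {
  coding <- match.arg(coding)
  n0 <- length(y)
  if (is.null(X0)) X0 <- matrix(1, n0, 1)
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  X0 <- X0[keep, , drop = FALSE]
  Ks <- K[keep, keep, drop = FALSE]
  V <- vc$lambda * Ks + diag(length(y))
  R <- chol(V)
  wh <- function(M) backsolve(R, M, transpose = TRUE)
  yw <- wh(y); X0w <- wh(X0)
  f0 <- lm.fit(X0w, yw)
  D <- .markerDesign(g, coding)
  Dw <- NULL
  if (ncol(D)) {
    Dw <- wh(D)
    colnames(Dw) <- colnames(D)   # backsolve drops dimnames
  }
  res <- .glsMarkerTest(X0w, Dw, yw, sum(f0$residuals^2), f0$rank)
  .markerRow(res, D, coding, length(y))
}

# assemble the standard per-marker result row from a GLS test
.markerRow <- function(res, D, coding, n) {
  effHsHs <- effHvHs <- NA_real_
  if (length(res$coef)) {
    if (coding == "additive") {
      effHsHs <- 2 * res$coef[["dose"]]
      effHvHs <- res$coef[["dose"]]
    } else {
      if ("HsHs" %in% colnames(D)) effHsHs <- res$coef[["HsHs"]]
      if ("HvHs" %in% colnames(D)) effHvHs <- res$coef[["HvHs"]]
    }
  }
  data.frame(effectHsHs = unname(effHsHs), effectHvHs = unname(effHvHs),
             Fstat = res$F, df1 = res$df1, df2 = res$df2, p = res$p, n = n)
}

# per-line response vector for one trait/environment from a long phenotype
# table (averaging years if present); named by line id
.responseVector <- function(phenos, trait, environment) {
  sub <- phenos[phenos$trait == trait & phenos$environment == environment, ,
                drop = FALSE]
  stopifnot_arg(nrow(sub) > 0,
                sprintf("no records for trait %s in environment %s", trait,
                        environment))
  v <- tapply(sub$value, sub$line, mean, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

#' Genome scan for a trait per se in one environment
#'
#' The per-environment mixed-model association scan: response is the
#' per-line (year-averaged) trait value in the given environment; fixed
#' effects are the intercept and family dummies; the polygenic random
#' effect has covariance proportional to the kinship matrix. Variance
#' components are estimated once on the null model and reused for every
#' marker (P3D); `exact = TRUE` re-estimates \eqn{\lambda} per marker
#' instead. Each marker is tested as a genotype-class factor with a joint
#' F-test; effects are reported relative to the recurrent-parent
#' homozygote.
#'
#' @param pop a [NamPopulation-class] (after [filterMarkers()]).
#' @param phenos long phenotype table (ideally adjusted line means).
#' @param trait trait name.
#' @param environment `"WW"` or `"WL"`.
#' @param kinship optional precomputed kinship; defaults to
#'   [computeKinship()] on `pop`.
#' @param markers optional character vector restricting the scan.
#' @param coding marker coding, `"class"` or `"additive"`.
#' @param exact logical; exact per-marker REML instead of P3D.
#' @return a [ScanResult-class].
#' @export
scanPerSe <- function(pop, phenos, trait, environment, kinship = NULL,
                      markers = NULL, coding = c("class", "additive"),
                      exact = FALSE) {
  coding <- match.arg(coding)
  checkPhenotypeTable(phenos)
  stopifnot_arg(environment %in% ENVS, "environment must be WW or WL")
  if (is.null(kinship)) kinship <- computeKinship(pop)
  y0 <- .responseVector(phenos, trait, environment)
  lines <- intersect(lineIds(pop), names(y0)[!is.na(y0)])
  stopifnot_arg(length(lines) >= 10, "too few phenotyped lines")
  y <- as.numeric(y0[lines])
  idx <- match(lines, lineIds(pop))
  fam <- droplevels(families(pop)[idx])
  X0 <- if (nlevels(fam) > 1) stats::model.matrix(~fam) else
    matrix(1, length(y), 1)
  K <- kinship[lines, lines]
  G <- genotypes(pop)[idx, , drop = FALSE]
  if (!is.null(markers)) {
    stopifnot_arg(all(markers %in% colnames(G)), "unknown marker requested")
    G <- G[, markers, drop = FALSE]
  }
  ns <- .fitNullSpectral(y, X0, K)
  tab <- .scanMarkers(ns, G, K, X0, y, coding, exact)
  mp <- pop@map[match(colnames(G), pop@map$marker), ]
  tab <- data.frame(marker = colnames(G), chrom = mp$chrom, pos = mp$pos,
                    tab, stringsAsFactors = FALSE, row.names = NULL)
  new("ScanResult", table = tab, trait = trait, environment = environment,
      model = "per-se")
}

# scan all columns of G; rotated fast path for complete markers, Cholesky
# fallback (or exact refit) otherwise
.scanMarkers <- function(ns, G, K, X0, y, coding, exact) {
  n <- length(y)
  sw <- sqrt(ns$w)
  X0w <- ns$X0t * sw
  yw <- ns$yt * sw
  rows <- vector("list", ncol(G))
  complete <- colSums(is.na(G)) == 0
  vc <- ns$vc
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    if (exact) {
      rows[[j]] <- .exactMarkerTest(y, X0, g, K, coding)
    } else if (complete[j]) {
      D <- .markerDesign(g, coding)
      Dw <- if (ncol(D)) crossprod(ns$U, D) * sw else NULL
      res <- .glsMarkerTest(X0w, Dw, yw, ns$rss0, ns$rank0)
      rows[[j]] <- .markerRow(res, D, coding, n)
    } else {
      rows[[j]] <- testMarker(y, X0, g, K, vc, coding)
    }
  }
  do.call(rbind, rows)
}

# exact refit: lambda re-optimized with the marker in the fixed effects;
# test is the REML-ratio-free GLS F-test at the marker-specific lambda
.exactMarkerTest <- function(y, X0, g, K, coding) {
  keep <- !is.na(y) & !is.na(g)
  ys <- y[keep]; gs <- g[keep]
  X0s <- X0[keep, , drop = FALSE]
  Ks <- K[keep, keep, drop = FALSE]
  D <- .markerDesign(gs, coding)
  if (ncol(D) == 0)
    return(data.frame(effectHsHs = NA_real_, effectHvHs = NA_real_,
                      Fstat = NA_real_, df1 = 0L, df2 = length(ys),
                      p = NA_real_, n = length(ys)))
  ns <- .fitNullSpectral(ys, cbind(X0s, D), Ks)
  vc <- ns$vc
  testMarker(ys, X0s, gs, Ks, vc, coding)
}
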