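# dense-matrix REML oracle, independent of the spectral engine
denseREML <- function(lambda, y, X, K) {
  n <- length(y); p <- qr(X)$rank
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * s2) + (n - p) +
                       determinant(V)$modulus + determinant(XVX)$modulus))
}

randomPSD <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  K <- tcrossprod(A) / n
  K / mean(diag(K))
}

test_that("REML engine matches a dense grid-search oracle on small instances", {
  for (seed in c(2, 9, 31)) {
    n <- 12
    K <- randomPSD(n, seed)
    set.seed(seed + 1)
    X <- cbind(1, rnorm(n))
    y <- drop(X %*% c(2, 1)) +
      drop(chol(K + diag(1e-10, n)) %*% rnorm(n)) + rnorm(n, 0, 0.8)
    vc <- fitNullREML(y, X, K)
    grid <- exp(seq(log(1e-5), log(1e5), length.out = 10000))
    gv <- vapply(grid, function(l) denseREML(l, y, X, K), numeric(1))
    expect_gte(vc$logREML, max(gv) - 1e-6)
    expect_equal(vc$logREML, denseREML(vc$lambda, y, X, K), tolerance = 1e-8)
  }
})

test_that("REML attributes (almost) no variance to kinship under a pure-noise model", {
  # at a true zero variance component the REML estimate is a boundary/
  # half-normal mixture, so smallness is asserted across replicates
  n <- 500
  K <- randomPSD(n, 4)
  h2hat <- lam <- numeric(5)
  for (i in 1:5) {
    set.seed(500 + i)
    y <- rnorm(n, 10, 2)   # no polygenic signal
    vc <- fitNullREML(y, NULL, K)
    lam[i] <- vc$lambda
    h2hat[i] <- vc$sigmaG2 / (vc$sigmaG2 + vc$sigmaE2)
    expect_equal(vc$sigmaG2 + vc$sigmaE2, var(y), tolerance = 0.1)
  }
  expect_lt(median(lam), 0.05)
  expect_true(all(h2hat < 0.15))
  expect_true(any(lam < 1e-3))   # boundary is reachable
})

test_that("identity kinship reduces the engine to the ordinary linear model", {
  set.seed(7)
  n <- 120
  g <- sample(0:2, n, TRUE)
  fam <- factor(rep(c("A", "B"), each = n / 2))
  X0 <- model.matrix(~fam)
  y <- rnorm(n) + 0.8 * (g == 2) + 0.3 * (fam == "B")
  vc <- fitNullREML(y, X0, diag(n))
  # with K = I the covariance is a multiple of I: GLS == OLS exactly
  row <- testMarker(y, X0, g, diag(n), vc)
  f1 <- lm(y ~ fam + factor(g))
  f0 <- lm(y ~ fam)
  an <- anova(f0, f1)
  expect_equal(row$Fstat, an$F[2], tolerance = 1e-8)
  expect_equal(row$p, an$`Pr(>F)`[2], tolerance = 1e-8)
  expect_equal(row$effectHsHs, unname(coef(f1)["factor(g)2"]), tolerance = 1e-8)
  expect_equal(row$effectHvHs, unname(coef(f1)["factor(g)1"]), tolerance = 1e-8)
})

test_that("REML rejects degenerate inputs", {
  expect_error(fitNullREML(rep(1, 10), NULL, diag(10)), "zero-variance")
  Kbad <- diag(10); Kbad[1, 1] <- -2
  expect_error(fitNullREML(rnorm(10), NULL, Kbad), "positive semidefinite")
})

# per-line WW response for a scanScenario, aligned to pop line order
.rowResponse <- function(sc) {
  ww <- sc$phenos[sc$phenos$environment == "WW", ]
  as.numeric(ww$value[match(lineIds(sc$pop), ww$line)])
}

test_that("marker tests drop missing lines and flag monomorphic markers", {
  sc <- scanScenario(seed = 21, effect = 6)
  y <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K,
                           markers = sc$causal))
  expect_equal(y$n, nLines(sc$pop))
  g <- genotypes(sc$pop)[, sc$causal]
  g[1:10] <- NA
  vc <- fitNullREML(.rowResponse(sc), NULL, sc$K)
  row <- testMarker(.rowResponse(sc), NULL, g, sc$K, vc)
  expect_equal(row$n, nLines(sc$pop) - 10)
  mono <- rep(0L, nLines(sc$pop))
  rowM <- testMarker(.rowResponse(sc), NULL, mono, sc$K, vc)
  expect_true(is.na(rowM$p))
  expect_equal(rowM$df1, 0L)
})

test_that("a strong simulated QTL is the genome-wide minimum p", {
  sc <- scanScenario(seed = 33, effect = 6, residSD = 2)
  res <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K))
  expect_equal(res$marker[which.min(res$p)], sc$causal)
  # effect estimated near truth and positive for the high-mean class
  row <- res[res$marker == sc$causal, ]
  expect_equal(row$effectHsHs, 6, tolerance = 1.5)
  expect_gt(row$effectHsHs, 0)
})

test_that("an additive effect is recovered within its confidence interval", {
  sc <- scanScenario(seed = 55, nFam = 10, linesPerFam = 100, nMarkers = 20,
                     effect = 5, residSD = 3)
  res <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K,
                             markers = sc$causal))
  # rough CI: +-2 SE with SE inferred from the F statistic scale
  expect_equal(res$effectHsHs, 5, tolerance = 1.2)
})

test_that("scan statistics are invariant to a consistent permutation of lines", {
  sc <- scanScenario(seed = 13, effect = 4)
  res1 <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K))
  set.seed(99)
  perm <- sample(nLines(sc$pop))
  pop2 <- new("NamPopulation", geno = genotypes(sc$pop)[perm, ],
              family = families(sc$pop)[perm], map = linkageMap(sc$pop))
  res2 <- scanTable(scanPerSe(pop2, sc$phenos, "T", "WW",
                              kinship = sc$K[perm, perm]))
  expect_equal(res2$p, res1$p, tolerance = 1e-6)
  expect_equal(res2$effectHsHs, res1$effectHsHs, tolerance = 1e-6)
})

test_that("identical phenotypes give identical scans in both environments", {
  sc <- scanScenario(seed = 17)
  ww <- sc$phenos[sc$phenos$environment == "WW", ]
  wl <- ww; wl$environment <- "WL"
  both <- rbind(ww, wl)
  r1 <- scanTable(scanPerSe(sc$pop, both, "T", "WW", kinship = sc$K))
  r2 <- scanTable(scanPerSe(sc$pop, both, "T", "WL", kinship = sc$K))
  expect_identical(r1, r2)
})

test_that("P3D approximates the exact per-marker refit closely off the QTL", {
  # under a polygenic architecture with no single large-effect locus the
  # null-model variance components transfer to every marker
  sc <- scanScenario(seed = 71, nFam = 10, linesPerFam = 50, nMarkers = 50,
                     effect = 0, residSD = 3)
  p3d <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K))
  exact <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K,
                               exact = TRUE))
  ok <- !is.na(p3d$p) & !is.na(exact$p) & p3d$p > 1e-8
  expect_gt(sum(ok), 40)
  d <- abs(log10(p3d$p[ok]) - log10(exact$p[ok]))
  # the approximation is tight for the bulk of markers; the rare marker
  # that itself soaks up polygenic variance deviates more, and there the
  # reused (larger) lambda can only understate the signal
  expect_lt(quantile(d, 0.9), 0.2)
  big <- which(d > 0.2)
  expect_true(all(p3d$p[ok][big] > exact$p[ok][big]))
})

test_that("at a strong QTL the P3D approximation errs on the conservative side", {
  sc <- scanScenario(seed = 72, nFam = 10, linesPerFam = 50, nMarkers = 30,
                     effect = 3, residSD = 3)
  p3d <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K,
                             markers = sc$causal))
  exact <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K,
                               markers = sc$causal, exact = TRUE))
  # the null fit absorbs part of the QTL effect into the polygenic term,
  # so reusing it can only understate the marker signal
  expect_gte(p3d$p, exact$p * 0.99)
})

test_that("additive coding gives a 1-df test with consistent effects", {
  sc <- scanScenario(seed = 81, effect = 5)
  res <- scanTable(scanPerSe(sc$pop, sc$phenos, "T", "WW", kinship = sc$K,
                             markers = sc$causal, coding = "additive"))
  expect_equal(res$df1, 1L)
  expect_equal(res$effectHsHs, 2 * res$effectHvHs)
})
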