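test_that("a WL-only effect produces a strong interaction signal", {
  sc <- scanScenario(seed = 41, qxe = 5, residSD = 2)
  res <- scanTable(scanQxE(sc$pop, sc$phenos, "T", kinship = sc$K))
  row <- res[res$marker == sc$causal, ]
  expect_equal(res$marker[which.min(res$p)], sc$causal)
  expect_lt(abs(row$effWW_HsHs), 1.5)
  expect_equal(row$effWL_HsHs, 5, tolerance = 1.5)
})

test_that("swapping environment labels preserves the interaction test", {
  sc <- scanScenario(seed = 43, qxe = 4)
  swapped <- sc$phenos
  swapped$environment <- ifelse(swapped$environment == "WW", "WL", "WW")
  r1 <- scanTable(scanQxE(sc$pop, sc$phenos, "T", kinship = sc$K))
  r2 <- scanTable(scanQxE(sc$pop, swapped, "T", kinship = sc$K))
  expect_equal(r2$p, r1$p, tolerance = 1e-6)
  expect_equal(r2$effWW_HsHs, r1$effWL_HsHs, tolerance = 1e-6)
  expect_equal(r2$effWL_HsHs, r1$effWW_HsHs, tolerance = 1e-6)
})

test_that("single-environment input is rejected with a pointer to the per-se scan", {
  sc <- scanScenario(seed = 45)
  ww <- sc$phenos[sc$phenos$environment == "WW", ]
  expect_error(scanQxE(sc$pop, ww, "T", kinship = sc$K), "scanPerSe")
})

test_that("markers with missing genotypes are tested on the reduced line set", {
  sc <- scanScenario(seed = 47, qxe = 5)
  g <- genotypes(sc$pop)
  g[1:6, sc$causal] <- NA
  pop2 <- new("NamPopulation", geno = g, family = families(sc$pop),
              map = linkageMap(sc$pop))
  res <- scanTable(scanQxE(pop2, sc$phenos, "T", kinship = sc$K,
                           markers = sc$causal))
  expect_equal(res$n, nLines(sc$pop) - 6)
  expect_lt(res$p, 1e-4)
})

test_that("cross-validation is deterministic, stratified and bounded", {
  sc <- scanScenario(seed = 49, qxe = 6, residSD = 2)
  cv1 <- crossval(sc$pop, sc$phenos, "T", model = "qxe", replicates = 8,
                  seed = 3, markers = sc$causal, kinship = sc$K)
  cv2 <- crossval(sc$pop, sc$phenos, "T", model = "qxe", replicates = 8,
                  seed = 3, markers = sc$causal, kinship = sc$K)
  expect_identical(scanTable(cv1), scanTable(cv2))
  t1 <- scanTable(cv1)
  expect_equal(t1$rate, t1$detections / t1$replicates)
  expect_true(all(t1$accepted == (t1$rate >= 0.30)))
  expect_error(crossval(sc$pop, sc$phenos, "T", fraction = 1.2,
                        environment = "WW"), "fraction")
})

test_that("an overwhelming effect is detected in every subsample", {
  sc <- scanScenario(seed = 51, effect = 30, residSD = 1)
  cv <- crossval(sc$pop, sc$phenos, "T", model = "per-se",
                 environment = "WW", replicates = 6, seed = 2,
                 markers = sc$causal, kinship = sc$K)
  expect_equal(scanTable(cv)$rate, 1.0)
  expect_true(scanTable(cv)$accepted)
})

test_that("subsampling draws ceiling(fraction * n) lines within every family", {
  map <- generateMap(1, 50, 5, seed = 1)
  pop <- simulatePopulation(map, 3, 9, seed = 1, missingRate = 0)
  fams <- families(pop)
  set.seed(31)
  ph <- phenoRecords(lineIds(pop), rnorm(27, 10),
                     family = as.character(fams))
  for (frac in c(0.5, 0.7)) {
    cv <- crossval(pop, ph, "T", model = "per-se", environment = "WW",
                   replicates = 3, fraction = frac, seed = 5,
                   markers = markerIds(pop)[1], keepDraws = TRUE)
    draws <- cv@params$draws
    expect_length(draws, 3)
    for (d in draws) {
      counts <- table(families(pop)[match(d, lineIds(pop))])
      expect_true(all(counts == ceiling(frac * table(fams))))
      expect_false(anyDuplicated(d) > 0)   # without replacement
    }
    # detection rate is order-invariant: a permutation-equivalent recount
    t1 <- scanTable(cv)
    expect_equal(t1$rate, t1$detections / t1$replicates)
  }
})

test_that("window peaks tile half-open 5-cM windows with deterministic ties", {
  tab <- data.frame(
    marker = c("a", "b", "c", "d", "e"),
    chrom = c(1, 1, 1, 1, 2),
    pos = c(1, 4.999, 5.0, 9.5, 54.2),
    p = c(1e-3, 1e-8, 1e-4, 1e-2, 1e-5))
  wp <- windowPeaks(tab, windowCM = 5)
  w1 <- wp[wp$chrom == 1 & wp$windowStart == 0, ]
  expect_equal(w1$peakMarker, "b")     # 4.999 still in [0, 5)
  expect_equal(w1$nMarkers, 2)
  w2 <- wp[wp$chrom == 1 & wp$windowStart == 5, ]
  expect_equal(w2$peakMarker, "c")     # 5.0 opens the next window
  expect_equal(wp[wp$chrom == 2, "windowStart"], 50)
  # ties: equal p broken by lower cM then marker id
  tie <- data.frame(marker = c("z", "y"), chrom = 1, pos = c(2, 1),
                    p = c(1e-4, 1e-4))
  expect_equal(windowPeaks(tie)$peakMarker, "y")
  tie2 <- data.frame(marker = c("z", "y"), chrom = 1, pos = c(2, 2),
                     p = c(1e-4, 1e-4))
  expect_equal(windowPeaks(tie2)$peakMarker, "y")
})

test_that("reaction norms equal raw class means for balanced single-family data", {
  g <- matrix(rep(c(0L, 1L, 2L), each = 20), ncol = 1)
  pop <- popFromMatrix(g)
  set.seed(6)
  vals <- c(outer(rep(10, 60) + rep(c(0, 1, 3), each = 20), c(0, -2), `+`)) +
    rnorm(120, 0, 0.01)
  ph <- rbind(phenoRecords(rep(lineIds(pop), 1), vals[1:60], environment = "WW"),
              phenoRecords(rep(lineIds(pop), 1), vals[61:120], environment = "WL"))
  rn <- reactionNorms(pop, ph, "m01", "T")
  raw <- tapply(vals, list(rep(c("HvHv", "HvHs", "HsHs")[g + 1], 2),
                           rep(c("WW", "WL"), each = 60)), mean)
  for (i in seq_len(nrow(rn)))
    expect_equal(rn$lsmean[i], raw[rn$genotype[i], rn$environment[i]],
                 tolerance = 1e-6)
})

test_that("a WL-protective wild allele flattens the carrier reaction norm", {
  sc <- scanScenario(seed = 61, qxe = 5, residSD = 2)
  # envEffect -4: non-carriers drop by 4, homozygous carriers by 4 - 5
  rn <- reactionNorms(sc$pop, sc$phenos, sc$causal, "T")
  drop0 <- rn$lsmean[rn$genotype == "HvHv" & rn$environment == "WW"] -
    rn$lsmean[rn$genotype == "HvHv" & rn$environment == "WL"]
  drop2 <- rn$lsmean[rn$genotype == "HsHs" & rn$environment == "WW"] -
    rn$lsmean[rn$genotype == "HsHs" & rn$environment == "WL"]
  expect_gt(drop0, drop2)
})

test_that("a marker with no effect shows flat class means", {
  sc <- scanScenario(seed = 63, residSD = 1)
  rn <- reactionNorms(sc$pop, sc$phenos, sc$causal, "T")
  byEnv <- split(rn$lsmean, rn$environment)
  for (e in names(byEnv))
    expect_lt(diff(range(byEnv[[e]], na.rm = TRUE)), 1.5)
})
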