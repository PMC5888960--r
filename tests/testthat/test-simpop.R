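test_that("generateMap spaces and sorts markers as requested", {
  m <- generateMap(1, 100, 11, even = TRUE)
  expect_equal(m$pos, seq(0, 100, by = 10))
  m2 <- generateMap(7, 150, 5709, seed = 4)
  expect_equal(nrow(m2), 5709)
  expect_equal(sort(unique(m2$chrom)), 1:7)
  expect_true(all(unlist(tapply(m2$pos, m2$chrom, diff)) >= 0))
  expect_false(anyDuplicated(m2$marker) > 0)
  m3 <- generateMap(2, 50, 2)
  expect_equal(m3$chrom, 1:2)
  expect_error(generateMap(3, 50, 2), "nMarkers")
  expect_error(generateMap(1, 0, 5), "chromLength")
})

test_that("breeding-scheme genotype frequencies follow the exact Markov chain", {
  expect_equal(unname(expectedGenotypeFreqs(breedingScheme(0, 0))), c(0, 1, 0))
  # BC1S0: enumerate recurrent x F1 gametes by hand -> half Hv/Hv, half Hv/Hs
  expect_equal(unname(expectedGenotypeFreqs(breedingScheme(1, 0))),
               c(0.5, 0.5, 0))
  expect_equal(unname(expectedGenotypeFreqs(breedingScheme(1, 3))),
               c(0.71875, 0.0625, 0.21875))
  # heterozygosity halves per selfing; distributions always sum to 1
  for (s in 0:6) {
    f <- expectedGenotypeFreqs(breedingScheme(1, s))
    expect_equal(sum(f), 1)
    expect_equal(unname(f["HvHs"]), 0.5 * 0.5^s)
  }
  expect_error(breedingScheme(-1, 0), "backcrosses")
})

test_that("simulateFamily matches the Markov-chain expectation within 3 SE", {
  map1 <- data.frame(marker = "m1", chrom = 1L, pos = 0)
  fam <- simulateFamily("D1", 10000, breedingScheme(1, 3), map1, seed = 42)
  obs <- tabulate(fam$geno[, 1] + 1L, 3) / 10000
  expected <- c(0.71875, 0.0625, 0.21875)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(obs - expected) <= 3 * se))
})

test_that("zero map distance gives identical genotype codes", {
  map0 <- data.frame(marker = c("a", "b"), chrom = 1L, pos = c(25, 25))
  fam <- simulateFamily("D1", 500, breedingScheme(1, 3), map0, seed = 9)
  expect_identical(fam$geno[, 1], fam$geno[, 2])
  expect_equal(nrow(simulateFamily("D", 0, map = map0)$geno), 0)
  expect_error(simulateFamily("D", 5, map = data.frame()), "map")
})

test_that("linkage between markers decays with map distance", {
  map <- data.frame(marker = c("p0", "p5", "p25", "p60"), chrom = 1L,
                    pos = c(0, 5, 25, 60))
  cors <- rowMeans(sapply(1:4, function(r) {
    g <- simulateFamily("D", 1500, breedingScheme(1, 3), map, seed = r)$geno
    c(cor(g[, 1], g[, 2]), cor(g[, 1], g[, 3]), cor(g[, 1], g[, 4]))
  }))
  expect_true(cors[1] > cors[2])
  expect_true(cors[2] > cors[3])
})

test_that("population simulation is reproducible and family-structured", {
  map <- generateMap(2, 80, 30, seed = 5)
  p1 <- simulatePopulation(map, 4, 20, seed = 77)
  p2 <- simulatePopulation(map, 4, 20, seed = 77)
  expect_identical(genotypes(p1), genotypes(p2))
  expect_equal(nLines(p1), 80)
  expect_equal(nlevels(families(p1)), 4)
  expect_true(mean(is.na(genotypes(p1))) > 0)   # missing injected
  p3 <- simulatePopulation(map, 4, 20, seed = 78)
  expect_false(identical(genotypes(p1), genotypes(p3)))
})

test_that("phenotype generator reduces to the deterministic mean at zero noise", {
  pop <- popFromMatrix(matrix(rep(c(0L, 1L, 2L), 4), nrow = 4, byrow = TRUE),
                       family = c("F1", "F1", "F2", "F2"))
  arch <- architectureSpec("T", mu = 10, residSD = c(WW = 1e-12, WL = 1e-12))
  ph <- simulatePhenotypes(pop, arch, years = 1, seed = 1)
  expect_equal(ph$value, rep(10, nrow(ph)), tolerance = 1e-9)
  # causal marker absent -> error
  archBad <- architectureSpec("T", mu = 0,
    loci = data.frame(marker = "nope", effect = 1, dominant = FALSE, qxe = 0))
  expect_error(simulatePhenotypes(pop, archBad, years = 1, seed = 1), "absent")
})

test_that("a WL-only locus shifts carrier means only under WL", {
  set.seed(3)
  n <- 4000
  g <- matrix(sample(0:2, n, TRUE, prob = c(0.72, 0.06, 0.22)), ncol = 1)
  pop <- popFromMatrix(g)
  e <- 5
  arch <- architectureSpec("T", mu = 100,
    loci = data.frame(marker = "m01", effect = 0, dominant = FALSE, qxe = e),
    residSD = c(WW = 2, WL = 2))
  ph <- simulatePhenotypes(pop, arch, years = 1, seed = 8)
  gg <- genotypes(pop)[match(ph$line, lineIds(pop)), 1]
  dWW <- with(ph[ph$environment == "WW", ],
              mean(value[gg[ph$environment == "WW"] == 2]) -
                mean(value[gg[ph$environment == "WW"] == 0]))
  dWL <- with(ph[ph$environment == "WL", ],
              mean(value[gg[ph$environment == "WL"] == 2]) -
                mean(value[gg[ph$environment == "WL"] == 0]))
  expect_lt(abs(dWW), 0.5)
  expect_lt(abs(dWL - e), 0.5)
})

test_that("WL-inflated residual SD shows up as a larger coefficient of variation", {
  map <- generateMap(1, 50, 10, seed = 2)
  pop <- simulatePopulation(map, 3, 40, seed = 2, missingRate = 0)
  arch <- architectureSpec("T", mu = 50, residSD = c(WW = 2, WL = 4))
  ph <- simulatePhenotypes(pop, arch, years = 1, seed = 4)
  s <- summarizeTraits(ph)$stats
  expect_gt(s$cv[s$environment == "WL"], s$cv[s$environment == "WW"])
})

test_that("variance decomposition of large simulations recovers heritability", {
  # a single REML fit at n = 600 still carries sampling noise, so the
  # generative check averages the estimate over independent populations
  h2 <- 0.5
  hhat <- vapply(1:8, function(s) {
    map <- generateMap(3, 100, 150, seed = s)
    pop <- simulatePopulation(map, 10, 60, seed = s, missingRate = 0)
    K <- computeKinship(pop)
    arch <- architectureSpec("T", mu = 0, h2 = h2,
                             residSD = c(WW = 1, WL = 1))
    ph <- simulatePhenotypes(pop, arch, years = 1, kinship = K, seed = s + 7)
    ww <- ph[ph$environment == "WW", ]
    y <- as.numeric(ww$value[match(lineIds(pop), ww$line)])
    vc <- fitNullREML(y, NULL, K / mean(diag(K)))
    vc$sigmaG2 / (vc$sigmaG2 + vc$sigmaE2)
  }, numeric(1))
  expect_equal(mean(hhat), h2, tolerance = 0.05)
})
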