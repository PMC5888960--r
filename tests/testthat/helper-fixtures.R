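# Small in-code fixtures shared across tests.

# hand-built toy population: 3 lines, 2 families, 2 markers
toyPopulation <- function() {
  g <- matrix(c(0L, 0L,
                1L, 2L,
                2L, 2L), nrow = 3, byrow = TRUE,
              dimnames = list(c("L1", "L2", "L3"), c("mA", "mB")))
  new("NamPopulation", geno = g, family = factor(c("F1", "F1", "F2")),
      map = data.frame(marker = c("mA", "mB"), chrom = c(1L, 1L),
                       pos = c(0, 10), stringsAsFactors = FALSE))
}

# population from arbitrary genotype matrix on a 1-cM-spaced single chromosome
popFromMatrix <- function(g, family = NULL) {
  if (is.null(rownames(g))) rownames(g) <- sprintf("L%02d", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- sprintf("m%02d", seq_len(ncol(g)))
  if (is.null(family)) family <- rep("F1", nrow(g))
  storage.mode(g) <- "integer"
  new("NamPopulation", geno = g, family = factor(family),
      map = data.frame(marker = colnames(g), chrom = 1L,
                       pos = seq(0, by = 1, length.out = ncol(g)),
                       stringsAsFactors = FALSE))
}

# long phenotype records for given values, one trait
phenoRecords <- function(lines, values, trait = "T", year = 1,
                         environment = "WW", family = "F1") {
  data.frame(line = lines, family = family, year = year,
             environment = environment, trait = trait, value = values,
             stringsAsFactors = FALSE)
}

# medium simulated scenario reused by several scan tests
scanScenario <- function(seed = 11, nFam = 8, linesPerFam = 30, nMarkers = 60,
                         qxe = 0, effect = 0, h2 = 0.3, residSD = 3,
                         years = 1, causalIndex = 5) {
  map <- generateMap(3, 120, nMarkers, seed = seed)
  pop <- simulatePopulation(map, nFamilies = nFam,
                            linesPerFamily = linesPerFam, seed = seed,
                            missingRate = 0, donorPolymorphicProb = 1)
  K <- computeKinship(pop)
  causal <- markerIds(pop)[causalIndex]
  arch <- architectureSpec("T", mu = 50,
                           familyEffects = seq_len(nFam) - mean(seq_len(nFam)),
                           loci = data.frame(marker = causal, effect = effect,
                                             dominant = FALSE, qxe = qxe),
                           h2 = h2, envEffect = -4,
                           residSD = c(WW = residSD, WL = residSD))
  ph <- simulatePhenotypes(pop, arch, years = years, kinship = K,
                           seed = seed + 1)
  list(pop = pop, K = K, phenos = ph, causal = causal)
}
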