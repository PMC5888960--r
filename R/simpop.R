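#' Breeding scheme for a backcross-selfing population
#'
#' Number of backcrosses to the recurrent parent and of subsequent selfing
#' generations. The default, one backcross and three selfings, is the BC1S3
#' design of NAM panels derived from wild x elite crosses.
#'
#' @param backcrosses non-negative integer count of backcrosses to the
#'   recurrent parent after the F1.
#' @param selfings non-negative integer count of selfing generations.
#' @return a `BreedingScheme` (list with `backcrosses`, `selfings`).
#' @examples
#' breedingScheme()           # BC1S3
#' breedingScheme(0, 0)       # the F1 itself
#' @export
breedingScheme <- function(backcrosses = 1L, selfings = 3L) {
  stopifnot_arg(length(backcrosses) == 1 && backcrosses >= 0 &&
                backcrosses == round(backcrosses), "backcrosses must be a count >= 0")
  stopifnot_arg(length(selfings) == 1 && selfings >= 0 &&
                selfings == round(selfings), "selfings must be a count >= 0")
  structure(list(backcrosses = as.integer(backcrosses),
                 selfings = as.integer(selfings)),
            class = "BreedingScheme")
}

#' Generate a genetic map
#'
#' Places markers on chromosomes of equal genetic length. By default marker
#' positions are uniform random draws (sorted within chromosome); with
#' `even = TRUE` markers are evenly spaced from 0 to `chromLength`,
#' inclusive. Markers are distributed over chromosomes as evenly as counts
#' allow and the result is sorted by (chromosome, position).
#'
#' @param nChromosomes number of chromosomes (7 for barley).
#' @param chromLength genetic length of each chromosome, cM.
#' @param nMarkers total marker count (>= `nChromosomes`).
#' @param seed integer seed for the random placement.
#' @param even logical; evenly spaced positions instead of random ones.
#' @return data.frame with columns `marker`, `chrom`, `pos`.
#' @examples
#' generateMap(1, 100, 11, even = TRUE)$pos  # 0, 10, ..., 100
#' @export
generateMap <- function(nChromosomes, chromLength, nMarkers, seed = 1L,
                        even = FALSE) {
  stopifnot_arg(nChromosomes >= 1 && nMarkers >= nChromosomes,
                "need nMarkers >= nChromosomes >= 1")
  stopifnot_arg(chromLength > 0, "chromLength must be > 0")
  perChrom <- rep(nMarkers %/% nChromosomes, nChromosomes)
  extra <- nMarkers %% nChromosomes
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  set.seed(deriveSeed(seed, 101))
  rows <- lapply(seq_len(nChromosomes), function(ch) {
    k <- perChrom[ch]
    pos <- if (even) {
      if (k == 1) chromLength / 2 else seq(0, chromLength, length.out = k)
    } else sort(runif(k, 0, chromLength))
    data.frame(chrom = ch, pos = pos)
  })
  map <- do.call(rbind, rows)
  map <- data.frame(marker = sprintf("M%02d_%05d", map$chrom,
                                     unlist(lapply(perChrom, seq_len))),
                    chrom = as.integer(map$chrom), pos = map$pos,
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  map
}

#' Expected genotype frequencies under a breeding scheme
#'
#' Exact single-locus genotype distribution of a line derived by the given
#' crossing scheme, obtained by Markov-chain enumeration over the genotype
#' states \{Hv/Hv, Hv/Hs, Hs/Hs\}. The F1 is fully heterozygous; a backcross
#' to the recurrent parent maps Hv/Hs to (1/2, 1/2, 0) and Hs/Hs to Hv/Hs; a
#' selfing maps Hv/Hs to (1/4, 1/2, 1/4).
#'
#' @param scheme a [breedingScheme()].
#' @return named numeric `c(HvHv, HvHs, HsHs)` summing to 1.
#' @examples
#' expectedGenotypeFreqs(breedingScheme(1, 3))  # 0.71875 0.0625 0.21875
#' @export
expectedGenotypeFreqs <- function(scheme = breedingScheme()) {
  stopifnot_arg(inherits(scheme, "BreedingScheme"), "scheme must be a BreedingScheme")
  p <- c(HvHv = 0, HvHs = 1, HsHs = 0)   # F1
  bc <- matrix(c(1, 0, 0,  0.5, 0.5, 0,  0, 1, 0), 3, 3, byrow = TRUE)
  sf <- matrix(c(1, 0, 0,  0.25, 0.5, 0.25,  0, 0, 1), 3, 3, byrow = TRUE)
  for (i in seq_len(scheme$backcrosses)) p <- drop(p %*% bc)
  for (i in seq_len(scheme$selfings))    p <- drop(p %*% sf)
  names(p) <- c("HvHv", "HvHs", "HsHs")
  p
}

# Haldane map function: cM distance -> recombination fraction (no interference)
haldane <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# Per-marker recombination fraction with the previous map marker;
# 0.5 at the first marker of each chromosome (independent assortment).
mapRecFracs <- function(map) {
  r <- rep(0.5, nrow(map))
  if (nrow(map) > 1) {
    same <- map$chrom[-1] == map$chrom[-nrow(map)]
    d <- map$pos[-1] - map$pos[-nrow(map)]
    r[-1][same] <- haldane(d[same])
  }
  r
}

# One gamete per line from a diploid parent given as two haplotype matrices
# (nLines x nMarkers, entries 0/1 = Hv/Hs). Crossovers between adjacent
# markers occur independently with the Haldane recombination fraction.
.gamete <- function(hapA, hapB, recFracs) {
  n <- nrow(hapA); m <- ncol(hapA)
  choice <- matrix(0L, n, m)
  cur <- as.integer(runif(n) < 0.5)
  choice[, 1] <- cur
  if (m > 1) for (j in 2:m) {
    sw <- runif(n) < recFracs[j]
    cur <- ifelse(sw, 1L - cur, cur)
    choice[, j] <- cur
  }
  choice * hapB + (1L - choice) * hapA
}

#' Simulate one NAM family by gamete-level simulation
#'
#' Breeds `nLines` independent lines from a cross between the recurrent
#' parent (all-Hv) and a wild donor, following the backcross/selfing scheme.
#' Recombination between adjacent markers uses the Haldane map function on
#' map distances; crossover interference is ignored. Markers where the donor
#' carries the recurrent-parent allele (`donorCarriesWild` = 0/FALSE) come out
#' monomorphic Hv/Hv in the family, emulating loci that are uninformative in
#' a given cross.
#'
#' @param donor family identifier (used as label).
#' @param nLines number of lines to breed (0 gives an empty fragment).
#' @param scheme a [breedingScheme()].
#' @param map genetic map data.frame (`marker`, `chrom`, `pos`), sorted.
#' @param seed integer seed.
#' @param donorCarriesWild logical/0-1 vector per marker; default all TRUE.
#' @return list with `geno` (nLines x nMarkers integer matrix, codes 0/1/2),
#'   `family` (label vector), `map`.
#' @export
simulateFamily <- function(donor, nLines, scheme = breedingScheme(), map,
                           seed = 1L, donorCarriesWild = NULL) {
  stopifnot_arg(is.data.frame(map) && nrow(map) > 0, "map must be non-empty")
  m <- nrow(map)
  if (is.null(donorCarriesWild)) donorCarriesWild <- rep(1L, m)
  stopifnot_arg(length(donorCarriesWild) == m,
                "donorCarriesWild must have one entry per marker")
  mask <- as.integer(donorCarriesWild != 0)
  geno <- matrix(integer(0), 0, m)
  if (nLines > 0) {
    set.seed(deriveSeed(seed, 211, nLines))
    r <- mapRecFracs(map)
    ones <- matrix(1L, nLines, m); zeros <- matrix(0L, nLines, m)
    # F1 is (donor haplotype, recurrent haplotype); each backcross keeps one
    # F-derived gamete against a fresh recurrent gamete.
    h1 <- ones; h2 <- zeros
    for (b in seq_len(scheme$backcrosses)) {
      h1 <- .gamete(h1, h2, r)
      h2 <- zeros
    }
    for (s in seq_len(scheme$selfings)) {
      n1 <- .gamete(h1, h2, r)
      n2 <- .gamete(h1, h2, r)
      h1 <- n1; h2 <- n2
    }
    geno <- (h1 + h2) * rep(mask, each = nLines)
    storage.mode(geno) <- "integer"
  }
  colnames(geno) <- as.character(map$marker)
  list(geno = geno, family = rep(as.character(donor), nLines), map = map)
}

#' Simulate a complete NAM population
#'
#' Breeds `nFamilies` families of `linesPerFamily` lines each from a common
#' recurrent parent, one wild donor per family. Each donor carries the wild
#' allele at a random subset of markers (`donorPolymorphicProb` per marker),
#' so markers segregate only in the families whose donor is informative
#' there — the family-private allele structure of a NAM panel. Missing
#' genotype calls are injected completely at random at `missingRate`.
#'
#' Defaults emulate a 25-family BC1S3 barley panel of about 1420 lines.
#'
#' @param map genetic map data.frame; e.g. `generateMap(7, 150, 5709)`.
#' @param nFamilies number of donor families.
#' @param linesPerFamily lines bred per family (1420/25 rounds to 57).
#' @param scheme a [breedingScheme()].
#' @param seed master seed; per-family streams are derived from it.
#' @param donorPolymorphicProb probability a donor is informative at a
#'   marker (about 5709/7864 of chip SNPs were informative in the panel
#'   this emulates).
#' @param missingRate fraction of genotype cells set to NA.
#' @return a [NamPopulation-class].
#' @export
simulatePopulation <- function(map, nFamilies = 25L, linesPerFamily = 57L,
                               scheme = breedingScheme(), seed = 1L,
                               donorPolymorphicProb = 0.75,
                               missingRate = 0.02) {
  stopifnot_arg(nFamilies >= 1 && linesPerFamily >= 0, "counts must be positive")
  m <- nrow(map)
  frags <- vector("list", nFamilies)
  for (f in seq_len(nFamilies)) {
    set.seed(deriveSeed(seed, 307, f))
    carries <- runif(m) < donorPolymorphicProb
    frags[[f]] <- simulateFamily(sprintf("F%02d", f), linesPerFamily, scheme,
                                 map, seed = deriveSeed(seed, 311, f),
                                 donorCarriesWild = carries)
  }
  geno <- do.call(rbind, lapply(frags, `[[`, "geno"))
  fam <- unlist(lapply(frags, `[[`, "family"))
  rownames(geno) <- sprintf("%s_L%03d", fam,
                            unlist(lapply(frags, function(x) seq_along(x$family))))
  if (missingRate > 0 && length(geno)) {
    set.seed(deriveSeed(seed, 401))
    geno[runif(length(geno)) < missingRate] <- NA_integer_
  }
  new("NamPopulation", geno = geno, family = factor(fam),
      map = data.frame(map, stringsAsFactors = FALSE))
}

#' Construct a trait architecture
#'
#' @param trait trait name.
#' @param mu population mean in trait units.
#' @param familyEffects numeric vector of per-family shifts (recycled to the
#'   number of families at simulation time; default none).
#' @param loci data.frame (`marker`, `effect`, `dominant`, `qxe`) of causal
#'   loci; `effect` is the Hs/Hs minus Hv/Hv difference expressed in both
#'   environments, `qxe` an additional Hs/Hs minus Hv/Hv difference expressed
#'   only under WL. Default: no causal loci.
#' @param h2 polygenic heritability attached to the kinship matrix, in [0,1].
#' @param envEffect additive shift applied to every WL record (trait units).
#' @param residSD named numeric `c(WW=, WL=)` residual standard deviations.
#' @return an [ArchitectureSpec-class].
#' @examples
#' architectureSpec("GN", mu = 334, envEffect = -103,
#'                  residSD = c(WW = 56, WL = 65))
#' @export
architectureSpec <- function(trait, mu, familyEffects = numeric(0),
                             loci = NULL, h2 = 0,
                             envEffect = 0, residSD = c(WW = 1, WL = 1)) {
  if (is.null(loci))
    loci <- data.frame(marker = character(0), effect = numeric(0),
                       dominant = logical(0), qxe = numeric(0))
  if (is.null(loci$dominant)) loci$dominant <- FALSE
  if (is.null(loci$qxe)) loci$qxe <- 0
  new("ArchitectureSpec", trait = trait, mu = mu,
      familyEffects = familyEffects, loci = loci, h2 = h2,
      envEffect = envEffect, residSD = residSD)
}

# effect dose per line for one causal locus; NA genotypes get the mean dose
.locusDose <- function(g, dominant) {
  dose <- if (dominant) as.numeric(g >= 1) else g / 2
  if (anyNA(dose)) dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
  dose
}

#' Simulate two-environment phenotypes for a population
#'
#' Generates trait records under the additive model
#' \deqn{y = \mu + F_i + \sum_l a_l d_l + 1[WL](E + \sum_l q_l d_l) + g + \varepsilon}
#' where \eqn{d_l} is the allele dose at causal locus \eqn{l} (0, 1/2, 1 of
#' the Hs/Hs-vs-Hv/Hv effect; full effect for heterozygotes of dominant
#' loci), \eqn{g} is a line-level polygenic draw with covariance
#' proportional to the kinship matrix scaled so that its variance equals
#' \eqn{h^2/(1-h^2)} times the WW residual variance, and \eqn{\varepsilon}
#' is i.i.d. Gaussian with the per-environment SD. The polygenic and family
#' components are constant across environments and years; residuals are
#' drawn per record. An optional multiplicative per-year scale emulates
#' between-season level shifts and gives the cross-year adjustment something
#' to undo.
#'
#' @param pop a [NamPopulation-class].
#' @param arch an [ArchitectureSpec-class] or list of them (one per trait).
#' @param years number of years (seasons) to simulate.
#' @param kinship symmetric PSD relatedness matrix over the lines of `pop`;
#'   required when any `h2 > 0` (see [computeKinship()]).
#' @param seed master seed; per-trait streams are derived from it.
#' @param yearScale numeric vector of length `years`; all records of year
#'   `t` are multiplied by `yearScale[t]` (default all 1).
#' @return a long-format phenotype data.frame: `line`, `family`, `year`,
#'   `environment`, `trait`, `value`.
#' @export
simulatePhenotypes <- function(pop, arch, years = 2L, kinship = NULL,
                               seed = 1L, yearScale = NULL) {
  if (is(arch, "ArchitectureSpec")) arch <- list(arch)
  stopifnot_arg(all(vapply(arch, is, TRUE, "ArchitectureSpec")),
                "arch must be ArchitectureSpec(s)")
  if (is.null(yearScale)) yearScale <- rep(1, years)
  stopifnot_arg(length(yearScale) == years, "yearScale must have one entry per year")
  g <- genotypes(pop)
  n <- nrow(g)
  fam <- families(pop)
  needK <- any(vapply(arch, function(a) a@h2 > 0, TRUE))
  if (needK && is.null(kinship))
    stop("kinship matrix required when h2 > 0", call. = FALSE)
  evec <- NULL
  if (needK) {
    stopifnot_arg(nrow(kinship) == n, "kinship dimension must match lines")
    evec <- eigen(kinship / mean(diag(kinship)), symmetric = TRUE)
    evec$values <- pmax(evec$values, 0)
  }
  out <- vector("list", length(arch))
  for (a in seq_along(arch)) {
    sp <- arch[[a]]
    miss <- setdiff(sp@loci$marker, colnames(g))
    if (length(miss))
      stop("causal marker(s) absent from population: ",
           paste(miss, collapse = ", "), call. = FALSE)
    set.seed(deriveSeed(seed, 503, a))
    fe <- if (length(sp@familyEffects))
      rep_len(sp@familyEffects, nlevels(fam))[as.integer(fam)] else 0
    base <- rep(sp@mu, n) + fe
    perse <- qxe <- rep(0, n)
    for (l in seq_len(nrow(sp@loci))) {
      dose <- .locusDose(g[, sp@loci$marker[l]], sp@loci$dominant[l])
      perse <- perse + sp@loci$effect[l] * dose
      qxe <- qxe + sp@loci$qxe[l] * dose
    }
    poly <- rep(0, n)
    if (sp@h2 > 0) {
      sg <- sqrt(sp@h2 / (1 - sp@h2)) * sp@residSD["WW"]
      poly <- drop(evec$vectors %*% (sqrt(evec$values) * rnorm(n))) * sg
    }
    recs <- vector("list", years * 2)
    k <- 1
    for (yr in seq_len(years)) for (env in ENVS) {
      mu <- base + perse + poly +
        if (env == "WL") sp@envEffect + qxe else 0
      val <- (mu + rnorm(n, 0, sp@residSD[env])) * yearScale[yr]
      recs[[k]] <- data.frame(line = rownames(g), family = as.character(fam),
                              year = yr, environment = env,
                              trait = sp@trait, value = val,
                              stringsAsFactors = FALSE)
      k <- k + 1
    }
    out[[a]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
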