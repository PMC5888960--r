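# Pot-experiment statistics: wild-allele carrier grouping, two-way
# factorial ANOVA (treatment x allelic state), compact letter displays and
# the percent-reduction summaries used for genotype-group comparisons.

#' Group lines by allelic state at a marker
#'
#' Carriers of the wild allele (genotype codes 2, Hs/Hs, and 1, Hv/Hs) are
#' pooled as `Hs/_`; code 0 is the cultivated class `Hv/Hv`. Lines with a
#' missing genotype are excluded with a warning.
#'
#' @param genotypes named vector of codes 0/1/2/NA at the marker of
#'   interest.
#' @return named factor with levels `Hv/Hv`, `Hs/_` (missing lines
#'   dropped).
#' @examples
#' groupAlleles(c(a = 2, b = 1, c = 0))   # Hs/_, Hs/_, Hv/Hv
#' @export
groupAlleles <- function(genotypes) {
  stopifnot_arg(all(genotypes %in% VALID_GENO_CODES | is.na(genotypes)),
                "genotype codes must be 0, 1, 2 or NA")
  if (anyNA(genotypes))
    warning(sum(is.na(genotypes)), " line(s) with missing genotype excluded")
  keep <- !is.na(genotypes)
  g <- genotypes[keep]
  factor(ifelse(g >= 1, "Hs/_", "Hv/Hv"), levels = c("Hv/Hv", "Hs/_"))
}

#' Two-way factorial ANOVA: treatment x allelic state
#'
#' Fixed-effects factorial ANOVA with interaction, as used for pot
#' experiments contrasting drought treatments against allele carrier
#' groups. Type-II sums of squares accommodate the unbalanced carrier
#' groups. If any treatment-by-allele cell is empty the interaction is
#' dropped with a warning and main effects are tested.
#'
#' @param values numeric response.
#' @param treatment factor (e.g. WW, early WL, late WL).
#' @param allele factor (e.g. from [groupAlleles()]).
#' @return data.frame with rows per term (`treatment`, `allele`,
#'   `treatment:allele`, `Residuals`) and columns `df`, `sumsq`, `meansq`,
#'   `F`, `p`.
#' @export
factorialAnova <- function(values, treatment, allele) {
  keep <- !is.na(values) & !is.na(treatment) & !is.na(allele)
  dat <- data.frame(value = values[keep],
                    treatment = droplevels(factor(treatment[keep])),
                    allele = droplevels(factor(allele[keep])))
  counts <- table(dat$treatment, dat$allele)
  withInter <- all(counts > 0)
  if (!withInter)
    warning("empty treatment x allele cell: interaction dropped")
  fml <- if (withInter) value ~ treatment * allele else
    value ~ treatment + allele
  if (var(dat$value) == 0) {
    # all-equal response: every SS is zero and no F is defined
    dfT <- nlevels(dat$treatment) - 1
    dfA <- nlevels(dat$allele) - 1
    terms <- c("treatment", "allele",
               if (withInter) "treatment:allele", "Residuals")
    dfs <- c(dfT, dfA, if (withInter) dfT * dfA,
             nrow(dat) - 1 - dfT - dfA - if (withInter) dfT * dfA else 0)
    return(data.frame(term = terms, df = dfs, sumsq = 0, meansq = 0,
                      F = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
  }
  fit <- lm(fml, data = dat)
  aT <- suppressWarnings(car::Anova(fit, type = 2))
  terms <- rownames(aT)
  out <- data.frame(term = terms, df = aT$Df, sumsq = aT$`Sum Sq`,
                    meansq = aT$`Sum Sq` / aT$Df,
                    F = aT$`F value`, p = aT$`Pr(>F)`,
                    stringsAsFactors = FALSE, row.names = NULL)
  # degenerate data (zero residual variance) gives NaN F; report NA
  out$F[!is.finite(out$F)] <- NA_real_
  out$p[!is.finite(out$p)] <- NA_real_
  out
}

# insert-and-absorb compact letter display from a logical "significantly
# different" matrix over groups
.letterDisplay <- function(diffMat) {
  groups <- rownames(diffMat)
  k <- length(groups)
  cols <- list(seq_len(k))   # columns = letter sets (indices of members)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!diffMat[i, j]) next
    for (ci in seq_along(cols)) {
      cc <- cols[[ci]]
      if (all(c(i, j) %in% cc)) {
        cols[[ci]] <- setdiff(cc, i)
        cols[[length(cols) + 1]] <- setdiff(cc, j)
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols))
      if (a != b && keep[a] && keep[b] && all(cols[[a]] %in% cols[[b]]) &&
          !identical(sort(cols[[a]]), sort(cols[[b]])))
        keep[a] <- FALSE
    dupes <- duplicated(lapply(cols, sort))
    cols <- cols[keep & !dupes]
  }
  letters_ <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, function(cc) g %in% cc, TRUE))],
           collapse = "")
  }, character(1))
  setNames(letters_, groups)
}

#' Compact letter display for group means
#'
#' All-pairs comparisons at level `alpha`, summarized as letters: groups
#' sharing any letter are not significantly different. Pairwise tests are
#' either two-sample Student's t-tests (pooled variance per pair, as used
#' for figure annotations) or the Tukey–Kramer honest significant
#' difference on the pooled one-way fit.
#'
#' @param values numeric response.
#' @param group factor of group membership (>= 2 groups).
#' @param method `"t"` or `"tukey"`.
#' @param alpha significance level.
#' @return list with `letters` (named character per group), `means` (group
#'   means) and `pairwiseP` (symmetric matrix of pairwise p-values).
#' @export
meanLetters <- function(values, group, method = c("t", "tukey"),
                        alpha = 0.05) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(group)
  v <- values[keep]
  g <- droplevels(factor(group[keep]))
  stopifnot_arg(nlevels(g) >= 2, "need at least 2 groups")
  lev <- levels(g)
  k <- length(lev)
  P <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  if (method == "t") {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      vi <- v[g == lev[i]]; vj <- v[g == lev[j]]
      p <- if (sd(c(vi, vj)) == 0) 1 else
        t.test(vi, vj, var.equal = TRUE)$p.value
      P[i, j] <- P[j, i] <- p
    }
  } else {
    tk <- TukeyHSD(aov(v ~ g))$g
    for (nm in rownames(tk)) {
      pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
      P[pair[1], pair[2]] <- P[pair[2], pair[1]] <- tk[nm, "p adj"]
    }
  }
  P[is.na(P)] <- 1
  diag(P) <- 1
  diffMat <- P < alpha
  list(letters = .letterDisplay(diffMat),
       means = tapply(v, g, mean), pairwiseP = P)
}

#' Percent reduction between two group means
#'
#' `100 * (reference - stressed) / reference`, reported to one decimal
#' (round-half-even). Used for summaries such as the reduction of grain
#' number between well-watered and water-limited means.
#'
#' @param meanReference mean under the reference (e.g. WW) condition;
#'   must be non-zero.
#' @param meanStressed mean under the stressed (e.g. WL) condition.
#' @return percent reduction, one decimal.
#' @examples
#' percentReduction(334, 221)  # 33.8
#' percentReduction(272, 252)  # 7.4
#' @export
percentReduction <- function(meanReference, meanStressed) {
  stopifnot_arg(is.numeric(meanReference) && is.numeric(meanStressed),
                "means must be numeric")
  if (any(meanReference == 0))
    stop("reference mean must be non-zero", call. = FALSE)
  round(100 * (meanReference - meanStressed) / meanReference, 1)
}
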