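#' Compute derived traits
#'
#' Adds the standard derived traits to a long-format phenotype table,
#' computed within each (line, year, environment) record set:
#' grain-filling period `GFP = MAT - HEA`, harvest index `HI = PGY / TDM`,
#' and vegetative dry weight `VDW = TDM - PGY`. A missing source value
#' yields a missing derived value; `TDM = 0` yields a missing `HI` with a
#' warning. Records for already-present derived traits are replaced.
#'
#' @param tab phenotype data.frame (`line`, `family`, `year`, `environment`,
#'   `trait`, `value`).
#' @return the table with GFP, HI and VDW records appended (where their
#'   source traits exist).
#' @export
deriveTraits <- function(tab) {
  checkPhenotypeTable(tab)
  wide <- tabToWide(tab)
  defs <- list(
    GFP = function(w) w$MAT - w$HEA,
    HI  = function(w) {
      h <- w$PGY / w$TDM
      zero <- !is.na(w$TDM) & w$TDM == 0
      if (any(zero)) {
        warning(sum(zero), " record(s) with TDM = 0: HI set to missing")
        h[zero] <- NA_real_
      }
      h
    },
    VDW = function(w) w$TDM - w$PGY)
  src <- list(GFP = c("MAT", "HEA"), HI = c("PGY", "TDM"),
              VDW = c("TDM", "PGY"))
  tab <- tab[!(tab$trait %in% names(defs)), , drop = FALSE]
  add <- list()
  for (d in names(defs)) {
    if (!all(src[[d]] %in% names(wide))) next
    val <- defs[[d]](wide)
    add[[d]] <- data.frame(wide[c("line", "family", "year", "environment")],
                           trait = d, value = val, stringsAsFactors = FALSE)
  }
  out <- rbind(tab, do.call(rbind, add))
  rownames(out) <- NULL
  out
}

# long -> wide on trait, one row per (line, family, year, environment)
tabToWide <- function(tab) {
  key <- unique(tab[c("line", "family", "year", "environment")])
  rownames(key) <- NULL
  kid <- paste(key$line, key$year, key$environment)
  for (tr in unique(tab$trait)) {
    sub <- tab[tab$trait == tr, ]
    key[[tr]] <- sub$value[match(kid, paste(sub$line, sub$year,
                                            sub$environment))]
  }
  key
}

#' Adjust trait values across years
#'
#' Removes between-season level differences by rescaling every value of a
#' trait-year cell with the factor
#' \deqn{f_{t,y} = \bar{x}_{t,\cdot} / \bar{x}_{t,y}}
#' i.e. the all-years trait mean divided by that year's trait mean (equal to
#' 1/(year mean / all-years mean)). After adjustment the per-year means of
#' each trait are equal. By default means pool both environments and all
#' lines within a year; `stratifyByEnvironment = TRUE` computes and applies
#' factors per (trait, year, environment) instead.
#'
#' @param tab phenotype data.frame.
#' @param stratifyByEnvironment logical; see above.
#' @return the adjusted table, with the factors used attached as attribute
#'   `"factors"`.
#' @export
adjustAcrossYears <- function(tab, stratifyByEnvironment = FALSE) {
  checkPhenotypeTable(tab)
  strata <- if (stratifyByEnvironment)
    interaction(tab$trait, tab$environment, drop = TRUE) else factor(tab$trait)
  out <- tab
  facs <- list()
  for (s in levels(strata)) {
    i <- strata == s
    grand <- mean(tab$value[i], na.rm = TRUE)
    for (y in unique(tab$year[i])) {
      j <- i & tab$year == y
      ym <- mean(tab$value[j], na.rm = TRUE)
      if (is.na(ym) || ym == 0)
        stop(sprintf("zero or undefined year mean for %s, year %s", s, y),
             call. = FALSE)
      f <- grand / ym
      out$value[j] <- tab$value[j] * f
      facs[[paste(s, y, sep = ".")]] <- f
    }
  }
  attr(out, "factors") <- unlist(facs)
  out
}

#' Per-line means across years
#'
#' Averages (adjusted) trait values over years within each (line,
#' environment, trait), giving the line means used as GWAS responses. Years
#' with missing values are simply omitted from the mean; a line missing in
#' all years stays missing.
#'
#' @param tab phenotype data.frame (normally after [adjustAcrossYears()]).
#' @return data.frame `line`, `family`, `environment`, `trait`, `value`.
#' @export
lineMeans <- function(tab) {
  checkPhenotypeTable(tab)
  agg <- aggregate(value ~ line + family + environment + trait, data = tab,
                   FUN = mean, na.rm = TRUE, na.action = NULL)
  agg$value[is.nan(agg$value)] <- NA_real_
  agg[order(agg$trait, agg$environment, agg$line), ]
}

#' Descriptive summaries per trait and environment
#'
#' Mean, standard deviation and coefficient of variation (CV = 100 SD/mean)
#' per (trait, environment), and the pairwise Pearson correlation matrix of
#' line means between traits within each environment (complete pairs only;
#' constant traits give NA correlations).
#'
#' @param tab phenotype data.frame.
#' @return list with `stats` (data.frame trait, environment, n, mean, sd,
#'   cv) and `correlations` (named list of per-environment matrices).
#' @export
summarizeTraits <- function(tab) {
  checkPhenotypeTable(tab)
  sp <- split(tab$value, list(tab$trait, tab$environment), drop = TRUE)
  stats <- do.call(rbind, lapply(names(sp), function(nm) {
    v <- sp[[nm]][!is.na(sp[[nm]])]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(trait = paste(head(parts, -1), collapse = "."),
               environment = parts[length(parts)], n = length(v),
               mean = mean(v), sd = sd(v),
               cv = 100 * sd(v) / mean(v), stringsAsFactors = FALSE)
  }))
  lm_ <- lineMeans(tab)
  cors <- lapply(setNames(ENVS, ENVS), function(e) {
    sub <- lm_[lm_$environment == e, ]
    if (!nrow(sub)) return(NULL)
    wide <- tabToWide(data.frame(sub[c("line", "family")], year = 1,
                                 environment = e, sub[c("trait", "value")],
                                 stringsAsFactors = FALSE))
    m <- as.matrix(wide[, setdiff(names(wide),
                                  c("line", "family", "year", "environment")),
                        drop = FALSE])
    suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  })
  list(stats = stats, correlations = cors[!vapply(cors, is.null, TRUE)])
}
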