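# Deterministic sub-seed derivation: one master seed fans out to independent
# streams (per family, per trait, per replicate) without seed collisions.
# Kept below 2^31 - R integers are 32-bit.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(s)
}

stopifnot_arg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)

# Environment labels used throughout: well-watered / water-limited
ENVS <- c("WW", "WL")

checkPhenotypeTable <- function(tab) {
  need <- c("line", "family", "year", "environment", "trait", "value")
  stopifnot_arg(is.data.frame(tab) && all(need %in% names(tab)),
    "phenotype table needs columns line, family, year, environment, trait, value")
  stopifnot_arg(all(tab$environment %in% ENVS),
    "environment must be WW or WL")
  key <- paste(tab$line, tab$year, tab$environment, tab$trait)
  stopifnot_arg(!anyDuplicated(key),
    "at most one record per (line, year, environment, trait)")
  invisible(tab)
}
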