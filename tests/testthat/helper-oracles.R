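# Independent oracle implementations used to cross-check the package.
# Deliberately written with different primitives than the implementation
# (explicit loops, prod()-based geometric means, subset enumeration,
# Monte-Carlo resampling); no helpers are shared with R/.

# Brute-force median-of-ratios: geometric mean via prod()^(1/n), median as
# the midpoint convention written out by hand.
brute_median_of_ratios <- function(counts) {
  keep <- c()
  for (s in seq_len(nrow(counts))) {
    if (all(counts[s, ] > 0)) keep <- c(keep, s)
  }
  if (length(keep) == 0) stop("no reference rows")
  refs <- numeric(length(keep))
  for (i in seq_along(keep)) {
    refs[i] <- prod(counts[keep[i], ])^(1 / ncol(counts))
  }
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ratios <- sort(counts[keep, j] / refs)
    m <- length(ratios)
    sf[j] <- if (m %% 2 == 1) ratios[(m + 1) / 2]
             else (ratios[m / 2] + ratios[m / 2 + 1]) / 2
  }
  sf
}

# Exhaustive-subset classification oracle: every candidate tissue for
# enriched/enhanced, every subset of size 2..max_group for group-enriched.
oracle_classify <- function(profile, fold = 7, cutoff = 1, max_group = 4) {
  nm <- names(profile)
  n <- length(profile)
  for (t in seq_len(n)) {
    if (profile[t] > cutoff && profile[t] >= fold * max(profile[-t]))
      return(list(category = "tissue_enriched", tissues = nm[t]))
  }
  for (g in 2:max_group) {
    subsets <- utils::combn(n, g)
    hits <- list()
    for (k in seq_len(ncol(subsets))) {
      S <- subsets[, k]
      if (all(profile[S] > cutoff) &&
          min(profile[S]) >= fold * max(profile[-S]))
        hits[[length(hits) + 1]] <- sort(nm[S])
    }
    if (length(hits) > 0) {
      stopifnot(length(hits) == 1)  # a qualifying group must be unique
      return(list(category = "group_enriched", tissues = hits[[1]]))
    }
  }
  qualifying <- c()
  for (t in seq_len(n)) {
    if (profile[t] > cutoff && profile[t] >= fold * mean(profile[-t]))
      qualifying <- c(qualifying, t)
  }
  if (length(qualifying) > 0) {
    # report the highest-expressed qualifying tissue (name-ordered on ties)
    best <- qualifying[order(-profile[qualifying], nm[qualifying])][1]
    return(list(category = "tissue_enhanced", tissues = nm[best]))
  }
  list(category = "not_elevated", tissues = character(0))
}

# Monte-Carlo rarefaction: subsample `depth` reads without replacement and
# count distinct sequences; returns mean and standard error.
mc_rarefaction <- function(counts, depth, n_draws = 1e4) {
  pool <- rep(seq_along(counts), counts)
  rich <- vapply(seq_len(n_draws), function(i) {
    length(unique(sample(pool, depth)))
  }, 0L)
  list(mean = mean(rich), se = stats::sd(rich) / sqrt(n_draws))
}
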