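ELEVATION_CATEGORIES <- c("tissue_enriched", "group_enriched",
                          "tissue_enhanced", "not_elevated")

#' Classify one expression profile into HPA tissue-specificity categories
#'
#' Given a sequence's (or gene's) mean normalized expression across tissues,
#' applies the Human Protein Atlas classification in order:
#'
#' 1. *tissue-enriched*: some tissue exceeds the expression cutoff and is at
#'    least `fold` times the highest of all other tissues;
#' 2. *group-enriched*: the smallest group g (2..`max_group`) of top
#'    tissues, all above the cutoff, whose minimum is at least `fold` times
#'    the highest tissue outside the group (a qualifying group is
#'    necessarily the top-g tissues by expression);
#' 3. *tissue-enhanced*: some tissue exceeds the cutoff and is at least
#'    `fold` times the mean of all other tissues;
#' 4. otherwise *not elevated*.
#'
#' The fold comparison is inclusive (`>=`, "at least"); the expression
#' cutoff applies to the defining tissue(s) and is strict (`>`). Ties are
#' broken deterministically (lexicographically smallest tissue name among
#' tied maxima) and, at fold boundaries, toward not elevated.
#'
#' @param profile named numeric vector, expression per tissue (all tissue
#'   names distinct; at least `max_group + 1` tissues so that the
#'   complement of a group is never empty)
#' @param fold fold-change threshold; the atlas analysis used 7, the HPA
#'   definitional value is 5
#' @param cutoff minimum expression in the defining tissue(s); default 1
#'   normalized count
#' @param max_group largest group-enriched set; default 4
#' @return list with elements `category` (one of tissue_enriched,
#'   group_enriched, tissue_enhanced, not_elevated), `tissues` (character
#'   vector; empty for not_elevated) and `fold_change` (achieved fold,
#'   possibly `Inf`; `NA` for not_elevated)
#' @examples
#' classify_sequence(c(A = 100, B = 5, C = 5, D = 5, E = 5), fold = 7)
#' @export
classify_sequence <- function(profile, fold = 7, cutoff = 1, max_group = 4) {
  if (is.null(names(profile)) || anyDuplicated(names(profile)))
    stop("profile must be named with distinct tissue names")
  n <- length(profile)
  if (n < max_group + 1)
    stop("need at least max_group + 1 = ", max_group + 1, " tissues, got ", n)
  if (any(!is.finite(profile)) || any(profile < 0))
    stop("expression values must be finite and non-negative")
  ord <- order(-profile, names(profile))
  expr <- profile[ord]

  # tissue-enriched: only the top tissue can qualify (fold > 1)
  top <- expr[1]
  max_rest <- expr[2]
  if (top > cutoff && top >= fold * max_rest) {
    fc <- if (max_rest == 0) Inf else unname(top / max_rest)
    return(list(category = "tissue_enriched", tissues = names(expr)[1],
                fold_change = fc))
  }

  # group-enriched: smallest qualifying top-g set
  for (g in 2:max_group) {
    grp_min <- expr[g]
    out_max <- expr[g + 1]
    if (grp_min > cutoff && grp_min >= fold * out_max) {
      fc <- if (out_max == 0) Inf else unname(grp_min / out_max)
      return(list(category = "group_enriched",
                  tissues = sort(names(expr)[seq_len(g)]),
                  fold_change = fc))
    }
  }

  # tissue-enhanced: top tissue vs mean of the others
  mean_rest <- mean(expr[-1])
  if (top > cutoff && top >= fold * mean_rest) {
    fc <- if (mean_rest == 0) Inf else unname(top / mean_rest)
    return(list(category = "tissue_enhanced", tissues = names(expr)[1],
                fold_change = fc))
  }

  list(category = "not_elevated", tissues = character(0), fold_change = NA_real_)
}

#' Classify every row of a normalized count set
#'
#' Replicates are averaged per source ([source_profiles()]) and
#' [classify_sequence()] is applied row-wise. Rows that are broadly
#' expressed with no qualifying fold come out not elevated, mirroring the
#' removal of specificity-"All" assignments.
#'
#' @param x a normalized [srna_set]
#' @param config a [pipeline_config()] supplying `fold_change_threshold`,
#'   `expression_cutoff` and `max_group_size`
#' @return data.frame of calls: `id`, `category`, `tissues`
#'   (semicolon-joined), `fold_change`
#' @export
classify_matrix <- function(x, config = pipeline_config()) {
  prof <- source_profiles(x)
  ids <- feature_ids(x)
  calls <- vector("list", nrow(prof))
  for (i in seq_len(nrow(prof))) {
    cl <- classify_sequence(prof[i, ],
                            fold = config$fold_change_threshold,
                            cutoff = config$expression_cutoff,
                            max_group = config$max_group_size)
    calls[[i]] <- data.frame(
      id = ids[i],
      category = cl$category,
      tissues = paste(cl$tissues, collapse = ";"),
      fold_change = cl$fold_change)
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(id = character(0), category = character(0),
                      tissues = character(0), fold_change = numeric(0))
  rownames(out) <- NULL
  out
}

#' Tissue-elevated sequence sets
#'
#' The union of the three specificity categories is termed
#' "tissue-elevated". Each sequence is placed in the set of every tissue in
#' its call, so a group-enriched sequence appears in several sets;
#' not-elevated sequences appear nowhere.
#'
#' @param calls data.frame from [classify_matrix()]
#' @return named list, tissue -> character vector of elevated ids
#' @export
elevated_sets <- function(calls) {
  keep <- calls$category != "not_elevated"
  if (!any(keep)) return(structure(list(), names = character(0)))
  calls <- calls[keep, , drop = FALSE]
  tissues <- strsplit(calls$tissues, ";", fixed = TRUE)
  long <- data.frame(tissue = unlist(tissues),
                     id = rep(calls$id, lengths(tissues)))
  lapply(split(long$id, long$tissue), unique)
}
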