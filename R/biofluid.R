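#' Sequences detected in a biofluid
#'
#' Applies the biofluid detection rule (raw count strictly above
#' `biofluid_min_count` in strictly more than `biofluid_min_fraction` of
#' the samples) and returns the detected sequence ids. Identical to the
#' rows kept by [filter_biofluid()].
#'
#' @param x an [srna_set] of one biofluid's samples
#' @param config a [pipeline_config()]
#' @return character vector of detected sequence ids
#' @export
detect_in_biofluid <- function(x, config = pipeline_config()) {
  res <- filter_biofluid(x, min_count = config$biofluid_min_count,
                         min_fraction = config$biofluid_min_fraction)
  feature_ids(res$matrix)
}

#' Attribute detected biofluid sequences to tissue-elevated sets
#'
#' The "direct" tissue-of-origin readout: for each tissue, the number of
#' detected sequences that belong to its tissue-elevated set, the sum of
#' their mean normalized counts in the biofluid, and that sum as a fraction
#' of the total over tissues. A sequence elevated in several tissues is
#' counted for each of them (double counting), and by default the fraction
#' denominator is the double-counted total, so fractions sum to 1. With
#' `denominator = "detected"` the denominator is instead the total mean
#' count of all detected tissue-elevated sequences, counted once each.
#'
#' @param detected character vector of sequence ids detected in the
#'   biofluid (see [detect_in_biofluid()])
#' @param elevated named list, tissue -> elevated sequence ids (see
#'   [elevated_sets()])
#' @param mean_counts named numeric vector: mean normalized count of each
#'   detected sequence over the biofluid's samples
#' @param biofluid name of the biofluid (carried into the result)
#' @param denominator `"elevated"` (default; fractions sum to 1) or
#'   `"detected"`
#' @return data.frame with columns `biofluid`, `tissue`,
#'   `n_detected_sequences`, `read_sum`, `read_fraction`
#' @examples
#' attribute(detected = c("s1", "s2", "s3"),
#'           elevated = list(A = c("s1", "s2"), B = c("s2", "s3")),
#'           mean_counts = c(s1 = 100, s2 = 50, s3 = 50))
#' @export
attribute <- function(detected, elevated, mean_counts,
                      biofluid = "biofluid",
                      denominator = c("elevated", "detected")) {
  denominator <- match.arg(denominator)
  missing_mc <- setdiff(detected, names(mean_counts))
  if (length(missing_mc) > 0)
    stop("mean_counts missing for detected sequence(s): ",
         paste(utils::head(missing_mc, 3), collapse = ", "))
  hits <- lapply(elevated, function(ids) intersect(detected, ids))
  n_det <- lengths(hits)
  sums <- vapply(hits, function(ids) sum(mean_counts[ids]), 0)
  total <- if (denominator == "elevated") sum(sums)
           else sum(mean_counts[unique(unlist(hits))])
  if (total > 0) {
    fracs <- sums / total
  } else {
    if (length(hits) > 0)
      warning("no tissue-elevated sequence detected; fractions set to 0")
    fracs <- rep(0, length(sums))
  }
  data.frame(biofluid = rep(biofluid, length(hits)),
             tissue = names(elevated),
             n_detected_sequences = as.integer(n_det),
             read_sum = as.numeric(sums),
             read_fraction = as.numeric(fracs),
             row.names = NULL)
}

#' Sequence and gene diversity per source
#'
#' Sequence diversity is the number of unique sequences whose
#' replicate-mean normalized expression in a source exceeds the cutoff;
#' gene diversity is the same count after collapsing all isoforms to their
#' parent gene ([collapse_to_genes()]). Collapsing can push a gene over a
#' cutoff its individual isoforms miss, so gene diversity is not bounded by
#' sequence diversity.
#'
#' @param x a normalized, sequence-level [srna_set]
#' @param cutoff normalized-expression threshold (strict `>`); default 10
#' @return data.frame with columns `source`, `gene_diversity`,
#'   `sequence_diversity`, `cutoff`
#' @export
diversity <- function(x, cutoff = 10) {
  seq_prof <- source_profiles(x)
  gene_prof <- source_profiles(collapse_to_genes(x))
  data.frame(source = colnames(seq_prof),
             gene_diversity = as.integer(colSums(gene_prof > cutoff)),
             sequence_diversity = as.integer(colSums(seq_prof > cutoff)),
             cutoff = cutoff,
             row.names = NULL)
}

#' Expected unique-sequence richness at a reduced sequencing depth
#'
#' The analytic (hypergeometric) rarefaction expectation
#' \eqn{E[S_d] = \sum_i (1 - C(N - n_i, d) / C(N, d))} for subsampling
#' `depth` reads without replacement from a library of \eqn{N = \sum n_i}
#' reads, computed via `vegan::rarefy`. Used to assess sequencing
#' saturation.
#'
#' @param counts non-negative integer vector of per-sequence read counts
#' @param depth number of reads drawn, `0 <= depth <= sum(counts)`
#' @return expected number of distinct sequences observed (real)
#' @examples
#' rarefaction(c(5, 5), 5)  # 2 * (1 - 1/choose(10, 5))
#' @export
rarefaction <- function(counts, depth) {
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (depth < 0 || depth > total)
    stop("depth must be between 0 and the total count (", total, ")")
  if (depth == 0) return(0)
  # vegan nags when the smallest count exceeds 1, which is the norm for
  # collapsed sequence tables; the expectation itself is unaffected
  as.numeric(suppressWarnings(
    vegan::rarefy(matrix(counts, nrow = 1), sample = depth)))
}

#' Rarefaction curve over a grid of depths
#'
#' @param counts per-sequence read counts
#' @param depths depths to evaluate; defaults to 20 evenly spaced depths up
#'   to the library size
#' @return data.frame with columns `depth` and `richness`
#' @export
rarefaction_curve <- function(counts,
                              depths = round(seq(0, sum(counts), length.out = 21))) {
  data.frame(depth = depths,
             richness = vapply(depths, function(d) rarefaction(counts, d), 0))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment returned in the original order; values must lie
#' in [0, 1].
#'
#' @param p_values numeric vector of raw p-values
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Annotate a differential-expression table with tissue-elevation calls
#'
#' Joins externally computed DE results (sequence, log2 fold change,
#' p-value) to tissue-specificity calls. If the table lacks an adjusted
#' p-value column, BH adjustment is computed here; a supplied `padj` column
#' is passed through and flagged. Records with `padj < alpha` are marked
#' significant; each record is labelled with its elevation category and
#' tissue set, defaulting to `not_elevated` for sequences without a call.
#'
#' @param de_table data.frame with columns `sequence`, `log2fc`, `pvalue`
#'   and optionally `padj`
#' @param calls data.frame from [classify_matrix()]
#' @param alpha significance level on adjusted p-values; default 0.05
#' @return `de_table` with added columns `padj`, `significant`, `category`,
#'   `tissues`; attribute `padj_source` records whether adjustment was
#'   computed or supplied
#' @export
annotate_de <- function(de_table, calls, alpha = 0.05) {
  need <- c("sequence", "log2fc", "pvalue")
  if (!all(need %in% names(de_table)))
    stop("de_table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(de_table$sequence))
    stop("duplicate sequence id in de_table: ",
         de_table$sequence[duplicated(de_table$sequence)][1])
  supplied <- "padj" %in% names(de_table)
  if (!supplied) de_table$padj <- bh_adjust(de_table$pvalue)
  de_table$significant <- de_table$padj < alpha
  idx <- match(de_table$sequence, calls$id)
  de_table$category <- ifelse(is.na(idx), "not_elevated", calls$category[idx])
  de_table$tissues <- ifelse(is.na(idx), "", calls$tissues[idx])
  attr(de_table, "padj_source") <- if (supplied) "supplied" else "computed"
  de_table
}
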