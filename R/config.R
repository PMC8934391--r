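#' Pipeline configuration
#'
#' Collects every scalar threshold used across the pipeline, with the
#' defaults of the atlas analysis this package implements:
#'
#' * tissues: a sequence is detected when strictly more than
#'   `tissue_min_count` (25) raw reads are seen in at least
#'   `tissue_min_replicates` (2) replicates of some source;
#' * biofluids: strictly more than `biofluid_min_count` (10) raw reads in
#'   strictly more than `biofluid_min_fraction` (50%) of the samples;
#' * tissue-specificity calls use `fold_change_threshold` (7; the Human
#'   Protein Atlas definitional value is 5) above an expression cutoff of
#'   `expression_cutoff` (1 normalized count), with group-enriched sets of
#'   at most `max_group_size` (4) tissues;
#' * diversity counts units with replicate-mean normalized expression
#'   strictly above `diversity_cutoff` (10);
#' * differential-expression annotation flags Benjamini-Hochberg adjusted
#'   p-values below `fdr_alpha` (0.05).
#'
#' @param tissue_min_count raw-count detection threshold for tissues
#'   (strict `>`)
#' @param tissue_min_replicates replicates that must pass the threshold
#' @param biofluid_min_count raw-count detection threshold for biofluids
#'   (strict `>`)
#' @param biofluid_min_fraction fraction of samples that must pass
#'   (strict `>`, in (0, 1))
#' @param fold_change_threshold minimum fold change for an elevation call
#' @param expression_cutoff minimum normalized expression in the defining
#'   tissue(s)
#' @param max_group_size largest group-enriched tissue set
#' @param diversity_cutoff normalized-expression threshold for diversity
#' @param fdr_alpha BH-adjusted significance level
#' @param seed integer seed driving all randomness
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(tissue_min_count = 25,
                            tissue_min_replicates = 2,
                            biofluid_min_count = 10,
                            biofluid_min_fraction = 0.5,
                            fold_change_threshold = 7,
                            expression_cutoff = 1,
                            max_group_size = 4,
                            diversity_cutoff = 10,
                            fdr_alpha = 0.05,
                            seed = 1L) {
  cfg <- list(tissue_min_count = tissue_min_count,
              tissue_min_replicates = tissue_min_replicates,
              biofluid_min_count = biofluid_min_count,
              biofluid_min_fraction = biofluid_min_fraction,
              fold_change_threshold = fold_change_threshold,
              expression_cutoff = expression_cutoff,
              max_group_size = max_group_size,
              diversity_cutoff = diversity_cutoff,
              fdr_alpha = fdr_alpha,
              seed = as.integer(seed))
  num <- setdiff(names(cfg), "seed")
  for (k in num) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("config value '", k, "' must be a single number")
    if (v <= 0) stop("config value '", k, "' must be > 0")
  }
  if (cfg$max_group_size < 2) stop("max_group_size must be >= 2")
  if (cfg$biofluid_min_fraction >= 1)
    stop("biofluid_min_fraction must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Load pipeline configuration from a YAML or JSON file
#'
#' Keys absent from the file take the defaults of [pipeline_config()]; every
#' effective value is reported via `message()`.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`); an empty file yields
#'   all defaults
#' @param quiet suppress the echo of effective values
#' @return a `pipeline_config`
#' @export
load_config <- function(path, quiet = FALSE) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(vals)) {
    if (!is.numeric(vals[[k]]))
      stop("config value '", k, "' must be numeric, got '", vals[[k]], "'")
  }
  cfg <- do.call(pipeline_config, vals)
  if (!quiet)
    message("effective config: ",
            paste(names(cfg), unlist(cfg), sep = "=", collapse = " "))
  cfg
}
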