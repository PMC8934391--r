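# Shared fixture builders for the test suite (all built in code).

toy_sequences <- function(n, len = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!(s %in% out)) out <- c(out, s)
  }
  out
}

toy_samples <- function(sources, replicates = 1, class = "tissue") {
  ids <- as.vector(t(outer(sources, seq_len(replicates),
                           function(s, r) sprintf("%s_r%d", s, r))))
  data.frame(sample_id = ids,
             source = rep(sources, each = replicates),
             source_class = class,
             replicate = rep(seq_len(replicates), times = length(sources)))
}

toy_set <- function(counts, sources = NULL, replicates = 1,
                    class = "tissue", biotype = "miRNA", seed = 99) {
  counts <- as.matrix(counts)
  if (is.null(sources)) sources <- sprintf("SRC%02d", seq_len(ncol(counts)))
  samples <- toy_samples(sources, replicates, class)
  stopifnot(nrow(samples) == ncol(counts))
  seqs <- toy_sequences(nrow(counts), seed = seed)
  dimnames(counts) <- list(seqs, samples$sample_id)
  srna_set(counts,
           data.frame(sequence = seqs,
                      biotype = rep_len(biotype, nrow(counts)),
                      parent_gene = sprintf("GENE-%03d", seq_len(nrow(counts)))),
           samples)
}

random_set <- function(seed, n_seq = 8, n_samp = 4, max_count = 50,
                       positive = FALSE) {
  set.seed(seed)
  lo <- if (positive) 1 else 0
  counts <- matrix(sample(lo:max_count, n_seq * n_samp, replace = TRUE),
                   n_seq, n_samp)
  genes <- sprintf("GENE-%03d", sample(ceiling(n_seq / 2), n_seq,
                                       replace = TRUE))
  bts <- BIOTYPES[(as.integer(factor(genes)) %% length(BIOTYPES)) + 1]
  seqs <- toy_sequences(n_seq)
  samples <- toy_samples(sprintf("S%02d", seq_len(n_samp)))
  dimnames(counts) <- list(seqs, samples$sample_id)
  srna_set(counts,
           data.frame(sequence = seqs, biotype = bts, parent_gene = genes),
           samples)
}

# The published expression profile of the gallbladder-enriched tRF
# (normalized counts averaged over replicates, 33 sources).
gallbladder_trf_profile <- function() {
  path <- system.file("extdata", "gallbladder_trf_profile.tsv",
                      package = "srnatlas")
  tab <- read.delim(path)
  stats::setNames(tab$normalized_counts, tab$tissue)
}

# Study conditions for the planted-enrichment recovery analysis: default
# atlas design, single-tissue enrichment plants at the given fold.
recovery_config <- function(seed, fold = 10) {
  simulation_config(seed = seed, planted_fold = fold,
                    planted_group_fraction = 0,
                    planted_enhanced_fraction = 0)
}

recovery_stats <- function(seed, fold = 10) {
  sim <- simulate_tissue_counts(recovery_config(seed, fold))
  filt <- filter_tissue(sim$matrix)$matrix
  calls <- classify_matrix(median_of_ratios(filt), pipeline_config())
  elevated <- calls$id[calls$category != "not_elevated"]
  planted <- sim$truth$plants$sequence
  list(tp = sum(planted %in% elevated),
       n_planted = length(planted),
       n_called = length(elevated),
       fp = sum(!(elevated %in% planted)))
}

# Study conditions for biofluid attribution recovery: plasma-like mixing
# weights over 6 of 8 tissues, per-tissue elevated sets large enough that
# baseline sums concentrate.
attribution_weights <- c(TISSUE_01 = 0.40, TISSUE_02 = 0.25,
                         TISSUE_03 = 0.15, TISSUE_04 = 0.10,
                         TISSUE_05 = 0.06, TISSUE_06 = 0.04)

attribution_config <- function(seed) {
  simulation_config(seed = seed, n_families = 400, planted_per_tissue = 40,
                    planted_group_fraction = 0,
                    biofluids = list(list(name = "PLASMA",
                                          weights = attribution_weights,
                                          background_fraction = 0.1,
                                          n_samples = 8)))
}

attribution_rank_cor <- function(seed) {
  cfg <- attribution_config(seed)
  sim <- simulate_tissue_counts(cfg)
  norm <- median_of_ratios(filter_tissue(sim$matrix)$matrix)
  elev <- elevated_sets(classify_matrix(norm, pipeline_config()))
  bf <- simulate_biofluid_counts(cfg, norm)
  detected <- detect_in_biofluid(bf, pipeline_config())
  mean_counts <- rowMeans(median_of_ratios(bf)$normalized)
  att <- attribute(detected, elev, mean_counts, biofluid = "PLASMA")
  w <- stats::setNames(rep(0, nrow(att)), att$tissue)
  w[names(attribution_weights)] <- attribution_weights
  stats::cor(att$read_fraction, w[att$tissue], method = "spearman")
}
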