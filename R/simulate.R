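#' Configuration for the synthetic small RNA data generator
#'
#' Describes the study design the simulator emulates: a panel of tissues
#' with biological replicates, unique sequences organised as isomiR
#' families around canonical sequences, a mixture of biotypes, planted
#' tissue-elevated sequences at a known fold, negative-binomial count
#' noise, and biofluids formed as weighted mixtures of tissue profiles
#' plus background.
#'
#' @param n_tissues number of tissue-like sources (default 8)
#' @param n_replicates biological replicates per tissue (default 3, as in
#'   the atlas design)
#' @param n_families number of parent genes / isomiR families
#' @param isomirs_per_family integer range `c(min, max)`: isoforms per
#'   family, drawn uniformly
#' @param biotype_proportions named vector over [BIOTYPES], summing to 1:
#'   family biotype mix
#' @param baseline_log_mean,baseline_log_sd log-normal parameters for
#'   family base expression
#' @param planted_per_tissue tissue-elevated sequences planted per tissue
#' @param planted_fold fold applied to planted sequences in their target
#'   tissue(s) (default 10)
#' @param planted_group_fraction fraction of plants that are 2-4-tissue
#'   group plants
#' @param planted_enhanced_fraction fraction of plants constructed to be
#'   tissue-enhanced (elevated over the mean of other tissues but not over
#'   their maximum)
#' @param nb_dispersion negative-binomial dispersion shared by all
#'   sequences (`0` means Poisson)
#' @param library_size expected reads per sample
#' @param biofluids list of biofluid descriptions, each a list with
#'   `name`, `weights` (named over tissues, summing to 1),
#'   `background_fraction` (in [0, 1)) and `n_samples`
#' @param seed integer; every random draw derives from it
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(n_tissues = 8,
                              n_replicates = 3,
                              n_families = 60,
                              isomirs_per_family = c(1, 5),
                              biotype_proportions = c(miRNA = 0.5, YRNA = 0.1,
                                                      tRNA = 0.15, piRNA = 0.1,
                                                      protein_coding = 0.1,
                                                      other = 0.05),
                              baseline_log_mean = log(200),
                              baseline_log_sd = 1,
                              planted_per_tissue = 5,
                              planted_fold = 10,
                              planted_group_fraction = 0.2,
                              planted_enhanced_fraction = 0,
                              nb_dispersion = 0.1,
                              library_size = 2e6,
                              biofluids = list(),
                              seed = 1L) {
  if (abs(sum(biotype_proportions) - 1) > 1e-9)
    stop("biotype_proportions must sum to 1")
  if (!setequal(names(biotype_proportions), BIOTYPES))
    stop("biotype_proportions must be named over the six biotypes")
  if (planted_fold <= 1) stop("planted_fold must be > 1")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (planted_group_fraction + planted_enhanced_fraction > 1)
    stop("planted category fractions must sum to at most 1")
  for (bf in biofluids) {
    if (!all(c("name", "weights", "n_samples") %in% names(bf)))
      stop("each biofluid needs name, weights and n_samples")
    if (abs(sum(bf$weights) - 1) > 1e-9)
      stop("mixing weights for '", bf$name, "' must sum to 1")
  }
  structure(list(n_tissues = n_tissues, n_replicates = n_replicates,
                 n_families = n_families,
                 isomirs_per_family = isomirs_per_family,
                 biotype_proportions = biotype_proportions,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 planted_per_tissue = planted_per_tissue,
                 planted_fold = planted_fold,
                 planted_group_fraction = planted_group_fraction,
                 planted_enhanced_fraction = planted_enhanced_fraction,
                 nb_dispersion = nb_dispersion,
                 library_size = library_size,
                 biofluids = biofluids,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# isomiRs as 5'/3' end-shift variants and single-base 3' additions of the
# canonical sequence
isomir_variants <- function(canonical, n) {
  variants <- character(0)
  guard <- 0
  while (length(variants) < n && guard < 200) {
    guard <- guard + 1
    v <- canonical
    if (stats::runif(1) < 0.5) v <- substr(v, 1 + sample(1:2, 1), nchar(v))
    if (stats::runif(1) < 0.5) v <- substr(v, 1, nchar(v) - sample(1:2, 1))
    if (stats::runif(1) < 0.4)
      v <- paste0(v, random_dna(1))
    if (nchar(v) >= 15 && v != canonical && !(v %in% variants))
      variants <- c(variants, v)
  }
  variants
}

nb_draw <- function(mu, dispersion) {
  if (dispersion == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a tissue atlas count set with planted ground truth
#'
#' Generates isomiR families (a canonical sequence plus end-shift
#' variants), draws family base expression log-normally and splits it
#' across family members by a symmetric Dirichlet draw, plants
#' tissue-elevated sequences by multiplying their target tissue(s) by
#' `planted_fold`, and draws counts from a negative binomial with each
#' sample's expected profile scaled to `library_size`. The same config and
#' seed reproduce the output exactly.
#'
#' @param config a [simulation_config()]
#' @return list with elements `matrix` (an [srna_set]) and `truth` (list
#'   with `plants`, a data.frame of planted sequence / category / tissues /
#'   fold; `mu`, the expected count of each sequence in each tissue's
#'   samples; and `biofluids`, the configured mixing weights)
#' @export
simulate_tissue_counts <- function(config = simulation_config()) {
  set.seed(config$seed)
  tissues <- sprintf("TISSUE_%02d", seq_len(config$n_tissues))

  gene_prefix <- c(miRNA = "MIR", YRNA = "YRF", tRNA = "TRF", piRNA = "PIR",
                   protein_coding = "PC", other = "OTH")
  fam_bt <- sample(BIOTYPES, config$n_families, replace = TRUE,
                   prob = config$biotype_proportions[BIOTYPES])
  seqs <- character(0); bts <- character(0); genes <- character(0)
  canonical <- logical(0); fam_of <- integer(0)
  for (f in seq_len(config$n_families)) {
    repeat {
      can <- random_dna(sample(19:28, 1))
      if (!(can %in% seqs)) break
    }
    k <- sample(config$isomirs_per_family[1]:config$isomirs_per_family[2], 1)
    members <- c(can, setdiff(isomir_variants(can, k - 1), seqs))
    gene <- sprintf("%s-%03d", gene_prefix[fam_bt[f]], f)
    seqs <- c(seqs, members)
    bts <- c(bts, rep(fam_bt[f], length(members)))
    genes <- c(genes, rep(gene, length(members)))
    canonical <- c(canonical, c(TRUE, rep(FALSE, length(members) - 1)))
    fam_of <- c(fam_of, rep(f, length(members)))
  }
  S <- length(seqs)

  fam_expr <- stats::rlnorm(config$n_families,
                            config$baseline_log_mean, config$baseline_log_sd)
  base <- numeric(S)
  for (f in seq_len(config$n_families)) {
    idx <- which(fam_of == f)
    w <- stats::rgamma(length(idx), 1)  # symmetric Dirichlet split
    base[idx] <- fam_expr[f] * w / sum(w)
  }

  profile <- matrix(base, S, config$n_tissues,
                    dimnames = list(seqs, tissues))
  n_plants <- config$planted_per_tissue * config$n_tissues
  if (n_plants > S)
    stop("infeasible config: ", n_plants, " plants but only ", S, " sequences")
  plant_rows <- if (n_plants > 0) sample(S, n_plants) else integer(0)
  plants <- vector("list", n_plants)
  i <- 0
  for (t in seq_len(config$n_tissues)) {
    for (p in seq_len(config$planted_per_tissue)) {
      i <- i + 1
      s <- plant_rows[i]
      u <- stats::runif(1)
      if (u < config$planted_group_fraction && config$n_tissues > 4) {
        g_extra <- sample(setdiff(seq_len(config$n_tissues), t),
                          sample(1:3, 1))
        target <- sort(c(t, g_extra))
        profile[s, target] <- profile[s, target] * config$planted_fold
        category <- "group_enriched"
      } else if (u < config$planted_group_fraction +
                   config$planted_enhanced_fraction &&
                 config$n_tissues > 3) {
        # elevated over the mean of the others but below fold x their max:
        # one secondary tissue is raised 3x baseline to break single-tissue
        # enrichment, the target sits 1.5x fold above the resulting mean
        t2 <- sample(setdiff(seq_len(config$n_tissues), t), 1)
        Tn <- config$n_tissues
        profile[s, t2] <- profile[s, t2] * 3
        m1 <- 1.5 * config$planted_fold * ((Tn - 2) + 3) / (Tn - 1)
        profile[s, t] <- profile[s, t] * m1
        target <- t
        category <- "tissue_enhanced"
      } else {
        profile[s, t] <- profile[s, t] * config$planted_fold
        target <- t
        category <- "tissue_enriched"
      }
      plants[[i]] <- data.frame(sequence = seqs[s], category = category,
                                tissues = paste(tissues[target],
                                                collapse = ";"),
                                fold = config$planted_fold)
    }
  }
  plants <- if (n_plants > 0) do.call(rbind, plants)
            else data.frame(sequence = character(0), category = character(0),
                            tissues = character(0), fold = numeric(0))

  n_samp <- config$n_tissues * config$n_replicates
  counts <- matrix(0L, S, n_samp)
  mu_mat <- matrix(0, S, config$n_tissues,
                   dimnames = list(seqs, tissues))
  ids <- character(n_samp)
  src <- character(n_samp); rep_no <- integer(n_samp)
  j <- 0
  for (t in seq_len(config$n_tissues)) {
    mu <- profile[, t] / sum(profile[, t]) * config$library_size
    mu_mat[, t] <- mu
    for (r in seq_len(config$n_replicates)) {
      j <- j + 1
      counts[, j] <- as.integer(nb_draw(mu, config$nb_dispersion))
      ids[j] <- sprintf("%s_r%d", tissues[t], r)
      src[j] <- tissues[t]
      rep_no[j] <- r
    }
  }
  dimnames(counts) <- list(seqs, ids)
  mat <- srna_set(counts,
                  data.frame(sequence = seqs, biotype = bts,
                             parent_gene = genes, is_canonical = canonical),
                  data.frame(sample_id = ids, source = src,
                             source_class = "tissue", replicate = rep_no))
  truth <- list(plants = plants,
                mu = mu_mat,
                biofluids = lapply(config$biofluids,
                                   function(bf) bf$weights))
  names(truth$biofluids) <- vapply(config$biofluids, `[[`, "", "name")
  list(matrix = mat, truth = truth)
}

#' Simulate biofluid count sets as mixtures of tissue profiles
#'
#' Each biofluid sample's expected profile is the weighted sum of the
#' tissues' replicate-mean normalized profiles, plus a uniform background
#' over a random subset of sequences, scaled to the library size; counts
#' are negative-binomial. The RNG stream is derived from the config seed
#' (seed + 1) so tissue and biofluid draws are independently reproducible.
#'
#' @param config a [simulation_config()] with a non-empty `biofluids` list
#' @param tissue_norm the normalized tissue [srna_set]
#'   (`median_of_ratios(simulate_tissue_counts(config)$matrix)` or a
#'   filtered version of it)
#' @return an [srna_set] with one column per biofluid sample
#' @export
simulate_biofluid_counts <- function(config, tissue_norm) {
  if (length(config$biofluids) == 0) stop("no biofluids configured")
  set.seed(config$seed + 1L)
  prof <- source_profiles(tissue_norm)
  S <- nrow(prof)
  cols <- list(); ids <- character(0); src <- character(0)
  rep_no <- integer(0)
  for (bf in config$biofluids) {
    unknown <- setdiff(names(bf$weights), colnames(prof))
    if (length(unknown) > 0)
      stop("mixing weights reference unknown tissue(s): ",
           paste(unknown, collapse = ", "))
    bg_frac <- if (is.null(bf$background_fraction)) 0
               else bf$background_fraction
    mix <- as.numeric(prof[, names(bf$weights), drop = FALSE] %*% bf$weights)
    bg <- numeric(S)
    if (bg_frac > 0) {
      subset_rows <- sample(S, max(1, round(0.3 * S)))
      bg[subset_rows] <- 1
      bg <- bg / sum(bg) * sum(mix)
    }
    expected <- (1 - bg_frac) * mix + bg_frac * bg
    mu <- expected / sum(expected) * config$library_size
    for (r in seq_len(bf$n_samples)) {
      cols[[length(cols) + 1]] <- as.integer(nb_draw(mu, config$nb_dispersion))
      ids <- c(ids, sprintf("%s_s%d", bf$name, r))
      src <- c(src, bf$name)
      rep_no <- c(rep_no, r)
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(rownames(prof), ids)
  feats <- tissue_norm$features
  srna_set(counts, feats,
           data.frame(sample_id = ids, source = src,
                      source_class = "biofluid", replicate = rep_no))
}

#' Expand a single-sample count column into reads plus alignment evidence
#'
#' Emits exactly `count` copies of each sequence as reads. Evidence lists
#' the true (gene, biotype) candidate and, at `decoy_rate`, an extra decoy
#' candidate of strictly lower biotype priority (inert under the priority
#' rule); a `unmapped_fraction` of reads is marked as not genome-mapped.
#'
#' @param x a single-column [srna_set]
#' @param decoy_rate probability of attaching a lower-priority decoy
#'   candidate to a read
#' @param unmapped_fraction probability that a read is marked unmapped
#' @param seed RNG seed for the decoy/unmapped draws
#' @return list with elements `reads` and `evidence` (data.frames accepted
#'   by [collapse_reads()])
#' @export
simulate_reads <- function(x, decoy_rate = 0, unmapped_fraction = 0,
                           seed = 1L) {
  if (ncol(x$counts) != 1) stop("expected a single-sample count set")
  if (decoy_rate < 0 || decoy_rate > 1 ||
      unmapped_fraction < 0 || unmapped_fraction > 1)
    stop("rates must lie in [0, 1]")
  set.seed(seed)
  n_per <- x$counts[, 1]
  seq_rep <- rep(x$features$sequence, n_per)
  gene_rep <- rep(x$features$parent_gene, n_per)
  bt_rep <- rep(x$features$biotype, n_per)
  n <- length(seq_rep)
  reads <- data.frame(read_id = sprintf("read_%06d", seq_len(n)),
                      sequence = seq_rep)
  cand <- paste(gene_rep, bt_rep, sep = ":")
  if (decoy_rate > 0 && n > 0) {
    with_decoy <- stats::runif(n) < decoy_rate
    rank <- match(bt_rep, BIOTYPES)
    can_decoy <- with_decoy & rank < length(BIOTYPES)
    if (any(can_decoy)) {
      decoy_bt <- BIOTYPES[rank[can_decoy] +
        vapply(length(BIOTYPES) - rank[can_decoy],
               function(k) sample(k, 1), 0L)]
      cand[can_decoy] <- paste0(cand[can_decoy], ";DECOY-",
                                seq_len(sum(can_decoy)), ":", decoy_bt)
    }
  }
  mapped <- if (n > 0) stats::runif(n) >= unmapped_fraction else logical(0)
  evidence <- data.frame(read_id = reads$read_id,
                         genome_mapped = mapped,
                         candidates = cand)
  list(reads = reads, evidence = evidence)
}
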