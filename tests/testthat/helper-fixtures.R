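# Shared fixture builders. All randomness goes through explicit seeds so
# fixtures are identical across runs.

toy_snp_records <- function(n, chrom = "chr1", pos = seq_len(n) * 1000L) {
  data.frame(snp_id = sprintf("rs%03d", seq_len(n)), chrom = chrom,
             pos = pos, major_allele = "A", minor_allele = "G",
             stringsAsFactors = FALSE)
}

toy_genotypes <- function(n_subjects, n_snps, seed = 1, maf = 0.3,
                          missing_rate = 0) {
  set.seed(seed)
  codes <- matrix(rbinom(n_subjects * n_snps, 2, maf), n_subjects)
  if (missing_rate > 0)
    codes[runif(length(codes)) < missing_rate] <- NA
  rownames(codes) <- sprintf("S%03d", seq_len(n_subjects))
  genotype_matrix(codes, toy_snp_records(n_snps))
}

# Small cohort with one strongly informative SNP, one informative
# categorical demographic, and noise.
toy_cohort <- function(n = 200, n_snps = 10, seed = 7) {
  set.seed(seed)
  gm <- toy_genotypes(n, n_snps, seed = seed + 1)
  labels <- rbinom(n, 1, plogis(0.3 + 0.9 * (gm$codes[, 1] - mean(gm$codes[, 1]))))
  dem <- data.frame(
    risk_cat = rbinom(n, 1, plogis(-0.5 + 1.2 * labels)),
    noise_cat = rbinom(n, 2, 0.4),
    cont_feat = rnorm(n, 50, 10))
  schema <- data.frame(
    name = c("risk_cat", "noise_cat", "cont_feat"),
    kind = c("categorical", "categorical", "continuous"),
    group = c("group1", "group1", "group2"), stringsAsFactors = FALSE)
  cohort(gm, dem, schema, labels, provenance = "toy fixture")
}

fast_params <- function(n_trees = 60, depth = 3) {
  hyperparams(n_trees = n_trees, tree_depth = depth, learning_rate = 0.1,
              subsample_rate = 0.8, min_child_weight = 1, gamma = 0,
              alpha = 0, scale_pos_weight = 1)
}

write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S001", "S002", "S003", sep = "\t"),
    paste("chr1", "100", "rs001", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "250", "rs002", "T", "C", ".", "PASS", ".", "GT",
          "0/1", "0/0", "0/0", sep = "\t"))
  writeLines(lines, path)
  path
}

# Independent brute-force average precision: loops over every cut-off and
# recomputes TP/FP/FN from scratch. Deliberately naive.
brute_force_ap <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  n_pos <- sum(labels == 1)
  for (t in thresholds) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}
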