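#' Read a published SNP / odds-ratio weight table
#'
#' The weights TSV has one header row and columns `snp_id`, `effect_allele`
#' and `OR` (odds ratio per effect-allele copy).
#'
#' @param path TSV file path.
#' @return A `prs_weights` data.frame.
#' @export
read_prs_weights <- function(path) {
  w <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("snp_id", "effect_allele", "OR")
  if (!all(req %in% names(w)))
    stop("weights file needs columns: ", paste(req, collapse = ", "))
  prs_weights(w$snp_id, w$effect_allele, w$OR)
}

#' @rdname read_prs_weights
#' @param snp_id,effect_allele,OR parallel vectors: SNP identifiers, the
#'   risk (effect) allele, and its odds ratio (> 0, finite).
#' @export
prs_weights <- function(snp_id, effect_allele, OR) {
  if (anyDuplicated(snp_id)) stop("duplicated snp_id in PRS weights")
  if (any(!is.finite(OR) | OR <= 0))
    stop("odds ratios must be finite and positive")
  structure(data.frame(snp_id = snp_id, effect_allele = effect_allele,
                       OR = OR, stringsAsFactors = FALSE),
            class = c("prs_weights", "data.frame"))
}

#' Polygenic risk scores
#'
#' The standard weighted allele-dosage sum: for subject `s`,
#' `score_s = sum_j d_sj * ln(OR_j)`, where `d_sj` is the subject's
#' effect-allele count at SNP `j`. When the effect allele is the declared
#' major allele the additive code is flipped (`2 - code`). Weighted SNPs
#' absent from the genotype panel are skipped with a warning; an effect
#' allele matching neither declared allele is an error. Scores are raw
#' ranking statistics — no refitting, centring or standardisation.
#'
#' @param gm a `genotype_matrix` (no missing calls among the scored SNPs).
#' @param weights a `prs_weights` table.
#' @return Named numeric vector of per-subject scores, with attribute
#'   `n_skipped`.
#' @export
prs_scores <- function(gm, weights) {
  stopifnot(inherits(weights, "prs_weights"))
  present <- weights$snp_id %in% gm$snps$snp_id
  if (!all(present))
    warning(sum(!present), " weighted SNP(s) absent from the genotype ",
            "panel were skipped")
  w <- weights[present, , drop = FALSE]
  scores <- stats::setNames(numeric(nrow(gm$codes)), rownames(gm$codes))
  for (i in seq_len(nrow(w))) {
    rec <- gm$snps[gm$snps$snp_id == w$snp_id[i], ]
    code <- gm$codes[, w$snp_id[i]]
    dosage <- if (w$effect_allele[i] == rec$minor_allele) code
      else if (w$effect_allele[i] == rec$major_allele) 2L - code
      else stop("effect allele '", w$effect_allele[i], "' of SNP ",
                w$snp_id[i], " matches neither declared allele (",
                rec$major_allele, "/", rec$minor_allele, ")")
    scores <- scores + dosage * log(w$OR[i])
  }
  attr(scores, "n_skipped") <- sum(!present)
  scores
}

#' Evaluate PRS scores as a classifier
#'
#' Average precision of the raw polygenic scores used directly as the
#' ranking statistic.
#'
#' @param scores per-subject PRS scores.
#' @param labels 0/1 labels.
#' @return AP value in `[0, 1]`.
#' @export
evaluate_prs <- function(scores, labels) average_precision(scores, labels)

#' Fixed-feature baseline model
#'
#' Trains the boosted-tree classifier on a fixed, pre-specified feature set
#' (no ranking, no adaptive search) over a split plan and reports the test
#' mAP. Covers the literature-SNP baseline, literature SNPs + demographic
#' group, and group-only models. Per split the model is fit on
#' train + validation and scored on the test fold; when `grid` is supplied
#' the hyperparameters are first tuned on the training set.
#'
#' @param cohort a [cohort()].
#' @param feature_names non-empty character vector of SNP identifiers
#'   and/or demographic feature names.
#' @param splits a `split_plan` from [make_splits()].
#' @param params fixed [hyperparams()] (ignored if `grid` is given).
#' @param grid optional [hyper_grid()] enabling per-split tuning.
#' @param tune_folds inner CV folds when tuning.
#' @param seed integer seed.
#' @return List with `map`, `sd`, and per-split `test_aps`.
#' @export
fixed_feature_model <- function(cohort, feature_names, splits,
                                params = hyperparams(), grid = NULL,
                                tune_folds = 5, seed = 1L) {
  if (!length(feature_names)) stop("empty feature list")
  all_snps <- cohort$genotypes$snps$snp_id
  snp_f <- feature_names[feature_names %in% all_snps]
  dem_f <- setdiff(feature_names, snp_f)
  unknown <- setdiff(dem_f, cohort$schema$name)
  if (length(unknown))
    stop("unknown feature(s): ", paste(utils::head(unknown, 3), collapse = ", "))
  y <- cohort$labels
  aps <- vapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    trainval <- c(sp$train, sp$validation)
    fm_tv <- assemble_features(cohort, snp_f, dem_f, subjects = trainval,
                               scaler_subjects = trainval)
    fm_te <- assemble_features(cohort, snp_f, dem_f, subjects = sp$test,
                               scaler_subjects = trainval)
    p <- if (!is.null(grid)) {
      fm_tr <- assemble_features(cohort, snp_f, dem_f, subjects = sp$train,
                                 scaler_subjects = sp$train)
      tune_sequential(fm_tr$x, y[sp$train], grid, folds = tune_folds,
                      seed = child_seed(seed, 600L + s))$params
    } else params
    mdl <- gbt_fit(fm_tv$x, y[trainval], p, seed = child_seed(seed, 700L + s))
    average_precision(gbt_predict(mdl, fm_te$x), y[sp$test])
  }, numeric(1))
  agg <- mean_ap(aps)
  list(map = agg$map, sd = agg$sd, test_aps = aps)
}
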