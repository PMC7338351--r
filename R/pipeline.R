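#' Repeated stratified cross-validation split plan
#'
#' Builds `k1` independent stratified `k2`-fold partitions. Within each
#' repetition, each outer fold serves once as the test set; one stratified
#' inner fold (1/`k2`) of the remaining subjects is reserved as the
#' validation set and the rest train the model. Train, validation and test
#' are pairwise disjoint within every (repetition, fold) pair, class
#' proportions are preserved to within one subject, and the test folds of a
#' repetition cover the cohort.
#'
#' @param labels 0/1 label vector (each class needs >= `k2` subjects).
#' @param k1 number of repetitions.
#' @param k2 number of folds.
#' @param seed integer seed; plans are fully reproducible from it.
#' @return A `split_plan`: list of `k1 * k2` elements, each with `rep`,
#'   `fold` and integer index sets `train`, `validation`, `test`.
#' @export
make_splits <- function(labels, k1 = 10, k2 = 5, seed = 1L) {
  stopifnot(all(labels %in% 0:1), k1 >= 1, k2 >= 2)
  for (cls in 0:1)
    if (sum(labels == cls) < k2)
      stop("class ", cls, " has fewer subjects (", sum(labels == cls),
           ") than folds (", k2, ")")
  plan <- list()
  for (r in seq_len(k1)) {
    with_seed(child_seed(seed, r), {
      outer <- stratified_folds(labels, k2)
      for (j in seq_len(k2)) {
        test <- which(outer == j)
        rest <- which(outer != j)
        # one stratified inner fold (1/k2 of the outer-training portion)
        validation <- integer()
        for (cls in 0:1) {
          idx <- shuffle(rest[labels[rest] == cls])
          validation <- c(validation, idx[seq_len(length(idx) %/% k2)])
        }
        validation <- sort(validation)
        train <- setdiff(rest, validation)
        if (length(intersect(train, validation)) ||
            length(intersect(train, test)) ||
            length(intersect(validation, test)))
          stop("internal error: overlapping split sets")  # never reached
        plan[[length(plan) + 1L]] <-
          list(rep = r, fold = j, train = train, validation = validation,
               test = test)
      }
    })
  }
  structure(plan, class = "split_plan", k1 = k1, k2 = k2, seed = seed)
}

# Single stratified train/test split per repetition at a given train
# fraction, with an inner validation fold carved from the train portion.
make_ratio_splits <- function(labels, k1, ratio, seed = 1L,
                              inner_frac = 0.2) {
  stopifnot(ratio > 0, ratio < 1)
  plan <- list()
  for (r in seq_len(k1)) {
    with_seed(child_seed(seed, 1000L + r), {
      test <- integer()
      rest <- integer()
      for (cls in 0:1) {
        idx <- shuffle(which(labels == cls))
        n_test <- round((1 - ratio) * length(idx))
        if (n_test < 2)
          stop("test fold below minimum size (2 per class) at ratio ",
               ratio, " for class ", cls)
        test <- c(test, idx[seq_len(n_test)])
        rest <- c(rest, idx[-seq_len(n_test)])
      }
      val <- integer()
      train <- integer()
      for (cls in 0:1) {
        idx <- shuffle(rest[labels[rest] == cls])
        n_val <- max(1L, round(inner_frac * length(idx)))
        val <- c(val, idx[seq_len(n_val)])
        train <- c(train, idx[-seq_len(n_val)])
      }
      plan[[length(plan) + 1L]] <-
        list(rep = r, fold = 1L, train = sort(train),
             validation = sort(val), test = sort(test))
    })
  }
  structure(plan, class = "split_plan", k1 = k1, k2 = 1L, seed = seed)
}

#' Discover networks of interacting genetic and demographic risk factors
#'
#' The central fitting function. For every (repetition, fold) split of a
#' repeated stratified cross-validation plan it (i) optionally tunes the
#' boosted-tree hyperparameters on the training genotypes, (ii) ranks all
#' SNPs on the training set by split-gain importance, (iii) concatenates
#' the top-`m` SNPs with the chosen demographic feature group to form the
#' candidate list, (iv) runs the greedy adaptive search against the
#' validation set to select one interacting-feature network, (v) refits on
#' train + validation with the selected network and scores average
#' precision on the held-out test fold. Per-split results aggregate into a
#' mean average precision (mAP) with its standard deviation and
#' feature-selection counts.
#'
#' SNP columns with missing calls are excluded before modelling.
#'
#' @param cohort a [cohort()].
#' @param group demographic group to interact with the SNPs: `"group1"`,
#'   `"group2"`, `"both"`, or `"none"` (SNP-only model).
#' @param m number of top-ranked SNPs concatenated to the group features;
#'   defaults to 18 (15 when `group = "both"`).
#' @param k1,k2 repetitions and folds of the split plan.
#' @param params fixed [hyperparams()] used when `tune = "none"`.
#' @param tune `"none"` (use `params`), `"per_rep"` (tune once per
#'   repetition, on the first fold's training set) or `"per_fold"`.
#' @param grid [hyper_grid()] searched when tuning.
#' @param tune_folds inner CV folds of the tuning stage.
#' @param epsilon acceptance tolerance of the adaptive search.
#' @param seed integer seed controlling splits, tuning and every refit.
#' @param splits optional pre-built `split_plan` overriding `k1`/`k2`.
#' @param verbose print per-split progress.
#' @return An `epiboost_fit` with per-split `networks`, `test_aps`,
#'   `train_aps`, tuned/fixed `params_per_split`, aggregate `map`,
#'   `map_sd`, `selection_counts`, the `splits` used, `settings`, and the
#'   `cohort`.
#' @seealso [leave_one_out_importance()], [sensitivity_sweep()],
#'   [make_splits()], [adaptive_search()]
#' @export
epiboost <- function(cohort, group = c("group1", "group2", "both", "none"),
                     m = NULL, k1 = 10, k2 = 5, params = NULL,
                     tune = c("none", "per_rep", "per_fold"),
                     grid = hyper_grid(), tune_folds = 5, epsilon = 0,
                     seed = 1L, splits = NULL, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  group <- match.arg(group)
  tune <- match.arg(tune)
  if (is.null(m)) m <- if (group == "both") 15L else 18L
  if (is.null(params)) params <- hyperparams()

  gm <- cohort$genotypes
  if (anyNA(gm$codes)) {
    gm <- filter_missing_snps(gm)
    cohort$genotypes <- gm
  }
  n_snps <- ncol(gm$codes)
  if (n_snps < 1) stop("no complete SNP columns available")
  m <- min(m, n_snps)
  gf <- if (group == "none") character() else group_features(cohort, group)
  y <- cohort$labels

  if (is.null(splits)) splits <- make_splits(y, k1, k2, seed)
  all_snps <- gm$snps$snp_id

  networks <- vector("list", length(splits))
  params_per_split <- vector("list", length(splits))
  test_aps <- numeric(length(splits))
  train_aps <- numeric(length(splits))
  tuned_by_rep <- list()

  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    step <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("repetition ", sp$rep, ", fold ", sp$fold, ", ", what, ": ",
             conditionMessage(e), call. = FALSE))
    }
    x_rank <- step("assembling genotypes", {
      fm <- assemble_features(cohort, snp_ids = all_snps,
                              subjects = sp$train)
      fm$x
    })
    p <- params
    if (tune == "per_fold" ||
        (tune == "per_rep" && is.null(tuned_by_rep[[as.character(sp$rep)]]))) {
      p <- step("tuning", tune_sequential(x_rank, y[sp$train], grid,
                                          folds = tune_folds,
                                          seed = child_seed(seed, 50L + s)))$params
      if (tune == "per_rep") tuned_by_rep[[as.character(sp$rep)]] <- p
    } else if (tune == "per_rep") {
      p <- tuned_by_rep[[as.character(sp$rep)]]
    }
    params_per_split[[s]] <- p

    ranked <- step("ranking", rank_features(x_rank, y[sp$train], p,
                                            seed = child_seed(seed, 100L + s)))
    candidates <- concat_candidates(ranked, m, gf)
    snp_cand <- candidates[candidates %in% all_snps]
    fm_train <- assemble_features(cohort, snp_cand, gf,
                                  subjects = sp$train,
                                  scaler_subjects = sp$train)
    fm_val <- assemble_features(cohort, snp_cand, gf,
                                subjects = sp$validation,
                                scaler_subjects = sp$train)
    nw <- step("adaptive search",
               adaptive_search(candidates, fm_train$x, y[sp$train],
                               fm_val$x, y[sp$validation], p,
                               epsilon = epsilon,
                               seed = child_seed(seed, 200L + s)))
    nw$provenance <- list(rep = sp$rep, fold = sp$fold,
                          candidates = candidates)
    networks[[s]] <- nw

    trainval <- c(sp$train, sp$validation)
    aps <- step("test evaluation", {
      fm_tv <- assemble_features(cohort, snp_cand, gf, subjects = trainval,
                                 scaler_subjects = trainval)
      fm_te <- assemble_features(cohort, snp_cand, gf, subjects = sp$test,
                                 scaler_subjects = trainval)
      mdl <- gbt_fit(fm_tv$x[, nw$features, drop = FALSE], y[trainval], p,
                     seed = child_seed(seed, 300L + s))
      c(test = average_precision(
          gbt_predict(mdl, fm_te$x[, nw$features, drop = FALSE]), y[sp$test]),
        train = average_precision(
          gbt_predict(mdl, fm_tv$x[, nw$features, drop = FALSE]), y[trainval]))
    })
    test_aps[s] <- aps[["test"]]
    train_aps[s] <- aps[["train"]]
    if (verbose)
      message(sprintf("rep %d fold %d: %d features, val AP %.3f, test AP %.3f",
                      sp$rep, sp$fold, length(nw$features), nw$val_ap,
                      test_aps[s]))
  }

  counts <- sort(table(unlist(lapply(networks, `[[`, "features"))),
                 decreasing = TRUE)
  agg <- mean_ap(test_aps)
  structure(list(networks = networks, test_aps = test_aps,
                 train_aps = train_aps, map = agg$map, map_sd = agg$sd,
                 selection_counts = counts,
                 params_per_split = params_per_split, splits = splits,
                 settings = list(group = group, m = m,
                                 k1 = attr(splits, "k1"),
                                 k2 = attr(splits, "k2"),
                                 epsilon = epsilon, seed = seed,
                                 tune = tune),
                 cohort = cohort, call = match.call()),
            class = "epiboost_fit")
}

#' Leave-one-feature-out importance
#'
#' For every feature in every selected network, refits the classifier from
#' scratch without that feature on the split's train + validation subjects
#' and recomputes the test-fold average precision. The relative change
#' `(AP_without - AP_full) / AP_full` is averaged over the splits in which
#' the feature was selected; negative means removing the feature hurts.
#' Removing the only feature of a single-feature network leaves no model;
#' its AP is reported at the constant-score baseline (test prevalence) and
#' the row is flagged.
#'
#' @param fit an `epiboost_fit`.
#' @return data.frame with `feature`, `source`, `n_selected`,
#'   `mean_rel_change`, `flagged`, ordered most important (most negative)
#'   first.
#' @export
leave_one_out_importance <- function(fit) {
  stopifnot(inherits(fit, "epiboost_fit"))
  cohort <- fit$cohort
  y <- cohort$labels
  all_snps <- cohort$genotypes$snps$snp_id
  rows <- list()
  for (s in seq_along(fit$networks)) {
    nw <- fit$networks[[s]]
    sp <- fit$splits[[s]]
    p <- fit$params_per_split[[s]]
    ap_full <- fit$test_aps[s]
    trainval <- c(sp$train, sp$validation)
    snp_feats <- nw$features[nw$features %in% all_snps]
    dem_feats <- setdiff(nw$features, snp_feats)
    fm_tv <- assemble_features(cohort, snp_feats, dem_feats,
                               subjects = trainval,
                               scaler_subjects = trainval)
    fm_te <- assemble_features(cohort, snp_feats, dem_feats,
                               subjects = sp$test,
                               scaler_subjects = trainval)
    for (f in nw$features) {
      rest <- setdiff(nw$features, f)
      flagged <- length(rest) == 0
      ap_wo <- if (flagged) mean(y[sp$test]) else {
        mdl <- gbt_fit(fm_tv$x[, rest, drop = FALSE], y[trainval], p,
                       seed = child_seed(fit$settings$seed, 400L + s))
        average_precision(gbt_predict(mdl, fm_te$x[, rest, drop = FALSE]),
                          y[sp$test])
      }
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, split = s,
                   rel_change = (ap_wo - ap_full) / ap_full,
                   flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, per$feature), function(d)
    data.frame(feature = d$feature[1],
               source = if (d$feature[1] %in% all_snps) "snp" else "demographic",
               n_selected = nrow(d), mean_rel_change = mean(d$rel_change),
               flagged = any(d$flagged), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$mean_rel_change), ]
  rownames(agg) <- NULL
  agg
}

#' Sensitivity sweeps over pipeline settings
#'
#' Re-runs the full pipeline once per value of one axis, all other settings
#' fixed, and reports the validation mAP curve (mean and sd over splits of
#' the selected networks' validation AP).
#'
#' @param cohort a [cohort()].
#' @param axis `"top_m"` (number of top-ranked SNPs; values may include
#'   `"all"`), `"repetitions"` (`k1` values), or `"split_ratio"` (train
#'   fractions; one stratified split per repetition at that ratio).
#' @param values axis values.
#' @param file optional TSV path for the curve.
#' @param ... further arguments passed to [epiboost()] (e.g. `group`,
#'   `params`, `k1`, `k2`, `seed`).
#' @return data.frame with `value`, `map_validation`, `sd`, `map_test`.
#' @export
sensitivity_sweep <- function(cohort, axis = c("top_m", "repetitions",
                                               "split_ratio"),
                              values, file = NULL, ...) {
  axis <- match.arg(axis)
  args <- list(...)
  rows <- lapply(values, function(v) {
    a <- args
    a$cohort <- cohort
    if (axis == "top_m") {
      a$m <- if (identical(v, "all")) ncol(cohort$genotypes$codes)
             else as.integer(v)
    } else if (axis == "repetitions") {
      a$k1 <- as.integer(v)
    } else {
      ratio <- as.numeric(v)
      a$splits <- make_ratio_splits(cohort$labels,
                                    k1 = a$k1 %||% 10L, ratio = ratio,
                                    seed = a$seed %||% 1L)
    }
    fit <- do.call(epiboost, a)
    val_aps <- vapply(fit$networks, `[[`, numeric(1), "val_ap")
    data.frame(value = as.character(v), map_validation = mean(val_aps),
               sd = if (length(val_aps) > 1) stats::sd(val_aps) else 0,
               map_test = fit$map, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
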