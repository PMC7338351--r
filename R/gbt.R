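#' Hyperparameters of the boosted-tree classifier
#'
#' The eight tunable settings of the gradient boosted tree model: ensemble
#' size, tree depth, learning rate (shrinkage), per-tree row subsampling
#' fraction (without replacement), minimum child weight, gamma (minimum
#' loss reduction to split), alpha (L1 regularisation), and the positive
#' class weight.
#'
#' @param n_trees number of boosting rounds.
#' @param tree_depth maximum tree depth.
#' @param learning_rate shrinkage factor in (0, 1].
#' @param subsample_rate per-tree subject subsampling fraction in (0, 1].
#' @param min_child_weight minimum sum of instance weights in a node.
#' @param gamma minimum loss reduction required to split.
#' @param alpha L1 regularisation on leaf weights.
#' @param scale_pos_weight weight multiplier for the positive class.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(n_trees = 200, tree_depth = 2, learning_rate = 0.01,
                        subsample_rate = 0.4, min_child_weight = 0,
                        gamma = 0, alpha = 2, scale_pos_weight = 1) {
  stopifnot(n_trees >= 1, tree_depth >= 1,
            learning_rate > 0, subsample_rate > 0, subsample_rate <= 1,
            min_child_weight >= 0, gamma >= 0, alpha >= 0,
            scale_pos_weight > 0)
  structure(list(n_trees = as.integer(n_trees),
                 tree_depth = as.integer(tree_depth),
                 learning_rate = learning_rate,
                 subsample_rate = subsample_rate,
                 min_child_weight = min_child_weight, gamma = gamma,
                 alpha = alpha, scale_pos_weight = scale_pos_weight),
            class = "hyperparams")
}

#' Hyperparameter search grid
#'
#' Candidate lists per hyperparameter. The defaults are the search ranges
#' used for sequential optimisation of the boosted-tree model on genotype
#' data: trees `[50..300]`, depth `[2,4,6,8]`, learning rate
#' `[0.001, 0.01, 0.1]`, subsampling `[0.1..1]`, minimum child weight
#' `[0..5]`, gamma `[0..9]`, alpha `[1e-5..100]`, and positive-class weight
#' `[0.56, 1]` (0.56 being the control/case ratio of the motivating
#' 250/445 cohort).
#'
#' @param n_trees,tree_depth,learning_rate,subsample_rate,min_child_weight,gamma,alpha,scale_pos_weight
#'   non-empty numeric candidate vectors.
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(n_trees = c(50, 100, 150, 200, 250, 300),
                       tree_depth = c(2, 4, 6, 8),
                       learning_rate = c(0.001, 0.01, 0.1),
                       subsample_rate = seq(0.1, 1, by = 0.1),
                       min_child_weight = c(0, 0.1, 0.2, 0.5, 0.6, 0.7, 0.8,
                                            0.9, 1, 2, 3, 4, 5),
                       gamma = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8,
                                 0.9, 1, 4, 9),
                       alpha = c(1e-5, 1e-2, 0.1, 1, 2, 5, 100),
                       scale_pos_weight = c(0.56, 1)) {
  g <- list(n_trees = n_trees, tree_depth = tree_depth,
            learning_rate = learning_rate, subsample_rate = subsample_rate,
            min_child_weight = min_child_weight, gamma = gamma,
            alpha = alpha, scale_pos_weight = scale_pos_weight)
  if (any(!lengths(g))) stop("every hyperparameter needs >= 1 candidate")
  structure(g, class = "hyper_grid")
}

as_xgb_params <- function(p, seed) {
  list(objective = "binary:logistic", max_depth = p$tree_depth,
       eta = p$learning_rate, subsample = p$subsample_rate,
       min_child_weight = p$min_child_weight, gamma = p$gamma,
       alpha = p$alpha, scale_pos_weight = p$scale_pos_weight,
       nthread = 1L, seed = seed)
}

#' Fit the boosted-tree classifier
#'
#' Trains an XGBoost ensemble with logistic loss for binary classification.
#' Each call trains from scratch (no warm starts); results are
#' deterministic given the data, hyperparameters and seed (single-threaded,
#' per-tree subsampling without replacement driven by the seed).
#'
#' @param x numeric design matrix (subjects x features, named columns).
#' @param y 0/1 labels.
#' @param params a [hyperparams()] object.
#' @param seed integer seed for the booster's RNG.
#' @return A `gbt_model`: the trained booster plus the feature descriptor
#'   order it expects and the hyperparameters used.
#' @export
gbt_fit <- function(x, y, params = hyperparams(), seed = 1L) {
  stopifnot(inherits(params, "hyperparams"), nrow(x) == length(y),
            all(y %in% 0:1), !is.null(colnames(x)))
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(params = as_xgb_params(params, seed),
                                data = dtrain, nrounds = params$n_trees,
                                verbose = 0)
  structure(list(booster = booster, features = colnames(x), params = params),
            class = "gbt_model")
}

#' @rdname gbt_fit
#' @param model a fitted `gbt_model`.
#' @param newx design matrix whose columns match the training descriptor
#'   order exactly.
#' @return `gbt_predict`: per-subject case probabilities in `[0, 1]`.
#' @export
gbt_predict <- function(model, newx) {
  stopifnot(inherits(model, "gbt_model"))
  if (!identical(colnames(newx), model$features))
    stop("feature descriptors of new data do not match the trained model")
  stats::predict(model$booster, xgboost::xgb.DMatrix(newx))
}

# Stratified fold assignment (1..k per subject); requires an active RNG.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("class ", cls, " has fewer subjects (", length(idx),
           ") than folds (", k, ")")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Mean cross-validated score of one hyperparameter setting over fixed folds.
cv_score <- function(x, y, params, fold_id, seed, criterion) {
  scores <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    m <- gbt_fit(x[tr, , drop = FALSE], y[tr], params, seed)
    p <- gbt_predict(m, x[!tr, , drop = FALSE])
    if (criterion == "ap") average_precision(p, y[!tr])
    else {
      eps <- 1e-15
      p <- pmin(1 - eps, pmax(eps, p))
      mean(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))  # higher = better
    }
  }, numeric(1))
  mean(scores)
}

#' Sequential hyperparameter optimisation
#'
#' Stage 1 performs a joint grid search over (number of trees, tree depth,
#' learning rate) with stratified k-fold cross-validation; stages 2-6 then
#' optimise the subsampling rate, minimum child weight, gamma, alpha and
#' the positive-class weight one at a time, in that order, each holding the
#' winners of earlier stages fixed. The selection criterion is mean
#' cross-validated average precision (`"ap"`, default) or mean log
#' likelihood (`"logloss"`). Ties are broken deterministically towards the
#' simpler / more regularised model: fewer trees, shallower depth, lower
#' learning rate, then (stages 2-6) the larger candidate value.
#'
#' The number of settings evaluated is exactly
#' `|trees| * |depth| * |rate| + sum of the later five list lengths`, not an
#' exhaustive product.
#'
#' @param x,y design matrix and 0/1 labels (each class needs >= `folds`
#'   subjects).
#' @param grid a [hyper_grid()].
#' @param folds number of cross-validation folds.
#' @param seed integer seed (fold assignment and booster RNG).
#' @param criterion `"ap"` or `"logloss"`.
#' @return A `gbt_tune`: list with `params` (the winning [hyperparams()]),
#'   `trace` (stage, parameter, candidate, CV score per evaluation) and
#'   `n_evals`.
#' @export
tune_sequential <- function(x, y, grid = hyper_grid(), folds = 5, seed = 1L,
                            criterion = c("ap", "logloss")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(grid, "hyper_grid"))
  if (min(table(y)) < folds)
    stop("each class needs at least ", folds, " subjects for ", folds,
         "-fold cross-validation")
  fold_id <- with_seed(child_seed(seed, 17L), stratified_folds(y, folds))

  current <- hyperparams(n_trees = grid$n_trees[1],
                         tree_depth = grid$tree_depth[1],
                         learning_rate = grid$learning_rate[1],
                         subsample_rate = 1, min_child_weight = 1,
                         gamma = 0, alpha = 0, scale_pos_weight = 1)
  trace <- list()

  # Stage 1: joint triple, candidates in tie-break preference order.
  triple <- expand.grid(learning_rate = sort(grid$learning_rate),
                        tree_depth = sort(grid$tree_depth),
                        n_trees = sort(grid$n_trees))
  triple <- triple[order(triple$n_trees, triple$tree_depth,
                         triple$learning_rate), ]
  s1 <- vapply(seq_len(nrow(triple)), function(i) {
    p <- current
    p$n_trees <- as.integer(triple$n_trees[i])
    p$tree_depth <- as.integer(triple$tree_depth[i])
    p$learning_rate <- triple$learning_rate[i]
    cv_score(x, y, p, fold_id, seed, criterion)
  }, numeric(1))
  best <- which.max(s1)
  current$n_trees <- as.integer(triple$n_trees[best])
  current$tree_depth <- as.integer(triple$tree_depth[best])
  current$learning_rate <- triple$learning_rate[best]
  trace[[1]] <- data.frame(stage = 1L, parameter = "trees/depth/rate",
                           candidate = sprintf("%d/%d/%g", triple$n_trees,
                                               triple$tree_depth,
                                               triple$learning_rate),
                           score = s1, stringsAsFactors = FALSE)

  # Stages 2-6: one hyperparameter each; larger candidate preferred on ties.
  stages <- c("subsample_rate", "min_child_weight", "gamma", "alpha",
              "scale_pos_weight")
  for (k in seq_along(stages)) {
    par_name <- stages[k]
    cand <- sort(grid[[par_name]], decreasing = TRUE)
    sc <- vapply(cand, function(v) {
      p <- current
      p[[par_name]] <- v
      cv_score(x, y, p, fold_id, seed, criterion)
    }, numeric(1))
    current[[par_name]] <- cand[which.max(sc)]
    trace[[k + 1]] <- data.frame(stage = k + 1L, parameter = par_name,
                                 candidate = as.character(cand), score = sc,
                                 stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, trace)
  structure(list(params = current, trace = trace, n_evals = nrow(trace)),
            class = "gbt_tune")
}

#' Rank features by boosted-tree importance
#'
#' Trains one ensemble on all provided features and orders them by
#' importance, descending. The default measure is split gain (the total
#' loss reduction attributed to splits on the feature); features the
#' ensemble never splits on receive importance 0 and are appended in input
#' order.
#'
#' @param x,y design matrix and 0/1 labels.
#' @param params a [hyperparams()].
#' @param seed integer seed.
#' @param measure `"gain"`, `"cover"` or `"frequency"`.
#' @return A `ranked_features` data.frame: `feature`, `importance`
#'   (non-increasing), `rank`.
#' @export
rank_features <- function(x, y, params = hyperparams(), seed = 1L,
                          measure = c("gain", "cover", "frequency")) {
  measure <- match.arg(measure)
  model <- gbt_fit(x, y, params, seed)
  imp <- tryCatch(xgboost::xgb.importance(model = model$booster),
                  error = function(e) NULL)
  scores <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (!is.null(imp) && nrow(imp)) {
    col <- c(gain = "Gain", cover = "Cover", frequency = "Frequency")[[measure]]
    scores[imp$Feature] <- imp[[col]]
  }
  ord <- order(-scores, seq_along(scores))  # stable: ties keep input order
  out <- data.frame(feature = names(scores)[ord],
                    importance = unname(scores[ord]),
                    rank = seq_along(scores), stringsAsFactors = FALSE)
  class(out) <- c("ranked_features", "data.frame")
  out
}
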