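small_grid <- function() {
  hyper_grid(n_trees = c(20, 40), tree_depth = c(2, 3),
             learning_rate = c(0.05, 0.1), subsample_rate = c(0.7, 1),
             min_child_weight = c(0, 1), gamma = c(0, 0.5),
             alpha = c(0, 0.1), scale_pos_weight = c(0.56, 1))
}

test_that("sequential tuning visits |triple| + sum(later stages) candidates", {
  ch <- toy_cohort(n = 80)
  fm <- assemble_features(ch, ch$genotypes$snps$snp_id,
                          group_features(ch, "both"))
  g <- small_grid()
  tuned <- tune_sequential(fm$x, ch$labels, g, folds = 3, seed = 2)
  expect_equal(tuned$n_evals, 2 * 2 * 2 + 2 + 2 + 2 + 2 + 2)
  expect_equal(nrow(tuned$trace), tuned$n_evals)

  # every returned value lies in its grid list
  p <- tuned$params
  expect_true(p$n_trees %in% g$n_trees)
  expect_true(p$tree_depth %in% g$tree_depth)
  expect_true(p$learning_rate %in% g$learning_rate)
  expect_true(p$subsample_rate %in% g$subsample_rate)
  expect_true(p$min_child_weight %in% g$min_child_weight)
  expect_true(p$gamma %in% g$gamma)
  expect_true(p$alpha %in% g$alpha)
  expect_true(p$scale_pos_weight %in% c(0.56, 1))
})

test_that("singleton grids return the single combination after six stages", {
  ch <- toy_cohort(n = 60)
  fm <- assemble_features(ch, ch$genotypes$snps$snp_id, character())
  g <- hyper_grid(n_trees = 25, tree_depth = 2, learning_rate = 0.1,
                  subsample_rate = 0.9, min_child_weight = 1, gamma = 0.2,
                  alpha = 0.01, scale_pos_weight = 1)
  tuned <- tune_sequential(fm$x, ch$labels, g, folds = 3, seed = 1)
  expect_equal(tuned$n_evals, 6L)
  expect_equal(tuned$params$n_trees, 25L)
  expect_equal(tuned$params$subsample_rate, 0.9)
  expect_equal(tuned$params$gamma, 0.2)
})

test_that("ties break deterministically towards the simpler model", {
  # constant features: every setting scores identically, so the winner must
  # be the preference-ordered first candidate
  x <- matrix(1, nrow = 40, ncol = 3,
              dimnames = list(NULL, paste0("c", 1:3)))
  y <- rep(c(0, 1), 20)
  g <- small_grid()
  tuned <- tune_sequential(x, y, g, folds = 2, seed = 5)
  expect_equal(tuned$params$n_trees, min(g$n_trees))
  expect_equal(tuned$params$tree_depth, min(g$tree_depth))
  expect_equal(tuned$params$learning_rate, min(g$learning_rate))
  # stages 2-6 prefer the larger (more regularised) candidate on ties
  expect_equal(tuned$params$min_child_weight, max(g$min_child_weight))
  expect_equal(tuned$params$gamma, max(g$gamma))
  expect_equal(tuned$params$alpha, max(g$alpha))

  tuned2 <- tune_sequential(x, y, g, folds = 2, seed = 5)
  expect_identical(tuned$params, tuned2$params)
})

test_that("tuning refuses classes smaller than the fold count", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(1, 3), rep(0, 17))
  expect_error(tune_sequential(x, y, small_grid(), folds = 5), "at least")
})

test_that("importance ranking puts a label-separating feature first", {
  set.seed(11)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  x <- cbind(perfect = y, matrix(rnorm(n * 50), n,
                                 dimnames = list(NULL, paste0("noise", 1:50))))
  ranked <- rank_features(x, y, fast_params(40), seed = 3)
  expect_equal(ranked$feature[1], "perfect")
  expect_true(all(diff(ranked$importance) <= 0))
})

test_that("all-noise importance is compatible with the permuted-label null", {
  set.seed(12)
  n <- 300
  x <- matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(n, 1, 0.5)
  obs <- rank_features(x, y, fast_params(30), seed = 1)$importance[1]
  perm <- vapply(1:20, function(i) {
    rank_features(x, sample(y), fast_params(30), seed = i)$importance[1]
  }, numeric(1))
  # observed max importance within the permutation distribution's range
  expect_lte(obs, max(perm) + sd(perm))
})

test_that("degenerate ranking inputs are handled", {
  x <- matrix(5, 30, 3, dimnames = list(NULL, c("z1", "z2", "z3")))
  y <- rep(c(0, 1), 15)
  ranked <- rank_features(x, y, fast_params(10), seed = 1)
  expect_equal(ranked$importance, c(0, 0, 0))
  expect_equal(ranked$feature, c("z1", "z2", "z3"))  # input order kept

  single <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "only"))
  r1 <- rank_features(single, y, fast_params(10), seed = 1)
  expect_equal(r1$rank, 1L)
})

test_that("duplicated columns share importance and are redundant for fit quality", {
  ch <- toy_cohort(n = 200)
  x <- assemble_features(ch, c("rs001", "rs002"), "risk_cat")$x
  xdup <- cbind(x, rs001_copy = x[, "rs001"])
  y <- ch$labels
  ranked <- rank_features(xdup, y, fast_params(), seed = 2)
  joint <- sum(ranked$importance[ranked$feature %in% c("rs001", "rs001_copy")])
  expect_gt(joint, 0)

  cv_ap_of <- function(design) {
    set.seed(3)
    fold <- sample(rep_len(1:4, nrow(design)))
    mean(vapply(1:4, function(f) {
      m <- gbt_fit(design[fold != f, , drop = FALSE], y[fold != f],
                   fast_params(), seed = 9)
      average_precision(gbt_predict(m, design[fold == f, , drop = FALSE]),
                        y[fold == f])
    }, numeric(1)))
  }
  expect_equal(cv_ap_of(xdup), cv_ap_of(x), tolerance = 0.05)
})

test_that("fit/predict: separable data, determinism, descriptor contract", {
  set.seed(21)
  y <- rep(c(0, 1), each = 50)
  x <- cbind(sep = y + rnorm(100, sd = 0.01),
             noise = rnorm(100))
  colnames(x) <- c("sep", "noise")
  m <- gbt_fit(x, y, fast_params(), seed = 4)
  p <- gbt_predict(m, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(average_precision(p, y), 1)

  m2 <- gbt_fit(x, y, fast_params(), seed = 4)
  expect_identical(gbt_predict(m2, x), p)

  x_swapped <- x[, c("noise", "sep")]
  expect_error(gbt_predict(m, x_swapped), "descriptors")
})

test_that("permuted labels give chance-level cross-validated AP", {
  ch <- toy_cohort(n = 120)
  x <- assemble_features(ch, ch$genotypes$snps$snp_id, "risk_cat")$x
  prevalence <- mean(ch$labels)
  set.seed(31)
  null_aps <- replicate(30, {
    y_perm <- sample(ch$labels)
    fold <- sample(rep_len(1:3, length(y_perm)))
    mean(vapply(1:3, function(f) {
      m <- gbt_fit(x[fold != f, , drop = FALSE], y_perm[fold != f],
                   fast_params(30, 2), seed = 1)
      average_precision(gbt_predict(m, x[fold == f, , drop = FALSE]),
                        y_perm[fold == f])
    }, numeric(1)))
  })
  expect_lt(abs(mean(null_aps) - prevalence),
            3 * sd(null_aps) / sqrt(length(null_aps)) + 0.03)
})
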