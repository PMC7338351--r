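#' Confusion counts for binary predictions
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels of the same length.
#' @return Named integer vector with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, predicted) {
  if (length(labels) != length(predicted))
    stop("labels and predictions differ in length")
  if (!all(labels %in% 0:1) || !all(predicted %in% 0:1))
    stop("labels and predictions must be binary 0/1")
  c(TP = sum(labels == 1 & predicted == 1),
    FP = sum(labels == 0 & predicted == 1),
    TN = sum(labels == 0 & predicted == 0),
    FN = sum(labels == 1 & predicted == 0))
}

#' Precision-recall curve
#'
#' Cut-offs are the unique scores in descending order; tied scores enter a
#' cut-off together (so AP cannot depend on the ordering of ties). At each
#' cut-off, subjects scoring at or above it are predicted positive.
#' Precision with zero predicted positives is defined as 1, which anchors
#' the curve at (recall 0, precision 1); the recall-increment weight there
#' is 0, so average precision is unaffected.
#'
#' @param scores real-valued classifier scores (higher = more case-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return A `pr_curve`: data.frame with `threshold`, `recall`, `precision`,
#'   first row the (0, 1) anchor.
#' @export
pr_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% 0:1)) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels))
    stop("both classes must be present to form a precision-recall curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_tie <- which(c(s[-1] != s[-length(s)], TRUE))
  cum_tp <- cumsum(y)[last_of_tie]
  n_pred <- last_of_tie
  curve <- data.frame(threshold = s[last_of_tie],
                      recall = cum_tp / n_pos,
                      precision = cum_tp / n_pred)
  curve <- rbind(data.frame(threshold = Inf, recall = 0, precision = 1),
                 curve)
  class(curve) <- c("pr_curve", "data.frame")
  curve
}

#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(x$recall, x$precision, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "Recall", ylab = "Precision", ...)
  invisible(x)
}

#' Average precision
#'
#' The weighted mean of precision over cut-offs, weighted by the recall
#' increment from the previous cut-off:
#' `AP = sum_i (recall_i - recall_{i-1}) * precision_i`. A single number in
#' `[0, 1]` summarising the area under the precision-recall curve.
#'
#' @param scores classifier scores, or a `pr_curve` object.
#' @param labels 0/1 labels (ignored when `scores` is already a curve).
#' @return Numeric AP value in `[0, 1]`.
#' @export
average_precision <- function(scores, labels = NULL) {
  curve <- if (inherits(scores, "pr_curve")) scores else pr_curve(scores, labels)
  sum(diff(curve$recall) * curve$precision[-1])
}

#' Mean average precision over test sets
#'
#' @param aps numeric vector of per-test-set AP values.
#' @return List with `map` (arithmetic mean), `sd` (sample standard
#'   deviation, `n - 1` denominator; 0 with `single = TRUE` flag when only
#'   one AP is supplied), and `n`.
#' @export
mean_ap <- function(aps) {
  if (!length(aps)) stop("empty AP list")
  list(map = mean(aps),
       sd = if (length(aps) > 1) stats::sd(aps) else 0,
       n = length(aps),
       single = length(aps) == 1)
}

#' Per-feature case/control association tests
#'
#' Categorical features are tested with the chi-squared test on the class x
#' category contingency table (Yates continuity correction for 2x2 tables,
#' none for larger ones); continuous features with a two-sample t-test
#' (Welch by default). P-values are not adjusted for multiple testing.
#' Class-conditional summaries accompany each test: category counts and
#' percentages, or mean (sd).
#'
#' @param cohort a [cohort()].
#' @param t_var_equal use the pooled-variance t-test instead of Welch.
#' @param chi_correct apply Yates continuity correction to 2x2 tables.
#' @return data.frame with one row per feature: `feature`, `kind`, `group`,
#'   `test`, `statistic`, `p_value`, `summary_case`, `summary_control`,
#'   `note` (e.g. when a single observed category makes the test
#'   inapplicable).
#' @export
association_tests <- function(cohort, t_var_equal = FALSE,
                              chi_correct = TRUE) {
  y <- cohort$labels
  if (length(unique(y)) < 2) stop("both classes must be present")
  rows <- lapply(seq_len(nrow(cohort$schema)), function(i) {
    nm <- cohort$schema$name[i]
    kind <- cohort$schema$kind[i]
    v <- cohort$demographics[[nm]]
    keep <- !is.na(v)
    out <- data.frame(feature = nm, kind = kind,
                      group = cohort$schema$group[i], test = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      summary_case = NA_character_,
                      summary_control = NA_character_, note = "",
                      stringsAsFactors = FALSE)
    if (kind == "categorical") {
      tab <- table(factor(y[keep], levels = c(1, 0)), v[keep])
      fmt <- function(r) paste(sprintf("%d:%d (%d%%)", as.integer(colnames(tab)),
                                       r, round(100 * r / sum(r))),
                               collapse = "; ")
      out$summary_case <- fmt(tab[1, ])
      out$summary_control <- fmt(tab[2, ])
      if (ncol(tab) < 2) {
        out$note <- "single observed category; test skipped"
        return(out)
      }
      correct <- chi_correct && all(dim(tab) == c(2, 2))
      ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      out$test <- if (correct) "chi-squared (Yates)" else "chi-squared"
      out$statistic <- unname(ht$statistic)
      out$p_value <- ht$p.value
    } else {
      v1 <- v[keep & y == 1]
      v0 <- v[keep & y == 0]
      out$summary_case <- sprintf("%.2f (%.2f)", mean(v1), stats::sd(v1))
      out$summary_control <- sprintf("%.2f (%.2f)", mean(v0), stats::sd(v0))
      if (length(v1) < 2 || length(v0) < 2) {
        out$note <- "too few observations; test skipped"
        return(out)
      }
      ht <- stats::t.test(v1, v0, var.equal = t_var_equal)
      out$test <- if (t_var_equal) "t-test (pooled)" else "t-test (Welch)"
      out$statistic <- unname(ht$statistic)
      out$p_value <- ht$p.value
    }
    out
  })
  do.call(rbind, rows)
}
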