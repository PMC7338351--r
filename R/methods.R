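#' @export
print.epiboost_fit <- function(x, ...) {
  s <- x$settings
  cat("Interacting-feature network model (epiboost)\n")
  cat(sprintf("  group: %s, top-m SNPs: %d, splits: %d (k1 = %d, k2 = %d)\n",
              s$group, s$m, length(x$networks), s$k1, s$k2))
  cat(sprintf("  test mAP: %.4f +/- %.4f\n", x$map, x$map_sd))
  cat(sprintf("  features selected at least once: %d\n",
              length(x$selection_counts)))
  invisible(x)
}

#' @export
summary.epiboost_fit <- function(object, top = 10L, ...) {
  sizes <- lengths(lapply(object$networks, `[[`, "features"))
  val_aps <- vapply(object$networks, `[[`, numeric(1), "val_ap")
  out <- list(map = object$map, map_sd = object$map_sd,
              map_train = mean(object$train_aps),
              map_validation = mean(val_aps),
              n_networks = length(object$networks),
              network_sizes = sizes,
              top_features = utils::head(object$selection_counts, top),
              settings = object$settings)
  class(out) <- "summary.epiboost_fit"
  out
}

#' @export
print.summary.epiboost_fit <- function(x, ...) {
  cat("epiboost fit over", x$n_networks, "splits\n")
  cat(sprintf("  mAP  train %.4f | validation %.4f | test %.4f +/- %.4f\n",
              x$map_train, x$map_validation, x$map, x$map_sd))
  cat(sprintf("  network size: median %g (range %d-%d)\n",
              stats::median(x$network_sizes), min(x$network_sizes),
              max(x$network_sizes)))
  cat("  most-selected features (selection counts):\n")
  print(x$top_features)
  invisible(x)
}

#' Plot an epiboost fit
#'
#' @param x an `epiboost_fit`.
#' @param type `"counts"` (selection counts of the most-selected features)
#'   or `"ap"` (per-split test AP against the mAP).
#' @param top number of features shown for `type = "counts"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.epiboost_fit <- function(x, type = c("counts", "ap"), top = 15L, ...) {
  type <- match.arg(type)
  if (type == "counts") {
    cnt <- utils::head(x$selection_counts, top)
    op <- graphics::par(mar = c(5, 9, 2, 1))
    on.exit(graphics::par(op))
    graphics::barplot(rev(as.numeric(cnt)), names.arg = rev(names(cnt)),
                      horiz = TRUE, las = 1, xlab = "Selection count", ...)
  } else {
    graphics::plot(x$test_aps, type = "h", ylim = c(0, 1),
                   xlab = "Split", ylab = "Test AP", ...)
    graphics::abline(h = x$map, lty = 2)
  }
  invisible(x)
}

#' Predict case probabilities from an epiboost fit
#'
#' Convenience predictor: refits the boosted-tree classifier on the full
#' training cohort using the features of the highest-validation-AP network
#' and scores new subjects. The cross-validated mAP of the fit, not this
#' single model, is the honest performance estimate.
#'
#' @param object an `epiboost_fit`.
#' @param newdata a [cohort()] sharing the fit's feature names (defaults to
#'   the training cohort).
#' @param ... unused.
#' @return Numeric vector of case probabilities.
#' @export
predict.epiboost_fit <- function(object, newdata = NULL, ...) {
  cohort <- object$cohort
  best <- which.max(vapply(object$networks, `[[`, numeric(1), "val_ap"))
  feats <- object$networks[[best]]$features
  all_snps <- cohort$genotypes$snps$snp_id
  snp_f <- feats[feats %in% all_snps]
  dem_f <- setdiff(feats, snp_f)
  fm_fit <- assemble_features(cohort, snp_f, dem_f)
  mdl <- gbt_fit(fm_fit$x[, feats, drop = FALSE], cohort$labels,
                 object$params_per_split[[best]],
                 seed = child_seed(object$settings$seed, 999L))
  target <- if (is.null(newdata)) fm_fit else {
    # scalers refit on the training cohort would require shared subjects;
    # scale new data with the training cohort's statistics
    fm_new <- assemble_features(newdata, snp_f, dem_f)
    for (d in names(fm_fit$scalers))
      fm_new$x[, d] <- apply_minmax(fm_fit$scalers[[d]],
                                    newdata$demographics[[d]])
    fm_new
  }
  gbt_predict(mdl, target$x[, feats, drop = FALSE])
}

#' Serialise a pipeline result to JSON
#'
#' @param fit an `epiboost_fit`.
#' @param path output `.json` path.
#' @export
write_result <- function(fit, path) {
  out <- list(
    settings = fit$settings,
    map = fit$map, map_sd = fit$map_sd,
    test_aps = fit$test_aps, train_aps = fit$train_aps,
    selection_counts = as.list(fit$selection_counts),
    networks = lapply(fit$networks, function(nw)
      list(rep = nw$provenance$rep, fold = nw$provenance$fold,
           features = nw$features, val_ap = nw$val_ap)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
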