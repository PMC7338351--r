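#' Build the candidate list for the adaptive search
#'
#' Concatenates the top-`m` importance-ranked SNPs (in rank order) with a
#' demographic feature group (in table order). The resulting ordered list is
#' the scan sequence of [adaptive_search()].
#'
#' @param ranked a `ranked_features` data.frame from [rank_features()].
#' @param m number of top-ranked SNPs to keep (>= 1).
#' @param group_features character vector of demographic feature names (may
#'   be empty).
#' @return Character vector of candidate feature names.
#' @export
concat_candidates <- function(ranked, m, group_features = character()) {
  if (m <= 0) stop("m must be positive; group-only models bypass this step")
  if (m > nrow(ranked))
    stop("m (", m, ") exceeds the ranked list length (", nrow(ranked), ")")
  c(ranked$feature[seq_len(m)], group_features)
}

#' Greedy adaptive search for an interacting-feature network
#'
#' Greedy forward selection over an ordered candidate list: the network is
#' initialised with the top candidate; each remaining candidate is examined
#' in order, the classifier is refit from scratch on the current network
#' plus the candidate, and the candidate is kept iff validation average
#' precision improves by more than `epsilon` (default 0, i.e. strict
#' improvement). The result is one network of interacting features together
#' with the validation AP it achieves; its AP is by construction at least
#' that of the top candidate alone, and the acceptance trace is monotone
#' non-decreasing along accepted steps.
#'
#' @param candidates ordered character vector of feature names (non-empty,
#'   all present as columns of the designs).
#' @param x_train,y_train training design and labels.
#' @param x_val,y_val validation design and labels (disjoint subjects; both
#'   classes required in the validation set).
#' @param params a [hyperparams()].
#' @param epsilon minimum AP improvement required to accept a candidate.
#' @param seed integer seed passed to every refit.
#' @return A `feature_network`: list with `features` (selected, in
#'   acceptance order), `val_ap`, and `trace` (one row per examined
#'   candidate: candidate, accepted, ap_with, ap_current).
#' @export
adaptive_search <- function(candidates, x_train, y_train, x_val, y_val,
                            params = hyperparams(), epsilon = 0, seed = 1L) {
  if (!length(candidates)) stop("empty candidate list")
  missing_cols <- setdiff(candidates, colnames(x_train))
  if (length(missing_cols))
    stop("candidates absent from the design: ",
         paste(utils::head(missing_cols, 3), collapse = ", "))
  if (length(unique(y_val)) < 2)
    stop("validation set must contain both classes")

  fit_ap <- function(feats) {
    m <- gbt_fit(x_train[, feats, drop = FALSE], y_train, params, seed)
    average_precision(gbt_predict(m, x_val[, feats, drop = FALSE]), y_val)
  }

  selected <- candidates[1]
  best_ap <- fit_ap(selected)
  trace <- data.frame(candidate = candidates[1], accepted = TRUE,
                      ap_with = best_ap, ap_current = best_ap,
                      stringsAsFactors = FALSE)
  for (cand in candidates[-1]) {
    ap_with <- fit_ap(c(selected, cand))
    accept <- ap_with > best_ap + epsilon
    if (accept) {
      selected <- c(selected, cand)
      best_ap <- ap_with
    }
    trace <- rbind(trace, data.frame(candidate = cand, accepted = accept,
                                     ap_with = ap_with,
                                     ap_current = best_ap))
  }
  structure(list(features = selected, val_ap = best_ap, trace = trace),
            class = "feature_network")
}

#' @export
print.feature_network <- function(x, ...) {
  cat("Feature network (", length(x$features), " features, validation AP ",
      sprintf("%.4f", x$val_ap), "):\n  ", sep = "")
  cat(paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise feature networks
#'
#' @param networks a `feature_network` or list of them.
#' @param path output path (`.json` for full descriptors and traces,
#'   `.tsv` for a flat per-network table).
#' @export
write_networks <- function(networks, path) {
  if (inherits(networks, "feature_network")) networks <- list(networks)
  if (grepl("\\.json$", path)) {
    out <- lapply(networks, function(nw)
      list(features = nw$features, val_ap = nw$val_ap, trace = nw$trace))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- do.call(rbind, lapply(seq_along(networks), function(i)
      data.frame(network = i,
                 features = paste(networks[[i]]$features, collapse = ","),
                 val_ap = networks[[i]]$val_ap)))
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
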