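#' Effect terms of the synthetic disease model
#'
#' An effect term contributes `beta` times a (product of) mean-centred
#' feature value(s) to the log-odds of disease. Interaction kinds name
#' exactly two distinct features.
#'
#' @param kind one of `"main_snp"`, `"main_demog"`, `"snp_snp"`,
#'   `"snp_demog"`.
#' @param features character vector: one feature name for main effects, two
#'   for interactions.
#' @param beta log-odds coefficient.
#' @return An object of class `effect_term`.
#' @export
effect_term <- function(kind = c("main_snp", "main_demog", "snp_snp",
                                 "snp_demog"),
                        features, beta) {
  kind <- match.arg(kind)
  n_expected <- if (kind %in% c("main_snp", "main_demog")) 1L else 2L
  if (length(features) != n_expected)
    stop("kind '", kind, "' needs exactly ", n_expected, " feature name(s)")
  if (n_expected == 2L && features[1] == features[2])
    stop("interaction terms must name two distinct features")
  structure(list(kind = kind, features = features, beta = beta),
            class = "effect_term")
}

#' Specify a synthetic case-control cohort
#'
#' The generative model: genotype codes are Binomial(2, MAF) with per-SNP
#' MAF drawn uniformly from `maf_range`; demographics follow their declared
#' distributions; disease labels are Bernoulli(logistic(intercept + sum of
#' effect terms)), where every term uses mean-centred feature values and
#' interaction terms are products of two centred values. Centring keeps the
#' intercept interpretable as the population logit prevalence and keeps
#' interaction terms orthogonal to main effects in expectation.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_snps number of SNPs.
#' @param target_prevalence case fraction in (0,1); the default 445/695
#'   mirrors the 445-case / 250-control class balance of the motivating
#'   breast-cancer cohort.
#' @param maf_range minor-allele-frequency range, a sub-interval of (0, 0.5].
#' @param demographics list of demographic feature declarations; each is a
#'   list with `name`, `kind` (`"categorical"`/`"continuous"`), `group`, and
#'   either `probs` (category probabilities for codes `0..k-1`) or
#'   `mean`/`sd`.
#' @param effects list of [effect_term()] objects.
#' @param intercept log-odds intercept, or `"auto"` to calibrate it to
#'   `target_prevalence` (see [calibrate_intercept()]).
#' @param ld optional linkage-disequilibrium block structure: a list with
#'   `block_size` and `rho` giving equicorrelated Gaussian-copula blocks of
#'   consecutive SNPs; `NULL` (default) simulates independent SNPs.
#' @param fixed_mafs optional named numeric vector pinning the MAF of named
#'   SNPs (e.g. planted causal variants) instead of drawing them from
#'   `maf_range`.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects, n_snps, target_prevalence = 445 / 695,
                           maf_range = c(0.05, 0.5), demographics = list(),
                           effects = list(), intercept = "auto",
                           ld = NULL, fixed_mafs = NULL, seed = 1L) {
  stopifnot(n_subjects >= 2, n_snps >= 0,
            target_prevalence > 0, target_prevalence < 1,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5)
  snp_ids <- if (n_snps > 0) sprintf("snp%04d", seq_len(n_snps)) else character()
  dem_names <- vapply(demographics, `[[`, "", "name")
  if (anyDuplicated(dem_names)) stop("duplicated demographic feature names")
  known <- c(snp_ids, dem_names)
  for (e in effects) {
    stopifnot(inherits(e, "effect_term"))
    bad <- setdiff(e$features, known)
    if (length(bad))
      stop("effect term names unknown feature(s): ",
           paste(bad, collapse = ", "))
  }
  if (!identical(intercept, "auto")) stopifnot(is.numeric(intercept))
  if (!is.null(fixed_mafs)) {
    bad <- setdiff(names(fixed_mafs), snp_ids)
    if (length(bad)) stop("fixed_mafs names unknown SNP(s): ",
                          paste(bad, collapse = ", "))
    stopifnot(all(fixed_mafs > 0), all(fixed_mafs <= 0.5))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps = as.integer(n_snps), snp_ids = snp_ids,
                 target_prevalence = target_prevalence,
                 maf_range = maf_range, demographics = demographics,
                 effects = effects, intercept = intercept, ld = ld,
                 fixed_mafs = fixed_mafs, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Draw the raw feature table (subjects x [snps, demographics]) for a spec.
simulate_features <- function(spec, n) {
  mafs <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  names(mafs) <- spec$snp_ids
  if (!is.null(spec$fixed_mafs))
    mafs[names(spec$fixed_mafs)] <- spec$fixed_mafs
  if (spec$n_snps > 0) {
    if (is.null(spec$ld)) {
      codes <- matrix(stats::rbinom(n * spec$n_snps, 2L, rep(mafs, each = n)),
                      nrow = n)
    } else {
      bs <- spec$ld$block_size
      rho <- spec$ld$rho
      block <- rep(seq_len(ceiling(spec$n_snps / bs)),
                   each = bs)[seq_len(spec$n_snps)]
      codes <- matrix(0L, n, spec$n_snps)
      for (copy in 1:2) {
        u_block <- matrix(stats::rnorm(n * max(block)), n)
        z <- sqrt(rho) * u_block[, block, drop = FALSE] +
          sqrt(1 - rho) * matrix(stats::rnorm(n * spec$n_snps), n)
        codes <- codes + (z < stats::qnorm(rep(mafs, each = n)))
      }
      storage.mode(codes) <- "integer"
    }
  } else codes <- matrix(integer(), n, 0)
  colnames(codes) <- spec$snp_ids

  dem <- list()
  for (d in spec$demographics) {
    dem[[d$name]] <- if (d$kind == "categorical") {
      sample(seq_along(d$probs) - 1L, n, replace = TRUE, prob = d$probs)
    } else stats::rnorm(n, d$mean, d$sd)
  }
  dem <- if (length(dem)) as.data.frame(dem) else
    as.data.frame(matrix(numeric(), n, 0))
  list(codes = codes, demographics = dem, mafs = mafs)
}

# Linear predictor contribution of the effect terms on centred features.
effect_linear_predictor <- function(spec, codes, demographics) {
  vals <- cbind(codes, as.matrix(demographics))
  centred <- if (ncol(vals)) scale(vals, center = TRUE, scale = FALSE) else vals
  lp <- numeric(nrow(vals))
  for (e in spec$effects) {
    term <- centred[, e$features[1]]
    if (length(e$features) == 2L) term <- term * centred[, e$features[2]]
    lp <- lp + e$beta * term
  }
  lp
}

#' Calibrate the intercept of a synthetic disease model
#'
#' Finds the log-odds intercept at which the model's simulated prevalence
#' matches `target_prevalence`, by root-finding on a Monte-Carlo prevalence
#' estimate over a large feature sample drawn with an internal seed derived
#' from the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param n_mc Monte-Carlo sample size for the prevalence estimate.
#' @param tol convergence tolerance on the prevalence.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(spec, n_mc = 20000L, tol = 1e-4) {
  lp <- with_seed(child_seed(spec$seed, 1L), {
    f <- simulate_features(spec, n_mc)
    effect_linear_predictor(spec, f$codes, f$demographics)
  })
  f_gap <- function(b0) mean(stats::plogis(b0 + lp)) - spec$target_prevalence
  root <- tryCatch(
    stats::uniroot(f_gap, interval = c(-30, 30), tol = tol),
    error = function(e) stop("intercept calibration failed to bracket a root: ",
                             conditionMessage(e)))
  root$root
}

#' Generate a synthetic case-control cohort with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `cohort` (a [cohort()]) and `truth`, the ground-truth
#'   record: realised `intercept`, the effect list, per-subject linear
#'   predictor `lp`, case `probability`, and the drawn per-SNP `mafs`.
#'   Fully reproducible from the spec's seed.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  b0 <- if (identical(spec$intercept, "auto")) calibrate_intercept(spec)
        else spec$intercept
  with_seed(spec$seed, {
    f <- simulate_features(spec, spec$n_subjects)
    lp <- b0 + effect_linear_predictor(spec, f$codes, f$demographics)
    prob <- stats::plogis(lp)
    labels <- stats::rbinom(spec$n_subjects, 1L, prob)
    rownames(f$codes) <- sprintf("sub%05d", seq_len(spec$n_subjects))
    snps <- synthetic_snp_records(spec$n_snps)
    schema <- data.frame(
      name = vapply(spec$demographics, `[[`, "", "name"),
      kind = vapply(spec$demographics, `[[`, "", "kind"),
      group = vapply(spec$demographics, `[[`, "", "group"),
      stringsAsFactors = FALSE)
    if (!nrow(schema))
      schema <- data.frame(name = character(), kind = character(),
                           group = character())
    ch <- cohort(genotype_matrix(f$codes, snps), f$demographics, schema,
                 labels,
                 provenance = paste0("synthetic (seed ", spec$seed, ")"))
    truth <- list(intercept = b0, effects = spec$effects, lp = lp,
                  probability = prob, mafs = f$mafs)
    list(cohort = ch, truth = truth)
  })
}

#' Write the ground truth of a synthetic cohort as JSON
#'
#' @param truth the `truth` component of [generate_cohort()] output.
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    intercept = truth$intercept,
    effects = lapply(truth$effects, function(e)
      list(kind = e$kind, features = e$features, beta = e$beta)),
    mafs = as.list(truth$mafs),
    mean_probability = mean(truth$probability))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

synthetic_snp_records <- function(n_snps) {
  data.frame(snp_id = sprintf("snp%04d", seq_len(n_snps)),
             chrom = rep("chr1", n_snps), pos = seq_len(n_snps) * 1000L,
             major_allele = rep("A", n_snps), minor_allele = rep("G", n_snps),
             stringsAsFactors = FALSE)
}

# Class-conditional marginals of the motivating breast-cancer cohort:
# category counts (codes 0..k-1) for categorical features, mean/sd for
# continuous ones, among 445 cases and 250 controls.
kbcp_margins <- function() {
  cat1 <- function(name, case, control)
    list(name = name, kind = "categorical", group = "group1",
         case = case, control = control)
  cat2 <- function(name, case, control)
    list(name = name, kind = "categorical", group = "group2",
         case = case, control = control)
  cont2 <- function(name, case, control)
    list(name = name, kind = "continuous", group = "group2",
         case = case, control = control)
  list(
    cat1("cancer_in_family",        c(196, 249), c(136, 114)),
    cat1("cancer_type_1",           c(394, 51),  c(235, 15)),
    cat1("cancer_type_2",           c(437, 8),   c(249, 1)),
    cat1("first_degree_relative_1", c(398, 47),  c(238, 12)),
    cat1("first_degree_relative_2", c(438, 7),   c(249, 1)),
    cat1("n_bc",                    c(393, 45, 7), c(235, 14, 1)),
    cat1("bc_risk_score",           c(396, 44, 5), c(238, 11, 1)),
    cat1("lateral_1",               c(394, 48, 3), c(235, 14, 1)),
    cat1("lateral_2",               c(437, 7, 1),  c(249, 1, 0)),
    cat2("oral_contraceptive_use",  c(300, 145), c(124, 126)),
    cont2("oral_contraceptive_duration", c(48.27, 51.50), c(40.86, 38.91)),
    cat2("menopausal_status",       c(127, 318), c(109, 141)),
    cat2("breast_feeding",          c(107, 338), c(39, 211)),
    cat2("pregnancy",               c(85, 360),  c(31, 219)),
    cont2("hrt_oestrogen_duration", c(53.94, 58.03), c(39.85, 47.86)),
    cont2("menstrual_cycle_length", c(26.94, 2.27),  c(27.26, 2.65)),
    cont2("first_pregnancy_length", c(39.20, 3.37),  c(39.18, 3.88)),
    cont2("second_pregnancy_length", c(39.66, 1.95), c(38.99, 4.64)),
    cont2("third_pregnancy_length", c(38.97, 3.93),  c(38.64, 5.70)),
    cont2("bmi",                    c(26.49, 4.60),  c(26.04, 4.29)))
}

#' Emulate the demographic marginals of the motivating cohort
#'
#' Draws the 9 familial-history (group 1) and 11 oestrogen-metabolism
#' (group 2) risk factors class-conditionally from their published
#' case/control marginals (category proportions for categorical features,
#' mean/sd normals for continuous ones), plus label-independent null
#' genotypes. Intended for association-test checks and pipeline smoke tests;
#' the joint dependence structure between features is not emulated.
#'
#' @param n_cases,n_controls class sizes (defaults 445/250, the motivating
#'   cohort's).
#' @param n_snps number of null SNPs to attach (MAF uniform on
#'   `[0.05, 0.5]`).
#' @param seed integer RNG seed.
#' @return A `cohort` (cases first, then controls).
#' @export
emulate_kbcp_margins <- function(n_cases = 445L, n_controls = 250L,
                                 n_snps = 50L, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  margins <- kbcp_margins()
  n <- n_cases + n_controls
  labels <- c(rep(1L, n_cases), rep(0L, n_controls))
  with_seed(seed, {
    dem <- list()
    for (m in margins) {
      draw <- function(par, k) {
        if (m$kind == "categorical")
          sample(seq_along(par) - 1L, k, replace = TRUE, prob = par / sum(par))
        else stats::rnorm(k, par[1], par[2])
      }
      dem[[m$name]] <- c(draw(m$case, n_cases), draw(m$control, n_controls))
    }
    dem <- as.data.frame(dem)
    schema <- data.frame(
      name = vapply(margins, `[[`, "", "name"),
      kind = vapply(margins, `[[`, "", "kind"),
      group = vapply(margins, `[[`, "", "group"),
      stringsAsFactors = FALSE)
    mafs <- stats::runif(n_snps, 0.05, 0.5)
    codes <- matrix(stats::rbinom(n * n_snps, 2L, rep(mafs, each = n)),
                    nrow = n)
    rownames(codes) <- sprintf("sub%05d", seq_len(n))
    snps <- synthetic_snp_records(n_snps)
    cohort(genotype_matrix(codes, snps), dem, schema, labels,
           provenance = paste0("marginals emulation (seed ", seed, ")"))
  })
}
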