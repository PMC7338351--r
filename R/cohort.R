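#' Construct a genotype matrix
#'
#' A genotype matrix holds additively coded SNP calls (minor-allele counts
#' 0/1/2, `NA` for missing) for an ordered set of subjects, together with the
#' SNP records (identifier, position, declared major/minor alleles).
#'
#' @param codes integer matrix, subjects x SNPs; entries in `{0, 1, 2, NA}`.
#'   Row names are subject identifiers, column names SNP identifiers.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `major_allele`, `minor_allele`; one row per column of `codes`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, snps) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  stopifnot(is.data.frame(snps))
  req <- c("snp_id", "chrom", "pos", "major_allele", "minor_allele")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols))
    stop("snps is missing columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(codes) != nrow(snps))
    stop("codes has ", ncol(codes), " columns but snps has ", nrow(snps), " rows")
  if (anyDuplicated(snps$snp_id))
    stop("duplicated snp_id in SNP records")
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  same <- snps$major_allele == snps$minor_allele
  if (any(same))
    stop("major and minor allele identical for SNP(s): ",
         paste(utils::head(snps$snp_id[same], 3), collapse = ", "))
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  colnames(codes) <- snps$snp_id
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("S", seq_len(nrow(codes)))
  structure(list(codes = codes, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$codes))
  cat("Genotype matrix: ", nrow(x$codes), " subjects x ", ncol(x$codes),
      " SNPs (", n_miss, " missing calls)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Additive encoding of a diploid allele call
#'
#' Counts the minor alleles in a two-character call, giving the standard
#' additive genotype code: homozygous major = 0, heterozygous = 1,
#' homozygous minor = 2.
#'
#' @param call character vector of allele pairs, e.g. `"AG"` (or `"A/G"`);
#'   `NA` passes through as `NA`.
#' @param major,minor single-character major and minor allele for the SNP.
#' @return Integer vector of minor-allele counts in `{0, 1, 2}`.
#' @export
encode_additive <- function(call, major, minor) {
  stopifnot(length(major) == 1L, length(minor) == 1L, major != minor)
  out <- rep(NA_integer_, length(call))
  ok <- !is.na(call)
  cleaned <- gsub("[/|]", "", call[ok])
  if (any(nchar(cleaned) != 2L))
    stop("allele calls must contain exactly two alleles")
  a1 <- substr(cleaned, 1L, 1L)
  a2 <- substr(cleaned, 2L, 2L)
  foreign <- !(a1 %in% c(major, minor)) | !(a2 %in% c(major, minor))
  if (any(foreign))
    stop("allele call(s) contain alleles other than ", major, "/", minor,
         ": ", paste(utils::head(call[ok][foreign], 3), collapse = ", "))
  out[ok] <- (a1 == minor) + (a2 == minor)
  out
}

#' Read a genotype matrix from VCF or tabular TSV
#'
#' The tabular dialect is a TSV whose header row holds SNP identifiers, with
#' one row per subject (first column `subject_id`) and cells that are either
#' additive codes `0/1/2`, `NA`, or allele pairs such as `"AG"`. Allele pairs
#' require SNP records supplied via `snps`; codes do not. For VCF input the
#' ALT allele is taken as the declared minor allele and REF as major;
#' diploid GT fields `0/0`, `0/1`, `1/1` map to 0, 1, 2. Multi-allelic sites
#' are rejected.
#'
#' @param path file path.
#' @param format `"tabular"` or `"vcf"`.
#' @param snps optional data.frame of SNP records (see [genotype_matrix()]);
#'   required when tabular cells are allele pairs, otherwise synthesised with
#'   placeholder alleles.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("tabular", "vcf"), snps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_genotypes_vcf(path))

  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (names(tab)[1] != "subject_id")
    stop("tabular genotype file must start with a 'subject_id' column")
  subjects <- tab[[1]]
  snp_ids <- names(tab)[-1]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  codes <- matrix(NA_integer_, nrow(cells), ncol(cells),
                  dimnames = list(subjects, snp_ids))
  for (j in seq_along(snp_ids)) {
    col <- cells[, j]
    is_na <- is.na(col) | col == "NA" | col == ""
    vals <- col[!is_na]
    if (all(grepl("^[012]$", vals))) {
      codes[!is_na, j] <- as.integer(vals)
    } else {
      if (is.null(snps))
        stop("column ", snp_ids[j],
             ": allele-pair cells need SNP records ('snps' argument)")
      rec <- snps[snps$snp_id == snp_ids[j], , drop = FALSE]
      if (nrow(rec) != 1L)
        stop("no SNP record for column ", snp_ids[j])
      codes[!is_na, j] <- tryCatch(
        encode_additive(vals, rec$major_allele, rec$minor_allele),
        error = function(e) stop("column ", snp_ids[j], ": ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  if (is.null(snps)) {
    snps <- data.frame(snp_id = snp_ids, chrom = NA_character_,
                       pos = seq_along(snp_ids), major_allele = "A",
                       minor_allele = "B", stringsAsFactors = FALSE)
  } else {
    snps <- snps[match(snp_ids, snps$snp_id), , drop = FALSE]
    if (anyNA(snps$snp_id)) stop("SNP records missing for some columns")
  }
  genotype_matrix(codes, snps)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic VCF site(s) not supported: ",
         paste(utils::head(fix$ID[multi], 3), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  code1 <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  codes <- matrix(map[code1], nrow = nrow(code1), dimnames = dimnames(code1))
  unknown <- !is.na(code1) & is.na(codes)
  if (any(unknown))
    stop("unsupported GT value(s): ",
         paste(utils::head(unique(code1[unknown]), 3), collapse = ", "))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     major_allele = fix$REF, minor_allele = fix$ALT,
                     stringsAsFactors = FALSE)
  genotype_matrix(t(codes), snps)
}

#' Write a genotype matrix in the tabular TSV dialect
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @export
write_genotypes <- function(gm, path) {
  tab <- data.frame(subject_id = rownames(gm$codes), gm$codes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop SNP columns containing missing calls
#'
#' Preprocessing excludes missing genotype values column-wise: any SNP with
#' at least one missing call is removed; per-call imputation is deliberately
#' not offered. Subject order is unchanged.
#'
#' @param gm a `genotype_matrix`.
#' @return The filtered `genotype_matrix`, with attribute `n_removed` giving
#'   the count of dropped SNPs. Removing every SNP raises a warning, not an
#'   error.
#' @export
filter_missing_snps <- function(gm) {
  keep <- colSums(is.na(gm$codes)) == 0L
  if (!any(keep))
    warning("all ", ncol(gm$codes), " SNPs contain missing calls; ",
            "returning an empty genotype matrix")
  out <- genotype_matrix(gm$codes[, keep, drop = FALSE],
                         gm$snps[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Minor allele frequencies from additive codes
#'
#' MAF per SNP is `sum(codes) / (2 * n_subjects)` over non-missing calls.
#' Values above 0.5 indicate a mis-declared minor allele; they are reported
#' via warning, never silently flipped.
#'
#' @param gm a `genotype_matrix`.
#' @return Named numeric vector of per-SNP frequencies.
#' @export
minor_allele_freq <- function(gm) {
  maf <- colMeans(gm$codes, na.rm = TRUE) / 2
  flipped <- !is.na(maf) & maf > 0.5
  if (any(flipped))
    warning("empirical MAF > 0.5 for ", sum(flipped),
            " SNP(s); check declared minor allele: ",
            paste(utils::head(names(maf)[flipped], 5), collapse = ", "))
  maf
}

#' Fit and apply min-max scalers
#'
#' Continuous demographic features are scaled to `[0, 1]` by min-max
#' normalisation. The scaler is fitted on a training subset only and applied
#' unchanged elsewhere; out-of-range values are clipped to `[0, 1]`, and a
#' degenerate (constant) scaler maps everything to 0.
#'
#' @param values numeric vector; `NA` ignored during fitting.
#' @return `fit_minmax`: a list with `min`, `max` and `degenerate` flag.
#' @export
fit_minmax <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("cannot fit a min-max scaler on all-missing values")
  structure(list(min = min(v), max = max(v), degenerate = min(v) == max(v)),
            class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler a fitted `minmax_scaler`.
#' @return `apply_minmax`: numeric vector in `[0, 1]` (`NA` preserved).
#' @export
apply_minmax <- function(scaler, values) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (scaler$degenerate) {
    out <- rep(0, length(values))
    out[is.na(values)] <- NA_real_
    return(out)
  }
  pmin(1, pmax(0, (values - scaler$min) / (scaler$max - scaler$min)))
}

#' Construct a case-control cohort
#'
#' Bundles a genotype matrix, a demographic feature table with its schema,
#' and binary case(1)/control(0) labels over one shared ordered subject list.
#'
#' @param genotypes a `genotype_matrix` (may have zero SNP columns).
#' @param demographics data.frame of per-subject feature values (integer
#'   codes for categorical features, reals for continuous; `NA` allowed).
#' @param schema data.frame with columns `name`, `kind`
#'   (`"categorical"`/`"continuous"`), `group` (`"group1"`, `"group2"`,
#'   `"other"`); one row per demographic column.
#' @param labels integer vector of 0/1 labels, one per subject.
#' @param provenance free-text record of the data source (and seed, for
#'   simulated cohorts).
#' @return An object of class `cohort`.
#' @export
cohort <- function(genotypes, demographics, schema, labels,
                   provenance = "unspecified") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  demographics <- as.data.frame(demographics)
  n <- nrow(genotypes$codes)
  if (nrow(demographics) != n)
    stop("demographics rows (", nrow(demographics),
         ") do not match subjects (", n, ")")
  if (length(labels) != n) stop("labels length does not match subjects")
  if (!all(labels %in% 0:1)) stop("labels must be 0 (control) or 1 (case)")
  if (!setequal(names(demographics), schema$name) ||
      ncol(demographics) != nrow(schema))
    stop("schema names do not match demographic columns")
  schema <- schema[match(names(demographics), schema$name), , drop = FALSE]
  if (!all(schema$kind %in% c("categorical", "continuous")))
    stop("schema kind must be 'categorical' or 'continuous'")
  if (!all(schema$group %in% c("group1", "group2", "other")))
    stop("schema group must be 'group1', 'group2' or 'other'")
  for (nm in schema$name[schema$kind == "categorical"]) {
    v <- demographics[[nm]]
    if (any(!is.na(v) & (v < 0 | v != floor(v))))
      stop("categorical feature '", nm, "' must hold non-negative integer codes")
  }
  structure(list(genotypes = genotypes, demographics = demographics,
                 schema = schema, labels = as.integer(labels),
                 provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Case-control cohort: ", length(x$labels), " subjects (",
      sum(x$labels == 1), " cases / ", sum(x$labels == 0), " controls)\n",
      sep = "")
  cat("  SNPs: ", ncol(x$genotypes$codes), "\n", sep = "")
  g <- table(factor(x$schema$group, c("group1", "group2", "other")))
  cat("  Demographic features: ", nrow(x$schema), " (group1 ", g[["group1"]],
      ", group2 ", g[["group2"]], ", other ", g[["other"]], ")\n", sep = "")
  cat("  Provenance: ", x$provenance[1], "\n", sep = "")
  invisible(x)
}

#' Names of demographic features in a group
#'
#' @param cohort a `cohort`.
#' @param group `"group1"`, `"group2"` or `"both"`.
#' @return Character vector of feature names in table order (group1 before
#'   group2 for `"both"`).
#' @export
group_features <- function(cohort, group = c("group1", "group2", "both")) {
  group <- match.arg(group)
  sel <- if (group == "both") c("group1", "group2") else group
  unlist(lapply(sel, function(g) cohort$schema$name[cohort$schema$group == g]),
         use.names = FALSE)
}

#' Assemble a combined feature design matrix
#'
#' Builds the numeric design for a chosen subject subset: SNP columns first
#' in the given order, then demographic columns. Continuous demographics are
#' min-max scaled with scalers fitted on `scaler_subjects` only (no leakage
#' into validation/test); missing continuous values are replaced by the
#' scaler-subset median, missing categorical values by an explicit extra
#' code (one above the largest scaler-subset code).
#'
#' @param cohort a `cohort`.
#' @param snp_ids character vector of SNP identifiers (may be empty).
#' @param demographic_names character vector of demographic feature names
#'   (may be empty).
#' @param subjects integer indices of the subjects to include (default all).
#' @param scaler_subjects integer indices used to fit scalers and imputation
#'   statistics; defaults to `subjects`. Disjointness from held-out subsets
#'   is the caller's responsibility.
#' @return A `feature_matrix`: list with the numeric matrix `x`, a
#'   `descriptors` data.frame (`name`, `source`, `group`, `kind`) in column
#'   order, and the fitted `scalers`.
#' @export
assemble_features <- function(cohort, snp_ids = character(),
                              demographic_names = character(),
                              subjects = NULL, scaler_subjects = NULL) {
  n <- length(cohort$labels)
  if (is.null(subjects)) subjects <- seq_len(n)
  if (is.null(scaler_subjects)) scaler_subjects <- subjects
  unknown_snp <- setdiff(snp_ids, cohort$genotypes$snps$snp_id)
  if (length(unknown_snp))
    stop("unknown SNP id(s): ", paste(utils::head(unknown_snp, 3), collapse = ", "))
  unknown_dem <- setdiff(demographic_names, cohort$schema$name)
  if (length(unknown_dem))
    stop("unknown demographic feature(s): ",
         paste(utils::head(unknown_dem, 3), collapse = ", "))

  cols <- list()
  scalers <- list()
  desc <- data.frame(name = character(), source = character(),
                     group = character(), kind = character(),
                     stringsAsFactors = FALSE)
  for (s in snp_ids) {
    cols[[s]] <- as.numeric(cohort$genotypes$codes[subjects, s])
    desc <- rbind(desc, data.frame(name = s, source = "snp", group = "snp",
                                   kind = "categorical"))
  }
  for (d in demographic_names) {
    row <- cohort$schema[cohort$schema$name == d, ]
    v_all <- cohort$demographics[[d]]
    v <- v_all[subjects]
    v_fit <- v_all[scaler_subjects]
    if (row$kind == "continuous") {
      sc <- fit_minmax(v_fit)
      med <- stats::median(v_fit, na.rm = TRUE)
      v[is.na(v)] <- med
      v <- apply_minmax(sc, v)
      scalers[[d]] <- sc
    } else {
      na_code <- max(v_fit, 0, na.rm = TRUE) + 1
      v[is.na(v)] <- na_code
    }
    cols[[d]] <- as.numeric(v)
    desc <- rbind(desc, data.frame(name = d, source = "demographic",
                                   group = row$group, kind = row$kind))
  }
  x <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(), nrow = length(subjects), ncol = 0)
  colnames(x) <- desc$name
  rownames(x) <- rownames(cohort$genotypes$codes)[subjects]
  structure(list(x = x, descriptors = desc, scalers = scalers,
                 subjects = subjects),
            class = "feature_matrix")
}

#' Read and write demographic and label tables
#'
#' The demographic TSV holds `subject_id` plus one column per feature; a
#' sidecar schema TSV (`name`, `kind`, `group`) declares each feature's kind
#' and group. Labels are a two-column TSV (`subject_id`, `label`).
#'
#' @param demographics_path,schema_path,labels_path file paths.
#' @param genotypes a `genotype_matrix` for the same subjects.
#' @param provenance free-text provenance record.
#' @return `read_cohort`: a `cohort` assembled from the three TSVs plus the
#'   genotype matrix.
#' @export
read_cohort <- function(genotypes, demographics_path, schema_path,
                        labels_path, provenance = "files") {
  dem <- utils::read.table(demographics_path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  schema <- utils::read.table(schema_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t")
  ord <- match(rownames(genotypes$codes), dem$subject_id)
  if (anyNA(ord)) stop("demographic table missing subjects present in genotypes")
  dem <- dem[ord, setdiff(names(dem), "subject_id"), drop = FALSE]
  lab <- lab$label[match(rownames(genotypes$codes), lab$subject_id)]
  if (anyNA(lab)) stop("label table missing subjects present in genotypes")
  cohort(genotypes, dem, schema, lab, provenance)
}

#' @rdname read_cohort
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `write_cohort`: invisibly, the paths written (genotypes,
#'   demographics, schema, labels).
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, c("_genotypes.tsv", "_demographics.tsv",
                                       "_schema.tsv", "_labels.tsv")))
  write_genotypes(cohort$genotypes, p[1])
  dem <- data.frame(subject_id = rownames(cohort$genotypes$codes),
                    cohort$demographics, check.names = FALSE)
  utils::write.table(dem, p[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$schema, p[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(subject_id = rownames(cohort$genotypes$codes),
                    label = cohort$labels)
  utils::write.table(lab, p[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}
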