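test_that("additive encoding counts minor alleles and is orientation-complementary", {
  expect_identical(encode_additive("AA", major = "A", minor = "G"), 0L)
  expect_identical(encode_additive(c("AG", "GA"), major = "A", minor = "G"),
                   c(1L, 1L))
  expect_identical(encode_additive("GG", major = "A", minor = "G"), 2L)
  expect_identical(encode_additive("A/G", major = "A", minor = "G"), 1L)
  expect_true(is.na(encode_additive(NA_character_, "A", "G")))
  expect_error(encode_additive("AT", major = "A", minor = "G"), "alleles")

  # swapping the declared major/minor orientation complements the code to 2
  calls <- c("AA", "AG", "GA", "GG")
  expect_equal(encode_additive(calls, "A", "G") +
                 encode_additive(calls, "G", "A"),
               rep(2L, 4))
})

test_that("tabular genotypes round-trip through write-then-read", {
  gm <- toy_genotypes(3, 2, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  gm2 <- read_genotypes(path, format = "tabular", snps = gm$snps)
  expect_identical(gm2$codes, gm$codes)
  expect_identical(gm2$snps$snp_id, gm$snps$snp_id)
})

test_that("tabular reader handles NA cells and allele pairs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\trs001\trs002",
               "S1\t0\tAG",
               "S2\tNA\tGG",
               "S3\t2\tAA"), path)
  gm <- read_genotypes(path, format = "tabular", snps = toy_snp_records(2))
  expect_identical(gm$codes[, "rs001"], c(S1 = 0L, S2 = NA_integer_, S3 = 2L))
  expect_identical(unname(gm$codes[, "rs002"]), c(1L, 2L, 0L))
})

test_that("VCF genotypes map GT against the declared minor (ALT) allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path)
  gm <- read_genotypes(path, format = "vcf")
  expect_identical(unname(gm$codes[, "rs001"]), c(0L, 1L, 2L))
  expect_identical(unname(gm$codes[, "rs002"]), c(1L, 0L, 0L))
  expect_identical(gm$snps$minor_allele, c("G", "C"))

  # multi-allelic site rejected
  bad <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(path)
  lines[4] <- sub("\tG\t", "\tG,T\t", lines[4])
  writeLines(lines, bad)
  expect_error(read_genotypes(bad, format = "vcf"), "multi-allelic")
})

test_that("missing-SNP filter drops exactly the columns with missing calls", {
  gm <- toy_genotypes(20, 10, seed = 3)
  gm$codes[5, 4] <- NA
  filtered <- filter_missing_snps(gm)
  expect_equal(ncol(filtered$codes), 9)
  expect_equal(attr(filtered, "n_removed"), 1)
  expect_false("rs004" %in% filtered$snps$snp_id)
  expect_identical(rownames(filtered$codes), rownames(gm$codes))

  # identity on complete matrices, idempotence in general
  complete <- toy_genotypes(10, 5, seed = 4)
  expect_identical(filter_missing_snps(complete)$codes, complete$codes)
  twice <- filter_missing_snps(filter_missing_snps(gm))
  expect_identical(twice$codes, filtered$codes)

  # degenerate: every SNP missing somewhere -> empty matrix with warning
  all_bad <- toy_genotypes(5, 3, seed = 5)
  all_bad$codes[1, ] <- NA
  expect_warning(empty <- filter_missing_snps(all_bad), "all")
  expect_equal(ncol(empty$codes), 0)
})

test_that("min-max scaling clips, handles NA and degenerates to zero", {
  sc <- fit_minmax(c(2, 4, 6))
  expect_equal(c(sc$min, sc$max), c(2, 6))
  expect_equal(apply_minmax(sc, 4), 0.5)
  expect_equal(apply_minmax(sc, 8), 1)    # clipped above
  expect_equal(apply_minmax(sc, 0), 0)    # clipped below
  expect_equal(fit_minmax(c(1, NA, 3))$max, 3)
  deg <- fit_minmax(c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(apply_minmax(deg, 5), 0)
  expect_error(fit_minmax(c(NA_real_, NA_real_)), "all-missing")

  # output always in [0,1] for arbitrary inputs
  set.seed(1)
  v <- rnorm(50, sd = 100)
  out <- apply_minmax(fit_minmax(v[1:10]), v)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("minor allele frequency equals sum(codes)/(2n) and reports flips", {
  gm <- toy_genotypes(100, 5, seed = 6, maf = 0.2)
  maf <- minor_allele_freq(gm)
  expect_equal(unname(maf), unname(colSums(gm$codes) / (2 * 100)))
  gm$codes[, 2] <- 2L  # mis-declared minor allele
  expect_warning(minor_allele_freq(gm), "MAF > 0.5")
})

test_that("assembled designs order SNPs before demographics and scale without leakage", {
  ch <- toy_cohort(n = 50)
  fm <- assemble_features(ch, snp_ids = c("rs002", "rs001"),
                          demographic_names = c("risk_cat", "cont_feat"),
                          subjects = 1:30, scaler_subjects = 1:30)
  expect_identical(colnames(fm$x), c("rs002", "rs001", "risk_cat", "cont_feat"))
  expect_identical(fm$descriptors$source,
                   c("snp", "snp", "demographic", "demographic"))
  expect_true(all(fm$x[, "cont_feat"] >= 0 & fm$x[, "cont_feat"] <= 1))

  # scalers from a training subset applied to other subjects clip to [0,1]
  fm_val <- assemble_features(ch, "rs001", "cont_feat", subjects = 31:50,
                              scaler_subjects = 1:30)
  expect_true(all(fm_val$x[, "cont_feat"] >= 0 & fm_val$x[, "cont_feat"] <= 1))

  # demographic-only design: the group-only baseline geometry
  fm_dem <- assemble_features(ch, character(), group_features(ch, "group1"))
  expect_equal(ncol(fm_dem$x), 2)
  expect_error(assemble_features(ch, "rs099"), "unknown SNP")
  expect_error(assemble_features(ch, character(), "nope"), "unknown demographic")

  # byte-for-byte determinism
  fm2 <- assemble_features(ch, snp_ids = c("rs002", "rs001"),
                           demographic_names = c("risk_cat", "cont_feat"),
                           subjects = 1:30, scaler_subjects = 1:30)
  expect_identical(fm$x, fm2$x)
})

test_that("cohort TSV dialects round-trip through write_cohort/read_cohort", {
  ch <- toy_cohort(n = 30)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir, prefix = "t")
  ch2 <- read_cohort(ch$genotypes,
                     file.path(dir, "t_demographics.tsv"),
                     file.path(dir, "t_schema.tsv"),
                     file.path(dir, "t_labels.tsv"))
  expect_identical(ch2$labels, ch$labels)
  expect_equal(ch2$demographics$cont_feat, ch$demographics$cont_feat,
               tolerance = 1e-9)
  expect_identical(ch2$schema$group, ch$schema$group)
})
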