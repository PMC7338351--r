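write_toy_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "src", "gene", "14500", "20000", ".", "+", ".",
          "ID=G1;Name=GENE1", sep = "\t"),
    paste("chr1", "src", "mRNA", "14500", "20000", ".", "+", ".",
          "ID=G1.t1;Parent=G1", sep = "\t"),
    paste("chr1", "src", "exon", "14500", "15000", ".", "+", ".",
          "Parent=G1.t1", sep = "\t"),
    paste("chr1", "src", "gene", "40000", "45000", ".", "-", ".",
          "ID=G2;Name=GENE2", sep = "\t"),
    paste("chr2", "src", "gene", "100", "900", ".", "+", ".",
          "ID=G3;Name=GENE3", sep = "\t")), path)
  path
}

test_that("GFF3 loading keeps gene features only; BED converts coordinates", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(gff)
  genes <- load_annotation(gff, format = "gff3")
  expect_equal(nrow(genes), 3)  # mRNA/exon children dropped
  expect_setequal(genes$gene_id, c("G1", "G2", "G3"))
  expect_equal(genes$start[genes$gene_id == "G1"], 14500)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tG1", bed)
  b <- load_annotation(bed, format = "bed")
  expect_equal(b$start, 100)  # 0-based half-open -> 1-based inclusive
  expect_equal(b$end, 200)

  # coordinate error reported with line number
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tA", "chr1\t50\t40\tB"), bad)
  expect_error(load_annotation(bad, format = "bed"), "line 2")

  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_warning(e <- load_annotation(empty, format = "gff3"), "empty")
  expect_equal(nrow(e), 0)
})

test_that("duplicate gene records collapse to the union span", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tGX", "chr1\t299\t400\tGX"), bed)
  g <- load_annotation(bed, format = "bed")
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end), c(100, 400))
})

test_that("window mapping honours the 5,000 bp boundary rule", {
  genes <- data.frame(gene_id = c("G1", "G2", "G3"),
                      gene_name = c("GENE1", "GENE2", "GENE3"),
                      chrom = "chr1",
                      start = c(14500, 15001, 15002),
                      end = c(20000, 20000, 20000),
                      strand = "+", stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 10000)
  m <- map_snps_to_genes(snps, genes, window = 5000)
  # gap 4,499 for G1; exactly 5,000 intervening bases for G2 (included);
  # 5,001 for G3 (excluded)
  expect_setequal(m$gene_id, c("G1", "G2"))
  expect_equal(m$distance[m$gene_id == "G2"], 5000)

  inside <- map_snps_to_genes(
    data.frame(snp_id = "rs2", chrom = "chr1", pos = 16000), genes, 5000)
  expect_true(all(inside$distance[inside$gene_id == "G1"] == 0))

  # upstream gene: negative signed distance
  up <- map_snps_to_genes(
    data.frame(snp_id = "rs3", chrom = "chr1", pos = 21001), genes, 5000)
  expect_equal(up$distance[up$gene_id == "G1"], -1000)
})

test_that("window mapping equals a brute-force overlap scan on random instances", {
  brute <- function(snps, genes, w) {
    hits <- list()
    for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] != genes$chrom[j]) next
      gap <- if (snps$pos[i] < genes$start[j])
        genes$start[j] - snps$pos[i] - 1
      else if (snps$pos[i] > genes$end[j])
        snps$pos[i] - genes$end[j] - 1
      else 0
      if (gap <= w)
        hits[[length(hits) + 1]] <- paste(snps$snp_id[i], genes$gene_id[j])
    }
    sort(unlist(hits))
  }
  for (seed in 1:100) {
    set.seed(seed)
    n_s <- 200
    n_g <- 200
    snps <- data.frame(snp_id = paste0("s", seq_len(n_s)),
                       chrom = sample(c("chr1", "chr2"), n_s, TRUE),
                       pos = sample.int(50000, n_s, TRUE))
    start <- sample.int(50000, n_g, TRUE)
    genes <- data.frame(gene_id = paste0("g", seq_len(n_g)),
                        gene_name = paste0("g", seq_len(n_g)),
                        chrom = sample(c("chr1", "chr2"), n_g, TRUE),
                        start = start,
                        end = start + sample.int(3000, n_g, TRUE),
                        strand = "+", stringsAsFactors = FALSE)
    w <- sample(c(0, 100, 5000), 1)
    got <- map_snps_to_genes(snps, genes, window = w)
    expect_identical(sort(paste(got$snp_id, got$gene_id)),
                     brute(snps, genes, w))
  }
})

test_that("shrinking the window never adds mappings", {
  set.seed(42)
  snps <- data.frame(snp_id = paste0("s", 1:50), chrom = "chr1",
                     pos = sample.int(100000, 50))
  start <- sample.int(100000, 40)
  genes <- data.frame(gene_id = paste0("g", 1:40), gene_name = paste0("g", 1:40),
                      chrom = "chr1", start = start,
                      end = start + sample.int(5000, 40), strand = "+")
  keys <- function(m) paste(m$snp_id, m$gene_id)
  m_small <- map_snps_to_genes(snps, genes, window = 1000)
  m_large <- map_snps_to_genes(snps, genes, window = 8000)
  expect_true(all(keys(m_small) %in% keys(m_large)))
})

test_that("gene-network export builds co-occurrence edges and honours curated input", {
  map <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                    gene_id = c("A", "B", "C", "A"),
                    gene_name = c("A", "B", "C", "A"),
                    distance = 0L, stringsAsFactors = FALSE)
  networks <- list(c("rs1", "rs2", "fam_history"),  # genes A, B
                   c("rs2", "rs3"),                 # genes B, C
                   c("rs1", "rs4"))                 # gene A only (self)
  g <- export_gene_network(map, networks)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 2)  # A-B and B-C, no self loops
  expect_equal(e$weight[order(paste(e$from, e$to))], c(1, 1))

  # SNP mapping to no gene contributes nothing (message, not error)
  expect_message(
    export_gene_network(map, list(c("rs1", "rs999"))), "no gene")

  # curated edges are appended; files are written
  prefix <- file.path(withr::local_tempdir(), "net")
  extra <- data.frame(gene_a = "A", gene_b = "D")
  g2 <- export_gene_network(map, networks, file = prefix,
                            extra_edges = extra)
  expect_true("D" %in% igraph::V(g2)$name)
  expect_true(file.exists(paste0(prefix, ".graphml")))
  expect_true(file.exists(paste0(prefix, "_edges.tsv")))
  edges <- read.delim(paste0(prefix, "_edges.tsv"))
  expect_true("curated" %in% edges$type)
})
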