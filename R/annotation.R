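#' Load gene intervals from GFF3 or BED
#'
#' Returns gene-level intervals only: GFF3 features of type `"gene"`, or
#' every BED record (BED's 0-based half-open coordinates are converted to
#' the 1-based inclusive convention used throughout). Records duplicated by
#' gene identifier are collapsed to their union span.
#'
#' @param path annotation file path.
#' @param format `"gff3"` or `"bed"` (guessed from the extension by
#'   default).
#' @return data.frame with `gene_id`, `gene_name`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
load_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  format <- match.arg(format, c("gff3", "bed"))

  lines <- readLines(path)
  content <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(content)) {
    warning("empty annotation file: ", path)
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  # coordinate sanity with line numbers before handing to the parser
  cols <- if (format == "bed") c(2L, 3L) else c(4L, 5L)
  for (i in content) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < max(cols)) next
    se <- suppressWarnings(as.numeric(f[cols]))
    if (anyNA(se)) next
    if (se[2] < se[1] + (format == "bed"))
      stop("interval end < start at line ", i, " of ", path)
  }

  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
    nms <- if (!is.null(gr$Name)) gr$Name else ids
  } else {
    ids <- if (!is.null(gr$name)) gr$name else
      paste0("bed", seq_along(gr))
    nms <- ids
  }
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  nms[is.na(nms)] <- ids[is.na(nms)]
  out <- data.frame(gene_id = as.character(ids),
                    gene_name = as.character(nms),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  # collapse duplicate gene_ids to the union span
  if (anyDuplicated(out$gene_id)) {
    out <- do.call(rbind, lapply(split(out, out$gene_id), function(d) {
      if (length(unique(d$chrom)) > 1)
        warning("gene ", d$gene_id[1], " spans multiple chromosomes; ",
                "keeping the first")
      d <- d[d$chrom == d$chrom[1], , drop = FALSE]
      data.frame(gene_id = d$gene_id[1], gene_name = d$gene_name[1],
                 chrom = d$chrom[1], start = min(d$start), end = max(d$end),
                 strand = d$strand[1], stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  }
  out
}

#' Map SNPs to genes within a base-pair window
#'
#' A gene maps to a SNP when at most `window` bases lie strictly between
#' the SNP position and the gene interval — i.e. genes overlapping the
#' region up to `window` bp upstream and downstream of the SNP, boundary
#' included; strand is ignored since the window is defined around the SNP.
#' The signed distance is 0 for a SNP inside the gene, positive when the
#' gene starts downstream of the SNP, negative when it ends upstream
#' (magnitude = intervening bases).
#'
#' @param snps data.frame of SNP records (`snp_id`, `chrom`, `pos`), e.g.
#'   the `snps` component of a `genotype_matrix`.
#' @param genes gene intervals from [load_annotation()].
#' @param window half-width of the window in bp (default 5000).
#' @return data.frame with `snp_id`, `gene_id`, `gene_name`, `distance`.
#' @export
map_snps_to_genes <- function(snps, genes, window = 5000) {
  stopifnot(window >= 0)
  if (!nrow(snps) || !nrow(genes))
    return(data.frame(snp_id = character(), gene_id = character(),
                      gene_name = character(), distance = integer()))
  if (!length(intersect(unique(snps$chrom), unique(genes$chrom))))
    warning("no shared chromosome names between SNPs and genes")
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, gene_gr, maxgap = window))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pos <- snps$pos[qi]
  gs <- genes$start[si]
  ge <- genes$end[si]
  dist <- ifelse(pos < gs, gs - pos - 1L,
                 ifelse(pos > ge, -(pos - ge - 1L), 0L))
  out <- data.frame(snp_id = snps$snp_id[qi], gene_id = genes$gene_id[si],
                    gene_name = genes$gene_name[si],
                    distance = as.integer(dist), stringsAsFactors = FALSE)
  out[order(match(out$snp_id, snps$snp_id), abs(out$distance)), ,
      drop = FALSE]
}

#' Export a gene network from selected feature networks
#'
#' Nodes are the genes mapped (within the annotation window) to the SNPs of
#' the selected networks; an edge joins two genes whose SNPs co-occur in at
#' least one network, weighted by the number of networks in which they
#' co-occur. User-supplied curated interaction edges may be added. SNPs
#' mapping to no gene contribute nothing (their count is reported via
#' message).
#'
#' @param map SNP-to-gene table from [map_snps_to_genes()].
#' @param networks list of `feature_network` objects (or character vectors
#'   of feature names).
#' @param file optional output path prefix; writes `<file>.graphml`,
#'   `<file>_nodes.tsv` and `<file>_edges.tsv`.
#' @param extra_edges optional data.frame (or TSV path) of curated edges
#'   with columns `gene_a`, `gene_b`.
#' @return The [igraph::graph] object, invisibly.
#' @export
export_gene_network <- function(map, networks, file = NULL,
                                extra_edges = NULL) {
  feats <- lapply(networks, function(nw)
    if (inherits(nw, "feature_network")) nw$features else as.character(nw))
  net_genes <- lapply(feats, function(f) {
    snp_f <- intersect(f, unique(map$snp_id))
    unique(map$gene_id[map$snp_id %in% snp_f])
  })
  all_snp_feats <- unique(unlist(lapply(feats, function(f) f)))
  unmapped <- setdiff(intersect(all_snp_feats,
                                c(unique(map$snp_id), all_snp_feats)),
                      unique(map$snp_id))
  unmapped <- unmapped[grepl("^snp|^rs", unmapped)]
  if (length(unmapped))
    message(length(unmapped), " selected SNP(s) map to no gene")

  nodes <- unique(unlist(net_genes))
  pair_counts <- list()
  for (g in net_genes) {
    if (length(g) < 2) next
    for (p in utils::combn(sort(g), 2, simplify = FALSE)) {
      key <- paste(p, collapse = "\r")
      pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
    }
  }
  edges <- if (length(pair_counts)) {
    ab <- do.call(rbind, strsplit(names(pair_counts), "\r"))
    data.frame(gene_a = ab[, 1], gene_b = ab[, 2],
               weight = unlist(pair_counts, use.names = FALSE),
               type = "co-occurrence", stringsAsFactors = FALSE)
  } else data.frame(gene_a = character(), gene_b = character(),
                    weight = integer(), type = character())
  if (!is.null(extra_edges)) {
    if (is.character(extra_edges))
      extra_edges <- utils::read.table(extra_edges, header = TRUE,
                                       sep = "\t", stringsAsFactors = FALSE)
    if (nrow(extra_edges)) {
      edges <- rbind(edges,
                     data.frame(gene_a = extra_edges$gene_a,
                                gene_b = extra_edges$gene_b, weight = 1L,
                                type = "curated"))
      nodes <- unique(c(nodes, extra_edges$gene_a, extra_edges$gene_b))
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(file)) {
    igraph::write_graph(g, paste0(file, ".graphml"), format = "graphml")
    utils::write.table(data.frame(gene = nodes), paste0(file, "_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(edges, paste0(file, "_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(g)
}
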