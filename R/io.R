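#' Read GWAS single-SNP summary statistics
#'
#' Reads a tab-delimited file of single-SNP association results. The file
#' must contain the header columns `snp_id`, `chr`, `pos`, `a1`, `a2`,
#' `betahat`, `se`, `n`: per-SNP marginal effect estimate, its standard
#' error, and the GWAS sample size. Rows with non-positive standard errors
#' or missing fields are dropped with a message reporting the count.
#' Alleles are carried along but not used in any computation; summary
#' statistics are assumed pre-harmonized to the LD reference panel.
#'
#' @param path Path to a tab-delimited text file.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `betahat`, `se`, `n`, sorted by chromosome then position, with class
#'   `rssnet_gwas`. The number of dropped rows is attached as attribute
#'   `dropped`.
#' @export
read_gwas_summary <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  assert_columns(raw, c("snp_id", "chr", "pos", "a1", "a2", "betahat", "se", "n"),
                 "GWAS summary file")
  for (col in c("snp_id", "chr", "a1", "a2")) raw[[col]] <- as.character(raw[[col]])
  gwas <- as_tibble(raw)
  names(gwas)[names(gwas) == "chr"] <- "chrom"
  ok <- complete.cases(gwas) & gwas$se > 0
  dropped <- sum(!ok)
  if (dropped > 0) {
    inform(sprintf("Dropped %d row(s) with missing fields or se <= 0.", dropped))
  }
  gwas <- gwas[ok, , drop = FALSE]
  if (anyDuplicated(gwas$snp_id)) {
    abort("Duplicate snp_id values in GWAS summary file.",
          class = "rssnet_validation_error")
  }
  gwas <- arrange(gwas, .data$chrom, .data$pos)
  attr(gwas, "dropped") <- dropped
  class(gwas) <- c("rssnet_gwas", class(gwas))
  gwas
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_gwas_summary()]; the pair is a lossless round trip at
#' full double precision.
#'
#' @param gwas A tibble as returned by [read_gwas_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  assert_columns(gwas, c("snp_id", "chrom", "pos", "a1", "a2", "betahat", "se", "n"),
                 "GWAS summary table")
  out <- as.data.frame(gwas)[, c("snp_id", "chrom", "pos", "a1", "a2",
                                 "betahat", "se", "n")]
  names(out)[names(out) == "chrom"] <- "chr"
  out$betahat <- format(out$betahat, digits = 17, scientific = TRUE, trim = TRUE)
  out$se <- format(out$se, digits = 17, scientific = TRUE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene catalog from BED with an auxiliary TF flag table
#'
#' The catalog is accepted in BED dialect (0-based, half-open chromStart /
#' chromEnd) and converted internally to 1-based inclusive transcribed-region
#' coordinates `tx_start`, `tx_end`; all window arithmetic in the package
#' uses the internal convention. An optional tab-delimited file with columns
#' `gene_id`, `is_tf` flags transcription factors; genes absent from it are
#' treated as non-TFs.
#'
#' @param bed_path BED file (chrom, chromStart, chromEnd, name, and
#'   optionally score, strand).
#' @param tf_path Optional TSV with columns `gene_id` and `is_tf` (0/1 or
#'   logical).
#' @return A tibble with columns `gene_id`, `chrom`, `tx_start`, `tx_end`,
#'   `is_tf`, class `rssnet_genes`.
#' @export
read_gene_catalog <- function(bed_path, tf_path = NULL) {
  bed <- read.delim(bed_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 4) {
    abort("Gene BED file needs at least 4 columns (chrom, start, end, name).",
          class = "rssnet_format_error")
  }
  genes <- tibble(
    gene_id = as.character(bed[[4]]),
    chrom = as.character(bed[[1]]),
    tx_start = as.integer(bed[[2]]) + 1L,
    tx_end = as.integer(bed[[3]]),
    is_tf = FALSE
  )
  if (!is.null(tf_path)) {
    tf <- read.delim(tf_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    assert_columns(tf, c("gene_id", "is_tf"), "TF flag table")
    genes$is_tf <- genes$gene_id %in% tf$gene_id[as.logical(tf$is_tf)]
  }
  validate_gene_catalog(genes)
}

#' Validate a gene catalog tibble
#'
#' Checks coordinate sanity (`tx_start < tx_end`, non-negative) and gene-id
#' uniqueness, sorts by position, and stamps the `rssnet_genes` class.
#' Coordinates are 1-based inclusive.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `tx_start`,
#'   `tx_end` and optionally `is_tf`.
#' @return The validated catalog tibble.
#' @export
validate_gene_catalog <- function(genes) {
  assert_columns(genes, c("gene_id", "chrom", "tx_start", "tx_end"),
                 "Gene catalog")
  genes <- as_tibble(genes)
  if (!"is_tf" %in% names(genes)) genes$is_tf <- FALSE
  if (anyDuplicated(genes$gene_id)) {
    abort("Duplicate gene_id values in gene catalog.",
          class = "rssnet_validation_error")
  }
  if (any(genes$tx_start >= genes$tx_end) || any(genes$tx_start < 0)) {
    abort("Gene coordinates must satisfy 0 <= tx_start < tx_end.",
          class = "rssnet_validation_error")
  }
  genes <- arrange(genes, .data$chrom, .data$tx_start)
  class(genes) <- unique(c("rssnet_genes", class(genes)))
  genes
}

#' Read a TF-TG network edge list
#'
#' Tab-delimited file with header columns `tf_id`, `tg_id`, `weight`;
#' weights must lie in (0, 1].
#'
#' @param path Edge-list TSV path.
#' @return A [regulatory_network()] object.
#' @export
read_network <- function(path) {
  edges <- as_tibble(read.delim(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
  assert_columns(edges, c("tf_id", "tg_id", "weight"), "Network edge list")
  regulatory_network(edges = edges)
}

#' Write a TF-TG network edge list
#'
#' @param network A [regulatory_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  out <- as.data.frame(network$edges)
  out$weight <- format(out$weight, digits = 17, scientific = TRUE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP-gene cis weights
#'
#' Tab-delimited file with columns `snp_id`, `gene_id`, `c` giving the
#' non-negative relative impact of a SNP on a cis gene (for example derived
#' from context-matched cis-eQTL). When no table is supplied, annotation
#' defaults to a flat weight of 1 for every gene in a SNP's cis window.
#'
#' @param path TSV path.
#' @return A tibble with columns `snp_id`, `gene_id`, `c`.
#' @export
read_cis_weights <- function(path) {
  cis <- as_tibble(read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
  assert_columns(cis, c("snp_id", "gene_id", "c"), "Cis weight table")
  if (any(cis$c < 0)) {
    abort("Cis weights must be non-negative.", class = "rssnet_validation_error")
  }
  cis
}

#' Read regulatory-element intervals from BED
#'
#' 0-based half-open BED intervals, converted to 1-based inclusive.
#'
#' @param path BED path (chrom, chromStart, chromEnd, ...).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_re_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3) {
    abort("RE BED file needs at least 3 columns.", class = "rssnet_format_error")
  }
  tibble(chrom = as.character(bed[[1]]),
         start = as.integer(bed[[2]]) + 1L,
         end = as.integer(bed[[3]]))
}

#' Export a grid fit as text tables
#'
#' Writes two TSV files: the grid table (hyper-parameters, slab variances,
#' evidence lower bound, convergence diagnostics) and the per-SNP
#' variational parameters in long format (`snp_id`, `grid_index`, `alpha`,
#' `nu`, `tau`).
#'
#' @param fit An `rssnet_fit`.
#' @param grid_path,snp_path Output TSV paths.
#' @return `grid_path`, invisibly.
#' @export
write_fit <- function(fit, grid_path, snp_path) {
  g <- as.data.frame(fit$grid)
  g$grid_index <- seq_len(nrow(g))
  write.table(g, grid_path, sep = "\t", quote = FALSE, row.names = FALSE)
  H <- nrow(g)
  p <- length(fit$snp_id)
  long <- data.frame(
    snp_id = rep(fit$snp_id, times = H),
    grid_index = rep(seq_len(H), each = p),
    alpha = as.vector(fit$alpha),
    nu = as.vector(fit$nu),
    tau = as.vector(fit$tau)
  )
  write.table(long, snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(grid_path)
}

#' Export a network annotation
#'
#' Writes the per-SNP table (`snp_id`, `a`, `s2sum`) and the sparse SNP-gene
#' weight table (`snp_id`, `gene_id`, `w`) as two TSV files.
#'
#' @param annotation A `network_annotation` from [annotate_network()] or
#'   [build_annotation()].
#' @param snp_path,weight_path Output TSV paths.
#' @return `snp_path`, invisibly.
#' @export
write_annotation <- function(annotation, snp_path, weight_path) {
  write.table(as.data.frame(annotation$snp), snp_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(annotation$weights), weight_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(snp_path)
}
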