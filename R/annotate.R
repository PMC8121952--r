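# SNP-level network annotation: proximity flags a_j, contributing gene sets
# O_j, combined SNP-gene weights w_jg and their squared sums.

# Pairs (snp_id, gene_id) such that the gene's transcribed region overlaps
# [pos - window, pos + window], per chromosome, both ends inclusive.
overlap_pairs <- function(snps, genes, window) {
  out <- vector("list", 0L)
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0 || nrow(s) == 0) next
    pos <- s$pos
    # gene g overlaps iff tx_start <= pos + window and tx_end >= pos - window
    hits <- lapply(seq_len(nrow(g)), function(i) {
      lo <- g$tx_start[i] - window
      hi <- g$tx_end[i] + window
      idx <- which(pos >= lo & pos <= hi)
      if (length(idx) == 0) return(NULL)
      tibble(snp_id = s$snp_id[idx], gene_id = g$gene_id[i])
    })
    out <- c(out, hits)
  }
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(snp_id = character(), gene_id = character()))
  }
  arrange(out, .data$snp_id, .data$gene_id)
}

#' Cis window gene sets per SNP
#'
#' For each SNP, the set G_j of genes whose transcribed region lies within
#' `window` base pairs (default 1 Mb, the standard cis-eQTL window) of the
#' SNP position on the same chromosome. Distances are measured from the
#' transcribed-region boundaries, inclusive at both ends. SNPs on
#' chromosomes absent from the catalog are skipped with a warning.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`.
#' @param genes Gene catalog tibble.
#' @param window Window size in base pairs (default 1e6).
#' @return Tibble of (`snp_id`, `gene_id`) pairs; SNPs with empty G_j have
#'   no rows.
#' @export
build_cis_window <- function(snps, genes, window = 1e6) {
  unknown <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    warn(sprintf("SNPs on chromosome(s) %s have no catalog genes; skipped.",
                 paste(unknown, collapse = ", ")))
  }
  overlap_pairs(snps, genes, window)
}

#' Network proximity flag per SNP
#'
#' a_j = 1 if SNP j lies within `window` base pairs (default 100 kb) of the
#' transcribed region of any member gene (TF or TG) of the network, or of
#' any of the network's regulatory-element intervals; otherwise 0. The SNPs
#' flagged here are the ones whose association probability is raised by the
#' enrichment parameter theta.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`.
#' @param network A `regulatory_network` (or anything accepted by
#'   [network_nodes()]).
#' @param genes Gene catalog resolving network node coordinates.
#' @param res Optional tibble of RE intervals (`chrom`, `start`, `end`),
#'   1-based inclusive.
#' @param window Window size in base pairs (default 1e5).
#' @return Integer vector a_j aligned with `snps`.
#' @export
build_proximity_flag <- function(snps, network, genes, res = NULL,
                                 window = 1e5) {
  members <- genes[genes$gene_id %in% network_nodes(network), , drop = FALSE]
  a <- rep(0L, nrow(snps))
  if (nrow(members) > 0) {
    pairs <- overlap_pairs(snps, members, window)
    a[snps$snp_id %in% pairs$snp_id] <- 1L
  }
  if (!is.null(res) && nrow(res) > 0) {
    for (ch in unique(res$chrom)) {
      idx <- which(snps$chrom == ch)
      if (length(idx) == 0) next
      r <- res[res$chrom == ch, ]
      pos <- snps$pos[idx]
      hit <- rep(FALSE, length(idx))
      for (i in seq_len(nrow(r))) {
        hit <- hit | (pos >= r$start[i] - window & pos <= r$end[i] + window)
      }
      a[idx[hit]] <- 1L
    }
  }
  a
}

#' Assemble SNP-gene annotation weights from a network
#'
#' Implements the cis/trans decomposition of a SNP's total effect: for SNP j
#' and any gene t,
#' \deqn{w_{jt} = c_{jt}[t \in G_j] +
#'   \sum_{g \in G_j \cap V_{TF}} c_{jg} v_{gt},}
#' the direct cis weight when t is in the SNP's cis window plus, for every
#' TF g in the window, the TF's cis weight times the TF-TG edge weight. The
#' contributing gene set is O_j = \{t : w_jt > 0\} and
#' s2sum_j = sum over O_j of w_jt^2 feeds the slab variance of the prior.
#'
#' @param network A `regulatory_network`.
#' @param cis Tibble (`snp_id`, `gene_id`, `c`) of cis weights covering the
#'   (j, g in G_j) pairs; missing pairs default to weight 1 when `cis` is
#'   built by [flat_cis_weights()].
#' @param snps Tibble with column `snp_id` (defines the SNP universe and
#'   order).
#' @return A `network_annotation`: list with `snp` (tibble `snp_id`,
#'   `s2sum`) and `weights` (tibble `snp_id`, `gene_id`, `w` with w > 0).
#' @export
build_annotation <- function(network, cis, snps) {
  assert_columns(cis, c("snp_id", "gene_id", "c"), "Cis weight table")
  cis_part <- tibble(snp_id = cis$snp_id, gene_id = cis$gene_id, w = cis$c)
  tf_cis <- cis[cis$gene_id %in% network$tf, , drop = FALSE]
  if (nrow(tf_cis) > 0 && nrow(network$edges) > 0) {
    trans_part <- inner_join(
      setNames(tf_cis, c("snp_id", "tf_id", "c")),
      network$edges, by = "tf_id", relationship = "many-to-many")
    trans_part <- tibble(snp_id = trans_part$snp_id,
                         gene_id = trans_part$tg_id,
                         w = trans_part$c * trans_part$weight)
  } else {
    trans_part <- tibble(snp_id = character(), gene_id = character(),
                         w = numeric())
  }
  weights <- summarise(group_by(bind_rows(cis_part, trans_part),
                                .data$snp_id, .data$gene_id),
                       w = sum(.data$w), .groups = "drop")
  weights <- weights[weights$w > 0, , drop = FALSE]
  s2 <- summarise(group_by(weights, .data$snp_id),
                  s2sum = sum(.data$w^2), .groups = "drop")
  snp_tab <- left_join(tibble(snp_id = snps$snp_id), s2, by = "snp_id")
  snp_tab$s2sum[is.na(snp_tab$s2sum)] <- 0
  structure(list(snp = snp_tab, weights = arrange(weights, .data$snp_id,
                                                  .data$gene_id)),
            class = "network_annotation")
}

#' @export
print.network_annotation <- function(x, ...) {
  cat(sprintf("<network_annotation> %d SNPs (%d flagged), %d SNP-gene weights\n",
              nrow(x$snp), if ("a" %in% names(x$snp)) sum(x$snp$a) else NA,
              nrow(x$weights)))
  invisible(x)
}

#' Flat default cis weights
#'
#' When no eQTL-derived table is supplied, every gene in a SNP's cis window
#' receives weight c_jg = 1.
#'
#' @param cis_pairs Tibble of (`snp_id`, `gene_id`) pairs from
#'   [build_cis_window()].
#' @return Tibble (`snp_id`, `gene_id`, `c`) with c = 1.
#' @export
flat_cis_weights <- function(cis_pairs) {
  mutate(cis_pairs, c = 1)
}

#' Full per-SNP annotation of a network
#'
#' One-stop wrapper: builds the cis windows, the proximity flag a_j and the
#' SNP-gene weights, returning the complete annotation the prior consumes.
#' Network genes absent from the catalog are dropped with a message.
#'
#' @param snps Tibble `snp_id`, `chrom`, `pos`.
#' @param genes Gene catalog tibble.
#' @param network A `regulatory_network`.
#' @param cis Optional (`snp_id`, `gene_id`, `c`) table; defaults to flat
#'   weights over the 1 Mb cis windows.
#' @param res Optional RE interval tibble (`chrom`, `start`, `end`).
#' @param proximity_window Window for a_j (default 100 kb).
#' @param cis_window Window for G_j (default 1 Mb).
#' @return A `network_annotation` whose `snp` tibble carries `snp_id`, `a`,
#'   `s2sum`.
#' @export
annotate_network <- function(snps, genes, network, cis = NULL, res = NULL,
                             proximity_window = 1e5, cis_window = 1e6) {
  known <- network_nodes(network) %in% genes$gene_id
  if (any(!known)) {
    inform(sprintf("%d network gene(s) absent from the catalog were dropped.",
                   sum(!known)))
    keep_nodes <- network_nodes(network)[known]
    edges <- network$edges[network$edges$tf_id %in% keep_nodes &
                             network$edges$tg_id %in% keep_nodes, ,
                           drop = FALSE]
    network <- regulatory_network(edges = edges,
                                  tf = intersect(network$tf, keep_nodes),
                                  tg = intersect(network$tg, keep_nodes))
  }
  if (is.null(cis)) {
    cis <- flat_cis_weights(build_cis_window(snps, genes, cis_window))
  }
  # restrict cis weights to member genes: only genes that can contribute
  # (cis members of O_j are network genes or any catalog gene? The
  # decomposition sums over all cis genes, so keep all of them.)
  ann <- build_annotation(network, cis, snps)
  ann$snp <- mutate(ann$snp,
                    a = build_proximity_flag(snps, network, genes, res,
                                             proximity_window),
                    .after = "snp_id")
  ann
}
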