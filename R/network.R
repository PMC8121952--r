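#' Construct a TF-TG regulatory network
#'
#' A regulatory network is a weighted directed bipartite graph
#' \{V_TF, V_TG, E_TF->TG\}: transcription factors (TFs) linked to target
#' genes (TGs) by edges whose weights in (0, 1] measure relative regulation
#' strength. Nodes default to the genes appearing in the edge list; extra
#' edge-free nodes (as in the near-gene control) may be supplied explicitly.
#'
#' @param edges Tibble with columns `tf_id`, `tg_id`, `weight`. May have
#'   zero rows.
#' @param tf,tg Optional character vectors of TF and TG node identifiers;
#'   must cover the genes in `edges`.
#' @return An object of class `regulatory_network`: a list with elements
#'   `tf`, `tg` (node id vectors) and `edges` (tibble).
#' @export
regulatory_network <- function(edges = NULL, tf = NULL, tg = NULL) {
  if (is.null(edges)) {
    edges <- tibble(tf_id = character(), tg_id = character(), weight = numeric())
  }
  edges <- as_tibble(edges)
  assert_columns(edges, c("tf_id", "tg_id", "weight"), "Edge list")
  if (nrow(edges) > 0 && (any(edges$weight <= 0) || any(edges$weight > 1))) {
    abort("Edge weights must lie in (0, 1].", class = "rssnet_validation_error")
  }
  if (anyDuplicated(edges[c("tf_id", "tg_id")])) {
    abort("Duplicate TF-TG edges.", class = "rssnet_validation_error")
  }
  tf <- sort(unique(c(as.character(tf %||% character()), edges$tf_id)))
  tg <- sort(unique(c(as.character(tg %||% character()), edges$tg_id)))
  edges <- arrange(edges, .data$tf_id, .data$tg_id)
  structure(list(tf = tf, tg = tg, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d TFs, %d TGs, %d edges\n",
              length(x$tf), length(x$tg), nrow(x$edges)))
  invisible(x)
}

#' Member genes of a network
#'
#' @param network A `regulatory_network`.
#' @return Character vector: the union of TF and TG node identifiers.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$tf, network$tg)))
}

#' Near-gene control network
#'
#' The adaptive enrichment threshold is computed against a control network
#' that has every catalog gene as a node and no edges: SNPs within 100 kb of
#' any gene carry the proximity flag, and no effect-size variance is
#' transmitted through edges. A network must beat this control's Bayes
#' factor to be called enriched in a given GWAS.
#'
#' @param genes A gene catalog tibble.
#' @return A `regulatory_network` with all genes as nodes and no edges.
#' @export
near_gene_control <- function(genes) {
  regulatory_network(tf = character(), tg = genes$gene_id)
}

#' Jaccard similarity between two networks
#'
#' Node similarity compares the unions of TF and TG sets; edge similarity
#' compares unweighted directed edge sets.
#'
#' @param a,b `regulatory_network` objects over a shared identifier space.
#' @return A tibble with columns `node_jaccard`, `edge_jaccard`.
#' @export
network_similarity <- function(a, b) {
  na <- network_nodes(a)
  nb <- network_nodes(b)
  ea <- paste(a$edges$tf_id, a$edges$tg_id, sep = "->")
  eb <- paste(b$edges$tf_id, b$edges$tg_id, sep = "->")
  if (length(na) == 0 && length(nb) == 0) {
    abort("Jaccard similarity is undefined for two empty networks.",
          class = "rssnet_validation_error")
  }
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0) return(NA_real_)
    length(intersect(x, y)) / u
  }
  tibble(node_jaccard = jac(na, nb), edge_jaccard = jac(ea, eb))
}

#' Harmonize externally derived edge weights
#'
#' Maps an external network's edge weight x to min(1, x^(1/6)), the
#' compressive rescaling used to bring weights from other inference
#' pipelines (for example CAGE-based co-expression networks) onto the (0, 1]
#' scale of trans-regulation-score weights.
#'
#' @param x Non-negative numeric vector of external edge weights.
#' @return Rescaled weights in \[0, 1\].
#' @export
rescale_external_weight <- function(x) {
  if (any(x < 0)) {
    abort("External edge weights must be non-negative.",
          class = "rssnet_validation_error")
  }
  pmin(1, x^(1 / 6))
}

#' Select the top-K edges of a candidate set
#'
#' Keeps exactly `k` edges with the largest weights; ties at the cutoff are
#' broken deterministically by (tf_id, tg_id) lexicographic order. Used to
#' match an external network's edge count to a reference network before
#' comparing enrichments.
#'
#' @param edges Tibble with columns `tf_id`, `tg_id`, `weight`.
#' @param k Target edge count; must not exceed `nrow(edges)`.
#' @return A `regulatory_network` with exactly `k` edges.
#' @export
select_top_edges <- function(edges, k) {
  edges <- as_tibble(edges)
  assert_columns(edges, c("tf_id", "tg_id", "weight"), "Candidate edge list")
  if (k > nrow(edges)) {
    abort("`k` exceeds the number of candidate edges.",
          class = "rssnet_validation_error")
  }
  ord <- order(-edges$weight, edges$tf_id, edges$tg_id)
  regulatory_network(edges = edges[ord[seq_len(k)], , drop = FALSE])
}

#' Rewire a network preserving nodes and edge count
#'
#' Draws a new edge set of the same size uniformly over TF x TG pairs not
#' present in the original network, keeping both node sets and the edge
#' count (TF out-degrees are resampled, so the regulatory fan-out
#' redistributes across TFs); the original weight multiset is permuted onto
#' the new edges. Used to build edge-altered negative controls that share
#' nodes and edge counts with a target network but differ in topology.
#'
#' @param network A `regulatory_network`.
#' @param seed Integer seed.
#' @return A rewired `regulatory_network`.
#' @export
rewire_network <- function(network, seed = NULL) {
  with_seed(seed, {
    m <- nrow(network$edges)
    pairs <- tidyr::expand_grid(tf_id = network$tf, tg_id = network$tg)
    pairs <- anti_join(pairs, network$edges[c("tf_id", "tg_id")],
                       by = c("tf_id", "tg_id"))
    if (nrow(pairs) < m) {
      abort("Too few non-edges to rewire while excluding original edges.",
            class = "rssnet_parameter_error")
    }
    out <- pairs[sample.int(nrow(pairs), m), ]
    out$weight <- sample(network$edges$weight)
    regulatory_network(edges = out, tf = network$tf, tg = network$tg)
  })
}

#' Remove a fraction of network edges
#'
#' Builds a noisy copy of a network by deleting a uniformly random subset of
#' edges, emulating incompleteness of algorithmically inferred networks.
#' Node sets are preserved.
#'
#' @param network A `regulatory_network`.
#' @param fraction Fraction of edges to remove, in \[0, 1).
#' @param seed Integer seed.
#' @return A `regulatory_network` with fewer edges.
#' @export
remove_network_edges <- function(network, fraction, seed = NULL) {
  stopifnot_scalar_prob(fraction, "fraction")
  with_seed(seed, {
    m <- nrow(network$edges)
    drop_n <- floor(fraction * m)
    keep <- sort(sample.int(m, m - drop_n))
    regulatory_network(edges = network$edges[keep, , drop = FALSE],
                       tf = network$tf, tg = network$tg)
  })
}
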