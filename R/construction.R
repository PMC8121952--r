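# Context-specific network construction from paired expression and
# chromatin-accessibility summaries.

#' Normalize a context-specific expression or accessibility level
#'
#' A feature's level y in one context is normalized against its median level
#' across all contexts: y_tilde = y^2 / y_med. Squaring sharpens context
#' specificity; division by the cross-context median removes feature-scale
#' differences.
#'
#' @param y Non-negative level(s) in the context of interest.
#' @param y_med Strictly positive cross-context median level(s), recycled
#'   against `y`.
#' @return Normalized level(s) `y^2 / y_med`.
#' @export
normalize_context_level <- function(y, y_med) {
  if (any(y_med <= 0)) {
    abort("Cross-context median must be strictly positive for used features.",
          class = "rssnet_validation_error")
  }
  y^2 / y_med
}

#' Trans-regulation score between a TF and a TG
#'
#' For a given cellular context the TRS combines: the cross-context
#' expression correlation R_gt of the TF and the TG; normalized
#' context-specific expression of both genes; and a sum over regulatory
#' elements (REs) of normalized accessibility times motif-binding strength
#' B_gi of the TF on the RE times the RE's overall regulating strength I_it
#' on the TG:
#' \deqn{TRS_{gt} = 2^{|R_{gt}|}\sqrt{\tilde{TF}_g \tilde{TG}_t}
#'   \sum_i \tilde{RE}_i B_{gi} I_{it}.}
#' Larger TRS indicates stronger context-specific regulation and naturally
#' ranks candidate TF-TG edges.
#'
#' @param r_gt Correlation in \[-1, 1\] of TF and TG expression across
#'   contexts.
#' @param tf_level,tg_level Normalized context-specific expression of the TF
#'   and TG (see [normalize_context_level()]).
#' @param re_level Normalized accessibility of each RE (vector over REs).
#' @param binding Motif binding strength B_gi of the TF on each RE.
#' @param regulating Regulating strength I_it of each RE on the TG.
#' @return The non-negative scalar TRS.
#' @export
trans_regulation_score <- function(r_gt, tf_level, tg_level,
                                   re_level = numeric(), binding = numeric(),
                                   regulating = numeric()) {
  if (abs(r_gt) > 1) {
    abort("|R_gt| must be at most 1.", class = "rssnet_validation_error")
  }
  if (any(c(tf_level, tg_level, re_level, binding, regulating) < 0)) {
    abort("Levels and strengths must be non-negative.",
          class = "rssnet_validation_error")
  }
  2^abs(r_gt) * sqrt(tf_level * tg_level) * sum(re_level * binding * regulating)
}

#' Score all candidate TF-TG pairs in a context
#'
#' Vectorized driver over a candidate edge list. Inputs are tidy tables:
#' normalized levels per gene and per RE, motif binding strengths as
#' (tf, re) triples, RE-TG regulating strengths as (re, tg) triples, and
#' cross-context expression correlations as (tf, tg) pairs. Candidates
#' default to every (tf, tg) pair present in the correlation table.
#'
#' @param correlations Tibble `tf_id`, `tg_id`, `r` of cross-context
#'   expression correlations.
#' @param gene_levels Tibble `gene_id`, `level` of normalized
#'   context-specific expression (covering the TFs and TGs used).
#' @param re_levels Tibble `re_id`, `level` of normalized accessibility.
#' @param binding Tibble `tf_id`, `re_id`, `b` with B_gi > 0 rows.
#' @param regulating Tibble `re_id`, `tg_id`, `i` with I_it > 0 rows.
#' @param candidates Optional tibble `tf_id`, `tg_id` restricting scoring.
#' @return Tibble `tf_id`, `tg_id`, `trs`.
#' @export
score_candidate_edges <- function(correlations, gene_levels, re_levels,
                                  binding, regulating, candidates = NULL) {
  assert_columns(correlations, c("tf_id", "tg_id", "r"), "Correlation table")
  assert_columns(gene_levels, c("gene_id", "level"), "Gene level table")
  assert_columns(re_levels, c("re_id", "level"), "RE level table")
  assert_columns(binding, c("tf_id", "re_id", "b"), "Binding table")
  assert_columns(regulating, c("re_id", "tg_id", "i"), "Regulating table")
  cand <- if (is.null(candidates)) {
    correlations[c("tf_id", "tg_id")]
  } else {
    as_tibble(candidates)[c("tf_id", "tg_id")]
  }
  # RE path sums per (tf, tg): sum_i RE_i * B_gi * I_it over shared REs
  paths <- inner_join(binding, regulating, by = "re_id",
                      relationship = "many-to-many")
  paths <- inner_join(paths, re_levels, by = "re_id")
  path_sum <- summarise(group_by(paths, .data$tf_id, .data$tg_id),
                        s = sum(.data$level * .data$b * .data$i),
                        .groups = "drop")
  out <- left_join(cand, correlations, by = c("tf_id", "tg_id"))
  out <- left_join(out, path_sum, by = c("tf_id", "tg_id"))
  out <- left_join(out, setNames(gene_levels, c("tf_id", "tf_level")),
                   by = "tf_id")
  out <- left_join(out, setNames(gene_levels, c("tg_id", "tg_level")),
                   by = "tg_id")
  out$s[is.na(out$s)] <- 0
  if (any(is.na(out$r) | is.na(out$tf_level) | is.na(out$tg_level))) {
    abort("Candidate pair references a gene absent from the input tables.",
          class = "rssnet_validation_error")
  }
  mutate(out[c("tf_id", "tg_id")],
         trs = 2^abs(out$r) * sqrt(out$tf_level * out$tg_level) * out$s)
}

#' Convert trans-regulation scores into edge weights
#'
#' Edge weights on the (0, 1] scale are obtained by
#' log2(1 + TRS) / max log2(1 + TRS) over the candidate set; the top edge
#' gets weight exactly 1, ranking by TRS is preserved, and zero-TRS
#' candidates are dropped.
#'
#' @param scored Tibble with columns `tf_id`, `tg_id`, `trs`.
#' @return A `regulatory_network` whose edge weights are the normalized
#'   scores.
#' @export
score_to_weight <- function(scored) {
  assert_columns(scored, c("tf_id", "tg_id", "trs"), "Scored edge table")
  if (any(scored$trs < 0)) {
    abort("TRS values must be non-negative.", class = "rssnet_validation_error")
  }
  keep <- scored$trs > 0
  if (!any(keep)) {
    abort("All TRS values are zero: no edges can be formed.",
          class = "rssnet_empty_network_error")
  }
  scored <- scored[keep, , drop = FALSE]
  lw <- log2(1 + scored$trs)
  regulatory_network(edges = tibble(tf_id = scored$tf_id,
                                    tg_id = scored$tg_id,
                                    weight = lw / max(lw)))
}

#' Build a context-specific network from PECA-style inputs
#'
#' Convenience pipeline: score candidates with the trans-regulation score,
#' then normalize scores into (0, 1] edge weights, optionally keeping only
#' scores above a quantile of the positive scores.
#'
#' @inheritParams score_candidate_edges
#' @param quantile_keep Optional quantile in \[0, 1); positive-TRS edges
#'   below this quantile are dropped before weight normalization. Default
#'   keeps all positive-TRS edges.
#' @return A `regulatory_network`.
#' @export
build_context_network <- function(correlations, gene_levels, re_levels,
                                  binding, regulating, candidates = NULL,
                                  quantile_keep = NULL) {
  scored <- score_candidate_edges(correlations, gene_levels, re_levels,
                                  binding, regulating, candidates)
  if (!is.null(quantile_keep)) {
    pos <- scored$trs[scored$trs > 0]
    thr <- stats::quantile(pos, quantile_keep, names = FALSE)
    scored <- scored[scored$trs >= thr | scored$trs == 0, , drop = FALSE]
  }
  score_to_weight(scored)
}
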