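# Benchmark metrics and the classical tests used to summarize enrichment
# results.

#' ROC and precision-recall evaluation
#'
#' AUROC is the Mann-Whitney probability that a random positive outscores a
#' random negative, counting ties as 1/2. AUPRC integrates precision over
#' recall step-wise across score thresholds (tied scores enter as one
#' threshold).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (1 = positive class).
#' @return List (class `rssnet_eval`): `auroc`, `auprc`, `roc` (tibble
#'   `fpr`, `tpr`), `prc` (tibble `recall`, `precision`).
#' @export
roc_prc_eval <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be non-empty.", class = "rssnet_parameter_error")
  }
  r <- rank(scores)
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  tpr <- tp / n1
  fpr <- fp / n0
  prec <- tp / (tp + fp)
  auprc <- sum(diff(c(0, tpr)) * prec)
  list(auroc = auroc, auprc = auprc,
       roc = tibble(fpr = c(0, fpr), tpr = c(0, tpr)),
       prc = tibble(recall = tpr, precision = prec)) |>
    structure(class = "rssnet_eval")
}

#' False positive and false discovery rates at a P1 cutoff
#'
#' Calls a gene significant when its posterior probability reaches the
#' cutoff (inclusive) and tabulates the confusion counts against true
#' labels. FDR is undefined (NA) when nothing is called; FPR is undefined
#' when there are no negatives.
#'
#' @param p1 Posterior probabilities.
#' @param labels True binary labels.
#' @param cutoff Significance cutoff (default 0.9).
#' @return One-row tibble: `called`, `fp`, `fpr`, `fdr`.
#' @export
fpr_fdr_eval <- function(p1, labels, cutoff = 0.9) {
  labels <- as.integer(labels)
  call <- p1 >= cutoff
  fp <- sum(call & labels == 0)
  negatives <- sum(labels == 0)
  tibble(called = sum(call), fp = fp,
         fpr = if (negatives == 0) NA_real_ else fp / negatives,
         fdr = if (sum(call) == 0) NA_real_ else fp / sum(call))
}

#' One-sided exact binomial tail
#'
#' P(X >= k) for X ~ Binomial(n, p0), computed on the log scale so that
#' tail probabilities far below double underflow remain accurate.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability in (0, 1).
#' @return One-row tibble: `k`, `n`, `p0`, `p_value`, `log10_p`.
#' @export
binomial_test_one_sided <- function(k, n, p0) {
  if (k < 0 || k > n || p0 <= 0 || p0 >= 1) {
    abort("Need 0 <= k <= n and p0 in (0, 1).",
          class = "rssnet_parameter_error")
  }
  lp <- if (k == 0) 0 else pbinom(k - 1, n, p0, lower.tail = FALSE,
                                  log.p = TRUE)
  tibble(k = k, n = n, p0 = p0, p_value = exp(lp), log10_p = lp / log(10))
}

#' One-sided two-proportion test
#'
#' Pooled two-proportion z test of H1: p1 > p2 with continuity correction
#' (the one-sided version of the chi-squared test with 1 degree of
#' freedom), with the tail computed in log space.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return One-row tibble: `estimate` (difference in proportions), `z`,
#'   `p_value`, `log10_p`.
#' @export
two_proportion_test_one_sided <- function(k1, n1, k2, n2, correct = TRUE) {
  if (min(k1, k2) < 0 || k1 > n1 || k2 > n2) {
    abort("Invalid counts.", class = "rssnet_parameter_error")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  d <- p1 - p2
  if (correct) {
    cc <- 0.5 * (1 / n1 + 1 / n2)
    d <- d - sign(d) * min(abs(d), cc)
  }
  z <- d / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  lp <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  tibble(estimate = p1 - p2, z = z, p_value = exp(lp),
         log10_p = lp / log(10))
}
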