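# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a grid fit
#'
#' One row per hyper-parameter grid point with the mapped slab variances,
#' the evidence lower bound, the normalized posterior weight of the point
#' (softmax of the bounds under the uniform grid prior), and convergence
#' diagnostics.
#'
#' @param x An `rssnet_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rssnet_fit <- function(x, ...) {
  g <- as_tibble(x$grid)
  g$weight <- exp(g$elbo - logsumexp(g$elbo))
  g
}

#' Glance at a grid fit
#'
#' @param x An `rssnet_fit`.
#' @param ... Unused.
#' @return One-row tibble: number of SNPs and grid points, the best grid
#'   point's hyper-parameters and bound, the posterior mass on enrichment
#'   (theta > 0 or rho > 0) points, and the fraction of converged points.
#' @export
glance.rssnet_fit <- function(x, ...) {
  g <- tidy(x)
  best <- g[which.max(g$elbo), ]
  tibble(n_snps = length(x$snp_id), n_grid = nrow(g),
         best_theta0 = best$theta0, best_theta = best$theta,
         best_eta = best$eta, best_rho = best$rho,
         best_elbo = best$elbo,
         mass_enriched = sum(g$weight[g$model != "M0"]),
         prop_converged = mean(g$converged))
}

#' Tidy an enrichment table
#'
#' @param x An `rssnet_enrich_result`.
#' @param ... Unused.
#' @return The per-network tibble of Bayes factors and flags.
#' @export
tidy.rssnet_enrich_result <- function(x, ...) {
  as_tibble(x$table)
}

#' Glance at an enrichment result
#'
#' @param x An `rssnet_enrich_result`.
#' @param ... Unused.
#' @return One-row tibble: control BF, number of networks tested/passing.
#' @export
glance.rssnet_enrich_result <- function(x, ...) {
  tibble(control_log10_bf = x$control_log10_bf,
         n_networks = nrow(x$table),
         n_passing = sum(x$table$passes_control))
}

#' Posterior-weight heat map over the hyper-parameter grid
#'
#' Displays the normalized grid-point weights aggregated over (theta, rho),
#' the two enrichment dimensions; mass away from the theta = 0, rho = 0
#' cell indicates enrichment.
#'
#' @param object An `rssnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rssnet_fit <- function(object, ...) {
  g <- tidy(object)
  agg <- summarise(group_by(g, .data$theta, .data$rho),
                   weight = sum(.data$weight), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$theta),
                                    y = factor(.data$rho),
                                    fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = expression(theta), y = expression(rho),
                  fill = "posterior\nweight")
}

#' Gene prioritization scatter plot
#'
#' Model-averaged network-based probabilities against the near-gene
#' reference; genes above the diagonal are promoted by regulatory topology.
#'
#' @param object An `rssnet_gene_report`.
#' @param cutoff Significance cutoff drawn as guides (default 0.9).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rssnet_gene_report <- function(object, cutoff = 0.9, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p1_near, y = .data$p1_bma)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 3) +
    ggplot2::labs(x = expression(P[1]^near), y = expression(P[1]^bma))
}

#' ROC / precision-recall curves
#'
#' @param object An `rssnet_eval` from [roc_prc_eval()].
#' @param type `"roc"` (default) or `"prc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rssnet_eval <- function(object, type = c("roc", "prc"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    subtitle = sprintf("AUROC = %.3f", object$auroc))
  } else {
    ggplot2::ggplot(object$prc, ggplot2::aes(x = .data$recall,
                                             y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "recall", y = "precision",
                    subtitle = sprintf("AUPRC = %.3f", object$auprc))
  }
}
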