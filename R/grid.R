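#' Hyper-parameter grid for the enrichment model
#'
#' The four hyper-parameters are: `theta0`, the genome-wide background
#' log10-odds of a SNP being trait-associated; `theta`, the log10-odds
#' increment for SNPs near network genes and REs; `eta`, roughly the
#' proportion of phenotypic variation explained by all SNPs; and `rho`, the
#' proportion of genetic variation attributable to the network's SNP-gene
#' weights. Each grid point is labelled with its enrichment pattern:
#' `M0` (theta = 0, rho = 0; baseline), `M11` (theta > 0, rho = 0),
#' `M12` (theta = 0, rho > 0), `M13` (theta > 0, rho > 0). The enrichment
#' model M1 is the union of M11, M12 and M13.
#'
#' @param theta0,theta,eta,rho Numeric vectors of grid values; the grid is
#'   their Cartesian product. `eta` and `rho` must lie in \[0, 1\].
#' @return A tibble with columns `theta0`, `theta`, `eta`, `rho`, `model`,
#'   class `hyper_grid`.
#' @export
hyper_grid <- function(theta0 = seq(-6, -2, by = 0.5),
                       theta = seq(0, 3, by = 0.3),
                       eta = c(0.05, 0.1, 0.2, 0.3, 0.5),
                       rho = c(0, 0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (any(eta < 0 | eta > 1) || any(rho < 0 | rho > 1)) {
    abort("`eta` and `rho` grid values must lie in [0, 1].",
          class = "rssnet_parameter_error")
  }
  if (any(theta < 0)) {
    abort("`theta` grid values must be non-negative.",
          class = "rssnet_parameter_error")
  }
  g <- tidyr::expand_grid(theta0 = theta0, theta = theta, eta = eta, rho = rho)
  g$model <- dplyr::case_when(
    g$theta == 0 & g$rho == 0 ~ "M0",
    g$theta > 0 & g$rho == 0 ~ "M11",
    g$theta == 0 & g$rho > 0 ~ "M12",
    TRUE ~ "M13"
  )
  class(g) <- c("hyper_grid", class(g))
  g
}

#' Default hyper-parameter grid
#'
#' Spans background association rates from roughly 1 per 10^6 to 1 per 10^2
#' SNPs, enrichment increments up to 3 on the log10-odds scale, and broad
#' ranges of total and network-attributable genetic variance. All values are
#' configurable via [hyper_grid()].
#'
#' @return A `hyper_grid` tibble (2,970 points).
#' @export
default_hyper_grid <- function() {
  hyper_grid()
}

#' Compact hyper-parameter grid
#'
#' A reduced grid for simulation studies and examples where refitting
#' thousands of grid points per dataset is unnecessary. Covers the same
#' qualitative ranges as [default_hyper_grid()] at coarse resolution.
#'
#' @return A `hyper_grid` tibble (36 points).
#' @export
compact_hyper_grid <- function() {
  hyper_grid(theta0 = c(-3.5, -3, -2.5),
             theta = c(0, 1.5, 3),
             eta = c(0.2, 0.4),
             rho = c(0, 0.5))
}
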