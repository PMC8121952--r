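# Mean-field variational engine: hyper-parameter mapping, coordinate
# ascent against the summary-statistic regression likelihood, evidence
# lower bounds, and a small-p exact-posterior oracle.

#' Map (eta, rho) to slab variances
#'
#' Re-parameterizes the slab variances on interpretable scales:
#' \deqn{\sigma_0^2 = \eta(1-\rho)\Big/\sum_j \pi_j/(n_j \hat s_j^2),
#'   \quad
#'   \sigma^2 = \eta\rho\Big/\sum_j \pi_j\,s2sum_j/(n_j \hat s_j^2),}
#' so that `eta` is roughly the proportion of phenotypic variance explained
#' by all SNPs and `rho` the share of genetic variance flowing through the
#' network weights. Since n * se^2 approximates the phenotype-to-genotype
#' variance ratio, the resulting SNP effects carry the trait's measurement
#' units and do not depend on sample size. When the network carries no
#' weights (all s2sum = 0) and rho > 0, sigma^2 is defined as 0 with a
#' warning.
#'
#' @param eta,rho Scalars in \[0, 1\].
#' @param pi Per-SNP prior association probabilities.
#' @param shat Per-SNP standard errors (> 0).
#' @param n GWAS sample size (scalar or per-SNP vector).
#' @param s2sum Per-SNP sum of squared annotation weights.
#' @return List with elements `sigma0_sq` and `sigma_sq`.
#' @export
map_hyperparams <- function(eta, rho, pi, shat, n, s2sum) {
  if (eta < 0 || eta > 1 || rho < 0 || rho > 1) {
    abort("`eta` and `rho` must lie in [0, 1].",
          class = "rssnet_parameter_error")
  }
  if (any(shat <= 0)) {
    abort("Standard errors must be strictly positive.",
          class = "rssnet_parameter_error")
  }
  inv_ns2 <- 1 / (n * shat^2)
  den0 <- sum(pi * inv_ns2)
  sigma0_sq <- if (eta == 0) 0 else eta * (1 - rho) / den0
  den1 <- sum(pi * s2sum * inv_ns2)
  if (den1 == 0) {
    if (eta > 0 && rho > 0) {
      warn("Network carries no annotation weights; sigma^2 set to 0.")
    }
    sigma_sq <- 0
  } else {
    sigma_sq <- if (eta == 0) 0 else eta * rho / den1
  }
  list(sigma0_sq = sigma0_sq, sigma_sq = sigma_sq)
}

#' Per-SNP prior moments
#'
#' The spike-and-slab prior for SNP j has mixture weight
#' \eqn{\pi_j = 1/[1 + 10^{-(\theta_0 + a_j\theta)}]} and slab variance
#' \eqn{\sigma_j^2 = \sigma_0^2 + \sigma^2 \cdot s2sum_j} (the per-gene
#' effect variance summed over the SNP's squared annotation weights).
#'
#' @param theta0 Background log10-odds of association.
#' @param theta Enrichment increment on the log10-odds scale.
#' @param a Binary proximity flags per SNP.
#' @param sigma0_sq,sigma_sq Slab variance components.
#' @param s2sum Per-SNP sum of squared annotation weights.
#' @return List with vectors `pi` and `sigma_j_sq`.
#' @export
prior_moments <- function(theta0, theta, a, sigma0_sq, sigma_sq, s2sum) {
  list(pi = log10odds_to_prob(theta0 + a * theta),
       sigma_j_sq = sigma0_sq + sigma_sq * s2sum)
}

# Constant part of the expected log-likelihood: log N(betahat; 0, S R S),
# computed once per dataset. Requires the banded LD matrix to be positive
# definite (block-complete bands from the simulator always are).
rss_loglik_const <- function(betahat, se, R) {
  p <- length(betahat)
  z <- betahat / se
  Rs <- Matrix::forceSymmetric(R)
  ldet <- as.numeric(Matrix::determinant(Rs, logarithm = TRUE)$modulus)
  quad <- sum(z * as.vector(Matrix::solve(Rs, z)))
  -0.5 * (p * log(2 * pi) + ldet + 2 * sum(log(se)) + quad)
}

# Evidence lower bound for the current variational state.
elbo_value <- function(betahat, se, R, alpha, nu, tau2, pi, sigma_j_sq,
                       loglik_const) {
  u <- alpha * nu / se
  Ru <- as.vector(R %*% u)
  # E_q[log likelihood] - loglik_const:
  #   sum_j alpha_j nu_j betahat_j / s_j^2
  #   - 1/2 [ u' R u - sum u_j^2 + sum alpha_j (nu_j^2 + tau_j^2)/s_j^2 ]
  elik <- sum(alpha * nu * betahat / se^2) -
    0.5 * (sum(u * Ru) - sum(u^2) + sum(alpha * (nu^2 + tau2) / se^2))
  # KL(q || prior), per SNP; zero for degenerate (sigma_j = 0) coordinates
  ok <- sigma_j_sq > 0
  a <- alpha[ok]
  pj <- pi[ok]
  kl_bin <- ifelse(a > 0, a * (log(a) - log(pj)), 0) +
    ifelse(a < 1, (1 - a) * (log1p(-a) - log1p(-pj)), 0)
  kl_gauss <- a * 0.5 * (log(sigma_j_sq[ok] / tau2[ok]) +
                           (tau2[ok] + nu[ok]^2) / sigma_j_sq[ok] - 1)
  loglik_const + elik - sum(kl_bin) - sum(kl_gauss)
}

# Internal coordinate-ascent engine on precomputed band storage.
ca_engine <- function(betahat, se, band, R, pi, sigma_j_sq, init,
                      tol = 1e-4, maxit = 300, sweep_order = "alternate",
                      seed = NULL, elbo_trace = FALSE, loglik_const = 0) {
  p <- length(betahat)
  # force fresh allocations: the C++ sweep updates these in place and the
  # initial values may be shared with a previous fit (warm start)
  alpha <- init$alpha * 1
  nu <- init$nu * 1
  alpha[sigma_j_sq <= 0] <- 0
  nu[sigma_j_sq <= 0] <- 0
  u <- alpha * nu / se
  r <- as.vector(R %*% u)
  tau2 <- ifelse(sigma_j_sq > 0,
                 se^2 * sigma_j_sq / (se^2 + sigma_j_sq), 0)
  fwd <- 0:(p - 1L)
  bwd <- rev(fwd)
  orders <- if (sweep_order == "random") {
    with_seed(seed, replicate(maxit, sample.int(p) - 1L, simplify = FALSE))
  }
  trace <- if (elbo_trace) numeric(0) else NULL
  converged <- FALSE
  niter <- 0L
  for (i in seq_len(maxit)) {
    ord <- if (!is.null(orders)) {
      orders[[i]]
    } else if (i %% 2L == 1L) fwd else bwd
    ch <- vb_sweep_cpp(betahat, se, band, pi, sigma_j_sq,
                       alpha, nu, u, r, ord)
    niter <- i
    if (elbo_trace) {
      trace <- c(trace, elbo_value(betahat, se, R, alpha, nu, tau2, pi,
                                   sigma_j_sq, loglik_const))
    }
    if (ch$max_dalpha < tol && ch$max_dmu < tol) {
      converged <- TRUE
      break
    }
  }
  elbo <- elbo_value(betahat, se, R, alpha, nu, tau2, pi, sigma_j_sq,
                     loglik_const)
  list(alpha = alpha, nu = nu, tau = sqrt(tau2), elbo = elbo,
       niter = niter, converged = converged, elbo_trace = trace,
       residual = r, u = u)
}

#' Mean-field coordinate ascent for one hyper-parameter setting
#'
#' Finds the closest fully factorized approximation (in Kullback-Leibler
#' divergence) to the posterior of SNP effects under the spike-and-slab
#' prior and the summary-statistic regression likelihood. The approximating
#' family is a product over SNPs of
#' \eqn{\alpha_j N(\beta_j; \nu_j, \tau_j^2) + (1-\alpha_j)\delta_0} with
#' \eqn{\tau_j = \hat s_j \sigma_j / \sqrt{\hat s_j^2 + \sigma_j^2}} fixed
#' by the prior, and \eqn{(\nu_j, \alpha_j)} updated by deterministic
#' alternating forward/backward sweeps until the largest change in
#' \eqn{\alpha_j} and in \eqn{\alpha_j \nu_j} both fall below `tol`.
#'
#' @param betahat,se Per-SNP marginal effect estimates and standard errors.
#' @param ld An `ld_matrix` aligned with the SNP order.
#' @param pi Per-SNP prior association probabilities.
#' @param sigma_j_sq Per-SNP slab variances; entries equal to zero force the
#'   spike (alpha = 0).
#' @param init Optional list with elements `alpha` and `nu` (warm start);
#'   defaults to a random initialization under `seed`.
#' @param tol Convergence tolerance on parameter changes (default 1e-4).
#' @param maxit Maximum number of outer sweeps (default 300).
#' @param sweep_order `"alternate"` (deterministic, default) or `"random"`
#'   (per-sweep random permutation under `seed`).
#' @param seed Seed for the random initialization (and random sweep order).
#' @param elbo_trace If `TRUE`, record the evidence lower bound after every
#'   sweep (slower; used to verify the ascent property).
#' @return A list (class `rssnet_vbfit`) with `alpha`, `nu`, `tau`, `elbo`,
#'   `niter`, `converged`, and optionally `elbo_trace`.
#' @export
coordinate_ascent <- function(betahat, se, ld, pi, sigma_j_sq, init = NULL,
                              tol = 1e-4, maxit = 300,
                              sweep_order = c("alternate", "random"),
                              seed = 1L, elbo_trace = FALSE) {
  sweep_order <- match.arg(sweep_order)
  p <- length(betahat)
  stopifnot(length(se) == p, length(pi) == p, length(sigma_j_sq) == p)
  if (is.null(init)) {
    init <- with_seed(seed, random_init(p, sigma_j_sq))
  }
  band <- ld_band_storage(ld)
  const <- rss_loglik_const(betahat, se, ld$R)
  out <- ca_engine(betahat, se, band, ld$R, pi, sigma_j_sq, init,
                   tol = tol, maxit = maxit, sweep_order = sweep_order,
                   seed = seed, elbo_trace = elbo_trace,
                   loglik_const = const)
  out$loglik_const <- const
  class(out) <- "rssnet_vbfit"
  out
}

random_init <- function(p, sigma_j_sq) {
  list(alpha = runif(p, 0.01, 0.99),
       nu = rnorm(p, 0, sqrt(pmax(sigma_j_sq, 0))))
}

#' Evidence lower bound of a variational fit
#'
#' Computes \eqn{\ell = E_q[\log f(\hat\beta \mid \beta)] - KL(q \,\|\,
#' \text{prior})} in closed form for the spike-and-slab mean-field family.
#' The bound never exceeds the log marginal likelihood of the
#' hyper-parameter setting, with equality when the exact posterior
#' factorizes (for example under an identity LD matrix).
#'
#' @param fit A fit from [coordinate_ascent()].
#' @param betahat,se,ld The data the fit was computed on.
#' @param pi,sigma_j_sq The prior used.
#' @return The scalar lower bound.
#' @export
lower_bound <- function(fit, betahat, se, ld, pi, sigma_j_sq) {
  const <- fit$loglik_const %||% rss_loglik_const(betahat, se, ld$R)
  elbo_value(betahat, se, ld$R, fit$alpha, fit$nu, fit$tau^2, pi,
             sigma_j_sq, const)
}

#' Fit the variational approximation over a hyper-parameter grid
#'
#' Maps every grid point through the hyper-parameter re-parameterization
#' and the per-SNP prior moments, then runs [coordinate_ascent()]. Grid
#' points are visited in (eta, rho, theta0, theta) order and each fit
#' warm-starts from the previous point's solution (the first point uses a
#' seeded random initialization), which mitigates local optima at modest
#' cost. Results are deterministic given `seed`.
#'
#' @param gwas A GWAS summary tibble (see [read_gwas_summary()]) aligned
#'   with `ld`.
#' @param ld An `ld_matrix` over the same SNPs in the same order.
#' @param annotation A `network_annotation` from [annotate_network()].
#' @param grid A `hyper_grid` tibble.
#' @param tol,maxit Convergence controls passed to the inner engine.
#' @param seed Seed for initialization.
#' @param warm_start Warm-start successive grid points (default `TRUE`).
#' @return An object of class `rssnet_fit`: list with `grid` (tibble of
#'   hyper-parameters, slab variances, `elbo`, `niter`, `converged`),
#'   matrices `alpha`, `nu`, `tau` (SNPs by grid points), `snp_id`, and the
#'   log-likelihood constant.
#' @export
fit_grid <- function(gwas, ld, annotation, grid = compact_hyper_grid(),
                     tol = 1e-4, maxit = 300, seed = 1L, warm_start = TRUE) {
  if (nrow(grid) == 0) {
    abort("Hyper-parameter grid is empty.", class = "rssnet_parameter_error")
  }
  if (!identical(as.character(gwas$snp_id), ld$snp_id)) {
    abort("GWAS and LD SNPs are not aligned.",
          class = "rssnet_validation_error")
  }
  ann <- left_join(tibble(snp_id = gwas$snp_id), annotation$snp,
                   by = "snp_id")
  if (any(is.na(ann$a)) || any(is.na(ann$s2sum))) {
    abort("Annotation does not cover all GWAS SNPs.",
          class = "rssnet_validation_error")
  }
  betahat <- gwas$betahat
  se <- gwas$se
  n <- gwas$n
  p <- length(betahat)
  a <- ann$a
  s2sum <- ann$s2sum

  grid <- arrange(as_tibble(grid), .data$eta, .data$rho, .data$theta0,
                  .data$theta)
  H <- nrow(grid)
  band <- ld_band_storage(ld)
  const <- rss_loglik_const(betahat, se, ld$R)

  alpha_m <- matrix(NA_real_, p, H)
  nu_m <- matrix(NA_real_, p, H)
  tau_m <- matrix(NA_real_, p, H)
  elbo <- niter <- numeric(H)
  conv <- logical(H)
  sigma0_sq <- sigma_sq <- numeric(H)

  init <- with_seed(seed, random_init(p, rep(1, p)))
  prev <- init
  for (h in seq_len(H)) {
    pm0 <- prior_moments(grid$theta0[h], grid$theta[h], a, 0, 0, s2sum)
    vs <- map_hyperparams(grid$eta[h], grid$rho[h], pm0$pi, se, n, s2sum)
    sigma0_sq[h] <- vs$sigma0_sq
    sigma_sq[h] <- vs$sigma_sq
    pm <- prior_moments(grid$theta0[h], grid$theta[h], a, vs$sigma0_sq,
                        vs$sigma_sq, s2sum)
    start <- if (warm_start) prev else with_seed(seed + h, random_init(p, pm$sigma_j_sq))
    fit <- ca_engine(betahat, se, band, ld$R, pm$pi, pm$sigma_j_sq, start,
                     tol = tol, maxit = maxit, loglik_const = const)
    alpha_m[, h] <- fit$alpha
    nu_m[, h] <- fit$nu
    tau_m[, h] <- fit$tau
    elbo[h] <- fit$elbo
    niter[h] <- fit$niter
    conv[h] <- fit$converged
    if (warm_start) prev <- list(alpha = fit$alpha, nu = fit$nu)
  }
  grid$sigma0_sq <- sigma0_sq
  grid$sigma_sq <- sigma_sq
  grid$elbo <- elbo
  grid$niter <- niter
  grid$converged <- conv
  if (any(!conv)) {
    inform(sprintf("%d of %d grid points did not converge within %d sweeps.",
                   sum(!conv), H, maxit))
  }
  structure(list(grid = grid, alpha = alpha_m, nu = nu_m, tau = tau_m,
                 snp_id = gwas$snp_id, loglik_const = const),
            class = "rssnet_fit")
}

#' @export
print.rssnet_fit <- function(x, ...) {
  cat(sprintf("<rssnet_fit> %d SNPs x %d grid points (%s)\n",
              length(x$snp_id), nrow(x$grid),
              paste(sprintf("%s:%d", names(table(x$grid$model)),
                            as.integer(table(x$grid$model))),
                    collapse = " ")))
  invisible(x)
}

#' Exact posterior by enumeration (small p oracle)
#'
#' Enumerates all 2^p spike/slab configurations; under each, the marginal
#' likelihood of the observed effect estimates is a closed-form Gaussian
#' under the summary-statistic regression likelihood. Combining
#' configurations with their prior mixture weights gives the exact log
#' evidence and exact posterior inclusion probabilities. Intended as an
#' independent check of the variational approximation; refuses p > 12.
#'
#' @param betahat,se Effect estimates and standard errors.
#' @param R LD matrix as a plain (dense) matrix.
#' @param pi,sigma_j_sq Prior mixture weights and slab variances.
#' @return List with `log_evidence` and `alpha` (exact inclusion
#'   probabilities).
#' @export
exact_posterior_oracle <- function(betahat, se, R, pi, sigma_j_sq) {
  p <- length(betahat)
  if (p > 12) {
    abort("Enumeration oracle is limited to p <= 12.",
          class = "rssnet_parameter_error")
  }
  R <- as.matrix(R)
  SRS <- R * outer(se, se)
  A <- R * outer(se, 1 / se)  # S R S^{-1}
  nconf <- 2^p
  logev <- numeric(nconf)
  logw <- numeric(nconf)
  zmat <- matrix(0L, nconf, p)
  for (m in seq_len(nconf)) {
    z <- as.integer(intToBits(m - 1)[1:p])
    zmat[m, ] <- z
    cov <- SRS
    idx <- which(z == 1L)
    if (length(idx) > 0) {
      Az <- A[, idx, drop = FALSE]
      cov <- cov + Az %*% (sigma_j_sq[idx] * t(Az))
    }
    ch <- chol(cov)
    q <- backsolve(ch, betahat, transpose = TRUE)
    logev[m] <- -0.5 * (p * log(2 * base::pi) + 2 * sum(log(diag(ch))) +
                          sum(q^2))
    logw[m] <- sum(ifelse(z == 1L, log(pi), log1p(-pi)))
  }
  tot <- logsumexp(logw + logev)
  alpha <- vapply(seq_len(p), function(j) {
    sel <- zmat[, j] == 1L
    exp(logsumexp(logw[sel] + logev[sel]) - tot)
  }, numeric(1))
  list(log_evidence = tot, alpha = alpha)
}
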