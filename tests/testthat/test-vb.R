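test_that("hyper-parameter mapping matches hand-computed sums", {
  # eta = 0 gives null variances
  z <- map_hyperparams(0, 0.5, pi = c(0.1, 0.2), shat = c(1, 2), n = 100,
                       s2sum = c(1, 4))
  expect_equal(z$sigma0_sq, 0)
  expect_equal(z$sigma_sq, 0)

  # single SNP, pi = 1, n * shat^2 = 1, eta = 0.5, rho = 0
  z <- map_hyperparams(0.5, 0, pi = 1, shat = 1, n = 1, s2sum = 0)
  expect_equal(z$sigma0_sq, 0.5)
  expect_equal(z$sigma_sq, 0)

  # rho = 1, two SNPs, explicit-sum oracle
  pi <- c(0.3, 0.8); shat <- c(0.5, 1.2); n <- 50; s2 <- c(2, 0.7)
  z <- map_hyperparams(0.4, 1, pi, shat, n, s2)
  expect_equal(z$sigma0_sq, 0)
  expect_equal(z$sigma_sq, 0.4 / sum(pi * s2 / (n * shat^2)))

  expect_error(map_hyperparams(1.2, 0, 1, 1, 1, 0),
               class = "rssnet_parameter_error")
  expect_warning(map_hyperparams(0.5, 0.5, pi = 1, shat = 1, n = 1,
                                 s2sum = 0),
                 "no annotation weights")
})

test_that("prior moments follow the log10-odds and variance formulas", {
  pm <- prior_moments(-2, 1, a = 1, sigma0_sq = 0, sigma_sq = 0, s2sum = 0)
  expect_equal(pm$pi, 1 / 11)
  pm0 <- prior_moments(-2, 1, a = 0, 0, 0, 0)
  expect_equal(pm0$pi, 1 / 101)
  pm99 <- prior_moments(-2, 99, a = 0, 0, 0, 0)
  expect_equal(pm99$pi, pm0$pi)  # theta irrelevant when a = 0
  pm2 <- prior_moments(-2, 1, 1, sigma0_sq = 1, sigma_sq = 2, s2sum = 1.25)
  expect_equal(pm2$sigma_j_sq, 3.5)
})

test_that("single-SNP fit equals the closed-form spike-slab posterior", {
  ld <- ld_identity("s1")
  f <- coordinate_ascent(0, 1, ld, pi = 0.5, sigma_j_sq = 1, seed = 2)
  expect_equal(f$tau, 1 / sqrt(2))
  expect_equal(f$nu, 0, tolerance = 1e-12)
  # odds = (tau/sigma) = 1/sqrt(2), alpha = odds/(1+odds) = sqrt(2) - 1
  expect_equal(f$alpha, sqrt(2) - 1, tolerance = 1e-10)

  # pi -> 1 with large slab: alpha -> 1, nu -> ridge estimate
  f2 <- coordinate_ascent(2, 0.5, ld_identity("s1"), pi = 1 - 1e-12,
                          sigma_j_sq = 100, seed = 2)
  tau2 <- 0.25 * 100 / (0.25 + 100)
  expect_gt(f2$alpha, 0.999)
  expect_equal(f2$nu, tau2 * 2 / 0.25, tolerance = 1e-8)
})

test_that("with identity LD the VB posterior is exact for every SNP", {
  for (seed in 1:5) {
    inst <- random_instance(8, seed)
    ldI <- ld_identity(sprintf("s%d", 1:8))
    fit <- coordinate_ascent(inst$betahat, inst$se, ldI, inst$pi,
                             inst$sigma_j_sq, seed = seed)
    oracle <- exact_posterior_oracle(inst$betahat, inst$se, diag(8),
                                     inst$pi, inst$sigma_j_sq)
    expect_lt(max(abs(fit$alpha - oracle$alpha)), 1e-6)
    # per-SNP closed forms for nu and tau
    tau2 <- inst$se^2 * inst$sigma_j_sq / (inst$se^2 + inst$sigma_j_sq)
    expect_equal(fit$nu, tau2 * inst$betahat / inst$se^2, tolerance = 1e-10)
    expect_equal(fit$tau, sqrt(tau2))
    # the factorized posterior is inside the mean-field family:
    # the bound is tight
    expect_equal(fit$elbo, oracle$log_evidence, tolerance = 1e-8)
  }
})

test_that("the ELBO never exceeds the enumeration oracle's log evidence", {
  worst_gap <- 0
  for (seed in 1:25) {
    p <- sample(3:8, 1)
    inst <- random_instance(p, seed)
    ld <- dense_ld(inst$R)
    fit <- coordinate_ascent(inst$betahat, inst$se, ld, inst$pi,
                             inst$sigma_j_sq, seed = seed)
    oracle <- exact_posterior_oracle(inst$betahat, inst$se, inst$R,
                                     inst$pi, inst$sigma_j_sq)
    expect_lte(fit$elbo, oracle$log_evidence + 1e-8)
    worst_gap <- max(worst_gap, abs(fit$elbo - oracle$log_evidence))
  }
  expect_gt(worst_gap, 0)  # the bound is not vacuously equal everywhere

  # gap shrinks to zero as off-diagonal LD shrinks
  inst <- random_instance(6, 99)
  gaps <- vapply(c(1, 0.3, 0.05, 0), function(k) {
    R <- inst$R * k
    diag(R) <- 1
    fit <- coordinate_ascent(inst$betahat, inst$se, dense_ld(R), inst$pi,
                             inst$sigma_j_sq, seed = 1)
    oracle <- exact_posterior_oracle(inst$betahat, inst$se, R, inst$pi,
                                     inst$sigma_j_sq)
    oracle$log_evidence - fit$elbo
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-8))
  expect_lt(gaps[4], 1e-8)
})

test_that("the enumeration oracle matches quadrature and independence", {
  # p = 2, uncorrelated: evidence is the product of single-SNP evidences
  inst <- random_instance(2, 3)
  o <- exact_posterior_oracle(inst$betahat, inst$se, diag(2), inst$pi,
                              inst$sigma_j_sq)
  single <- function(b, s, pi, v) {
    log((1 - pi) * dnorm(b, 0, s) + pi * dnorm(b, 0, sqrt(s^2 + v)))
  }
  expect_equal(o$log_evidence,
               sum(single(inst$betahat, inst$se, inst$pi, inst$sigma_j_sq)),
               tolerance = 1e-10)

  # p = 2, correlated: cross-check the slab-slab component against 2-D
  # quadrature over the latent effects
  skip_if_not_installed("pracma")
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  se <- c(0.8, 1.1); betahat <- c(0.5, -0.3)
  pi_slab <- c(1, 1)  # force the slab-slab configuration
  s2 <- c(0.7, 1.3)
  o2 <- exact_posterior_oracle(betahat, se, R, pi_slab, s2)
  SRS <- R * outer(se, se)
  A <- R * outer(se, 1 / se)
  Sinv <- solve(SRS)
  dens <- function(b1, b2) {
    # N(betahat; A b, SRS) * N(b1; 0, s2[1]) * N(b2; 0, s2[2]), vectorized
    out <- numeric(length(b1))
    for (i in seq_along(b1)) {
      rvec <- betahat - A %*% c(b1[i], b2[i])
      q <- as.numeric(t(rvec) %*% Sinv %*% rvec)
      out[i] <- exp(-q / 2) / (2 * pi * sqrt(det(SRS))) *
        dnorm(b1[i], 0, sqrt(s2[1])) * dnorm(b2[i], 0, sqrt(s2[2]))
    }
    out
  }
  # nested adaptive 1-D quadrature for high precision
  inner <- function(b1) {
    stats::integrate(function(b2) dens(rep(b1, length(b2)), b2),
                     -10 * sqrt(s2[2]), 10 * sqrt(s2[2]),
                     rel.tol = 1e-11, abs.tol = 0)$value
  }
  quad <- stats::integrate(Vectorize(inner),
                           -10 * sqrt(s2[1]), 10 * sqrt(s2[1]),
                           rel.tol = 1e-11, abs.tol = 0)$value
  expect_equal(o2$log_evidence, log(quad), tolerance = 1e-6)

  expect_error(exact_posterior_oracle(rnorm(13), rep(1, 13), diag(13),
                                      rep(0.5, 13), rep(1, 13)),
               class = "rssnet_parameter_error")
})

test_that("residual bookkeeping reproduces the literal sums", {
  inst <- random_instance(40, 7)
  # diagonally dominant banded correlation: guaranteed positive definite
  bw <- 6L
  k <- abs(outer(1:40, 1:40, "-"))
  Rb <- 0.3^k * (k <= bw)
  ld <- ld_matrix(Rb, sprintf("s%d", 1:40), rep("1", 40), bandwidth = bw)
  fit <- coordinate_ascent(inst$betahat, inst$se, ld, inst$pi,
                           inst$sigma_j_sq, seed = 1)
  u <- fit$alpha * fit$nu / inst$se
  expect_lt(max(abs(fit$residual - as.vector(Rb %*% u))), 1e-10)
})

test_that("the bound ascends and fits are permutation-equivariant", {
  inst <- random_instance(12, 13)
  ld <- dense_ld(inst$R)
  fit <- coordinate_ascent(inst$betahat, inst$se, ld, inst$pi,
                           inst$sigma_j_sq, seed = 4, elbo_trace = TRUE)
  expect_true(all(diff(fit$elbo_trace) > -1e-8))

  # relabeling SNPs permutes the posterior and leaves the bound unchanged
  # (tight tolerance so both runs land on the same fixed point)
  perm <- sample.int(12)
  Rp <- inst$R[perm, perm]
  fitp <- coordinate_ascent(inst$betahat[perm], inst$se[perm], dense_ld(Rp),
                            inst$pi[perm], inst$sigma_j_sq[perm],
                            init = list(alpha = rep(0.5, 12),
                                        nu = rep(0, 12)), tol = 1e-9)
  fit2 <- coordinate_ascent(inst$betahat, inst$se, ld, inst$pi,
                            inst$sigma_j_sq,
                            init = list(alpha = rep(0.5, 12),
                                        nu = rep(0, 12)), tol = 1e-9)
  expect_equal(fitp$alpha, fit2$alpha[perm], tolerance = 1e-6)
  expect_equal(fitp$elbo, fit2$elbo, tolerance = 1e-6)
})

test_that("tau is monotone in sigma and degenerate slabs force the spike", {
  se <- 1.3
  sig <- c(0, 0.01, 0.1, 1, 10, 1e4)
  tau <- se * sqrt(sig) / sqrt(se^2 + sig)
  expect_true(all(diff(tau) > 0))
  expect_equal(tau[1], 0)
  expect_true(all(tau <= pmin(se, sqrt(sig)) + 1e-12))

  # eta = 0: all sigma_j = 0, every alpha collapses to the spike
  inst <- random_instance(5, 17)
  fit <- coordinate_ascent(inst$betahat, inst$se, dense_ld(inst$R),
                           inst$pi, rep(0, 5), seed = 1)
  expect_equal(fit$alpha, rep(0, 5))
  expect_equal(fit$nu, rep(0, 5))
})

test_that("prior variance decomposition holds under Monte Carlo", {
  # Var(beta_j) = pi_j (sigma0^2 + sigma^2 * s2sum_j): draw a large number
  # of effects for one SNP configuration and compare moments
  pi_j <- 0.3; sigma0_sq <- 0.5; sigma_sq <- 2; s2sum <- 1.25
  B <- 1e6
  set.seed(123)
  z <- runif(B) < pi_j
  beta <- ifelse(z, rnorm(B, 0, sqrt(sigma0_sq + sigma_sq * s2sum)), 0)
  v_target <- pi_j * (sigma0_sq + sigma_sq * s2sum)
  # SE of the sample variance of a spike-and-slab draw
  m4 <- pi_j * 3 * (sigma0_sq + sigma_sq * s2sum)^2
  se_v <- sqrt((m4 - v_target^2) / B)
  expect_lt(abs(var(beta) - v_target), 3 * se_v)
})

test_that("grid fits are deterministic and warm starts match cold starts", {
  st <- simulate_study(n = 400, p = 300, n_genes = 60, n_chrom = 2,
                       n_tf = 6, n_tg = 30, n_edges = 60, n_re = 20,
                       seed = 5)
  sc <- sim_scenario("M13", seed = 6)
  eff <- simulate_effects(sc, st$annotation, st$snps, st$geno_var)
  y <- simulate_phenotype(st$X, eff$beta, 0.3, seed = 7)
  ss <- single_snp_stats(st$X, y, st$snps, bandwidth = 20)
  grid <- hyper_grid(theta0 = c(-3, -2.5), theta = c(0, 2), eta = 0.3,
                     rho = c(0, 0.5))

  f1 <- fit_grid(ss$gwas, ss$ld, st$annotation, grid, seed = 1)
  f2 <- fit_grid(ss$gwas, ss$ld, st$annotation, grid, seed = 1)
  expect_identical(f1$alpha, f2$alpha)  # bitwise determinism

  # grid of one point equals a direct coordinate_ascent call
  g1 <- hyper_grid(theta0 = -3, theta = 2, eta = 0.3, rho = 0.5)
  fg <- fit_grid(ss$gwas, ss$ld, st$annotation, g1, seed = 1)
  pm0 <- prior_moments(-3, 2, st$annotation$snp$a, 0, 0,
                       st$annotation$snp$s2sum)
  vs <- map_hyperparams(0.3, 0.5, pm0$pi, ss$gwas$se, ss$gwas$n,
                        st$annotation$snp$s2sum)
  pm <- prior_moments(-3, 2, st$annotation$snp$a, vs$sigma0_sq, vs$sigma_sq,
                      st$annotation$snp$s2sum)
  init <- rssnet:::with_seed(1, rssnet:::random_init(nrow(ss$gwas),
                                                     rep(1, nrow(ss$gwas))))
  fd <- coordinate_ascent(ss$gwas$betahat, ss$gwas$se, ss$ld, pm$pi,
                          pm$sigma_j_sq, init = init)
  expect_equal(fg$grid$elbo, fd$elbo, tolerance = 1e-9)
  expect_equal(fg$alpha[, 1], fd$alpha, tolerance = 1e-9)

  # warm start reaches the same bound as cold start on a small instance
  fw <- fit_grid(ss$gwas, ss$ld, st$annotation, grid, seed = 1,
                 warm_start = TRUE)
  fc <- fit_grid(ss$gwas, ss$ld, st$annotation, grid, seed = 1,
                 warm_start = FALSE)
  expect_equal(fw$grid$elbo, fc$grid$elbo, tolerance = 1e-6)
})
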