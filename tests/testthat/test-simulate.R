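test_that("genotype simulation hits target frequencies and LD", {
  genes <- simulate_gene_catalog(n_genes = 40, n_chrom = 1, seed = 1)
  snps <- simulate_snp_table(genes, p = 300, seed = 2)

  # independence: near-zero adjacent correlation when latent LD is 0
  X0 <- simulate_genotypes(5000, snps, block_size = 20,
                           within_block_ld = 0, seed = 3)
  r_adj <- vapply(1:299, function(j) cor(X0[, j], X0[, j + 1]), numeric(1))
  expect_lt(mean(abs(r_adj)), 0.05)

  # determinism
  X1 <- simulate_genotypes(200, snps, seed = 4)
  X2 <- simulate_genotypes(200, snps, seed = 4)
  expect_identical(X1, X2)

  # empirical MAF within 0.02 of target at large n
  X3 <- simulate_genotypes(5000, snps, within_block_ld = 0.5, seed = 5)
  maf_hat <- colMeans(X3) / 2
  expect_lt(max(abs(maf_hat - attr(X3, "maf"))), 0.02)

  # adjacent allelic correlation matches the thresholded-Gaussian oracle
  snps_eq <- snps
  X4 <- simulate_genotypes(5000, snps_eq, block_size = 20,
                           within_block_ld = 0.9,
                           maf_range = c(0.3, 0.3), seed = 6)
  within <- vapply(1:299, function(j) {
    if ((j - 1) %/% 20 == j %/% 20) cor(X4[, j], X4[, j + 1]) else NA_real_
  }, numeric(1))
  implied <- implied_threshold_corr(0.3, 0.9)
  expect_lt(abs(mean(within, na.rm = TRUE) - implied), 0.1)
})

test_that("effect models reproduce their association rates", {
  st <- simulate_study(n = 300, p = 2000, n_genes = 300, n_chrom = 3,
                       n_tf = 10, n_tg = 80, n_edges = 200, n_re = 50,
                       seed = 31)

  # M0 with theta0 = -3: causal fraction within 3 binomial SDs
  sc0 <- sim_scenario("M0", theta0 = -3, seed = 32)
  e0 <- simulate_effects(sc0, st$annotation, st$snps, st$geno_var)
  p0 <- 10^-3 / (1 + 10^-3)
  expect_lt(abs(sum(e0$causal) - 2000 * p0),
            3 * sqrt(2000 * p0 * (1 - p0)) + 1)

  # M1: flagged SNPs are associated more often than unflagged ones,
  # by construction of the log-odds model
  sc1 <- sim_scenario("M13", theta0 = -2, theta = 2, seed = 33)
  e1 <- simulate_effects(sc1, st$annotation, st$snps, st$geno_var)
  a <- st$annotation$snp$a
  expect_gt(mean(e1$pi[a == 1]), mean(e1$pi[a == 0]))
  set.seed(99)
  hits <- replicate(20, {
    scr <- sim_scenario("M13", theta0 = -2, theta = 2,
                        seed = sample.int(1e6, 1))
    er <- simulate_effects(scr, st$annotation, st$snps, st$geno_var)
    mean(er$causal[a == 1]) >= mean(er$causal[a == 0])
  })
  expect_gte(mean(hits), 0.95)

  # edge-altered networks keep nodes and edge counts, change edges
  alt <- rewire_network(st$network, seed = 34)
  expect_identical(sort(network_nodes(alt)), sort(network_nodes(st$network)))
  expect_equal(nrow(alt$edges), nrow(st$network$edges))
  expect_lt(network_similarity(alt, st$network)$edge_jaccard, 1)

  # MAF/LD-dependent effects need their annotations
  ld <- ld_matrix(rssnet:::banded_cor(st$X, st$snps$chrom, 20),
                  st$snps$snp_id, st$snps$chrom, 20)
  scm <- sim_scenario("maf_ld_dependent", theta0 = -2.5, theta = 2,
                      seed = 35)
  em <- simulate_effects(scm, snps = st$snps, geno_var = st$geno_var,
                         ld_scores = ld_scores(ld), maf = st$maf)
  expect_true(all(em$var_j > 0))
  # higher-variance SNPs are also more often associated (both rate and size)
  expect_gt(cor(em$pi, em$var_j), 0)

  # near-gene random enrichment elevates a subset of near-gene SNPs
  scg <- sim_scenario("near_gene_random", theta0 = -2.5, theta = 2,
                      seed = 36)
  eg <- simulate_effects(scg, snps = st$snps, geno_var = st$geno_var,
                         eligible = st$a_gene == 1)
  expect_true(all(eg$pi[st$a_gene == 0] == min(eg$pi)))

  expect_error(simulate_effects(structure(list(effect_model = "nope",
                                               seed = 1),
                                          class = "sim_scenario"),
                                snps = st$snps, geno_var = st$geno_var),
               class = "rssnet_parameter_error")
})

test_that("signal matching equalizes counts and explained variance", {
  set.seed(41)
  X <- matrix(rbinom(500 * 300, 2, 0.3), 500, 300)
  beta_pos <- numeric(300); beta_pos[sample.int(300, 10)] <- rnorm(10, 0, 0.3)
  beta_neg <- numeric(300); beta_neg[sample.int(300, 20)] <- rnorm(20, 0, 0.5)

  m <- match_signal(beta_pos, beta_neg, X, seed = 42)
  expect_equal(sum(m != 0), sum(beta_pos != 0))
  pve <- function(b) var(as.vector(X %*% b))
  expect_lt(abs(pve(m) - pve(beta_pos)) / pve(beta_pos), 0.01)

  # already matched: only the (identity) rescaling applies
  m2 <- match_signal(beta_pos, beta_pos, X, seed = 43)
  expect_equal(m2, beta_pos)

  expect_error(match_signal(beta_neg, beta_pos, X),
               class = "rssnet_parameter_error")
  expect_error(match_signal(numeric(300), beta_neg, X),
               class = "rssnet_parameter_error")
})

test_that("phenotypes realize the requested heritability exactly", {
  set.seed(51)
  X <- matrix(rbinom(400 * 100, 2, 0.4), 400, 100)
  beta <- numeric(100); beta[1:5] <- 0.3

  y <- simulate_phenotype(X, beta, 0.5, seed = 52)
  g <- as.vector(X %*% beta)
  expect_equal(var(g) / var(y), 0.5, tolerance = 1e-10)

  y2 <- simulate_phenotype(X, beta, 0.5, seed = 52)
  expect_identical(y, y2)

  y0 <- simulate_phenotype(X, numeric(100), 0, seed = 53)
  expect_equal(length(y0), 400)
  expect_error(simulate_phenotype(X, numeric(100), 0.3, seed = 1),
               class = "rssnet_parameter_error")
})

test_that("single-SNP statistics match hand OLS and are calibrated", {
  # hand-computed example: slope 0.5, se sqrt(0.75)
  snps1 <- tibble::tibble(snp_id = "s1", chrom = "1", pos = 100L,
                          a1 = "A", a2 = "G")
  ss <- single_snp_stats(matrix(c(-1, 0, 1), 3, 1), c(-1, 1, 0), snps1,
                         bandwidth = 0)
  expect_equal(ss$gwas$betahat, 0.5)
  expect_equal(ss$gwas$se, sqrt(0.75))
  expect_equal(ss$gwas$n, 3L)

  # orthogonal phenotype gives slope 0
  ss0 <- single_snp_stats(matrix(c(-1, 0, 1, 0), 4, 1), c(1, -1, 1, -1),
                          snps1, bandwidth = 0)
  expect_equal(ss0$gwas$betahat, 0)

  # monomorphic SNPs are dropped with a warning
  snps2 <- tibble::tibble(snp_id = c("s1", "s2"), chrom = "1",
                          pos = c(1L, 2L), a1 = "A", a2 = "G")
  expect_warning(
    ssm <- single_snp_stats(cbind(c(0, 1, 2, 1), c(1, 1, 1, 1)),
                            rnorm(4), snps2, bandwidth = 0),
    "monomorphic")
  expect_equal(nrow(ssm$gwas), 1L)

  # null z-scores are standard normal (unlinked SNPs so the
  # Kolmogorov-Smirnov test's independence assumption holds)
  genes <- simulate_gene_catalog(n_genes = 30, n_chrom = 1, seed = 61)
  snps <- simulate_snp_table(genes, p = 200, seed = 62)
  set.seed(63)
  ok <- replicate(20, {
    sd <- sample.int(1e6, 1)
    X <- simulate_genotypes(5000, snps, within_block_ld = 0, seed = sd)
    y <- rnorm(5000)
    s <- single_snp_stats(X, y, snps, bandwidth = 0)
    stats::ks.test(s$gwas$betahat / s$gwas$se, "pnorm")$p.value > 0.01
  })
  expect_gte(mean(ok), 0.9)

  # LD is the banded sample correlation (spot check against cor())
  X <- simulate_genotypes(800, snps, within_block_ld = 0.7, seed = 63)
  s <- single_snp_stats(X, rnorm(800), snps, bandwidth = 3, shrink = 0)
  R <- as.matrix(s$ld)
  expect_equal(R[5, 6], cor(X[, 5], X[, 6]), tolerance = 1e-12)
  expect_equal(R[5, 9], 0)  # beyond the band
})

test_that("true gene labels flag genes near causal SNPs", {
  genes <- toy_genes()
  snps <- toy_snps()
  beta <- numeric(10)
  beta[2] <- 1  # s02 at 120 kb on chr 1: within 100 kb of gA? gap 109 kb -> no
  lab <- true_gene_labels(genes, snps, beta)
  # s02 at 120,000; gA ends 11,000 (distance 109,000); gB starts 500,000
  expect_equal(sum(lab$label), 0L)
  beta[1] <- 1  # s01 inside gA
  lab2 <- true_gene_labels(genes, snps, beta)
  expect_equal(lab2$label[lab2$gene_id == "gA"], 1L)
})
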