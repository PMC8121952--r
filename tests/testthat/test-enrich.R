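# A minimal hand-built fit object is enough to exercise the evidence
# aggregation and P1 machinery.
fake_fit <- function(elbo, model, alpha) {
  structure(list(
    grid = tibble::tibble(theta0 = -3, theta = ifelse(model == "M0", 0, 1),
                          eta = 0.3, rho = 0, model = model, elbo = elbo,
                          converged = TRUE),
    alpha = alpha, snp_id = sprintf("s%d", seq_len(nrow(alpha)))),
    class = "rssnet_fit")
}

test_that("subgrid evidence is the log-mean-exp of the bounds", {
  expect_equal(log_evidence(2.5), 2.5)
  expect_equal(log_evidence(c(7, 7)), 7)
  expect_equal(log_evidence(c(0, log(3))), log(2))  # log((1 + 3)/2)
  expect_error(log_evidence(numeric(0)), class = "rssnet_parameter_error")
})

test_that("Bayes factors compare enrichment subgrids against baseline", {
  # identical evidence under M0 and M1: log10 BF = 0
  f <- fake_fit(elbo = c(5, 5, 5, 5),
                model = c("M0", "M11", "M12", "M13"),
                alpha = matrix(0.5, 2, 4))
  bf <- bayes_factor(f)
  expect_equal(bf$log10_bf, 0)
  expect_equal(bf$log10_bf_m11, 0)

  # hand-computed aggregation
  f2 <- fake_fit(elbo = c(0, log(2), log(6), log(4)),
                 model = c("M0", "M11", "M12", "M13"),
                 alpha = matrix(0.5, 2, 4))
  bf2 <- bayes_factor(f2)
  expect_equal(bf2$log10_bf, log10(4))  # log10(mean(2,6,4)/1)
  expect_equal(bf2$log10_bf_m12, log10(6))
  expect_equal(bf2$best_pattern, "M12")

  # invariant to duplicating a grid point (uniform weights recomputed)
  f3 <- fake_fit(elbo = c(0, log(2), log(2), log(6), log(4)),
                 model = c("M0", "M11", "M11", "M12", "M13"),
                 alpha = matrix(0.5, 2, 5))
  expect_equal(bayes_factor(f3)$log10_bf_m11, bf2$log10_bf_m11)
})

test_that("locus P1 averages grid points by exponentiated bounds", {
  # one SNP, one grid point, alpha 0.9
  f <- fake_fit(elbo = c(1, 2), model = c("M0", "M13"),
                alpha = cbind(0.1, 0.9))
  expect_equal(locus_p1(f, 1L), 0.9)
  expect_equal(locus_p1(f, 1L, models = "M0"), 0.1)
  expect_equal(locus_p1(f, integer(0)), 0)

  # two SNPs, alpha (0.5, 0.5): P1 = 1 - 0.25
  f2 <- fake_fit(elbo = 0, model = "M13",
                 alpha = matrix(c(0.5, 0.5), 2, 1))
  expect_equal(locus_p1(f2, 1:2), 0.75)

  # two equally weighted grid points whose per-point survival products are
  # 0.2 and 0.4: P1 = 1 - (0.2 + 0.4)/2 = 0.7
  f3 <- fake_fit(elbo = c(3, 3), model = c("M13", "M13"),
                 alpha = cbind(0.8, 0.6))
  expect_equal(locus_p1(f3, 1L), 0.7)

  # P1 is monotone: adding a SNP never decreases it
  set.seed(2)
  am <- matrix(runif(12), 6, 2)
  f4 <- fake_fit(elbo = c(0, 1), model = c("M13", "M13"), alpha = am)
  p_small <- locus_p1(f4, 1:3)
  p_big <- locus_p1(f4, 1:4)
  expect_gte(p_big, p_small)
})

test_that("model averaging weights loci by Bayes factor in log space", {
  expect_equal(bma_p1(0.7, log10_bf = 3), 0.7)
  expect_equal(bma_p1(c(0.2, 0.4), log10_bf = c(5, 5)), 0.3)
  # dominance: BF 10^100 vs 1
  expect_equal(bma_p1(c(0.9, 0.1), log10_bf = c(100, 0)), 0.9,
               tolerance = 1e-10)
  # log-space equals the direct formula when BFs are representable
  p1 <- c(0.3, 0.8, 0.5); lbf <- c(2, 8, 5)
  direct <- sum(p1 * 10^lbf) / sum(10^lbf)
  expect_equal(bma_p1(p1, lbf), direct, tolerance = 1e-12)
  expect_error(bma_p1(numeric(0), numeric(0)),
               class = "rssnet_parameter_error")
})

test_that("gene loci are transcribed regions plus 100 kb flanks", {
  genes <- toy_genes()
  snps <- toy_snps()
  loci <- gene_loci(genes, snps, window = 1e5)
  # brute force
  for (g in seq_len(nrow(genes))) {
    want <- which(snps$chrom == genes$chrom[g] &
                    snps$pos >= genes$tx_start[g] - 1e5 &
                    snps$pos <= genes$tx_end[g] + 1e5)
    expect_identical(loci[[genes$gene_id[g]]], want)
  }
})

test_that("end-to-end enrichment separates target network from control", {
  st <- simulate_study(n = 600, p = 800, n_genes = 150, n_chrom = 2,
                       n_tf = 10, n_tg = 60, n_edges = 150, n_re = 30,
                       seed = 21)
  sc <- sim_scenario("M13", theta0 = -2.5, theta = 2.5, eta = 0.4,
                     rho = 0.5, seed = 22)
  eff <- simulate_effects(sc, st$annotation, st$snps, st$geno_var)
  y <- simulate_phenotype(st$X, eff$beta, 0.4, seed = 23)
  ss <- single_snp_stats(st$X, y, st$snps, bandwidth = 20)
  grid <- hyper_grid(theta0 = c(-3, -2.5), theta = c(0, 1.5, 3),
                     eta = c(0.2, 0.4), rho = c(0, 0.5))
  res <- enrich_networks(ss$gwas, ss$ld, st$genes,
                         networks = list(target = st$network),
                         cis = st$cis, grid = grid, seed = 1)
  expect_s3_class(tidy(res), "tbl_df")
  expect_true(is.finite(res$control_log10_bf))
  expect_gt(res$table$log10_bf[1], res$control_log10_bf)

  # the control network itself can never pass its own threshold
  res2 <- enrich_networks(ss$gwas, ss$ld, st$genes,
                          networks = list(ctrl = near_gene_control(st$genes)),
                          cis = st$cis, grid = grid, seed = 1)
  expect_false(res2$table$passes_control[1])

  # gene report: probabilities in [0, 1], boundary-inclusive significance
  rep <- gene_report(res, st$genes, st$snps)
  expect_true(all(rep$p1_bma >= 0 & rep$p1_bma <= 1))
  expect_identical(rep$significant, rep$p1_bma >= 0.9)
  # a gene with no SNPs in its locus has zero probability everywhere
  loci <- gene_loci(st$genes, st$snps)
  empty <- which(lengths(loci) == 0)
  if (length(empty) > 0) {
    expect_equal(rep$p1_bma[empty], rep(0, length(empty)))
  }
  expect_equal(glance(res2)$n_passing, 0L)
})
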