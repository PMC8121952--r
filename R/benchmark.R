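# Packaged benchmark drivers: the simulation studies that validate the
# method end to end. Both the test suite and scripts/acceptance.R call
# these, so the study conditions live in exactly one place.

#' Hyper-parameter grid used by the packaged benchmarks
#'
#' Coarse but covering: background rates around the simulated architecture,
#' enrichment increments up to 3, and enough resolution in (eta, rho) to
#' separate the proximity and edge channels.
#'
#' @return A `hyper_grid` tibble (108 points).
#' @export
benchmark_grid <- function() {
  hyper_grid(theta0 = c(-3.5, -3, -2.5), theta = c(0, 1, 2, 3),
             eta = c(0.2, 0.3, 0.5), rho = c(0, 0.3, 0.6))
}

# Precomputed single-SNP regression engine for a fixed genotype matrix:
# centering and sums of squares are done once, so each dataset's summary
# statistics cost one crossproduct. Produces output identical to
# single_snp_stats() on the same inputs (asserted in the test suite).
scaffold_stats_engine <- function(st, bandwidth = 20, shrink = 0.1) {
  n <- nrow(st$X)
  xc <- st$X - rep(colMeans(st$X), each = n)
  sxx <- colSums(xc^2)
  ld <- ld_matrix(banded_cor(st$X, st$snps$chrom, bandwidth, shrink = shrink),
                  st$snps$snp_id, st$snps$chrom, bandwidth = bandwidth)
  function(y) {
    yc <- y - mean(y)
    betahat <- as.vector(crossprod(xc, yc)) / sxx
    rss <- sum(yc^2) - betahat^2 * sxx
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    gwas <- mutate(st$snps, betahat = betahat, se = se, n = n)
    class(gwas) <- c("rssnet_gwas", class(gwas))
    list(gwas = gwas, ld = ld)
  }
}

# One grid fit of an annotation for an effect vector drawn on the shared
# scaffold; phenotype heritability h2 (pure noise when beta is null).
fit_scaffold <- function(st, engine, beta, h2, grid, seed,
                         annotation = st$annotation) {
  y <- simulate_phenotype(st$X, beta, if (any(beta != 0)) h2 else 0,
                          seed = seed)
  ss <- engine(y)
  fit_grid(ss$gwas, ss$ld, annotation, grid = grid, seed = 1)
}

#' Mis-specification benchmark: network detection under matched negatives
#'
#' Simulates `nrep` positive datasets whose SNP effects follow the
#' enrichment model of a target network (both elevated association rates
#' near the network, theta = 2, and effect sizes through its edges,
#' rho = 0.7), plus `nrep` matched negative datasets for each of four
#' mis-specification families: random near-gene enrichment, random
#' near-RE enrichment, MAF- and LD-dependent effects, and enrichment in an
#' edge-altered copy of the target (rewired per replicate). All datasets
#' share one genotype matrix and LD computation, are conditioned on equal
#' numbers of associated SNPs, and are matched to their positive in
#' explained variance. Each dataset is scored by the target network's
#' log10 Bayes factor; gene-level probabilities of the positives are
#' scored against true labels at P1 >= 0.9.
#'
#' @param seed Integer seed for all randomness.
#' @param nrep Datasets per class (default 20).
#' @param n,p Individuals and SNPs (defaults 3,000 x 5,000).
#' @param h2 Heritability of every non-null dataset (default 0.5).
#' @param grid Hyper-parameter grid (default [benchmark_grid()]).
#' @param contrast Additionally fit each positive and each edge-altered
#'   dataset under the altered network's annotation and record the BF
#'   contrast (target minus altered), the statistic that isolates topology
#'   sensitivity from dataset-level signal variation (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return List with `scores` (tibble: class, rep, log10_bf, and for the
#'   positive and edge-altered classes `log10_bf_contrast`), `auroc`
#'   (tibble: class, auroc, plus an `edge_altered_contrast` row when
#'   `contrast` is on), `fdr` (per positive replicate at P1 >= 0.9),
#'   `m13_mass` (posterior grid mass on theta > 0 and rho > 0 per
#'   positive replicate).
#' @export
benchmark_enrichment <- function(seed, nrep = 20, n = 3000, p = 5000,
                                 h2 = 0.5, grid = benchmark_grid(),
                                 contrast = TRUE, quiet = FALSE) {
  st <- simulate_study(n = n, p = p, seed = seed)
  engine <- scaffold_stats_engine(st)
  ldsc <- ld_scores(engine(rnorm(n))$ld)
  loci <- gene_loci(st$genes, st$snps)
  say <- function(...) if (!quiet) inform(paste0(...))

  classes <- c("positive", "near_gene", "near_re", "maf_ld", "edge_altered")
  scores <- list()
  fdr <- m13 <- numeric(nrep)
  # derived seeds stay well inside 32-bit integer range for any input seed
  base <- (as.integer(seed) %% 1000000L) * 1000L
  for (i in seq_len(nrep)) {
    alt <- rewire_network(st$network, seed = base + 500L + i)
    ann_alt <- annotate_network(st$snps, st$genes, alt, cis = st$cis)
    scp <- sim_scenario("M13", theta0 = -3, theta = 2, eta = h2, rho = 0.7,
                        h2 = h2, seed = base + i)
    ep <- simulate_effects(scp, st$annotation, st$snps, st$geno_var,
                           exact_count = TRUE)
    fp <- fit_scaffold(st, engine, ep$beta, h2, grid, base + 100L + i)
    bf_pos <- bayes_factor(fp)$log10_bf
    lr_pos <- if (contrast) {
      falt <- fit_scaffold(st, engine, ep$beta, h2, grid, base + 100L + i,
                           annotation = ann_alt)
      bf_pos - bayes_factor(falt)$log10_bf
    } else NA_real_
    scores[[length(scores) + 1]] <-
      tibble(class = "positive", rep = i, log10_bf = bf_pos,
             log10_bf_contrast = lr_pos)
    g <- tidy(fp)
    m13[i] <- sum(g$weight[g$theta > 0 & g$rho > 0])
    p1 <- vapply(loci, function(ix) locus_p1(fp, ix), numeric(1))
    lab <- true_gene_labels(st$genes, st$snps, ep$beta)$label
    fdr[i] <- fpr_fdr_eval(p1, lab)$fdr

    negs <- list(
      near_gene = simulate_effects(
        sim_scenario("near_gene_random", theta0 = -3, theta = 2.5,
                     eta = h2, rho = 0.7, seed = base + 200L + i),
        snps = st$snps, geno_var = st$geno_var,
        eligible = st$a_gene == 1, exact_count = TRUE),
      near_re = simulate_effects(
        sim_scenario("near_re_random", theta0 = -3, theta = 3, eta = h2,
                     rho = 0.7, enrich_fraction = 0.5,
                     seed = base + 300L + i),
        snps = st$snps, geno_var = st$geno_var,
        eligible = st$a_re == 1, exact_count = TRUE),
      maf_ld = simulate_effects(
        sim_scenario("maf_ld_dependent", theta0 = -2.5, theta = 2,
                     eta = h2, seed = base + 400L + i),
        snps = st$snps, geno_var = st$geno_var,
        ld_scores = ldsc, maf = st$maf, exact_count = TRUE),
      edge_altered = simulate_effects(
        sim_scenario("edge_altered", theta0 = -3, theta = 2, eta = h2,
                     rho = 0.7, seed = base + 600L + i),
        ann_alt, st$snps, st$geno_var, exact_count = TRUE)
    )
    for (cls in names(negs)) {
      bneg <- match_signal(ep$beta, negs[[cls]]$beta, st$X,
                           seed = base + 700L + i)
      fneg <- fit_scaffold(st, engine, bneg, h2, grid, base + 800L + i)
      bf_neg <- bayes_factor(fneg)$log10_bf
      lr_neg <- if (contrast && cls == "edge_altered") {
        falt <- fit_scaffold(st, engine, bneg, h2, grid, base + 800L + i,
                             annotation = ann_alt)
        bf_neg - bayes_factor(falt)$log10_bf
      } else NA_real_
      scores[[length(scores) + 1]] <-
        tibble(class = cls, rep = i, log10_bf = bf_neg,
               log10_bf_contrast = lr_neg)
    }
    say("replicate ", i, "/", nrep, " done")
  }
  scores <- bind_rows(scores)
  pos <- scores$log10_bf[scores$class == "positive"]
  auroc <- bind_rows(lapply(setdiff(classes, "positive"), function(cls) {
    neg <- scores$log10_bf[scores$class == cls]
    tibble(class = cls,
           auroc = roc_prc_eval(c(pos, neg),
                                rep(1:0, c(length(pos), length(neg))))$auroc)
  }))
  if (contrast) {
    lp <- scores$log10_bf_contrast[scores$class == "positive"]
    ln <- scores$log10_bf_contrast[scores$class == "edge_altered"]
    auroc <- bind_rows(auroc, tibble(
      class = "edge_altered_contrast",
      auroc = roc_prc_eval(c(lp, ln), rep(1:0, c(length(lp),
                                                 length(ln))))$auroc))
  }
  list(scores = scores, auroc = auroc, fdr = fdr, m13_mass = m13)
}

#' Recovery and null-calibration benchmark
#'
#' Simulates `nrep` datasets from the enrichment model at the reference
#' condition (theta0 = -3, theta = 2, eta = 0.3, rho = 0.5, h2 = 0.3) and
#' `nrep` baseline datasets (theta = 0, rho = 0) on a shared scaffold of
#' 5,000 individuals by 5,000 SNPs, fits the grid, and reports the
#' posterior grid mass on enriched hyper-parameters (theta > 0 and
#' rho > 0) for the former and the target-network log10 Bayes factors for
#' the latter.
#'
#' @param seed Integer seed.
#' @param nrep Replicates per condition (default 20).
#' @param n,p Scaffold size (defaults 5,000 x 5,000).
#' @param grid Hyper-parameter grid.
#' @param quiet Suppress progress messages.
#' @return List with `m1_mass` (per enriched replicate), `null_log10_bf`
#'   (per baseline replicate).
#' @export
benchmark_recovery <- function(seed, nrep = 20, n = 5000, p = 5000,
                               grid = benchmark_grid(), quiet = FALSE) {
  st <- simulate_study(n = n, p = p, seed = seed + 1L)
  engine <- scaffold_stats_engine(st)
  say <- function(...) if (!quiet) inform(paste0(...))
  base <- (as.integer(seed) %% 1000000L) * 1000L
  m1_mass <- null_bf <- numeric(nrep)
  for (i in seq_len(nrep)) {
    sc <- sim_scenario("M13", theta0 = -3, theta = 2, eta = 0.3, rho = 0.5,
                       h2 = 0.3, seed = base + i)
    eff <- simulate_effects(sc, st$annotation, st$snps, st$geno_var)
    fit <- fit_scaffold(st, engine, eff$beta, 0.3, grid, base + 100L + i)
    g <- tidy(fit)
    m1_mass[i] <- sum(g$weight[g$theta > 0 & g$rho > 0])

    s0 <- sim_scenario("M0", theta0 = -3, eta = 0.3, h2 = 0.3,
                       seed = base + 200L + i)
    e0 <- simulate_effects(s0, st$annotation, st$snps, st$geno_var)
    f0 <- fit_scaffold(st, engine, e0$beta, 0.3, grid, base + 300L + i)
    null_bf[i] <- bayes_factor(f0)$log10_bf
    say("replicate ", i, "/", nrep, " done")
  }
  list(m1_mass = m1_mass, null_log10_bf = null_bf)
}

#' Small-instance oracle comparison
#'
#' Draws random instances with p <= 10 SNPs, runs the coordinate ascent,
#' and compares against the exact enumeration posterior: the evidence
#' lower bound must never exceed the exact log evidence, and under
#' identity LD the variational posterior must match the exact factorized
#' posterior.
#'
#' @param seed Integer seed.
#' @param n_instances Number of random instances (default 100).
#' @return Tibble: per instance, `p`, `gap` (exact log evidence minus
#'   ELBO), `identity_alpha_err`, `identity_nu_err`, `identity_tau_err`
#'   (maximum absolute errors under identity LD).
#' @export
benchmark_oracle <- function(seed, n_instances = 100) {
  out <- vector("list", n_instances)
  for (k in seq_len(n_instances)) {
    out[[k]] <- with_seed(seed + k, {
      p <- sample(3:10, 1)
      A <- matrix(rnorm(p * p), p)
      R <- stats::cov2cor(crossprod(A) + diag(p))
      betahat <- rnorm(p)
      se <- runif(p, 0.5, 1.5)
      pi <- runif(p, 0.05, 0.6)
      s2 <- runif(p, 0.1, 2)
      ld <- ld_matrix(R, sprintf("s%d", 1:p), rep("1", p), bandwidth = p - 1L)
      fit <- coordinate_ascent(betahat, se, ld, pi, s2, seed = seed + k)
      oracle <- exact_posterior_oracle(betahat, se, R, pi, s2)
      ldI <- ld_identity(sprintf("s%d", 1:p))
      fitI <- coordinate_ascent(betahat, se, ldI, pi, s2, seed = seed + k)
      oI <- exact_posterior_oracle(betahat, se, diag(p), pi, s2)
      tau2 <- se^2 * s2 / (se^2 + s2)
      tibble(p = p,
             gap = oracle$log_evidence - fit$elbo,
             identity_alpha_err = max(abs(fitI$alpha - oI$alpha)),
             identity_nu_err = max(abs(fitI$nu - tau2 * betahat / se^2)),
             identity_tau_err = max(abs(fitI$tau - sqrt(tau2))))
    })
  }
  bind_rows(out)
}
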