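# Synthetic-data generation: gene catalogs, networks, block-LD genotypes,
# network-induced and mis-specified SNP effects, phenotypes, and the
# single-SNP association statistics computed from them.

#' Simulation scenario description
#'
#' Bundles the settings of one simulated dataset: the effect model
#' (baseline `M0`; enrichment patterns `M11`, `M12`, `M13`; mis-specified
#' `near_gene_random`, `near_re_random`, `maf_ld_dependent`; and
#' `edge_altered` / `noisy_network`, which follow the `M13` effect model
#' under an altered or degraded network annotation), the hyper-parameters,
#' the heritability, and the mandatory seed.
#'
#' @param effect_model One of the labels above.
#' @param theta0 Background log10-odds of association. The default -3
#'   gives a sparse architecture (about 1 associated SNP per 1,000); -2
#'   gives a polygenic one.
#' @param theta Enrichment increment (log10-odds) for flagged SNPs.
#' @param eta Proportion of phenotypic variance explained by all SNPs.
#' @param rho Share of genetic variance through network weights.
#' @param h2 Trait heritability in \[0, 1).
#' @param enrich_fraction For the random near-gene / near-RE scenarios: the
#'   fraction of eligible SNPs receiving elevated association rates and
#'   effect sizes.
#' @param seed Integer seed (mandatory).
#' @return A list with class `sim_scenario`.
#' @export
sim_scenario <- function(effect_model = c("M0", "M11", "M12", "M13",
                                          "near_gene_random",
                                          "near_re_random",
                                          "maf_ld_dependent",
                                          "edge_altered", "noisy_network"),
                         theta0 = -3, theta = 2, eta = 0.3, rho = 0.5,
                         h2 = 0.3, enrich_fraction = 0.33, seed) {
  effect_model <- match.arg(effect_model)
  if (missing(seed) || is.null(seed)) {
    abort("A seed is mandatory for simulation scenarios.",
          class = "rssnet_parameter_error")
  }
  structure(list(effect_model = effect_model, theta0 = theta0,
                 theta = theta, eta = eta, rho = rho, h2 = h2,
                 enrich_fraction = enrich_fraction, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Synthetic gene catalog
#'
#' Tiles genes along synthetic chromosomes with random lengths and
#' intergenic gaps sized so that the 100 kb proximity and 1 Mb cis windows
#' are both exercised (some SNPs near several genes, some near none). A
#' random subset of genes is flagged as transcription factors.
#'
#' @param n_genes Total genes (default 1,000 over `n_chrom` chromosomes).
#' @param n_chrom Number of chromosomes (default 5).
#' @param tf_fraction Fraction of genes flagged as TFs.
#' @param gene_length_range,gap_range Ranges (bp) for gene lengths and
#'   intergenic gaps.
#' @param seed Integer seed.
#' @return A gene catalog tibble (`rssnet_genes`).
#' @export
simulate_gene_catalog <- function(n_genes = 1000, n_chrom = 5,
                                  tf_fraction = 0.1,
                                  gene_length_range = c(5e3, 5e4),
                                  gap_range = c(5e4, 3e5), seed = 1) {
  with_seed(seed, {
    per <- rep(n_genes %/% n_chrom, n_chrom)
    per[seq_len(n_genes %% n_chrom)] <- per[seq_len(n_genes %% n_chrom)] + 1L
    rows <- vector("list", n_chrom)
    for (ch in seq_len(n_chrom)) {
      m <- per[ch]
      len <- round(runif(m, gene_length_range[1], gene_length_range[2]))
      gap <- round(runif(m, gap_range[1], gap_range[2]))
      start <- cumsum(gap) + cumsum(c(0, head(len, -1)))
      rows[[ch]] <- tibble(
        gene_id = sprintf("g%d_%03d", ch, seq_len(m)),
        chrom = as.character(ch),
        tx_start = as.integer(start),
        tx_end = as.integer(start + len)
      )
    }
    genes <- bind_rows(rows)
    genes$is_tf <- FALSE
    genes$is_tf[sample.int(n_genes, round(tf_fraction * n_genes))] <- TRUE
    validate_gene_catalog(genes)
  })
}

#' Synthetic SNP table
#'
#' Places SNPs uniformly at random along the chromosomes spanned by a gene
#' catalog (with a margin beyond the last gene), sorted by position.
#'
#' @param genes Gene catalog defining chromosomes and their extents.
#' @param p Number of SNPs.
#' @param margin Extra sequence beyond the outermost genes (bp).
#' @param seed Integer seed.
#' @return Tibble `snp_id`, `chrom`, `pos`, `a1`, `a2`.
#' @export
simulate_snp_table <- function(genes, p = 5000, margin = 2e5, seed = 1) {
  with_seed(seed, {
    chroms <- unique(genes$chrom)
    len <- vapply(chroms, function(ch) {
      max(genes$tx_end[genes$chrom == ch]) + margin
    }, numeric(1))
    per <- as.integer(round(p * len / sum(len)))
    per[1] <- per[1] + (p - sum(per))
    rows <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
      pos <- sort(sample.int(len[i], per[i]))
      rows[[i]] <- tibble(chrom = chroms[i], pos = pos)
    }
    snps <- bind_rows(rows)
    snps <- arrange(snps, .data$chrom, .data$pos)
    mutate(snps,
           snp_id = sprintf("rs%06d", row_number()),
           a1 = "A", a2 = "G", .before = 1)
  })
}

#' Synthetic TF-TG regulatory network
#'
#' Samples a bipartite network over a gene catalog: TFs are drawn from the
#' catalog's TF-flagged genes and target genes from the remainder. Two
#' features of real inferred regulatory networks are reproduced because the
#' topology benchmarks depend on them: regulatory fan-out is concentrated
#' in hub TFs (edge propensity proportional to 1/rank^hub_exponent across
#' TFs, giving a skewed out-degree distribution), and edge weights are
#' heavy-tailed on (0, 1] (most edges weak, a few strong), as produced by
#' log-scale normalization of trans-regulation scores.
#'
#' @param genes Gene catalog.
#' @param n_tf,n_tg Node counts (defaults scale the published networks'
#'   TF:TG:gene proportions down to a 1,000-gene catalog).
#' @param n_edges Edge count.
#' @param hub_exponent Skew of the out-degree distribution (0 = uniform).
#' @param seed Integer seed.
#' @return A `regulatory_network`.
#' @export
simulate_network <- function(genes, n_tf = 30, n_tg = 300, n_edges = 900,
                             hub_exponent = 1, seed = 1) {
  with_seed(seed, {
    tf_pool <- genes$gene_id[genes$is_tf]
    tg_pool <- genes$gene_id[!genes$is_tf]
    tf <- sample(tf_pool, min(n_tf, length(tf_pool)))
    tg <- sample(tg_pool, min(n_tg, length(tg_pool)))
    pairs <- tidyr::expand_grid(tf_id = tf, tg_id = tg)
    prop <- seq_along(tf)^(-hub_exponent)
    pick <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)),
                       prob = prop[match(pairs$tf_id, tf)])
    edges <- pairs[pick, ]
    edges$weight <- pmax(runif(nrow(edges))^3, 1e-4)
    regulatory_network(edges = edges, tf = tf, tg = tg)
  })
}

#' Synthetic regulatory-element intervals
#'
#' Scatters fixed-width regulatory elements across the catalog's
#' chromosomes, used for the near-RE proximity flag and the near-RE random
#' enrichment scenario.
#'
#' @param genes Gene catalog (defines chromosome extents).
#' @param n_re Number of REs.
#' @param width RE width in bp.
#' @param seed Integer seed.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
simulate_regulatory_elements <- function(genes, n_re = 200, width = 1000,
                                         seed = 1) {
  with_seed(seed, {
    chroms <- unique(genes$chrom)
    len <- vapply(chroms, function(ch) {
      max(genes$tx_end[genes$chrom == ch])
    }, numeric(1))
    ch <- sample(chroms, n_re, replace = TRUE, prob = len / sum(len))
    start <- vapply(ch, function(c) sample.int(len[match(c, chroms)], 1L),
                    numeric(1))
    arrange(tibble(chrom = ch, start = as.integer(start),
                   end = as.integer(start + width)), .data$chrom, .data$start)
  })
}

#' Simulate genotypes with block-wise LD
#'
#' Haplotypes are generated from a latent Gaussian with AR(1) correlation
#' within consecutive blocks of SNPs (independent across blocks and
#' chromosomes) and thresholded at each SNP's target minor-allele
#' frequency, drawn uniformly from `maf_range`; a genotype is the sum of
#' two independent haplotypes, giving allele counts 0/1/2. Thresholding
#' attenuates the latent correlation, so the realized allele-level LD is
#' somewhat below `within_block_ld`.
#'
#' @param n Individuals.
#' @param snps SNP tibble (`chrom` defines block boundaries).
#' @param block_size SNPs per LD block (default 20).
#' @param within_block_ld Latent AR(1) correlation in \[0, 1).
#' @param maf_range Range of target minor-allele frequencies.
#' @param seed Integer seed.
#' @return Integer matrix n x p with attribute `maf` (target MAFs).
#' @export
simulate_genotypes <- function(n, snps, block_size = 20,
                               within_block_ld = 0.8,
                               maf_range = c(0.01, 0.5), seed = 1) {
  p <- nrow(snps)
  with_seed(seed, {
    maf <- runif(p, maf_range[1], maf_range[2])
    thr <- qnorm(maf)
    phi <- within_block_ld
    # block id: consecutive runs within chromosome
    block <- integer(p)
    b <- 0L
    for (ch in unique(snps$chrom)) {
      idx <- which(snps$chrom == ch)
      block[idx] <- b + ((seq_along(idx) - 1L) %/% block_size) + 1L
      b <- max(block[idx])
    }
    # Cholesky factors of the AR(1) latent correlation, one per block size
    chol_for <- new.env()
    ar1_chol <- function(m) {
      key <- as.character(m)
      if (is.null(chol_for[[key]])) {
        chol_for[[key]] <- chol(phi^abs(outer(seq_len(m), seq_len(m), "-")))
      }
      chol_for[[key]]
    }
    X <- matrix(0L, n, p)
    for (hap in 1:2) {
      for (bl in split(seq_len(p), block)) {
        m <- length(bl)
        Z <- if (phi == 0 || m == 1) {
          matrix(rnorm(n * m), n, m)
        } else {
          matrix(rnorm(n * m), n, m) %*% ar1_chol(m)
        }
        X[, bl] <- X[, bl] + (Z < rep(thr[bl], each = n))
      }
    }
    attr(X, "maf") <- maf
    X
  })
}

#' Simulate SNP effects under a scenario
#'
#' Draws the true effect vector beta for one dataset. Under `M0` and the
#' enrichment patterns (`M11`, `M12`, `M13`, and their aliases
#' `edge_altered` / `noisy_network`, which differ only in the annotation
#' supplied), each SNP is associated with probability
#' \eqn{\pi_j = 1/[1+10^{-(\theta_0 + a_j\theta)}]} and an associated SNP's
#' effect is normal with variance \eqn{\sigma_0^2 + \sigma^2 s2sum_j}. The
#' variance components are mapped from (eta, rho) exactly as in model
#' fitting, with n * se^2 replaced by its population analogue (the inverse
#' genotype variance on a unit-variance trait). `near_gene_random` and
#' `near_re_random` elevate both association rate and effect variance for
#' a random subset of eligible SNPs (a mis-specified pseudo-annotation);
#' `maf_ld_dependent` assigns per-SNP variance additively over 10 MAF bins
#' and 6 LD-score annotations, with association log-odds increasing in the
#' same score.
#'
#' @param scenario A [sim_scenario()].
#' @param annotation `network_annotation` of the effect-generating network
#'   (for `edge_altered`/`noisy_network`, of the altered network).
#' @param snps SNP tibble.
#' @param geno_var Per-SNP genotype variances (empirical column variances
#'   or 2 maf (1-maf)).
#' @param eligible For the random-enrichment scenarios: logical vector of
#'   eligible SNPs (near-gene or near-RE flags).
#' @param ld_scores For `maf_ld_dependent`: per-SNP LD scores (sum of r^2
#'   within the band); computed from an `ld_matrix` via [ld_scores()].
#' @param maf For `maf_ld_dependent`: per-SNP minor-allele frequencies.
#' @param maf_coef,ld_coef Optional bin coefficient vectors (lengths 10 and
#'   6); defaults decrease in MAF bin and increase in LD score.
#' @param exact_count If `TRUE`, condition on the expected number of
#'   associated SNPs: exactly `round(sum(pi))` SNPs are drawn causal, by
#'   weighted sampling without replacement with weights `pi`. This is the
#'   matched-signal design used by the benchmarks, where datasets are
#'   compared at equal numbers of trait-associated SNPs; the default
#'   (`FALSE`) draws independent Bernoulli indicators.
#' @return List: `beta`, `pi`, `var_j`, `causal` (logical).
#' @export
simulate_effects <- function(scenario, annotation = NULL, snps,
                             geno_var, eligible = NULL, ld_scores = NULL,
                             maf = NULL, maf_coef = NULL, ld_coef = NULL,
                             exact_count = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  p <- nrow(snps)
  model <- scenario$effect_model
  with_seed(scenario$seed, {
    if (model %in% c("M0", "M11", "M12", "M13", "edge_altered",
                     "noisy_network")) {
      if (is.null(annotation)) {
        abort("Model-based scenarios need a network annotation.",
              class = "rssnet_parameter_error")
      }
      ann <- left_join(tibble(snp_id = snps$snp_id), annotation$snp,
                       by = "snp_id")
      a <- ann$a
      s2sum <- ann$s2sum
      th <- switch(model, M0 = 0, M12 = 0, scenario$theta)
      rh <- switch(model, M0 = 0, M11 = 0, scenario$rho)
      pi <- log10odds_to_prob(scenario$theta0 + a * th)
      vs <- map_hyperparams(scenario$eta, rh, pi,
                            shat = sqrt(1 / geno_var), n = 1,
                            s2sum = s2sum)
      var_j <- vs$sigma0_sq + vs$sigma_sq * s2sum
    } else if (model %in% c("near_gene_random", "near_re_random")) {
      if (is.null(eligible)) {
        abort("Random-enrichment scenarios need the eligible SNP flags.",
              class = "rssnet_parameter_error")
      }
      sel <- rep(FALSE, p)
      elig_idx <- which(eligible)
      pick <- sample(elig_idx,
                     max(1L, round(scenario$enrich_fraction *
                                     length(elig_idx))))
      sel[pick] <- TRUE
      a <- as.integer(sel)
      pi <- log10odds_to_prob(scenario$theta0 + a * scenario$theta)
      vs <- map_hyperparams(scenario$eta, scenario$rho, pi,
                            shat = sqrt(1 / geno_var), n = 1, s2sum = a)
      var_j <- vs$sigma0_sq + vs$sigma_sq * a
    } else if (model == "maf_ld_dependent") {
      if (is.null(ld_scores) || is.null(maf)) {
        abort("maf_ld_dependent needs `maf` and `ld_scores`.",
              class = "rssnet_parameter_error")
      }
      maf_coef <- maf_coef %||% seq(1.0, 0.1, length.out = 10)
      ld_coef <- ld_coef %||% seq(0.2, 1.2, length.out = 6)
      mb <- cut_quantile_bins(maf, 10)
      lb <- cut_quantile_bins(ld_scores, 6)
      raw <- maf_coef[mb] + ld_coef[lb]
      score <- (raw - min(raw)) / max(raw - min(raw) + 1e-12)
      pi <- log10odds_to_prob(scenario$theta0 + scenario$theta * score)
      # normalize so the expected genetic variance on a unit trait is eta
      scale <- scenario$eta / sum(pi * raw * geno_var)
      var_j <- raw * scale
    } else {
      abort(sprintf("Unknown scenario label '%s'.", model),
            class = "rssnet_parameter_error")
    }
    if (exact_count) {
      m <- max(1L, round(sum(pi)))
      causal <- rep(FALSE, p)
      causal[sample.int(p, m, prob = pi)] <- TRUE
    } else {
      causal <- runif(p) < pi
    }
    beta <- numeric(p)
    beta[causal] <- rnorm(sum(causal), 0, sqrt(var_j[causal]))
    list(beta = beta, pi = pi, var_j = var_j, causal = causal)
  })
}

cut_quantile_bins <- function(x, k) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE,
                 labels = FALSE)) |>
    pmin(k) |> pmax(1L)
}

#' Per-SNP LD scores
#'
#' Sum of squared within-band correlations per SNP (including the SNP
#' itself), the synthetic analogue of LD scores used in the MAF/LD-dependent
#' mis-specification scenario.
#'
#' @param ld An `ld_matrix`.
#' @return Numeric vector of LD scores.
#' @export
ld_scores <- function(ld) {
  R2 <- ld$R
  R2@x <- R2@x^2
  as.vector(R2 %*% rep(1, length(ld$snp_id)))
}

#' Match a negative dataset's signal to a positive one
#'
#' Thins the negative effect vector (seeded subsample of its associated
#' SNPs) so both datasets have exactly equal numbers of trait-associated
#' SNPs, then rescales it so both explain the same genetic variance
#' Var(X beta) (a single multiplicative rescaling, exact up to floating
#' point).
#'
#' @param beta_pos,beta_neg Effect vectors with at least one non-zero
#'   entry each; the negative must have at least as many associated SNPs
#'   as the positive.
#' @param X Genotype matrix used to measure explained variance.
#' @param seed Integer seed for the thinning subsample.
#' @return The matched negative effect vector.
#' @export
match_signal <- function(beta_pos, beta_neg, X, seed = 1) {
  n_pos <- sum(beta_pos != 0)
  n_neg <- sum(beta_neg != 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Cannot match: a dataset has no associated SNPs.",
          class = "rssnet_parameter_error")
  }
  if (n_neg < n_pos) {
    abort("Cannot match: negative dataset has fewer associated SNPs.",
          class = "rssnet_parameter_error")
  }
  out <- beta_neg
  if (n_neg > n_pos) {
    nz <- which(beta_neg != 0)
    drop <- with_seed(seed, sample(nz, n_neg - n_pos))
    out[drop] <- 0
  }
  v_pos <- var(as.vector(X %*% beta_pos))
  v_neg <- var(as.vector(X %*% out))
  if (v_neg == 0) {
    abort("Cannot match: negative dataset explains no variance.",
          class = "rssnet_parameter_error")
  }
  out * sqrt(v_pos / v_neg)
}

#' Simulate a phenotype at exact heritability
#'
#' y = X beta + eps under the additive multiple-SNP model. The Gaussian
#' noise is orthogonalized against the genetic value and rescaled so the
#' realized sample proportion of variance explained equals `h2` exactly.
#'
#' @param X Genotype matrix.
#' @param beta True effect vector.
#' @param h2 Heritability in \[0, 1); must be 0 when beta explains no
#'   variance.
#' @param seed Integer seed.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(X, beta, h2, seed = 1) {
  if (h2 < 0 || h2 >= 1) {
    abort("`h2` must lie in [0, 1).", class = "rssnet_parameter_error")
  }
  g <- as.vector(X %*% beta)
  vg <- var(g)
  if (vg == 0 && h2 > 0) {
    abort("Null effects cannot produce positive heritability.",
          class = "rssnet_parameter_error")
  }
  with_seed(seed, {
    n <- nrow(X)
    eps <- rnorm(n)
    if (vg == 0) return(eps)
    # remove the sample projection on g, then scale to the exact noise
    # variance implied by h2
    gc <- g - mean(g)
    eps <- eps - mean(eps) - gc * sum((eps - mean(eps)) * gc) / sum(gc^2)
    eps <- eps * sqrt(vg * (1 - h2) / h2 / var(eps))
    g + eps
  })
}

#' Single-SNP association statistics and banded LD
#'
#' The standard GWAS computation on an individual-level dataset: per SNP,
#' the least-squares slope of the centered phenotype on the centered
#' genotype, its standard error on n - 2 degrees of freedom, and the
#' banded sample correlation of the genotypes (zero across chromosomes).
#' Monomorphic SNPs are dropped with a warning.
#'
#' @param X Genotype matrix (n x p).
#' @param y Phenotype vector.
#' @param snps SNP tibble aligned with the columns of `X`.
#' @param bandwidth LD band to retain (default 20; at least the simulator's
#'   block size so the band captures the true LD structure).
#' @param shrink Shrinkage factor applied to off-diagonal LD entries
#'   (default 0.1), the usual regularization of banded reference-panel
#'   estimates; guarantees a positive-definite matrix when p exceeds n.
#' @param ld Optional precomputed `ld_matrix` for these genotypes. Since LD
#'   depends only on the genotype matrix, batches of datasets simulated on
#'   shared genotypes can reuse one LD computation.
#' @return List with `gwas` (tibble `snp_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `betahat`, `se`, `n`, class `rssnet_gwas`) and `ld` (an `ld_matrix`).
#' @export
single_snp_stats <- function(X, y, snps, bandwidth = 20, shrink = 0.1,
                             ld = NULL) {
  n <- nrow(X)
  if (n < 3) {
    abort("Need at least 3 individuals.", class = "rssnet_parameter_error")
  }
  xc <- X - rep(colMeans(X), each = n)
  mono <- colSums(xc^2) == 0
  if (any(mono)) {
    warn(sprintf("Dropped %d monomorphic SNP(s).", sum(mono)))
    X <- X[, !mono, drop = FALSE]
    xc <- xc[, !mono, drop = FALSE]
    snps <- snps[!mono, , drop = FALSE]
  }
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  betahat <- sxy / sxx
  rss <- sum(yc^2) - betahat^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  gwas <- mutate(snps, betahat = betahat, se = se, n = n)
  class(gwas) <- c("rssnet_gwas", class(gwas))
  if (is.null(ld)) {
    R <- banded_cor(X, snps$chrom, bandwidth, shrink = shrink)
    ld <- ld_matrix(R, snps$snp_id, snps$chrom, bandwidth = bandwidth)
  }
  list(gwas = gwas, ld = ld)
}

#' Distance-decaying SNP-gene cis weights
#'
#' Emulates eQTL-derived SNP-gene relevance: within the cis window, the
#' weight decays exponentially with the distance between the SNP and the
#' gene's transcribed region, c = exp(-d / scale), with c = 1 for SNPs
#' inside the gene body. Concentrating cis impact near genes (rather than
#' flat weights across the whole 1 Mb window) matches the behaviour of real
#' eQTL effect profiles and lets regulatory topology, not window overlap,
#' carry the trans signal.
#'
#' @param snps SNP tibble.
#' @param genes Gene catalog.
#' @param scale Decay length in bp (default 50 kb).
#' @param window Cis window (default 1 Mb).
#' @return Tibble (`snp_id`, `gene_id`, `c`).
#' @export
simulate_cis_weights <- function(snps, genes, scale = 5e4, window = 1e6) {
  pairs <- build_cis_window(snps, genes, window)
  pos <- snps$pos[match(pairs$snp_id, snps$snp_id)]
  i <- match(pairs$gene_id, genes$gene_id)
  d <- pmax(0, pmax(genes$tx_start[i] - pos, pos - genes$tx_end[i]))
  mutate(pairs, c = exp(-d / scale))
}

#' True trait-associated gene labels
#'
#' A gene is labelled trait-associated if at least one SNP with a non-zero
#' true effect lies within `window` (default 100 kb) of its transcribed
#' region.
#'
#' @param genes Gene catalog.
#' @param snps SNP tibble.
#' @param beta True effect vector aligned with `snps`.
#' @param window Flank in bp.
#' @return Tibble `gene_id`, `label` (0/1).
#' @export
true_gene_labels <- function(genes, snps, beta, window = 1e5) {
  loci <- gene_loci(genes, snps, window)
  tibble(gene_id = genes$gene_id,
         label = vapply(loci, function(ix) as.integer(any(beta[ix] != 0)),
                        integer(1), USE.NAMES = FALSE))
}

#' Generate a complete synthetic study scaffold
#'
#' Builds the fixed ingredients shared by a batch of simulated datasets:
#' gene catalog, SNP table, target network, regulatory elements, genotype
#' matrix, banded LD and annotations (target network and near-gene
#' control). Individual datasets then draw effects and phenotypes per
#' scenario on top of this scaffold.
#'
#' @param n,p Individuals and SNPs.
#' @param n_genes,n_chrom Catalog size.
#' @param n_tf,n_tg,n_edges Network size.
#' @param hub_exponent Out-degree skew passed to [simulate_network()].
#' @param n_re Regulatory-element count.
#' @param block_size,within_block_ld,maf_range Genotype LD structure.
#' @param bandwidth LD band (defaults to `block_size`).
#' @param cis_decay_scale Decay length for the synthetic cis weights
#'   (default 50 kb); `NULL` for flat weights of 1 across the cis window.
#' @param seed Integer seed.
#' @return List with elements `genes`, `snps`, `network`, `res`, `X`,
#'   `geno_var`, `cis`, `annotation` (target), `annotation_control`,
#'   `a_gene` (any-gene 100 kb flag), `a_re` (any-RE flag), `maf`.
#' @export
simulate_study <- function(n = 2500, p = 5000, n_genes = 1000, n_chrom = 5,
                           n_tf = 30, n_tg = 300, n_edges = 900, n_re = 400,
                           hub_exponent = 1.5,
                           block_size = 20, within_block_ld = 0.8,
                           maf_range = c(0.01, 0.5), bandwidth = block_size,
                           cis_decay_scale = 5e4, seed = 1) {
  genes <- simulate_gene_catalog(n_genes = n_genes, n_chrom = n_chrom,
                                 seed = seed)
  snps <- simulate_snp_table(genes, p = p, seed = seed + 1L)
  network <- simulate_network(genes, n_tf = n_tf, n_tg = n_tg,
                              n_edges = n_edges, hub_exponent = hub_exponent,
                              seed = seed + 2L)
  res <- simulate_regulatory_elements(genes, n_re = n_re, seed = seed + 3L)
  X <- simulate_genotypes(n, snps, block_size = block_size,
                          within_block_ld = within_block_ld,
                          maf_range = maf_range, seed = seed + 4L)
  cis <- if (is.null(cis_decay_scale)) {
    flat_cis_weights(build_cis_window(snps, genes))
  } else {
    simulate_cis_weights(snps, genes, scale = cis_decay_scale)
  }
  annotation <- annotate_network(snps, genes, network, cis = cis)
  control <- near_gene_control(genes)
  annotation_control <- annotate_network(snps, genes, control, cis = cis)
  xc <- X - rep(colMeans(X), each = n)
  list(genes = genes, snps = snps, network = network, res = res, X = X,
       geno_var = colSums(xc^2) / (n - 1), cis = cis,
       annotation = annotation, annotation_control = annotation_control,
       a_gene = annotation_control$snp$a,
       a_re = build_proximity_flag(snps, regulatory_network(), genes,
                                   res = res),
       maf = attr(X, "maf"))
  }
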