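# Shared fixtures, all generated in code.

# Tiny deterministic gene catalog on two chromosomes (1-based inclusive).
toy_genes <- function() {
  validate_gene_catalog(tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chrom = c("1", "1", "1", "2", "2"),
    tx_start = c(1000L, 500000L, 2000000L, 10000L, 3000000L),
    tx_end = c(11000L, 520000L, 2040000L, 30000L, 3020000L),
    is_tf = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  ))
}

toy_snps <- function() {
  tibble::tibble(
    snp_id = sprintf("s%02d", 1:10),
    chrom = c(rep("1", 6), rep("2", 4)),
    pos = c(5000L, 120000L, 505000L, 1500000L, 2039000L, 3200000L,
            15000L, 140000L, 2999000L, 4500000L),
    a1 = "A", a2 = "G"
  )
}

toy_network <- function() {
  regulatory_network(edges = tibble::tibble(
    tf_id = c("gA", "gA", "gD"),
    tg_id = c("gC", "gE", "gB"),
    weight = c(0.5, 0.25, 1)
  ))
}

# Random dense correlation matrix (positive definite, unit diagonal).
random_corr <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(A) + diag(p))
}

# Random small VB problem instance.
random_instance <- function(p, seed = 1) {
  set.seed(seed)
  list(R = random_corr(p, seed),
       betahat = rnorm(p),
       se = runif(p, 0.5, 1.5),
       pi = runif(p, 0.05, 0.6),
       sigma_j_sq = runif(p, 0.1, 2))
}

dense_ld <- function(R, chrom = NULL) {
  p <- nrow(R)
  ld_matrix(R, sprintf("s%03d", seq_len(p)),
            chrom %||% rep("1", p), bandwidth = p - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard bivariate normal CDF P(Z1 < a, Z2 < b) with correlation rho,
# by one-dimensional quadrature (independent oracle for the genotype
# simulator's threshold model).
pbivariate_normal <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a) * pnorm(b))
  f <- function(z) dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# Correlation of two threshold indicators 1{Z < qnorm(m)} under latent
# correlation rho (equal margins m); genotype correlation equals this.
implied_threshold_corr <- function(m, rho) {
  q <- qnorm(m)
  p11 <- pbivariate_normal(q, q, rho)
  (p11 - m^2) / (m * (1 - m))
}
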