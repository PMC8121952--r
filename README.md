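# rssnet

Bayesian integration of GWAS summary statistics with cell-type- and
tissue-specific TF→TG regulatory networks, for researchers who want to
know **which** regulatory network a trait's genetic signal concentrates in
and **which genes** inside that network drive it — using only published
single-SNP association statistics and a public LD reference panel, no
individual-level data.

## The model in brief

The total effect of SNP *j* is decomposed through genes: a cis part via
genes within 1 Mb and a trans part via the target genes of any TF in that
window, with combined SNP–gene weight

&nbsp;&nbsp;*w<sub>jt</sub>* = *c<sub>jt</sub>*·[t cis] + Σ<sub>g∈cis∩TF</sub> *c<sub>jg</sub>* *v<sub>gt</sub>*.

This induces a spike-and-slab prior per SNP,

&nbsp;&nbsp;β*<sub>j</sub>* ~ π*<sub>j</sub>* N(0, σ₀² + σ² Σ<sub>g</sub> *w²<sub>jg</sub>*) + (1−π*<sub>j</sub>*) δ₀,
&nbsp;&nbsp;log₁₀ odds(π*<sub>j</sub>*) = θ₀ + *a<sub>j</sub>* θ,

where *a<sub>j</sub>* flags SNPs within 100 kb of any network gene or
regulatory element. θ raises the *rate* of association near the network;
σ² raises effect *sizes* in proportion to the network's squared weights —
the channel through which edge topology acts. The prior combines with the
summary-statistic regression likelihood
β̂ ~ N(ŜR̂Ŝ⁻¹β, ŜR̂Ŝ) over a banded LD matrix R̂. Mean-field variational
inference over a hyper-parameter grid yields, per network,

* a **Bayes factor** comparing the enrichment model M1 (θ > 0 or σ² > 0)
  to the baseline M0, with restricted variants M11/M12/M13 isolating the
  proximity, edge, and combined channels, thresholded adaptively against
  a near-gene control network (all genes, no edges); and
* **gene-level posterior probabilities** P1 that a gene's ±100 kb locus
  holds at least one associated SNP, under M0 (`p1_base`), the control
  (`p1_near`), each network (`p1_net`), and Bayes-factor-weighted model
  averaging over enriched networks (`p1_bma`), with significance at
  P1 ≥ 0.9.

The package also builds context-specific networks from paired expression
and chromatin-accessibility summaries via trans-regulation scores,
harmonizes externally derived networks, and ships a complete
synthetic-data generator (block-LD genotypes, network-induced and
mis-specified effect models, phenotypes, single-SNP statistics) plus the
ROC/PRC and classical-test machinery used to benchmark such methods.

## Worked example

Simulate a study whose signal is genuinely enriched in a target network,
then test that network against the adaptive control and prioritize genes:

```r
library(rssnet)

st  <- simulate_study(n = 600, p = 800, n_genes = 150, n_chrom = 2,
                      n_tf = 10, n_tg = 60, n_edges = 150, seed = 21)
sc  <- sim_scenario("M13", theta0 = -2.5, theta = 2.5, eta = 0.4,
                    rho = 0.5, seed = 22)
eff <- simulate_effects(sc, st$annotation, st$snps, st$geno_var)
y   <- simulate_phenotype(st$X, eff$beta, 0.4, seed = 23)
ss  <- single_snp_stats(st$X, y, st$snps, bandwidth = 20)

res <- enrich_networks(ss$gwas, ss$ld, st$genes,
                       networks = list(target = st$network),
                       cis = st$cis,
                       grid = hyper_grid(theta0 = c(-3, -2.5),
                                         theta = c(0, 1.5, 3),
                                         eta = c(0.2, 0.4),
                                         rho = c(0, 0.5)),
                       seed = 1)
res
#> <rssnet_enrich_result> control log10 BF = 6.21
#> # A tibble: 1 × 7
#>   network log10_bf log10_bf_m11 log10_bf_m12 log10_bf_m13 best_pattern passes_control
#>   <chr>      <dbl>        <dbl>        <dbl>        <dbl> <chr>        <lgl>
#> 1 target      9.63         8.28       -0.253         10.0 M13          TRUE
```

The target network's log₁₀ BF (9.63) exceeds the near-gene control's
(6.21), so the network passes the adaptive enrichment threshold, and the
best-supported pattern is M13 — both elevated association rates near the
network and larger effects through its edges. Gene-level output:

```r
rep <- gene_report(res, st$genes, st$snps)
dplyr::arrange(rep, dplyr::desc(p1_bma))
#> # A tibble: 150 × 7
#>   gene_id p1_base p1_near p1_target p1_bma significant network_driven
#>   <chr>     <dbl>   <dbl>     <dbl>  <dbl> <lgl>       <lgl>
#> 1 g2_063    0.999   0.999     1.000  1.000 TRUE        TRUE
#> 2 g2_064    0.998   0.998     1.000  1.000 TRUE        TRUE
#> 3 g2_007    0.702   0.989     0.999  0.999 TRUE        TRUE
#> # …
```

Genes with `p1_bma ≥ 0.9` are flagged significant; `network_driven`
marks genes whose network-conditional probability exceeds the near-gene
reference — the genes promoted specifically by regulatory topology.
`tidy()`, `glance()` and `autoplot()` methods cover the fit, enrichment
and gene-report objects.

(The numbers above are from the seeds shown; your platform's BLAS may
shift the last digits.)

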