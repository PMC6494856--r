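# coralnet

Structure and stability analysis of host-associated microbiomes from 16S
OTU tables.

Reef-building corals (and many other hosts) carry dense, diverse bacterial
communities whose composition reflects both who the host is and where and
when it was sampled.  Given a samples × OTUs count matrix and a design with
host **genus**, **species** (nested in genus), **site**, and **time**,
coralnet quantifies how strongly each factor structures the microbiome and
how stable host-specific signatures are across space and time.  It is
written for microbial ecologists working with amplicon surveys of
repeatedly sampled hosts.

The analysis has three legs:

1. **Composition.** Median-of-ratios library-size normalization
   (`normalize_median_of_ratios`), prevalence-based core-microbiome
   detection (an OTU is core to a host group when present in **more than**
   a threshold fraction — default 95% — of its samples;
   `core_microbiome`), and class-level abundance profiles through a
   QIIME-style taxonomy (`class_abundance_profile`).
2. **Multivariate inference.** Bray-Curtis dissimilarity
   (d(a,b) = Σᵢ|xₐᵢ−x_bᵢ| / Σᵢ(xₐᵢ+x_bᵢ)); sequential (Type-I) PERMANOVA on
   the Gower-centered distance matrix with realized-rank degrees of freedom
   for nested/interaction terms (`permanova`); pairwise post-hoc tests with
   sequential Bonferroni (Holm) correction (`pairwise_permanova`,
   `holm_adjust`); SIMPER decomposition of between-group dissimilarity into
   additive per-OTU (and per-class) contributions (`simper`); and a
   Monte-Carlo ANCOVA of log dissimilarity on log great-circle distance to
   test distance decay of community similarity (`distance_decay_table`,
   `ancova_mc`).
3. **Network.** Pearson sample-sample correlations (`sample_correlation`),
   homophily/heterophily scores per design factor (`homophily_scores`), a
   weighted undirected graph under a declared negative-weight policy
   (`build_graph`), Newman leading-eigenvector community detection with a
   stratified Monte-Carlo modularity null
   (`leading_eigenvector_communities`, `modularity_null`), χ² module-factor
   association and module-majority classification rates
   (`module_factor_chisq`, `misclassification_rate`), and power-iteration
   eigenvector centrality with group comparisons
   (`eigen_centrality_scores`).

A negative-binomial synthetic-survey generator (`simulate_survey`,
`sim_config`, `fixture_small`) emulates the whole design — nested host
taxonomy, spatially correlated site effects, planted core OTUs, log-normal
library sizes — so every stage is testable with known ground truth.
`run_all()` drives the full pipeline and writes every result table plus a
run manifest.

## Worked example

A reduced synthetic survey (3 genera / 6 species × 4 sites × 3 times, one
colony per cell, 80 OTUs), analyzed end to end:

```r
library(coralnet)

sim  <- simulate_survey(sim_config(colonies_per_cell = 1, n_otus = 80, seed = 7))
norm <- normalize_median_of_ratios(sim$counts, "pseudo-geomean")
d    <- bray_curtis(norm)

permanova(d, sim$metadata, c("genus", "site", "time", "species(genus)"),
          permutations = 999, seed = 17)
#>             term df     SS      F     R2     p
#> 1          genus  2  7.706 40.688 0.4917 0.001
#> 2           site  3  1.330  4.682 0.0849 0.001
#> 3           time  2  0.613  3.237 0.0391 0.002
#> 4 species(genus)  3  0.245  0.862 0.0156 0.605
#> 5       Residual 61  5.777     NA 0.3686    NA
#> 6          Total 71 15.671     NA 1.0000    NA
```

Host genus explains far more of the community variation (R² = 0.49,
p = 0.001) than site (0.085) or time (0.039), matching the effect sizes
planted by the generator; R² over all terms plus residual sums to 1.

```r
net <- build_graph(sample_correlation(norm))
homophily_scores(net, sim$metadata)
#>   factor homophily heterophily
#> 1  genus     0.608       0.150
#> 2   site     0.325       0.290
#> 3   time     0.303       0.296

mod <- leading_eigenvector_communities(net)
mod
#> coral_modules: 3 modules, Q = 0.3227

modularity_null(net, sim$metadata$samples$genus,
                permutations = 199, seed = 17)$p_value
#> [1] 0
misclassification_rate(mod, sim$metadata$samples$genus)
#> [1] 0.972
```

Samples from the same genus are far more correlated (homophily 0.61) than
samples sharing a site (0.33) or month (0.30); the network resolves three
modules — one per genus, classifying 97% of samples — and no stratified
null network reaches the observed modularity (p = 0, the minimum the
199-permutation proportion rule can report).

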