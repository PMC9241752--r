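# dysbionet

Statistical analysis of fecal 16S ASV communities in case–control IBD
cohorts, built around the question of whether dysbiosis persists during
clinical remission. Starting from a sample × ASV count table, a taxonomy
table, a rooted phylogeny and subject metadata (condition ∈ {Control,
CD, UC}, age, gender, BMI, smoking, medication, Montreal subtypes,
SCCAI/CDAI activity scores), the package runs the full workflow:

* **Preprocessing** — rarefaction to a common depth (default 11,800
  reads/sample), Good's coverage, prevalence filtering, Hellinger
  transform, rank aggregation.
* **Alpha diversity** — Chao1, Gini-Simpson, Pielou evenness, and the
  phylogenetic indices NRI/NTI against a richness-preserving null
  (999 permutations; positive = phylogenetic clustering), with
  backward-AIC covariate models (`index ~ condition × age +
  condition × bmi + gender`) and pairwise subset contrasts.
* **Beta diversity** — Bray-Curtis, binary Jaccard and generalized
  UniFrac d^α (α = 0.5 default), PCoA on square-root transformed
  distances, sequential PERMANOVA with covariates entered before
  condition, pairwise contrasts under a BH family, and permutation
  goodness-of-fit of covariates on the ordination.
* **Differential abundance & indicators** — per-taxon negative-binomial
  Wald tests (`abundance ~ gender + age + condition`, median-of-ratios
  size factors, 5% prevalence filter, BH per contrast and taxonomic
  level) and IndVal.g indicator analysis
  (`IndVal.g = sqrt(specificity × fidelity)`) with permutation P values.
* **Co-abundance network** — SparCC correlations (50 Dirichlet
  samplings, 100 strong-pair exclusion iterations), permutation
  significance, edges kept at `P_FDR ≤ 0.05` and `|r|` above the median
  of nonzero correlations, fast-greedy modules on weights `|r|`,
  centralities (degree, betweenness on 1/|r| paths, PageRank,
  eigenvector) with vertex-permutation Z-tests, indicator-vs-rest
  centrality comparison, **per-subject module completeness** (fraction
  of a module's members detected in a subject, 0–1) with binomial-GLM
  associations to condition and activity scores, and eigengene-style
  Hellinger-RDA module differentiation.
* **Synthetic cohorts** — a generator reproducing the statistical
  structure the analysis assumes (195 subjects in the published group
  sizes, log-normal basis with planted correlation modules and condition
  effects, multinomial reads with a depth floor at 11,800), so every
  stage is testable without access to the original sequence archives.

The per-subject module-completeness statistic is the distinctive piece:
it turns a community-level network module into a subject-level quantity
that can be regressed on disease condition and clinical activity the
same way any other phenotype is.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
default synthetic cohort (195 subjects, 150 ASVs, a planted
Enterobacteriaceae-like module of 10 taxa with basis correlation 0.8,
enriched in CD) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_alpha_diversity.R
Rscript analysis/03_beta_diversity.R
Rscript analysis/04_differential_abundance.R
Rscript analysis/05_conetwork.R
```

Stage 2 reports the preprocessing state:

```
rarefied 195 samples (dropped 0); mean Good's coverage 99.95%
```

— nobody falls below the 11,800-read floor, and coverage says the
samples are sequenced essentially to exhaustion.

Stage 4 finds the planted signals (module members ASV_1–ASV_10 were
planted at log2FC = 3 in CD; ASV_24 at −2 in UC):

```
ASV level: 450 taxon-contrast results, 41 at P_FDR <= 0.05
    taxon_id      contrast log2_fold_change    P_FDR
174   ASV_24 UC-vs-Control            -2.54 3.14e-24
1      ASV_1 CD-vs-Control             3.04 6.81e-21
8      ASV_8 CD-vs-Control             3.01 8.21e-21
6      ASV_6 CD-vs-Control             3.28 4.01e-20
```

Stage 5 reconstructs the planted module from the counts alone and ties
it back to disease:

```
network: 150 nodes, 45 edges (|r| > 0.041), Q = 0.000, 1 modules
      measure statistic        P   P_FDR
1      degree      1808 0.000999 0.00133
2 betweenness      1132 1.000000 1.00000
3    pagerank      1808 0.000999 0.00133
4 eigenvector      1808 0.000999 0.00133

module completeness ~ condition:
  module    coef_name estimate    se        P separation    P_FDR
1      1 condition:CD  2.16002 0.215 7.77e-24      FALSE 7.77e-24
2      1 condition:UC  0.00897 0.102 9.30e-01      FALSE 9.30e-01
```

The 45 retained edges are exactly the pairs within the planted
10-taxon module (a single clique, hence one module and Q = 0 for the
connected part); its members are significantly more central than
non-indicator taxa on degree, PageRank and eigenvector centrality; and
per-subject completeness of the module is strongly higher in CD
(logit coefficient 2.16, P_FDR ≈ 8 × 10⁻²⁴) with no shift in UC —
the planted condition, recovered end to end.

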