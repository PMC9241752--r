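---
title: "Methods: from ASV counts to co-abundance module completeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ASV counts to co-abundance module completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dysbionet` implements the statistical workflow for comparing fecal 16S
ASV communities between healthy controls and IBD patients in remission
(Crohn's disease, CD; ulcerative colitis, UC): within-sample diversity
with phylogenetic null models and covariate regression, between-sample
distances with ordination and PERMANOVA, covariate-adjusted differential
abundance and indicator analysis, and a SparCC co-abundance network layer
whose modules are summarized per subject as a *completeness* statistic
and associated with disease condition and clinical activity scores.

Everything upstream of the count table — sequencing, denoising,
taxonomic classification, tree building — is out of scope: the package
starts from a sample-by-ASV integer matrix, a taxonomy table, a rooted
tree with branch lengths, and subject metadata.

# Preprocessing

**Rarefaction.** Samples are subsampled uniformly *without replacement*
to a common depth, by default 11,800 reads/sample; samples below the
depth are dropped rather than kept at native depth, since the point of
rarefaction here is comparable coverage. The draw is a single rarefaction
under a fixed seed (not an average over repeated draws); repeated draws
with different seeds are unbiased around the expected proportional
allocation, which the test suite checks by Monte Carlo.

**Coverage.** Good's coverage `1 - F1/N` (singletons over total reads)
quantifies how exhaustively each sample was sequenced.

**Prevalence filters.** ASVs observed in fewer than
`ceiling(fraction * n_samples)` samples are removed — 5% before
differential abundance testing and 10% before network inference. The
ceiling makes the rule conservative at non-integer cutoffs.

**Orientation.** Samples are rows and taxa are columns in every matrix
the package produces or consumes.

# Alpha diversity

Per rarefied sample: observed richness; bias-corrected Chao1
`S + F1(F1-1) / (2(F2+1))` (the bias-corrected form avoids division by
zero when no doubletons exist); Gini-Simpson `1 - sum(p^2)` (bounded in
[0, 1), matching diversity values that rise toward 1; the unbounded
inverse form is not used); and Pielou evenness `H / ln(S)`, undefined
(`NA`) for single-taxon samples.

**NRI/NTI.** Mean pairwise distance (MPD) and mean nearest-taxon
distance (MNTD) on the tree are standardized against a *richness* null:
each null community keeps the sample's taxon count and draws taxa
uniformly from the pool of taxa present anywhere in the table (999 draws
by default, via `picante`). Indices are sign-flipped,
`NRI = -(MPD_obs - mean_null)/sd_null`, so positive values mean
phylogenetic clustering. Metrics are presence-based by default — the
null preserves only richness, so abundance weighting would mix two
different null hypotheses — with `abundance_weighted = TRUE` available.
Degenerate cases are explicit: fewer than two taxa gives `NA`; a null
with zero spread (every sample holds the full pool) gives index 0 with a
`degenerate` flag. Self-consistency — communities generated *by* the
null have standardized effect sizes with mean ≈ 0 and sd ≈ 1 — is an
acceptance test.

**Covariate models.** Each index is regressed on
`condition * age + condition * bmi + gender` by OLS and simplified by
backward elimination: at each step the term whose deletion most lowers
the AIC is removed, never removing a main effect contained in a retained
interaction, until no deletion lowers AIC. `stats::step()` implements
exactly this; its `extractAIC` omits the additive constant of the
Gaussian log-likelihood, which cancels in every comparison, so the
selected model is identical to one chosen with the full-constant AIC.
The final model is summarized with sequential ANOVA F-tests. Pairwise
interpretation refits the selected model on each two-condition subset
and reports the subset P of the condition term (average differences) and
of any retained age/BMI interaction (slope differences, e.g.
`Age:Contr.-CD`).

A deliberate caution about backward AIC: under a pure-noise response it
retains a spurious ~2-df term with probability ≈ 0.13 per candidate, so
an intercept-only outcome is modal but not overwhelming (~1/3 of
replicates at n = 200, with ~2/3 keeping at most one term). The test
suite asserts this measured behavior; a stricter criterion such as BIC
would prune harder but is not what the workflow specifies.

# Beta diversity

Three dissimilarities, all in [0, 1]:

* **Bray-Curtis** `sum|x - y| / sum(x + y)` on rarefied counts
  (differential abundance of ASVs); may violate the triangle inequality,
  which is accepted and documented.
* **Binary Jaccard** `1 - |A ∩ B| / |A ∪ B|` on presence/absence
  (differential occurrence).
* **Generalized UniFrac** with exponent `alpha`: over tree branches `b`
  of length `l_b` carrying per-sample abundance proportions `p_b`,
  `q_b`,
  `d = Σ l_b (p+q)^α |p-q|/(p+q) / Σ l_b (p+q)^α`.
  `alpha = 0.5` (the `d^0.5` compromise between rare- and
  abundant-lineage influence) is the default and is exposed as a
  parameter; `alpha = 1` reproduces the normalized weighted form. No
  installed package provides the generalized form, so the branch
  summation is implemented directly from the tree's edge/tip incidence
  and verified against hand enumeration on a 4-tip tree.

**Ordination.** Classical (Gower-centered) scaling of the element-wise
*square root* of the dissimilarity, which removes the negative
eigenvalues Bray-Curtis/Jaccard would otherwise produce. Axis
proportions are reported against the positive-eigenvalue total.

**PERMANOVA.** Sequential (Type I) partition of distance-matrix variance
(`vegan::adonis2`, `by = "terms"`), with covariates (age, BMI, gender)
entered before condition so condition effects are tested after
adjustment. Permutations are free (the design is unpaired);
`P = (b + 1)/(m + 1)`. Per-term adjusted R² is
`1 - (1 - R²)(n - 1)/(n - k - 1)`. Pairwise condition contrasts rerun
the model on two-condition subsets with BH correction across the three
contrasts. Samples are sorted by identifier internally, so results are
invariant to input row order under a fixed seed. Goodness-of-fit of a
covariate on the first two PCoA axes uses `vegan::envfit` (squared
multiple correlation for continuous variables, centroid fit for
factors), with a constant variable defined to fit nothing (R² = 0,
P = 1).

# Differential abundance and indicators

**NB-Wald.** Per taxon, a negative-binomial GLM with log link,
median-of-ratios size factors as offsets, and the design
`abundance ~ gender + age + condition` (Control as reference).
Dispersion is estimated per taxon by maximum likelihood
(`MASS::glm.nb`); when that fails (e.g. zero-variance taxa) a
method-of-moments estimate from a Poisson fit, floored at 1e-8, fixes
the dispersion and the model is refit; in that branch the Wald
covariance is evaluated at dispersion 1, as the NB likelihood has no
free scale once theta is fixed. Contrasts CD–Control, UC–Control and
UC–CD are Wald tests on coefficient differences, BH-adjusted across taxa
separately per contrast and per taxonomic level (phylum-level counts are
aggregated *before* the prevalence filter, so the filter applies at the
tested level). This is a deliberate, documented simplification of the
DESeq2 machinery — no empirical-Bayes dispersion shrinkage, no
independent filtering — retaining the model formula, the 5% prevalence
filter, and the FDR procedure; a unit test cross-checks the estimates
against DESeq2 on a shared fixture (log2 fold changes agree to r > 0.98).
One known behavior worth stating: with strong one-sided planted effects,
median-of-ratios normalization absorbs part of the shift, attenuating
estimated fold changes by ~15–20% — visible in the parameter-recovery
results and inherent to the normalization, not a defect of the fit.

**IndVal.g.** For taxon `k` and group `g`, specificity
`A = mean abundance in g / Σ_h mean abundance in h` (group-size
corrected, since group means rather than sums are compared) and fidelity
`B = occurrence fraction in g`; `IndVal.g = sqrt(A·B)`, association =
argmax over groups, significance by permuting group labels with BH
across taxa. Run on rarefied counts by default (it accompanies the
rarefied diversity workflow); the permutation floor `1/(m+1)` is only
attainable when the number of distinct label assignments exceeds the
permutation count.

# SparCC network layer

**Correlation inference.** SparCC estimates correlations between
log-scale basis abundances from compositions. Each of 50 samplings draws
per-sample fractions from `Dirichlet(counts + 1)` (zeros never reach a
logarithm), computes the log-ratio variation matrix
`t_ij = var(log x_i/x_j)`, and solves the sparsity-assumption linear
system for basis variances; correlations follow as
`r_ij = (ω_i + ω_j - t_ij) / (2 sqrt(ω_i ω_j))`. The most strongly
correlated pair above 0.1 is excluded from the system and the basis
re-solved, up to 100 iterations, stopping early if an exclusion would
leave a taxon with fewer than three partners (the system becomes
unidentifiable below four taxa, hence the hard minimum of 4). The
reported matrix is the element-wise median over samplings, clipped to
[-1, 1]. Tables whose taxa sit in identical proportions in every sample
have zero log-ratio variance and are rejected up front.

**Significance.** Each permutation shuffles every taxon column
independently — destroying covariance, preserving margins — and
recomputes SparCC with one Dirichlet sampling and 10 exclusion
iterations (a tractability reduction; the point estimate keeps the full
settings). Two-sided pseudo-P `(#{|r_perm| ≥ |r_obs|} + 1)/(m + 1)`,
BH-adjusted over the upper triangle.

A piece of arithmetic that matters in practice: the smallest attainable
BH-adjusted P over `M` taxon pairs with `k` true edges is roughly
`M / (k (m+1))`. With 150 taxa (`M ≈ 11,000`) and a 10-pair module,
1,000 permutations cannot reach 0.05 — the workflow's 10,000
permutations are not ornamental. Test-scale analyses therefore use
smaller taxon panels rather than weaker thresholds.

**Edge rule.** An edge is kept iff `P_FDR ≤ 0.05` *and* `|r|` is
*strictly* above the median of the nonzero off-diagonal correlations.
The median is computed before significance filtering by default
(`median_of = "significant"` switches this, since the original
description is ambiguous on the point). Isolated nodes remain in the
node set.

**Modules.** Fast-greedy (CNM) modularity maximization on weights
`|r|`; the merge tree is cut at maximal weighted Q, with numerical ties
resolved toward the coarser partition so that, e.g., a clique is exactly
one module. Components are never merged. Reported Q is re-derivable from
the partition by the definitional formula `Σ_c (e_cc - a_c²)`, which a
test checks to 1e-10, and on ≤ 10-node graphs greedy Q is checked
against the exhaustively optimal two-block partition.

**Centralities and their null.** Degree (unweighted edge count),
betweenness (geodesics under edge length `1/|r|`, so stronger
correlation = shorter path), PageRank (damping 0.85, weights `|r|`), and
eigenvector centrality (weights `|r|`, max-normalized; per component
with a flag when the graph is disconnected). Significance permutes
vertex *labels* over the fixed topology — read literally from the
workflow's description — so each node's null distribution is the
empirical distribution of observed centralities; one-sided
`Z = (obs - mean)/sd`, `P = 1 - Φ(Z)` ("more central than expected";
two-sided by flag), BH per measure. A vertex-transitive graph makes the
null spread zero and the result `NA` by construction. Indicator vs
non-indicator centralities are compared by a rank-sum statistic with a
flag-permutation P, BH across the four measures.

**Module completeness.** For each subject and module, the fraction of
member taxa with nonzero counts — 0 (no members) to 1 (all members).
Computed on the *pre-rarefaction* table by default, since
presence/absence is depth-sensitive and rarefaction would discard
genuine detections. Associations use a binomial GLM on
(members present, members absent) with logit link — condition over the
full cohort (Control reference), SCCAI restricted to UC subjects, CDAI
to CD — with Wald P and BH across modules per coefficient. Complete
separation (infinite MLE) is detected from runaway estimates or standard
errors and handled by a Haldane continuity correction (0.5 added to each
subject's success and failure counts), flagged in the output.

**Module differentiation.** Eigengene-style: the count table restricted
to a module is Hellinger-transformed on the subset's own row sums
(subjects carrying no member contribute an all-zero row, keeping
fully condition-determined modules testable), then redundancy analysis
constrained on condition gives variance explained, pseudo-F and a
label-permutation P, BH across modules.

# The synthetic cohort generator

The generator reproduces the statistical structure the analysis assumes,
not the biology of any particular gut. Defaults encode the study
conditions: 97 controls, 32 CD, 66 UC (195 subjects); several hundred
taxa on a random Yule tree with exponential branch lengths; read depths
log-normal with a floor of 11,800 so default rarefaction drops nothing;
demographic covariates drawn to the cohort's published proportions
(gender and smoking per condition, adult ages, every UC subject on
5-ASA, Montreal codes within their condition, SCCAI/CDAI in the
remission range, absent elsewhere).

Counts follow the compositional model SparCC assumes: per subject, basis
abundances are multivariate log-normal; the log-scale covariance carries
planted module correlations (block correlation ρ) and the log-means
carry planted condition effects (log2 fold changes); the closed
composition feeds a multinomial read draw at the subject's depth, so
each row sums exactly to its depth. A Dirichlet-multinomial variant is
available behind `model = "dirichlet"` for robustness checks. Covariates
are independent of counts unless explicitly planted (an optional
per-condition age coefficient shrinks the log-mean spread with age,
creating an age-by-condition evenness trend).

Two generator choices deserve emphasis. A planted module intended to
behave like a rare pathobiont group (variable presence across subjects,
so completeness carries signal) needs a low shared baseline
(`meanlog ≈ -4`); a planted pair intended for correlation-recovery
checks needs a typical baseline (`meanlog = 0`), because correlations
among taxa observed at a handful of reads are attenuated by the
Dirichlet smoothing — with 10-member modules the attenuated pairwise
estimates still pass the significance screen and the module is recovered
intact. What the generator does **not** emulate: sequencing error and
chimeras, taxon-specific amplification bias, overdispersion beyond the
log-normal/multinomial hierarchy, phylogenetic signal in abundances
(the tree is independent of the covariance), and longitudinal structure.
Passing tests on this generator therefore demonstrate correctness of the
statistical machinery under its assumptions, not performance on real
sequencing artifacts.

# Problem sizes and numerical choices

Test and acceptance runs use desk-scale versions of the study
conditions, chosen once: the full 195-subject cohort for end-to-end
module recovery on a 60-taxon panel with 1,000 network permutations
(keeping the BH floor below 0.05 at that pair count); n = 200 and 50
taxa for SparCC pair recovery; n = 60/group for fold-change recovery;
500 replicates at 999 permutations for each null-calibration suite; 999
draws for phylogenetic nulls. The analysis scripts under `analysis/` run
a 150-taxon cohort with the full 10,000 network permutations.
Tolerances: Hellinger row norms and R² partitions to 1e-10–1e-12;
permutation-vs-exhaustive agreement to 0.02; calibration bands
[0.03, 0.08] at α = 0.05; recovery bands ±0.15 on a planted ρ = 0.8 and
±0.5 on a planted log2FC = 2.

# Known limitations

* NB-Wald without dispersion shrinkage is noisier than DESeq2 for very
  small groups; it is calibrated at the cohort's sample sizes.
* Median-of-ratios size factors are biased when a large, one-sided
  fraction of taxa shifts (see above); this matches the behavior of the
  normalization it mirrors.
* The SparCC permutation null uses reduced internal samplings; raw
  permutation P values are slightly conservative for weak correlations.
* Backward-AIC model selection is liberal under noise by construction.
* The label-permutation centrality null tests "is this node more
  central than a random label assignment", not "than a random graph";
  degree-preserving rewiring nulls are a different question and are not
  implemented.
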