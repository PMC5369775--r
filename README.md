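# riskclust

Risk-factor cluster analysis for high-risk pregnancy cohorts: Bayesian
clustering of binary clinical risk-factor profiles, cluster-specific risk
ratios of pregnancy outcomes relative to general-population reference rates,
and a risk-versus-number-of-risk-factors trend model.

## The problem

Antenatal clinics stratify women by clinical risk factors for preeclampsia
(previous preeclampsia, chronic hypertension, obesity, maternal age,
autoimmune disease, type 1 diabetes, ...). Individual factors are usually
studied one at a time, but women carry *combinations* of factors, and the
risk conferred by a combination is not the sum of its parts. `riskclust`
groups subjects by their whole binary risk-factor profile and then asks, for
every (cluster, outcome) pair, how much more likely each pregnancy outcome
(preeclampsia and its severity/timing subtypes, gestational hypertension,
SGA birth, gestational diabetes) is than in the general pregnant population.

## The model

**Clustering.** Subjects are clustered with a collapsed Beta–Bernoulli
mixture over partitions. For a partition *C* of the n subjects, the marginal
likelihood integrates the per-cluster, per-factor Bernoulli parameters out
under Beta(α₀, β₀) priors:

    log P(X | C) = Σ_{c,j} log [ B(α₀ + k_cj, β₀ + n_c − k_cj) / B(α₀, β₀) ]

where k_cj is the number of subjects in cluster c carrying factor j and B is
the beta function. The default partition prior is the Ewens (Chinese
restaurant process) prior with concentration θ = 1; the MAP partition is
found by a stochastic greedy search (single-profile reassignment, cluster
merge, 2-medoids split; multiple restarts) over weighted unique profiles,
and can be verified against exhaustive enumeration for n ≤ 10.

**Risk ratios.** For a cluster of size n with k events of an outcome whose
general-population rate is p₀, the risk ratio is RR = (k/n)/p₀, with 95%
bounds from the Clopper–Pearson exact binomial interval on k/n divided by
p₀, and a two-sided exact binomial p-value (minimum-likelihood convention).
Benjamini–Hochberg q-values are computed jointly across the whole cluster ×
outcome grid; a Bonferroni flag uses α/(K·M). Default reference rates are
Finnish national register estimates (preeclampsia 2.5%, of which 24% severe,
8% early-onset, 15% intermediate, 77% term, 23% preterm; gestational
hypertension 4.4%; SGA 2.3%; gestational diabetes 9%).

**Trend.** Logistic regression of the outcome on the per-subject risk-factor
count gives the slope b (log-odds per additional factor) with a Wald test,
alongside an exact-interval RR-by-count curve.

A synthetic-cohort generator (`predo_default_config()`,
`generate_cohort()`) draws cohorts with known latent cluster structure,
study-like risk-factor marginals and cluster-dependent outcome risks, so the
whole pipeline is testable without any subject-level data.

## Worked example

```r
library(riskclust)

co  <- generate_cohort(predo_default_config(seed = 1))
res <- run_pipeline(co$factors, co$outcomes,
                    settings = search_settings(seed = 1),
                    outdir = "results")
print(res$partition)
print(res$trend)
```

```
Partition of 903 subjects into 7 clusters
cluster
  1   2   3   4   5   6   7
142 123 109 323  89  58  59
Logistic trend (n = 903): slope b = 0.4136 (se 0.1554), Wald p = 0.0078
```

The risk table (`res$risk_table`, also written to `results/risks.csv`) has
one row per (cluster, outcome). For total preeclampsia:

```
 cluster outcome   n  k  rr ci_low ci_high  p_value  q_value significant_nominal
       1      pe 142 31 8.7   6.10    11.8 2.66e-20 1.68e-18                TRUE
       2      pe 123  1 0.3   0.01     1.8 3.80e-01 4.60e-01               FALSE
       3      pe 109 10 3.7   1.80     6.5 4.28e-04 1.34e-03                TRUE
       4      pe 323 41 5.1   3.70     6.7 3.14e-17 4.95e-16                TRUE
       5      pe  89  6 2.7   1.00     5.6 2.44e-02 4.05e-02                TRUE
       6      pe  58 11 7.6   3.90    12.6 1.83e-07 1.16e-06                TRUE
       7      pe  59  4 2.7   0.80     6.6 6.02e-02 9.03e-02               FALSE
```

Cluster 1 (dominated by women with preeclampsia in a previous pregnancy) has
31 preeclampsia cases among 142 women: 21.8% against the 2.5% reference rate
gives RR 8.7 (95% CI 6.1–11.8), significant at any of the multiplicity
levels. Cluster 2 (women over 40 without other major factors) has RR 0.3 —
no excess risk. The trend fit says each additional risk factor multiplies
the odds of preeclampsia by exp(0.41) ≈ 1.5.

`run_pipeline()` also writes `heatmap.svg` — clusters as rows (ordered by
size), left panel the within-cluster risk-factor composition as black boxes
with area proportional to prevalence, right panel the per-outcome RR cells
coloured on a log scale only where significant — plus `partition.csv`,
`trend.csv` and a `manifest.json` with the seed, settings and artifact
checksums.

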