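# cnimpact

Quantifying how strongly copy-number alterations (CNAs) drive gene
expression in tumor cohorts.

## The problem

In copy-number-unstable cancers, many genes are amplified or lost without
any consequence for their mRNA level, while a few dosage-sensitive genes
translate every extra copy into expression. Distinguishing the two —
functional versus passenger CNAs — requires a model that measures how
much of a gene's expression variation its own allele-specific copy number
explains. `cnimpact` implements such a framework for matched expression
counts and allele-specific absolute copy numbers (major/minor allele
counts `A >= B`, as produced by ASCAT-style callers), aimed at
computational cancer biologists working with bulk (or decomposed) RNA-seq
and WGS-derived copy-number calls.

## The model

Expression counts are Poisson with identity link in copy number and
nonnegative coefficients, times a per-sample scale `g_j`. The core
families per gene *i*:

* constant (null): `X_ij ~ Poi(b0 * g_j)`
* linear: `X_ij ~ Poi((b0 + a (A_ij + B_ij)) g_j)`
* interaction: adds `c * A_ij * B_ij` (`c` free in sign: synergistic /
  linear / antagonistic allele interplay)
* monotonic (default): `X_ij ~ Poi((b0 + Σ_k a_k (1[A_ij ≥ k] +
  1[B_ij ≥ k])) g_j)`, all `a_k ≥ 0` — a non-decreasing step response in
  each allele's copy number
* stacked monotonic: two-group variant with nonnegative group deviations
  on every coefficient; the deviating group is chosen by likelihood

The **copy-number impact** of a gene is `CNI = sqrt(1 − D_alt / D_null)`,
the square root of the deviance-based explained variance of the
copy-number model over the constant one, with a likelihood-ratio test
(chi-square, rank-difference degrees of freedom) for significance.
Pathway CNI pools member deviances before forming the ratio. On top of
this sit: leave-one-out gene contributions summarized by perplexity (the
effective number of genes carrying a pathway's CNI), functional
transition points (the copy number at which the fitted dosage curve
crosses the cohort's median expression, with a five-level
deletion/loss/normal/gain/amplification categorization), a
driver-calibrated CNA-versus-CNI landscape separating CN-driven,
conserved, passenger and non-CN-driven pathways, per-pathway response
group enrichment from the stacked models, and a seeded synthetic-cohort
generator with planted truth. A TP53-VAF purity estimator
(`purity = 2 / ((CN/VAF) − (CN − 2))`) and a segment-to-gene copy-number
mapper cover the upstream plumbing.

See `vignettes/copy-number-impact.Rmd` for the full methods account.

## Worked example

Simulate a small cohort with planted gene classes, score genes and
pathways, and classify the landscape:

```r
library(cnimpact)
cfg <- sim_config(n_genes = 300, n_samples = 100, seed = 7,
                  n_pathways = 8, pathway_size = c(6L, 10L))
co  <- simulate_cohort(cfg)
tb  <- cni_table(co$expr, co$cn)            # per-gene CNI + LRT
pw  <- pathway_cni_table(tb, co$pathways, cn = co$cn)
ref <- build_reference_distributions(tb, co$pathways, co$truth$cn_drivers,
                                     co$truth$mut_drivers, co$cn,
                                     n_resamples = 200, seed = 7)
thr <- calibrate_landscape(ref)
classify_quadrants(pw, thr)[, c("pathway", "cni", "mean_cna", "quadrant")]
```

```
              pathway       cni mean_cna      quadrant
1     PW_cn_driven_01 0.8326045 3.021000     cn_driven
2     PW_cn_driven_02 0.7968980 3.022222     cn_driven
3     PW_passenger_01 0.1495509 3.411429     passenger
4     PW_passenger_02 0.1487979 3.184286     passenger
5     PW_conserved_01 0.5360003 1.980000     conserved
6     PW_conserved_02 0.5966774 1.990000     conserved
7 PW_non_cn_driven_01 0.1022784 1.977143 non_cn_driven
8 PW_non_cn_driven_02 0.1457500 1.964286 non_cn_driven
```

The planted `cn_driven` pathways (strong dosage response on dispersed
copy numbers) score CNI ≈ 0.80–0.83 at mean CNA ≈ 3; `passenger`
pathways carry just as many aberrations (mean CNA ≈ 3.2–3.4) but explain
almost nothing (CNI ≈ 0.15); `conserved` pathways respond strongly to
the few aberrations they have (CNI ≈ 0.54–0.60 at near-diploid CNA);
and all eight land in their planted quadrant under the calibrated
thresholds (here CNI ≥ 0.471, mean CNA ≥ 2.485). Per-gene rows in `tb`
carry the raw material: e.g. gene `G0003` has CNI 0.94 with LRT statistic
664 on 7 df (BH-adjusted p ≈ 7e-138).

A full pipeline (simulate → gene CNI → pathway CNI → transitions →
stacked group models → enrichment → landscape) is available as
`run_pipeline(run_config(...))`, or from a shell via the thin wrapper
`inst/cli/cnimpact.R` (subcommands `simulate`, `map-cn`, `cni`,
`transition`, `run`).

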