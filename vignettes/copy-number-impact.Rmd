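---
title: "Quantifying copy-number impact on gene expression"
author: "cnimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying copy-number impact on gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnimpact)
```

## The problem

Copy-number alterations (CNAs) are pervasive in genomically unstable
cancers such as ovarian high-grade serous carcinoma, but a gene's mRNA
level is shaped by many regulatory layers besides its DNA dosage. Counting
aberrations alone therefore conflates *abundant* CNAs with *functional*
ones. `cnimpact` quantifies, per gene and per pathway, how much of the
expression variation across a cohort is attributable to the gene's own
allele-specific absolute copy number — its copy-number impact (CNI) — and
uses that quantity to separate putatively CN-driven biology from passenger
aberrations.

The inputs are a gene-by-sample matrix of expression counts
$X_{ij}$, matched allele-specific absolute copy numbers per gene and
sample — the major and minor allele counts $A_{ij} \ge B_{ij} \ge 0$, as
produced by allele-specific callers in the ASCAT family — and optionally
gene sets (GMT), binary response-group labels, and driver-gene lists.

## The model family

Counts are modeled as Poisson with an identity link in copy number and
nonnegative coefficients, times a per-sample scale $g_j$ capturing the
sample's global expression level:

* **constant** (null): $X_{ij} \sim \mathrm{Poi}(b_{i,0}\, g_j)$;
* **linear**: $X_{ij} \sim \mathrm{Poi}\big((b_{i,0} + a_i (A_{ij} +
  B_{ij}))\, g_j\big)$;
* **interaction**: adds $c_i A_{ij} B_{ij}$ with $c_i$ free in sign —
  $c_i > 0$, $= 0$, $< 0$ mark synergistic, linear and antagonistic
  interplay between the two parental allele counts;
* **monotonic**: $X_{ij} \sim \mathrm{Poi}\big((b_{i,0} + \sum_{k \ge 1}
  a_{i,k}\,(\mathbf 1[A_{ij} \ge k] + \mathbf 1[B_{ij} \ge k]))\,
  g_j\big)$ with all $a_{i,k} \ge 0$, so each allele's contribution is a
  non-decreasing step function of its copy number. This is the package's
  default: it captures saturating and thresholded dosage response that a
  straight line misses, while nesting both the linear model (equal steps)
  and the constant model (zero steps);
* **stacked monotonic**: for two-group cohorts, one group follows the base
  monotonic model and the other adds nonnegative deviations $d_{i,0},
  d_{i,k}$ to every coefficient. Both direction assignments are fitted and
  the better-likelihood one kept, recording which group carries the extra
  dosage response.

The identity link is deliberate: expression is modeled as proportional to
dosage plus a basal term, not log-linear, and the nonnegativity
constraints encode that extra copies do not reduce expression.

### Fitting

The constant model has the closed-form MLE $b_0 = \sum_j x_j / \sum_j
g_j$. All other families are maximized with box-constrained L-BFGS-B on
the coefficient vector (lower bound 0 except the interaction coefficient),
analytic gradient, initialization at the constant-model MLE with all other
coefficients at zero, and a fixed ladder of deterministic fallback starts
on non-convergence. Because optimization starts at the null MLE and only
improves, every alternative fit's likelihood is at least the constant
model's — the nesting property the likelihood-ratio test relies on. The
mean is floored at $10^{-10}$ inside the objective so the log stays finite
when coefficients hit the boundary while a count is positive. Step levels
never observed in a gene's data are structurally fixed at zero and
excluded from the model's rank, which is computed as the rank of the
active design matrix. The default `k_max = 8` truncates the step model;
allele counts above it still trigger all lower indicators.

The scales $g_j$ are treated as known by the models; the packaged
estimator is the sample's column sum divided by the mean column sum (mean
1 by construction). Any externally computed size factor can be passed
instead. Deviances and likelihood-ratio statistics are invariant to a
common rescaling of $g$.

## CNI: explained deviance

The residual Poisson deviance of a fit is $D = 2\sum_j [x_j \ln(x_j /
\mu_j) - (x_j - \mu_j)]$. The explained variance of an alternative model
over the constant one is realized as $EV = 1 - D_{alt} / D_{null}$ — the
likelihood-consistent analogue of $R^2$, reducing to the classical
definition in the Gaussian limit — and the CNI is $\sqrt{EV}$ clipped to
$[0, 1]$ (raw, possibly slightly negative, $EV$ is preserved in outputs).
A classical mean-squared-residual $R^2$ on $x_j / g_j$ is available via
`ev_method = "mse"` for sensitivity analysis. A gene whose copy number
carries no usable variation is assigned $EV = 0$ exactly, with a
zero-degree-of-freedom test.

Significance comes from a likelihood-ratio test with statistic
$2(\ell_{alt} - \ell_{null})$ and degrees of freedom equal to the rank
difference, referred to the upper chi-square tail. The nonnegativity
constraints place the null on the parameter-space boundary, so the
chi-square reference is conservative; the packaged null-calibration
check (1,000 constant-model genes with dispersed copy numbers) verifies
the empirical rejection rate at $\alpha = 0.05$ stays below the nominal
level without vanishing. Gene-level and pathway-level p-values are each
adjusted by Benjamini–Hochberg.

At the pathway level, member genes' alternative and null deviances are
summed separately before forming $EV$, so the pathway CNI is the
generalized correlation of the member-model collection rather than an
average of per-gene values. A consequence worth knowing: pooling is
deviance-weighted, so one strong, highly expressed gene can dominate a
large pathway — which is precisely what the contribution analysis below
measures.

## Gene contributions and perplexity

Each member gene's contribution is obtained by leave-one-out: $\Delta_i$
is the drop in pooled $EV$ when gene $i$ is removed, negatives are clipped
to zero, and contributions are normalized to $p_i = \Delta_i / \sum
\Delta$ (uniform if no removal lowers the pooled $EV$). The perplexity
$\pi = \exp(-\sum_i p_i \log p_i)$, with $0 \log 0 = 0$, is the effective
number of genes carrying the pathway's CNI: 1 for a single dominant gene,
the member count for perfectly diffuse impact.

## Functional transition points

For each gene the fitted monotonic model is reduced to a one-dimensional
curve over total copy number $c$ using the balanced allele split $A =
\lceil c/2 \rceil$, $B = \lfloor c/2 \rfloor$ (an all-major split is
available; the balanced split is the default because cohort allele splits
concentrate near balance and the curve is drawn for a typical sample).
The cohort median and quartiles of $x_j / g_j$ (median-unbiased type-8
quantiles, stated for reproducibility) are projected onto the curve and
inverted by linear interpolation: the median crossing is the transition
point, the quartile crossings the transition bandwidth. The preimage of a
height lying on a flat stretch is that stretch's midpoint; heights outside
the curve's range clamp to the grid ends with a flag; a completely flat
curve yields no transition. Transition points map onto a five-level
aberration scheme anchored at integer copy numbers — deletion (0), loss
(1), normal (2), gain ($2 < c \le 5$), amplification ($c > 5$) — with
real-valued boundaries at 0.5, 1.5, 2 and 5; the boundaries at 2 and 5
follow the integer anchors exactly. Pathway-level categories take the
modal member category, breaking ties toward the category more extreme
relative to normal (gain preferred over loss, amplification over
deletion): an equivocal pathway is more usefully flagged by its aberrant
mode than by "normal".

## The CNA-versus-CNI landscape

Pathways are placed in a plane spanned by mean absolute CNA (average of
$A + B$ over samples and member genes; a `deviation` mode averaging
$|A + B - 2|$ is provided because homozygous-deletion-driven aberration is
invisible to the total) and pathway CNI. Thresholds on the two axes are
calibrated independently from driver-gene lists: pathways containing
known CN drivers populate the high reference, pathways containing known
mutation drivers the low one. To strip each side of the other class's
signal, every resampling round replaces the mutation drivers inside
CN-driver pathways (and, symmetrically, the CN drivers inside
mutation-driver pathways) with genes drawn uniformly from the genome
pool, recomputing the pathway statistics each time; 1,000 rounds are the
default. A pathway containing both driver kinds is treated as a CN-driver
pathway only: its mutation drivers are replaceable noise, whereas
stripping the CN drivers of a genuinely CN-driven pathway would fabricate
a background pathway on the mutation side. The threshold on each axis is
the exact accuracy-maximizing cut over midpoints of adjacent order
statistics of the pooled reference samples (smallest such cut on ties; no
grid parameter). The four quadrants are CN-driven (both high), conserved
(high CNI, low CNA — strong dosage response, few manifest aberrations),
passenger (low CNI, high CNA) and non-CN-driven (both low).

For two-group cohorts, a gene is group-significant when its
stacked-versus-constant LRT survives the FDR threshold (default 0.05),
and a pathway is labeled with a response group when it contains at least
one significant gene whose deviations lie in that group, with `both` when
both directions occur. The any-hit rule is a deliberate design choice: it
is the reading under which a pathway can be enriched in both groups at
once, and single dominant genes — the case the contribution analysis
highlights — are exactly what it should not dilute away.

## The synthetic-data generator

`sim_config()` / `simulate_cohort()` generate seeded cohorts with planted
truth. Five gene classes are drawn: `cn_driven` and `passenger` genes
take dispersed total copy numbers over 0–8 (mode at 2–3 copies, a long
gained tail, 5% homozygous losses); `conserved` and `independent` genes
concentrate near diploid (70% at 2 copies, 15% at 1 and 3 — roughly a
third of samples deviating from diploid at a typical locus of a
CN-unstable tumor); `group_modulated` genes are dispersed with nonnegative
deviations planted in one response group. Allele splits are balanced with
probability 0.7, otherwise uniform. Dosage-responsive classes draw step
sizes relative to $b_0 / 2$ (0.5–1.5 of it per step, under linear,
saturating, or thresholded profiles), because a gene whose expression is
proportional to total copy number has slope exactly $b_0 / 2$ per allele
copy. Basal levels are uniform on 2–20 counts; sample scales are
log-normal with $\sigma = 0.3$, renormalized to mean 1, mimicking
library-size spread. Planted pathways are split over the four landscape
quadrants and drawn from the matching class pools; a configurable number
of mutation-driver genes is mixed into each CN-driven pathway (these are
what the landscape resampling removes). Strong dosage genes are *not*
mixed into non-CN-driven pathways: under deviance pooling even one such
gene dominates, which would make the planted label wrong rather than
noisy.

What the generator does **not** emulate: segment-level autocorrelation
along chromosomes (gene copy numbers are drawn independently), tumor
purity and stromal admixture, batch effects, and — importantly —
overdispersion: counts are exactly Poisson, matching the model's own
assumption. Tests passing on these cohorts therefore demonstrate the
estimators' correctness under the stated model, not robustness to
negative-binomial noise or to decomposition artifacts in real bulk
RNA-seq.

## Numerical choices and test scales

Convergence uses L-BFGS-B's default relative-objective tolerance
(`factr = 1e7`); likelihood comparisons in tests allow $10^{-6}$ slack.
Optimizer non-convergence is carried, never hidden: affected genes keep a
`converged = FALSE` flag and a missing CNI. Likelihood-ratio statistics
are clamped at zero (with a warning beyond $10^{-6}$). All randomness
flows through explicit seeds; no function mutates global RNG state. The
packaged checks run at sizes chosen for stable statistics on a laptop:
1,000 genes for the closed-form and null-calibration checks, 50–100
replicates for recovery rates, and a 600-gene, 150-sample, 40-pathway
cohort with 1,000 resampling rounds for landscape recovery.

## A short worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 300, n_samples = 100, seed = 7,
                  n_pathways = 8, pathway_size = c(6, 10))
co <- simulate_cohort(cfg)
tb <- cni_table(co$expr, co$cn)
pw <- pathway_cni_table(tb, co$pathways, cn = co$cn)
ref <- build_reference_distributions(tb, co$pathways, co$truth$cn_drivers,
                                     co$truth$mut_drivers, co$cn,
                                     n_resamples = 200, seed = 7)
classify_quadrants(pw, calibrate_landscape(ref))
```

## Known limitations

Poisson noise understates real RNA-seq dispersion, so p-values on
overdispersed data will be anti-conservative even though the boundary
constraints pull the other way; a negative-binomial variant is the
natural extension. The transition point is undefined for flat fitted
curves and carries no confidence interval (a bootstrap would be the next
step). The landscape calibration inherits whatever biases the supplied
driver lists carry, and the group-enrichment rule is sensitive to single
strong genes by design.
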