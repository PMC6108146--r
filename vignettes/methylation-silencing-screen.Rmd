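---
title: "Methods: ER-stratified association screening and methylation silencing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ER-stratified association screening and methylation silencing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiScreen)
```

# The scientific question

Tumor suppressor genes are frequently inactivated not by mutation but by
promoter hypermethylation. For a gene such as ID4 in breast cancer, the
silencing hypothesis has three testable signatures on a public cohort of
the TCGA kind:

1. expression of the target gene differs between estrogen-receptor (ER)
   strata;
2. promoter-probe methylation (beta values) correlates negatively with
   target expression;
3. the dichotomized expression level predicts overall survival — but
   only in the stratum where silencing operates.

A fourth, exploratory signature asks *what the target gene associates
with*: scoring the target against a curated panel of breast-cancer genes
separately per ER stratum and comparing the selected sets (a Venn
partition) reveals whether the target participates in different
regulatory neighborhoods in ER+ versus ER− disease. `epiScreen`
implements all four analyses plus the wet-lab quantification math
(droplet digital PCR, MS-MLPA) used to validate methylation calls, and a
synthetic-cohort generator that plants each signature with known ground
truth so the entire chain is testable without downloads.

# The pairwise singular-value association score

For target profile $t$ and gene profile $g$ on one stratum's samples
(pairwise-complete, $n \ge 3$), both vectors are centered and scaled to
unit Euclidean norm. The $n \times 2$ matrix $M = [t, g]$ then has
cross-product matrix

$$M^\top M = \begin{pmatrix} 1 & r \\ r & 1 \end{pmatrix},$$

with $r$ the Pearson correlation, and singular values
$\{\sqrt{1+r},\, \sqrt{1-r}\}$. A conventional SVD routine returns these
sorted, which severs the link between a singular value and "its" column.
We instead orthogonalize by a single one-sided Jacobi rotation — the
angle $\theta$ solves $\tan 2\theta = 2c/(a-b)$ with $a = b = 1$,
$c = r$, so $\theta = \pi/4$, taking the positive angle as tie-break —
and read the score off the *post-rotation norm of the column in the
gene's original position*. That norm is exactly $\sqrt{1 - r}$. Two
properties follow:

- the score is invariant to affine rescaling of either input (both are
  standardized first);
- negative correlation scores highest. In silenced-gene biology this is
  the interesting direction: a methylated, down-regulated target moving
  *against* pathway genes.

A sign-agnostic alternative, $\sqrt{1 + |r|}$ (the larger singular
value), is available as `mode = "abs_correlation"` for questions where
the direction is irrelevant. The default stays `"jacobi_position"`
because it makes the score's ranking transparent in $r$ and matches the
fact that strata-specific hits of interest here are anticorrelated.

Both modes are pairwise (one gene at a time against the target). A
one-sided Jacobi sweep over the full 67-column system would be a natural
extension but changes the question (joint versus marginal association);
it is deliberately not implemented.

## Selection rule and the choice of quantile

Within each stratum, the threshold is a quantile (default 0.5, the
median) of that stratum's 66 scores, and a gene is selected only if its
score is *strictly greater* — ties at the threshold are excluded, which
also makes the all-tied degenerate case select nothing.

The quantile is a free parameter for a structural reason: a strict
above-median rule in each of two strata, followed by a union, selects at
least half of the panel whenever scores are distinct — it can never
produce a small hit list like 12 or 15 genes out of 66. When the goal is
to recover a planted set of $k$ associated genes from a panel of $m$,
the threshold belongs at the planted-fraction boundary,
$q = 1 - k/m$. The package's recovery experiments (see below) plant 12
associated genes in the larger stratum of a 66-gene panel and therefore
screen at $q = 1 - 12/66 \approx 0.818$; this value is derived from the
design arithmetic, not fitted. For exploratory use on real cohorts the
median default errs on the inclusive side.

# Group statistics

- `studentTTest` is the pooled-variance test (Welch behind a flag),
  two-sided. Zero-variance corner cases follow fixed conventions
  ($t = 0, p = 1$ for equal means; $p \to 0$, flagged, otherwise).
- `oneWayAnova` is the classical fixed-effects F; on two groups
  $F = t^2$ exactly, which the tests exploit as an identity check.
- `bonferroniAdjust` is $\min(1, m p)$.
- `wilcoxonRankSum` uses midranks and computes the two-sided p *by full
  enumeration* of rank assignments whenever $n_1 + n_2 \le 12$ — unlike
  the textbook exact distribution, enumeration remains valid under ties.
  The crossover at 12 keeps the worst case at $\binom{12}{6} = 924$
  subsets. Beyond it, the normal approximation with tie and continuity
  corrections takes over.
- `probeCorrelationPanel` reports raw per-probe p-values (the way
  per-probe methylation browsers display them) with an opt-in
  Benjamini–Hochberg column; probes with fewer than 3 complete pairs or
  constant values are reported as missing with a reason rather than
  dropped.

# Survival conventions

`dichotomizeByMedian` labels "high" strictly above the sample median;
values equal to the median go to "low". Some convention is required —
public survival tools do not document theirs — and the strict rule keeps
the high arm unambiguous under heavy ties. Medians are computed *within
stratum*, since the strata are analyzed as separate cohorts.
Kaplan–Meier estimation and the log-rank test follow the standard
conventions (events precede censoring at tied times; hypergeometric
expectation and variance per event time, $\chi^2$ on 1 df) and are
computed through the `survival` package, with the package's tests
checking them against independent hand-rolled oracles (the empirical
survival function without censoring; a brute-force walk of the
$2 \times 2$ tables). No hazard-ratio model is fitted: hazard ratios
exist only as generator ground truth.

# Molecular quantification

Droplet digital PCR: with $\hat p$ the positive-droplet fraction, the
Poisson correction $\lambda = -\ln(1 - \hat p)$ undoes multiple template
occupancy, and concentration is $\lambda$ over the droplet volume. The
volume defaults to 0.85 nl — the de-facto constant of the QX200 system —
and is configurable, since "copies per microliter" is meaningless
without it. The 95% CI is the binomial Wilson interval on $\hat p$
mapped through $-\ln(1-\cdot)$, which is monotone, so coverage is
inherited. Saturated wells ($\hat p = 1$) return a flagged lower bound
from $(n - \tfrac12)/n$ instead of throwing, matching instrument
software behavior; technical replicates combine as the mean of
per-replicate concentrations.

MS-MLPA: the methylation dosage ratio is
$(T_d / R_d)\,/\,(T_u / R_u)$ for target/reference signals in the
digested/undigested reactions, with the mean over reference probes when
several are given; a site is called methylated strictly above the 8%
cutoff. The ddMSP methylated/unmethylated ratio is taken between
parallel reactions' concentrations; a zero unmethylated concentration is
an explicit error, not infinity.

# The synthetic cohort generator

`generateCohort` realizes the three signatures with closed-form,
recoverable ground truth:

- **Expression.** Per stratum, a latent standard normal $z$ drives the
  target; each panel gene is $r z + \sqrt{1-r^2}\,\varepsilon$ with its
  planted correlation $r$ (zero for null genes) — a one-factor Gaussian
  copula, positive definite for any $|r| < 1$, with exact population
  correlation to the target. Margins are scaled by `noiseSD` (default
  1.0 log2 units, a typical within-stratum spread for a moderately
  expressed transcript) around a baseline mean of 8, and the target mean
  shifts by `targetShift` (default −1.5 log2 in ER+, the silencing
  direction).
- **Methylation.** Promoter-probe betas are a logistic squash
  $\mathrm{plogis}(\mu_i + 0.8\,\ell)$ of a latent
  $\ell = \rho\,\tilde t + \sqrt{1-\rho^2}\,\varepsilon$ tied to the
  *cohort-wide standardized* target expression $\tilde t$ at
  $\rho$ = `methExprCorrelation` (default −0.4). Tying to the pooled
  profile rather than within-stratum noise means ER+ samples — whose
  target expression is shifted down — automatically carry higher betas,
  which is the silencing geometry, and the pooled correlation realizes
  the planted value. The squash keeps betas strictly inside (0,1) and
  attenuates the correlation slightly (the scale 0.8 keeps the squash
  near-linear over ±2 SD); the *realized* per-probe correlations are
  returned in the ground-truth object so tests assert against what was
  actually attained. Gene-body probes are independent noise with varied
  offsets. Defaults simulate 5 promoter and 8 body probes, the probe
  count of a typical 450K gene neighborhood.
- **Survival.** Within each stratum the high arm is target expression
  strictly above the stratum median — deliberately the same rule the
  survival module applies, so recovery tests are internally consistent.
  Event times are exponential at `baselineHazard` × HR^high (defaults:
  0.005/month baseline, i.e. median ~11.5 years, breast-cancer-like; HR
  0.5 protective in ER+ and 1.0 in ER−), censoring exponential at
  0.01/month (median follow-up ~6 years). Exponential forms are chosen
  for closed-form expectations when sizing test tolerances.
- **Sample sizes** default to 601 ER+ / 179 ER−, the composition of the
  motivating cohort; ER status is assigned directly (never inferred from
  ESR1-like expression), and PAM50 labels are drawn from stratum-typical
  mixtures as covariate dressing.

Everything derives from one seed; two runs with equal configs are
bit-identical (R's default Mersenne–Twister, single-threaded draws in
fixed order).

What the generator does **not** emulate: 450K probe geometry and
type-I/II chemistry, tumor purity and cellularity, copy number, batch
effects, non-Gaussian expression margins, and informative censoring.
Passing recovery tests therefore demonstrates the *estimators* are
correct and powered under the planted model — not that real TCGA data
satisfy that model.

# Test and experiment sizes

The packaged experiments are sized to be decisive yet quick: 1,000
random pairs (n = 50) for the closed-form score oracle; 100 seeded
cohorts of 500 samples per stratum for screen recovery (12 planted
stratum-A genes, 9 stratum-B, 6 of them shared, all at $|r| = 0.4$,
screened at $q = 1 - 12/66$); one 600-sample cohort for promoter
correlation recovery (tolerance ±0.1 around −0.4, about three sampling
SDs plus squash attenuation); 100 seeded cohorts of 300 per stratum for
survival power/size; 200 droplet simulations at $\lambda = 1.2$,
n = 20,000 (delta-method SE ≈ 0.011, so ±2% is ≈ 2.2 SE). Null-size
checks use 1,000 replicates with a ±0.02 band around 0.05.

# Known limitations

- The screen is marginal (pairwise); correlated panel genes select
  together, and no multiplicity adjustment is applied to the selection
  itself (the quantile rule fixes the selected *count*, not an error
  rate).
- Exact reproduction of p-values from public web survival tools is not
  expected: their median-tie handling and follow-up truncation are
  undocumented, and this package's conventions are explicit substitutes.
- The exact Wilcoxon path is $O\!\binom{N}{n_1}$ and intentionally
  capped at $N = 12$.
- `readClinicalTable` maps unrecognized categorical values to
  `"unknown"` rather than failing; stratified analyses exclude the
  `"unknown"` level, so silently mis-encoded columns shrink strata —
  the warning count is the guard rail.
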