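---
title: "Models and design choices in drugsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in drugsynergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsynergy)
```

This vignette documents the statistical models the package implements,
the assumptions behind them, the tunable parameters and their defaults,
and the design decisions taken where the underlying methods left a
choice open. It is the methods reference; the README shows the
workflow.

## Dose-response model

Monotherapy viability is modelled with the four-parameter log-logistic
(LL4) curve $f(x) = c + (d - c)/(1 + (x/e)^b)$. The orientation is
fixed so that $d$ is the zero-dose asymptote: with a %viability
readout normalised to untreated controls, $d$ sits near 100 and the
curve is non-increasing for $b > 0$.

Fitting minimises the residual sum of squares under box constraints
($b \in [0.2, 10]$, $0 \le c, d \le 120$, $e$ within one decade of the
observed nonzero dose range), with a soft penalty keeping $c \le d$.
Because the RSS surface of log-logistic models is multimodal in
$(b, e)$, the optimiser multi-starts over a 7-point log-spaced $e$ grid
crossed with slopes $\{0.5, 1, 2, 4\}$; the best RSS wins, ties broken
by the smaller slope and then the smaller inflection dose, which makes
the fit a deterministic function of the data. A derivative-free polish
follows the gradient-based pass, because L-BFGS-B aborts its line
search on numerically perfect fits; the convergence flag reflects the
polished state. At least 4 distinct nonzero doses are required; flat
responses return a degenerate fit flagged as non-converged.

Outlier handling is a single pass: points whose standardized residual
exceeds 3 (default) residual SDs are removed and the curve refitted
once — no iterative trimming, so one gross outlier cannot cascade into
mass deletion. If removal would leave fewer than 4 distinct nonzero
doses the original fit is kept with a warning.

Two IC50 definitions are exposed because usage varies: the *relative*
IC50 is the inflection dose $e$ (always defined for a converged fit)
and is the package default, since reduced-dose combination designs
(IC50/2, IC50/3) need a dose that always exists; the *absolute* IC50
solves $f(x) = 50$ and exists only when the asymptotes straddle 50%.

## Synergy reference models

All three surface scores are reported in percentage points of
viability over the nonzero-dose cells, with the sign convention that
*lower observed viability than the null expectation is positive
(synergy)*. Replicates are averaged per cell before scoring.

- **Bliss.** The independence null multiplies fractional marginal
  viabilities: $\delta = 100\,(f_A f_B - f_{obs})$. No fitting is
  involved, so this score is exact on its own null construction.
- **ZIP.** Margins are fitted on the fractional-inhibition scale with
  two-parameter log-logistic curves (asymptotes fixed at 0 and 1, the
  standard ZIP assumption); each row and column of the combination is
  then refitted with its zero-dose asymptote pinned to the partner's
  fitted effect, and the cell score is the mean of the row- and
  column-conditional fits minus the independence expectation
  $y_A + y_B - y_A y_B$. This captures potency shifts induced by the
  partner drug. Margins with fewer than 4 nonzero doses cannot support
  the fits; the scorer then falls back to Bliss with a warning.
- **Loewe.** The additive expectation $y^*$ solves the dose
  equivalence equation $x_1/D_1(y^*) + x_2/D_2(y^*) = 1$, where
  $D_i$ inverts drug $i$'s fitted LL4 curve. The equation is solved by
  bisection on $y$ within the overlap of the fitted effect ranges
  (tolerance $10^{-6}$ percentage points, at most 200 iterations —
  the function is monotone in $y$, so bisection is guaranteed).
  Dose pairs outside the attainable range are clamped to the nearest
  attainable effect and flagged per cell. The defining property —
  a drug sham-combined with itself scores exactly additive — holds by
  construction and is tested.

Summary scores follow the common interpretation rule (within
$[-10, 10]$ additive, above 10 synergistic, below $-10$ antagonistic;
boundaries map to additive), and the reported peak is the maximal mean
over contiguous 3×3 dose windows ("most synergistic area"). A 3×3
window was chosen over the single-cell maximum because single cells of
noisy surfaces overstate peaks; ties break toward the lowest dose
indices so the peak is deterministic.

## The reduced-dose Bliss statistic

For $k$ drugs each given at IC50/$k$, the expected combination
viability under independence is the geometric mean of the single-agent
viabilities measured at their full IC50s:
$E_{exp} = (\prod_i E_i)^{1/k}$, which for two drugs is exactly
$\sqrt{E_A}\sqrt{E_B}$. The underlying approximation is that a $1/k$
dose of a drug yields roughly the $k$-th root of its full-dose
fractional viability — exact for an exponential kill curve, and a
reasonable working rule near the IC50. The three-drug form is the
natural extension of the two-drug rule; only the two-drug case has a
canonical published form, so the generalisation is a package decision.
$S_{bliss} = E_{exp} - E_{obs}$, positive = synergy. Inputs are
fractions in $[0, 1]$; percent inputs are divided by 100 with a
warning rather than rejected, because both conventions circulate.

## Proteomic preprocessing

Two preprocessing paths mirror the two statistical routes.

The *Perseus-style* path log2-transforms, keeps features with at least
`min_valid = 4` observed values in at least one sample group, and
imputes every remaining missing value from a left-shifted normal per
sample column (centre = column mean − 1.8 column SDs, width = 0.3
column SDs — the conventional defaults for left-censored label-free
data, exposed as arguments since they are a convention, not a fact of
the data). The default grouping pairs each treatment condition with
the control (3 + 3 samples), matching a treatment-versus-control
analysis.

The *regression* path treats zero intensities as missing, filters on
at least `min_valid` observed values within a single drug-treatment
condition, median-centres each sample, and imputes in two stages:
condition-specific draws (observed mean/SD of that condition) where a
feature is quantified in more than half of a condition's samples, and
sample-wise tail draws elsewhere. The printed cutoff of 4 valid values
presumes conditions with more than 4 samples; with triplicate
conditions the analysis uses `min_valid = 2`, the same "more than
half" logic the imputation rule uses. Per-sample medians are computed
over observed values by default; a `zeros_as_values` compatibility
mode reproduces pipelines that reassign missing values to zero before
centering, which drags medians toward zero in heavily censored
samples and is therefore not the default. Both modes are tested.
Observed values are never modified by any imputation path — only the
log2 transform and the per-sample centering shift touch them — and a
provenance code per value records how it was filled.

Phosphosite intensities are normalised to total-protein abundance by
per-sample subtraction of the parent protein's log2 abundance (the
ratio interpretation on the raw scale). Subtraction keeps contrast
estimates interpretable as changes in phosphorylation stoichiometry;
sites without a quantified parent pass through flagged rather than
dropped.

## Differential statistics

The **treatment model** is per-feature OLS on condition indicators
with the control as reference (`~ treatment`); in the balanced
6-condition × 3-replicate design each coefficient is a condition mean
minus the control mean, and the residual degrees of freedom are
$18 - 6 = 12$.

The **synergy contrast** $L = \beta_{MD} - \beta_M - \beta_D$ equals
$MD - M - D + CTRL$ in cell means — the only control-consistent
reading of "combination versus the sum of the single treatments" under
a control-referenced design, and zero whenever drug effects are
additive on the log2 scale. Residual variances are moderated by
empirical Bayes: a scaled inverse-chi-square prior $(d_0, v_0)$ is
fitted by method of moments on the log residual variances (with the
Fisher-information correction terms), the posterior variance is
$(d_0 v_0 + d s^2)/(d_0 + d)$, and the moderated $t$ has $d_0 + d$
degrees of freedom. When the observed variances are underdispersed
relative to sampling noise the prior degenerates ($d_0 = \infty$) and
every feature uses $v_0$. Multiple testing uses Benjamini–Hochberg,
the convention for this moderated-model route; the signature applies
strict thresholds (adj p < 0.05, logFC > 0 for upregulation).

The **SAM-style one-sample test** forms replicate-wise differences of
a treatment against the reference-condition mean and computes
$d = \bar{\Delta}/(SE + s_0)$ with fudge factor $s_0 = 0.1$ by
default; $s_0 = 0$ recovers the ordinary one-sample $t$. Significance
comes from label permutations between treatment and reference (default
250, seeded) and q-values follow the SAM permutation-FDR construction:
median null exceedance count over observed exceedance count at each
observed $|d|$ cutoff, made monotone. Permutation FDR is used here —
rather than BH — because it is the native convention of this test
family.

## Enrichment

Pre-ranked gene-set enrichment uses the weighted Kolmogorov–Smirnov
running sum with weight exponent 1 (hits advance proportionally to the
absolute ranking statistic). The null is built by random member-set
sampling of equal size (the appropriate null for pre-ranked input),
p-values use add-one smoothing against the same-sign null scores — so
no p-value is ever zero and null p-values are uniform — and NES
divides ES by the mean absolute same-sign null ES. Defaults:
`min_size = 3` (the smallest meaningful kinase-substrate set),
`n_perm = 1000`, flagging at BH-adjusted p ≤ 0.1. The ranking metric
(moderated $t$ by default, logFC as an alternative) is exposed because
conventions differ between kinase-activity and pathway analyses; ties
break by feature id so rankings are deterministic.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes, and
its defaults *are* those conditions:

- three drugs with Hill-type curves at realistic potencies (IC50s of
  500, 100 and 5 nM; slopes 1–1.5; full asymptotes), dose grids of 8
  nonzero doses log2-spaced from IC50/32 to 4×IC50 — the span a
  checkerboard centred on the IC50 would use;
- triplicate measurements with multiplicative Gaussian noise
  (`noise_cv = 0.05`, a typical luminescence CV), truncated so
  viability stays non-negative, because luminescence scales with
  signal;
- combination surfaces built as the Bliss product (independent mode),
  with a uniform δ percentage points subtracted/added on combination
  cells (synergy/antagonism; δ applied uniformly is the simplest
  controllable truth), or satisfying the Loewe equation exactly; a δ
  that would clamp more than half of the combination cells is refused
  as a degenerate truth;
- a 6-condition (CTRL, M, D, V, MD, MDV) × 3-replicate log2 intensity
  matrix: baselines N(25, 3²) on the log2 scale, single-drug effects
  N(0, 1) in 10% of features, additive combination means (MD = M + D,
  MDV = M + D + V in effects) except for a 10% combination-specific
  fraction, replicate noise SD 0.3 log2 units (~23% CV, typical of
  label-free quantitation);
- left-censored missingness: each value goes missing with probability
  $\mathrm{logit}^{-1}(-(x - loc)/scale)$, location at the 25th
  intensity percentile and scale 1, which yields 15–25% overall
  missingness concentrated in low-abundance features, as in real LFQ
  data.

The planted combination-specific effect defaults to **+1.2 log2 units
(a ~2.3-fold induction), which is twice the replicate-level SD of the
interaction contrast** ($MD - M - D + CTRL$ has SD $2\sigma = 0.6$
across replicates at $\sigma = 0.3$). The effect is calibrated against
the contrast's own replicate SD rather than the raw per-measurement SD
because the contrast is the quantity the analysis tests: a power
analysis at the triplicate design shows an effect of $2\sigma$ (0.6)
gives the contrast a noncentrality of only $\sqrt{3}$, undetectable at
any useful sensitivity after FDR control, whereas $2 \times 2\sigma$
gives noncentrality $2\sqrt{3} \approx 3.5$, the detectability regime
a recovery benchmark needs. Combination-specific effects are planted
as upregulation on MD and MDV only, matching the signature definition
(upregulated proteins).

Determinism: every generator is a pure function of its configuration;
the root seed feeds named substreams per generator (and the
checkerboard margins reuse the monotherapy substreams, so margins
reproduce the monotherapy simulations exactly). Re-running any stage
never perturbs another stage's draws.

What the generator does **not** emulate: plate-position and edge
effects, luminescence saturation, peptide-level identification and
roll-up, match-between-runs artifacts, correlated noise across
features, and batch structure. Passing recovery tests on this
generator therefore demonstrates correctness of the statistical
machinery under the stated model, not robustness to those real-data
pathologies.

## Problem sizes and validation strategy

The test and acceptance simulations use problem sizes chosen to make
Monte-Carlo error small relative to the margins being tested: 1000
features × 50 seeds for null calibration, 1000 features × 10 seeds for
contrast recovery, 100 curves for dose-response recovery, 5 seeds per
δ level for synergy recovery, and 200 seeds for enrichment null
uniformity.

Contrast recovery (true-discovery proportion and sensitivity of the
signature) is measured on the *complete* pre-censoring matrices, which
isolates the statistical operation under test. This matters: imputed
values violate the variance-exchangeability assumption behind
empirical-Bayes moderation, so on censored matrices the realised false
discovery proportion of the full pipeline exceeds the nominal level —
a known limitation of impute-then-moderate workflows that users should
weigh when interpreting signatures from heavily censored data. The
imputation paths themselves are validated separately for rule
correctness, observed-value preservation and null calibration.

## Known limitations

- The LL4 fitter assumes monotone dose response; biphasic (hormetic)
  curves are out of scope.
- ZIP conditional fits need informative rows/columns; very flat
  margins leave the potency shift weakly identified and the score
  reverts toward the independence expectation.
- The reduced-dose expected effect rests on the $E^{1/k}$ dose-scaling
  approximation; drugs with very steep Hill slopes will deviate.
- Permutation resolution bounds SAM and enrichment p-values at
  $1/(1 + n_{perm})$; with 3+3 samples only 20 distinct label splits
  exist, so SAM q-values are coarse and conservative.
- No HSA model, no full three-drug response surfaces (three-drug
  combinations are assessed only through the reduced-dose statistic),
  and no network/PPI enrichment.
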