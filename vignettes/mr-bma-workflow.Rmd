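---
title: "Bidirectional MR screening and Bayesian model averaging with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional MR screening and Bayesian model averaging with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`mrscreen` implements a two-stage causal screen over GWAS summary
statistics. The motivating design is a panel of correlated molecular
exposures — for example 41 circulating cytokines measured in a Finnish
cohort of 8,293 individuals — screened against binary disease outcomes
such as digestive-tract polyps (gastric polyp: 6,155 cases vs 341,871
controls). Stage one is a *bidirectional univariable* two-sample Mendelian
randomization (MR) screen over every exposure-outcome pair; stage two is a
*multivariable* Bayesian model-averaging analysis (MR-BMA) that asks which
of the univariably significant, mutually correlated exposures carry the
direct causal signal.

Throughout, effect sizes for binary traits are on the log-odds scale and
for quantitative traits in SD units; per-SNP summary rows are
\((\hat\gamma_j, \sigma_{Xj})\) for the exposure and
\((\hat\Gamma_j, \sigma_{Yj})\) for the outcome.

```{r setup}
library(mrscreen)
```

## Instrument selection and harmonization

Instruments are variants with \(p \le 5\times10^{-8}\); exposures with
fewer than `min_snps = 3` surviving instruments fall back to
\(p \le 5\times10^{-6}\) (three is the minimum for the Egger and
weighted-median estimators to be meaningful — the trigger count is a
package choice, made once). Clumping is greedy by ascending p-value inside
a 10,000-kb window (inclusive: \(|pos_i - pos_j| \le\) `clump_kb`
\(\times 1000\)), with ties broken by chromosome, position, then variant
id so the result is independent of input row order. The package never
queries an external LD reference: when an LD matrix is supplied, a
within-window pair survives if its \(r^2 \le 0.001\); when it is not,
distance alone decides, which is strictly more conservative. A pair
present in the window but absent from a supplied matrix is treated as
unresolved and clumped.

Harmonization aligns every other table to the exposure's effect allele:
identical alleles pass through, swapped alleles negate the beta and flip
the allele frequency, anything else is dropped as a mismatch. Palindromic
(A/T, C/G) variants are dropped unconditionally — strand cannot be
resolved from alleles alone, and no frequency-based rescue is attempted.
Every drop carries a machine-readable reason code.

Instrument strength is reported per SNP as the single-variant Wald form
\(F = (\hat\gamma/\sigma_X)^2\) with \(R^2 = F/(F + n - 2)\), plus the
allele-frequency form \(2\,\mathrm{eaf}(1-\mathrm{eaf})\hat\gamma^2\)
when frequencies are available; \(F < 10\) marks a conventionally weak
instrument. Both per-SNP values and their summary are available because
reported aggregate F statistics in the literature are often ambiguous
between the two.

## Univariable estimators

All univariable estimators are built on per-SNP Wald ratios
\(\hat\beta_j = \hat\Gamma_j/\hat\gamma_j\) with first-order SEs
\(\sigma_{Yj}/|\hat\gamma_j|\).

* **IVW**: \(\hat\beta = \sum w_j\hat\beta_j / \sum w_j\) with
  \(w_j = \hat\gamma_j^2/\sigma_{Yj}^2\), identical to the no-intercept
  weighted regression of \(\hat\Gamma\) on \(\hat\gamma\). Cochran's
  \(Q = \sum w_j(\hat\beta_j - \hat\beta)^2\) on \(J-1\) df selects the
  model: fixed-effect SE when the heterogeneity p exceeds 0.05, otherwise
  a multiplicative random-effects SE
  \(\mathrm{se}_F\sqrt{\max(1, Q/(J-1))}\). The point estimate is the
  same under both; only the SE grows.
* **MR-Egger**: instruments are re-oriented so \(\hat\gamma_j > 0\), then
  \(\hat\Gamma\) is regressed on \(\hat\gamma\) *with* an intercept
  (weights \(1/\sigma_Y^2\)). The intercept estimates average directional
  pleiotropy; inference uses \(t_{J-2}\) with the residual dispersion
  floored at 1. The floor makes the test conservative in exactly-specified
  data and exact under genuine overdispersion (which balanced pleiotropy
  produces), a property the calibration tests exploit.
* **Weighted median**: the midpoint-cumulative-weight interpolated median
  of the ratio estimates (\(s^*_j = s_{j-1} + w_j/2\) on normalized
  weights; conventions differ, so the package states its own). The SE is
  a parametric bootstrap — ratios resampled from
  \(N(\hat\beta_j, se_j)\), weights fixed, default 1000 draws — with a
  mandatory explicit seed.
* **Leave-one-out**: J re-fitted IVW estimates, each omitting one
  instrument, flagging rows whose CI lands entirely on the opposite side
  of zero from the full estimate.

IVW and weighted-median CIs use normal quantiles, Egger uses
\(t_{J-2}\): that matches the estimators' original formulations, and the
published values the package round-trips (via `wald_from_or_ci()`) are
normal-quantile constructions. Nominal p-values are primary; a Bonferroni
column is emitted across the screen but never gates anything.

The bidirectional screen runs every ordered pair in both directions and
always completes: pairs that fail instrument selection or harmonization
become rows with a reason code, never silent omissions.

## MR-BMA

With K gated exposures and the union of their instruments (rows missing
any factor's beta are dropped and listed), each candidate model is a
subset \(S\) of factors. On the inverse-variance weighted scale
(\(\tilde y_j = \hat\Gamma_j/\sigma_{Yj}\), row j of the design scaled the
same way) the scoring model is Bayesian linear regression without
intercept, residual variance 1, independent \(N(0, \sigma^2)\) priors
(\(\sigma^2 = 0.25\)) on coefficients of *unit-norm* factor columns, and
an independent-inclusion model prior (\(p = 0.1\)):

\[
\log ML(S) = -\tfrac12\Big[\log\det(I + \sigma^2 X_S^\top X_S)
  + \tilde y^\top \tilde y
  - \sigma^2 \tilde y^\top X_S (I + \sigma^2 X_S^\top X_S)^{-1}
    X_S^\top \tilde y\Big].
\]

One scaling choice deserves emphasis. Scaling factor columns to unit norm
puts all factors on an equal footing under the shared prior. Scaling the
*outcome* vector to unit norm as well — a symmetric-looking choice — would
cap the fit term of the Bayes factor at \(\sigma^2/(1+\sigma^2) = 0.2\),
below the \(\log(1+\sigma^2) = 0.223\) complexity penalty, so no model
could ever beat the null no matter how strong the signal. The outcome
therefore stays on the weighted z-score scale, which is also the scale on
which "residual variance 1" is actually true. The test-suite pins this
down from both sides: under a pure null the mean marginal inclusion
probability stays at the prior (≈ 0.1), and with one causal factor its
MIP goes to 1.

All \(2^K - 1\) non-empty models (plus the null baseline) are enumerated
exhaustively — exact and deterministic at screen scale, guarded against
\(K > 20\) without a size cap — rather than stochastically searched.
Posterior probabilities are normalized across all of them; per factor,
MIP is the summed PP of models containing it and MACE the PP-weighted
average of its model-specific estimates (MSCE, the posterior-mean
coefficient mapped back to the original scale). MACE is shrunk toward
zero by construction, doubly so here because the \(\sigma^2 = 0.25\)
prior on unit-norm columns is deliberately tight; rankings, not effect
magnitudes, are the estimand of this stage. An optional permutation
p-value per factor (outcome associations permuted across instruments,
default 10,000 replicates when enabled, off by default) quantifies how
often chance alone reaches the observed MIP.

### Outlier diagnostics

For each reported top model the per-instrument heterogeneity contribution
is \(q_j = (\tilde y_j - \hat{\tilde y}_j)^2\), observed minus predicted
on the z-score scale, and Cook's distance comes from the same weighted
fit. Predictions use the model's unpenalized WLS coefficients: the
shrunken posterior means would leak causal signal into every residual and
swamp the \(q > 10\) rule. Flagging takes the *minimum* of each statistic
across the top models — an instrument must be outlying under every
well-supported model — and by default only the Q rule
(\(\min_m q_j > 10\)) gates removal. Cook's distance (threshold \(4/J\)
by default, configurable to a fixed value such as \(6/67 \approx 0.09\))
is reported alongside and can be combined via `flag_rule = "and"` or
`"or"`. Two empirical facts drove this default, both reproducible in the
test suite: the plain \(4/J\) rule alone habitually flags several
unremarkable instruments (it is an upper-order-statistic of leverage
times residual), and a gross outlier at a low-leverage position barely
moves the fit, so its Cook's distance can be negligible while its q is in
the hundreds. Removal happens exactly once: flagged instruments are
dropped and the ranking re-run on the remainder, with both passes
retained and labeled.

## The synthetic-data generator

`simulate_gwas()` emulates the structure the analysis assumes, with
defaults set to the study conditions above: quantitative exposure panel
with n = 8,293; binary outcome with 6,155/341,871 cases/controls and SEs
from the effective sample size \(n_\mathrm{eff} = 4/(1/\mathrm{cases} +
1/\mathrm{controls})\) via \(\sigma_Y \approx
1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n_\mathrm{eff}}\); per-SNP
exposure SEs \(1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}\) for a
standardized phenotype; MAF uniform on (0.1, 0.5). Each instrument has one
primary exposure with true z-score drawn uniformly from (10, 20) — per-SNP
F of 100–400, matching panels whose instruments all clear F > 10 — and
with configurable probability also affects one other exposure (measured
pleiotropy). Direct instrument-outcome effects can be none, balanced
(\(\alpha_j \sim N(0, s^2)\)) or directional (\(\alpha_j \sim N(s,
(s/2)^2)\)); outliers add a configured multiple of \(\sigma_{Yj}\) to the
outcome beta; filler null SNPs carry no true effects. Instruments sit on a
deterministic genomic grid 11 Mb apart (one clump window plus margin) so
selection is decoupled from LD unless compound-symmetric LD blocks are
explicitly requested. Everything is reproducible from a single seed, to
the byte, in written files.

What the generator does *not* emulate: realistic human LD maps,
winner's-curse bias in instrument discovery, sample overlap between the
two GWAS, allele-frequency-dependent effect-size architecture, and
population stratification. Passing recovery tests therefore demonstrate
the estimators' correctness under the stated model, not robustness to
those real-data pathologies.

The canonical fixtures (`fixture_config()`): a 41-exposure x 3-outcome
screen shape; a 6-factor, 67-instrument multivariable dataset with one
planted 10-\(\sigma_Y\) outlier and one weakly causal factor
(\(\theta_1 = 0.1\), chosen at the scale of published cytokine-polyp
MSCEs, with a narrow instrument-strength band z in (12, 15)); and
degenerate cases (single instrument, all-palindromic, no significant
SNPs).

## Numerical and design choices

* Coordinates are 1-based; the clump window is inclusive.
* Equal clumping p-values break ties by (chromosome, position, id).
* `bma_rank()` accepts K = 1, where the single factor's MIP reduces to
  the two-model closed form \(p\,ML_1/(p\,ML_1 + (1-p)\,ML_0)\).
* \(I + \sigma^2 X_S^\top X_S\) is positive definite for every
  \(\sigma^2 > 0\); there is no singular path.
* The residual-dispersion floor in Egger SEs is at 1 (never deflate).
* The multivariable gate (forward IVW p < 0.05) runs only when at least
  two exposures pass; otherwise the stage is skipped with a logged
  reason.
* The pipeline writes no timestamps; identical config and seed reproduce
  every output byte for byte, and the manifest echoes all eleven
  workflow parameters plus seed and package version.

Problem sizes in the shipped tests were chosen to make the statistical
checks sharp but quick: 400 reverse-direction null tests, 1000 Egger
size replicates, 200 replicates each for prior calibration (J = 60,
K = 6) and one-causal recovery, 60-plus-seed scans for the outlier rule.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  n_exposures = 4, instruments_per_exposure = 8,
  n_outcome_traits = 1, outcome_instruments = 5,
  shared_instrument_fraction = 0.9, shared_effect_scale = 0.8,
  true_causal = c(0.25, 0, 0, 0), n_null_snps = 20, seed = 7)
sim <- simulate_gwas(cfg)

iv <- select_instruments(sim$exposures[[1]])
h  <- harmonize(iv, sim$outcomes[[1]])
mr_ivw(h)$estimate

sets <- lapply(sim$exposures, select_instruments)
hm <- harmonize(sets, sim$outcomes[[1]], exposure_tables = sim$exposures)
bma_with_outlier_removal(hm, bma_config())
```

## Known limitations

* No MR-PRESSO, mode-based, Steiger or contamination-mixture methods.
* No proxy-SNP lookup, liftover, multi-allelic handling or remote LD
  reference; LD is user-supplied or absent.
* The MR-BMA stage assumes uncorrelated instruments (no LD-aware
  extension) and exhaustive enumeration bounds K.
* MACE magnitudes are strongly prior-shrunk by design; interpret
  rankings and MIPs, or re-fit selected models by WLS for effect sizes.
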