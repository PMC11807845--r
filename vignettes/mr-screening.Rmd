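---
title: "Screening many exposures with two-sample Mendelian randomization"
author: "mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening many exposures with two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Two-sample Mendelian randomization (MR) asks whether an exposure causes an
outcome by using genetic variants as instrumental variables: because alleles
are assorted at conception, a variant that robustly shifts the exposure and
satisfies the exclusion restriction shifts the outcome only through the
exposure. `mrscreen` implements the whole screening workflow used in
phenome-style scans where a few hundred exposure GWAS (for example the 206
white-matter structural-connectivity traits of the GCST90302648-GCST90302853
GWAS Catalog series) are screened against one disease outcome (such as
Alzheimer's disease, ebi-a-GCST90027158) from summary statistics alone, plus
a synthetic summary-statistics generator so that every stage of the pipeline
can be validated against a known truth without any external download.

## The model

For instrument $j$ let $\hat\gamma_j$ (SE $\sigma_{xj}$) be its estimated
effect on the exposure and $\hat\Gamma_j$ (SE $\sigma_{yj}$) its estimated
effect on the outcome, both expressed per copy of the same effect allele.
Each instrument yields a Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard error
$\sigma_{yj}/|\hat\gamma_j|$ and weight $w_j$ equal to its inverse variance.
The five estimators combine these ratios differently:

* **IVW**: $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, the
  inverse-variance weighted mean, equal to the slope of the zero-intercept
  weighted regression of $\hat\Gamma$ on $\hat\gamma$. The fixed-effect SE
  is $(\sum w_j)^{-1/2}$; when Cochran's Q rejects homogeneity at 0.05 the
  multiplicative random-effects SE, scaled by $\max(1, \sqrt{Q/(K-1)})$, is
  used instead (`model = "auto"`).
* **MR-Egger**: weighted least squares of $\hat\Gamma$ on $\hat\gamma$ with
  a free intercept after orienting every instrument to $\hat\gamma_j \ge 0$.
  The slope estimates the causal effect under InSIDE; the intercept
  estimates the average directional pleiotropic effect, and its two-sided
  test is the pleiotropy diagnostic. Both SEs carry the same multiplicative
  heterogeneity scale, floored at 1.
* **Weighted median**: the value at which the cumulative normalized weight
  of the ordered ratios crosses one half (linear interpolation between the
  bracketing ratios); consistent while valid instruments carry more than
  half the weight.
* **Simple and weighted mode**: the argmax of a Gaussian-kernel density of
  the ratios on a 512-point grid spanning the ratios plus/minus three
  bandwidths, with equal or inverse-variance weights.

The outcome is treated as a log-odds scale trait, so every estimate is
reported with $\mathrm{OR} = e^{\hat\theta}$ and a 95% interval
$\hat\theta \pm 1.96\,\mathrm{SE}$.

Instrument strength is quantified per variant by
$R^2 = \beta^2 / (\beta^2 + \mathrm{SE}^2 N)$ — the standard
summary-statistic form in which the $2\,\mathrm{EAF}(1-\mathrm{EAF})$
factor cancels exactly between numerator and denominator — and
$F = [(N - K - 1)/K] \cdot R^2/(1 - R^2)$; variants with $F < 10$ are
treated as weak and removed.

## The screening procedure

`screen_exposure()` runs, in order: candidate selection at $p < 5\times
10^{-6}$; greedy LD clumping (window 10,000 kb, $r^2 < 0.001$, sweep by
ascending p-value, cross-chromosome pairs never clumped); the weak
instrument filter; harmonization onto the exposure's effect-allele frame
(swapped alleles negate the outcome effect, complementary alleles are
strand-flipped first, palindromic A/T and C/G variants are removed
unconditionally with no frequency-based rescue); the five estimators; and
the sensitivity battery. The decision rule is sequential and stops at the
first failure:

1. exclude if the IVW p-value is at least 0.05 (`ivw_not_significant`);
2. exclude if the five odds ratios do not lie strictly on one side of 1
   (`direction_inconsistent`; an OR exactly 1 fails);
3. exclude if either Cochran's Q (IVW form, $K-1$ df) or the Rücker Q'
   about the Egger fit ($K-2$ df) has $p < 0.05$ (`heterogeneity`);
4. exclude if the Egger intercept test has $p < 0.05$ (`pleiotropy`);
5. exclude if the leave-one-out IVW estimates are not sign- and
   significance-stable (`loo_unstable`);
6. otherwise retain, classing the exposure as a risk factor (all ORs
   above 1) or protective (all below 1).

Exposures with fewer than three usable instruments are recorded as excluded
(`too_few_instruments`) rather than raising, so batch screens always
complete. The reverse-causation stage reuses the identical machinery with
the roles swapped and the stricter genome-wide instrument threshold
$p < 5\times 10^{-8}$; a target is reverse-null when the reverse IVW
p-value is at least 0.05.

## Design choices in the open corners

Published descriptions of this workflow leave several details unstated;
the package fixes them as follows.

* **Variant matching is by identifier.** Exposure and outcome records are
  joined on `variant_id`; chromosome/position disagreements (builds often
  differ between deposits) are tallied, not fatal.
* **Heterogeneity can trigger on either Q.** The exclusion fires if either
  the IVW Q or the Egger Q' is significant; `screening_config()` can
  restrict it to the IVW form. No multiple-testing correction is applied
  across exposures — the screen intentionally uses raw $p < 0.05$ — though
  a Benjamini-Hochberg option exists and is off by default.
* **Leave-one-out stability** has no standard numeric rule, so it is
  operationalized as: every $K-1$ subset IVW estimate keeps the sign of the
  full estimate and matches its significance at 0.05. The level is
  configurable.
* **Wald-ratio SEs are first order** ($\sigma_{yj}/|\hat\gamma_j|$); the
  neglected term is $\theta^2\sigma_{xj}^2$, under 5% of the ratio variance
  in the regimes simulated below.
* **P-values use the standard normal** for all methods; a t reference with
  $K-2$ df is available for Egger via `dist = "t"`.
* **Bootstrap SEs** for the median and mode methods are parametric
  (resample each ratio from $N(\hat\theta_j, \mathrm{se}_j)$); every
  stochastic step takes an explicit seed, and `mr_fit()` derives one seed
  per method from a stable hash so results do not depend on which methods
  are requested. Batch screens derive per-exposure seeds the same way, so
  `screen_many()` is order-independent.
* **Mode bandwidth** is a modified Silverman rule,
  $0.9\min(\mathrm{sd},\mathrm{mad})K^{-1/5}$, falling back to the sd when
  the mad degenerates; with all ratios identical the estimate is that
  value for any bandwidth.

## What the generator emulates — and what it does not

`simulate_pair()` produces summary statistics directly on the z-score
scale. Variants sit in LD blocks with AR(1) correlation; a tag at
correlation $r$ to its block's index variant inherits $r$ times the index's
noncentrality — the exact marginal relation for standardized genotypes —
and within-block noise is correlated accordingly (independently for the
two samples, as in a genuine two-sample design). Instrument effects are
Gaussian, pleiotropic direct effects are Gaussian and independent of
instrument strength (InSIDE holds by construction; a correlated switch
exists for stress tests), allele frequencies are uniform on (0.05, 0.95),
and standard errors follow $1/\sqrt{2N\,\mathrm{eaf}(1-\mathrm{eaf})}$.
Palindromic variants and swapped outcome allele order are injected at
configurable rates to exercise harmonization.

Defaults define the reference study conditions: 240 variants in 30 blocks
($\rho = 0.8$), 30 instruments with $\gamma \sim N(0.08, 0.04^2)$ —
per-SNP F mostly in the tens to low hundreds, matching the 20-180 range
typical of connectivity GWAS instruments — equal exposure and outcome
sample sizes of 30,000 so the first-order ratio SE stays accurate, 5%
palindromic variants and 20% swapped alleles. The generator does not
attempt realistic human LD maps, empirical allele-frequency spectra, or
case-control liability-scale conversions; passing tests demonstrate
statistical correctness of the machinery under its stated model, not
robustness to everything real GWAS data can contain.

## Validation at desk scale

The test suite and `scripts/acceptance.R` recompute, from fresh
simulations (problem sizes chosen to give stable Monte-Carlo estimates at
interactive runtimes):

* closed-form agreement of IVW with the weighted mean and the
  zero-intercept weighted regression on random instrument sets, and exact
  line recovery by Egger;
* null calibration over 2000 replicates of the default conditions with
  $\theta = 0$: IVW type-I error near 0.05, Cochran's Q p-values uniform
  (Q is exactly chi-square under the null here because the outcome noise
  is independent of the exposure noise), Egger intercept rejection near
  0.05;
* recovery of $\theta = 0.2$ by all five methods (means within 0.02 of
  truth) with IVW coverage near 95% — coverage sits in the low 0.94s
  because of the first-order SE and mild winner's curse from instrument
  selection;
* robustness with 30% directionally invalid instruments at $K = 100$: the
  weighted median's bias is several-fold smaller than IVW's, and the Egger
  intercept test attains full power when the directional effect (mean
  0.05) applies across instruments, the regime in which the intercept
  estimates that mean;
* the direction-consistency rule applied to the thirteen published
  odds-ratio quintets shipped in `inst/extdata`, reproducing the
  three published exclusions;
* a 206-exposure batch with ten planted effects (two risk, eight
  protective): planted effects pass the significance and direction steps,
  retained ones are classified correctly, and false retention among nulls
  stays below the 5% screening level. Because the three sensitivity gates
  are themselves calibrated at the 5% level, any single planted effect can
  occasionally be lost to a sensitivity false alarm; the tests bound that
  attrition binomially rather than demanding an event the screen's own
  calibration makes improbable.

## Worked example

```{r example}
cfg_sim <- sim_config(theta = 0.2, seed = 42)
sim <- simulate_pair(cfg_sim)
ids <- select_by_pvalue(sim$exposure, 5e-6)
ids <- ld_clump(ids, sim$ld, sim$exposure)
strength <- instrument_strength(sim$exposure, ids)
h <- harmonize(sim$exposure, sim$outcome,
               strength$variant_id[!strength$weak])
fit <- mr_fit(h, seed = 7)
summary(fit)
```

```{r screen}
rec <- screen_exposure(sim$exposure, sim$outcome, sim$ld,
                       screening_config(seed = 5))
rec$decision
rec$effect_class
```

## Known limitations

The package screens; it does not adjudicate. It implements none of the
outlier-removal or model-averaging estimators (MR-PRESSO, contamination
mixture, CAUSE), no Steiger filtering, no multivariable MR, and no
liability-scale effect translation. Clumping requires a user-supplied LD
matrix — results on real data inherit the reference panel's quirks. The
leave-one-out stability rule and the either-Q heterogeneity trigger are
reasonable operationalizations of practice, not identities; both are
exposed in `screening_config()` so a user can match another group's exact
protocol.
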