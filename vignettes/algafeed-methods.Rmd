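---
title: "Methods: growth, digestibility and feed-cost analysis for microalgae-based aquafeeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth, digestibility and feed-cost analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algafeed)
```

# Scope

`algafeed` implements the quantitative workflow used to evaluate fish-free
aquafeeds — diets that replace fishmeal with defatted microalgal biomass
(e.g. *Nannochloropsis oculata* left over after EPA oil extraction) and fish
oil with DHA-rich whole-cell *Schizochytrium* sp. — in tilapia feeding
trials. Four stages are covered: growth-trial performance statistics,
in-vitro protein digestibility from pH-stat titration, hedonic pricing of
the novel ingredients from commodity price panels, and feed-cost / economic
conversion ratio (ECR) estimation with bootstrap uncertainty. Each stage has
a synthetic-data generator that inverts it, which is how the package
validates itself end to end.

# Growth-trial statistics

## Metrics

For a tank with mean initial and final wet weights $w_0, w_f$ (g), trial
length $T$ (days), per-fish feed intake $F$ and protein fed $P$ (g), and
fish counts $n_0, n_f$:

* weight gain $= w_f - w_0$; percent gain $= 100\,(w_f - w_0)/w_0$
* feed conversion ratio $\mathrm{FCR} = F / (w_f - w_0)$
* specific growth rate $\mathrm{SGR} = 100\,(\ln w_f - \ln w_0)/T$ (%/day)
* protein efficiency ratio $\mathrm{PER} = (w_f - w_0)/P$
* survival $= 100\, n_f / n_0$ (%)

The tank is the replicate unit. Metrics are computed per tank first and then
averaged within diets (mean ± SE over tanks); the package never forms
ratio-of-means statistics. This ordering matters: group means of per-tank
percent gain or SGR generally differ from the same formulas applied to group
mean weights, because both are nonlinear in the weights. Published growth
tables built from per-tank values therefore cannot be reconstructed exactly
from their own printed group means, and `algafeed` does not try to — it
reports per-tank-first statistics and, where only printed summaries exist,
provides the summary-statistics ANOVA reconstruction below.

Feed is weighed per tank; `per_fish_feed()` divides the tank total by the
mean of initial and final counts, $(n_0+n_f)/2$, so fish lost mid-trial
count for roughly half of it. This is a convention choice (trial reports
rarely state one); it only matters when mortality is non-zero.

A tank with non-positive gain makes FCR undefined; `fcr()` raises an error
rather than returning a silent `NA`, so shrinking tanks are handled
deliberately by the analyst.

## ANOVA, reconstruction, and letters

`anova_oneway()` is a classical pooled-variance one-way fixed-effects ANOVA
(delegated to `stats::aov()`) with Tukey HSD pairwise comparisons
(`stats::TukeyHSD()`) at $\alpha = 0.05$, matching the 95% confidence level
conventional in feeding trials. No Welch correction is applied: replicate
counts are tiny (n = 3) and balanced, and heteroscedasticity is not
estimable with any power at that size.

`anova_from_summaries()` rebuilds the same test from published mean/SE/n
rows: within-group variance of group $i$ is recovered as $n_i\,se_i^2$,
pooled into the error mean square; the between-group mean square comes from
the reported means; Tukey p-values use the studentized range with the pooled
variance (Tukey–Kramer for unequal $n$). For balanced summaries of raw data
the reconstruction is algebraically identical to the raw-data ANOVA, which
the test suite verifies. Against published tables the reconstruction is
limited by rounding of the printed means and SEs — reconstructed F
statistics land within about ±0.1 of printed ones, not exactly on them.

The compact letter display uses the insert-and-absorb construction: start
from one set containing all groups; for each significant pair, split every
set containing both members; drop sets absorbed by supersets; assign letters
to the surviving sets in order of descending group mean. By construction two
groups share a letter exactly when their Tukey-adjusted p-value is at or
above $\alpha$ — a property the tests check over randomized designs.

# In-vitro protein digestibility

The pH-stat assay digests a ground feed sample with crude stomach enzyme
extract at pH 2.0 and then intestinal extract at pH 8.0, with an
auto-titrator holding pH constant; the titrant consumed measures peptide
bonds cleaved. Degree of hydrolysis (DH, %):

* stomach (acid) phase: $DH = \dfrac{V N}{E} \cdot \dfrac{1}{P} \cdot
  F_{pH} \cdot 100$, with $V$ the acid volume (mL), $N$ its normality,
  $E$ the substrate protein mass (g), $P = 8.0$ mol peptide bonds per g
  protein when the amino-acid composition is unknown, and $F_{pH} = 1.08$
  the correction for pH 2.0 at 25 °C.
* intestinal (alkali) phase: $DH = B\, N_b\, (1/a) \cdot \dfrac{1}{M_P}
  \cdot \dfrac{1}{H_{tot}} \cdot 100$, with $B$ the alkali volume,
  $1/a = 1.50$ the dissociation factor for pH 8.0 at 25 °C, and $H_{tot}$
  the total peptide bonds of the substrate, constrained to
  $[7.6, 9.2]$ meqv/g protein. The default $H_{tot} = 8.0$ is the range
  midpoint, used when the protein source is unspecified; values outside the
  range are rejected unless explicitly overridden.

Predicted in-vitro protein digestibility is the linear calibration
$\mathrm{IPD} = 3.5093\,DH + 70.248$ (%), strictly increasing with intercept
70.248 at $DH = 0$.

Two open choices are made explicit rather than hidden. First, published
tables report one DH per diet without naming the phase; `titration_to_result()`
takes a `reported` selector (`intestine`, the default because the IPD
calibration is built on intestinal-phase hydrolysis; or `stomach`, or
`sum`). Second, auto-titrators log incremental doses; both DH functions
accept either a total volume or a dosing log, which is summed.

# Hedonic ingredient pricing

A novel ingredient has no market price. The hedonic approach regresses
observed commodity prices on intrinsic composition and evaluates the fitted
surface at the novel ingredient's composition. Two model structures are
implemented, one for protein meals and one for oils, both over a 10-year
annual panel (defaults emulate 12 meal and 7 oil commodities, 2010–2019):

* meal: price $= \beta_0 + \beta_1 CP^2 + \beta_2 Met^2 + \beta_3 Lys^2 +
  (\beta_4 + b_{2,t})\,EE + b_{1,t}\,CP + b_{0,t} + \varepsilon$
* oil: price $= \beta_0 + \beta_1 (20{:}5n\text{-}3)^2 + \beta_2 (14{:}0)^2 +
  \beta_3 (16{:}1n\text{-}7)^2 + (\beta_4 + b_{1,t})\,14{:}0 +
  (\beta_5 + b_{2,t})\,16{:}0 + b_{0,t} + \varepsilon$

with composition variables standardized ($x \mapsto (x - c)/s$; by default
$c, s$ are the panel mean and SD, and externally supplied constants can be
injected via `scaling_params()`), year-level random effects $b_{\cdot,t}$,
and Gaussian residuals. Prices are handled internally in USD/tonne; divide
by 1000 for USD/kg. A freight component (`freight_adjust()`) converts
free-on-board commodity prices to delivered prices: a modal-share-weighted
domestic leg (rail/truck/barge rate × distance) plus an ocean leg.

Design choices:

* **Estimation is maximum likelihood** (`REML = FALSE` in `lme4::lmer()`),
  with REML behind a flag.
* **The model notation carries two covariate-tagged random intercepts per
  year** (e.g. $b_{0,CP_t}$ and $b_{0,EE_t}$). Two additive random
  intercepts over the same grouping factor enter the likelihood only through
  their sum and are not separately identifiable, so the package fits a
  single year intercept; its variance estimates the sum of the two component
  variances. The synthetic generator draws the two components independently
  and sums them, keeping the round trip honest.
* **Random-effects covariance defaults to diagonal** (independent variance
  components, `(1 + x1 + x2 || year)`): with only ~10 year levels a free
  3×3 covariance is weakly identified; a `re_cov = "free"` option exists.
* **Degenerate panels fall back to OLS.** A single-year panel cannot
  identify year effects (warning + fixed-effects fit). A panel whose prices
  lie exactly on the fixed-effects surface (relative residual SD < 1e-8)
  makes the variance components degenerate; the OLS solution is the ML
  solution and is returned directly — this is what makes zero-noise
  simulation recovery exact.
* **Confidence intervals for fixed effects** default to Satterthwaite
  degrees of freedom (via lmerTest). With 10 grouping levels, Wald z
  intervals ignore variance-component uncertainty and visibly undercover
  for the intercept; Satterthwaite df restore near-nominal coverage. Wald
  and profile intervals are available.
* **Extrapolation is permitted but flagged**: pricing the novel ingredient
  is the point of the model, but `predict_price()` warns when any scaled
  covariate falls more than 25% of the observed span outside the panel's
  range.

`predict_price()` evaluates the exact polynomial form at the scaled
composition: `year = "marginal"` sets random effects to zero,
`year = "each"` returns the per-year price distribution. An oil price is
converted to a whole-cell biomass price by the cell's lipid mass fraction
(`oil_to_whole_cell()`, default 0.54 for *Schizochytrium* sp.), valuing the
whole cell at its extractable oil.

# Feed cost, ECR, and the bootstrap

Feed cost is the inclusion-weighted price sum over a formulation,
$\sum_i (g_i/100)\, p_i$ in USD/kg feed, with inclusions required to total
100 g ± 1 g. The economic conversion ratio is
$\mathrm{ECR} = \mathrm{FCR} \times \text{feed price}$ — the feed cost per
kg of fish produced — and is bilinear in both arguments. Per-ingredient ECR
contributions $(g_i/100)\,p_i\,\mathrm{FCR}$ sum exactly to the total,
which is the disaggregation shown in ingredient-level cost figures.

`bootstrap_median_ci()` is a nonparametric bootstrap of the sample median,
10,000 replicates by default, with a bias-corrected and accelerated (BCa,
"adjusted percentile") 95% interval computed by `boot::boot.ci()`. It is
bit-reproducible under a fixed seed. A constant sample collapses the
interval to a point (warning); a two-point sample warns that the
acceleration estimate is unstable; if the BCa endpoints are undefined the
percentile interval is returned with a warning.

`ecr_table()` combines both uncertainty sources. How trial FCR variability
and price uncertainty should be pooled into one ECR interval is a genuinely
open choice; the package's convention is: each bootstrap replicate resamples
every ingredient's annual price observations (taking the replicate median
price) *and* one tank FCR, and the ECR interval is the percentile interval
of those products. The feed-cost interval is likewise percentile over
replicates (BCa needs a flat sample; the composite product distribution does
not have one). Significance of ECR differences across diets uses one-way
ANOVA with Tukey letters on per-tank point ECRs (tank FCR × median feed
cost): the tank is the only true replicate unit, so price uncertainty is
held at its median for the hypothesis test. USD values are reported to full
precision; round to 2 decimals for presentation.

# Synthetic-data generators

Every generator is a measurable inverse of its analysis stage and is
bit-reproducible under its seed.

* `simulate_trial()` defaults to the reference study design: 4 diets × 3
  tanks × 40 fish (480 fish), initial weight 34.5 ± 2.06 g, 184 days, 37%
  dietary crude protein, per-diet true SGR (0.62/0.81/0.74/0.87 %/day) and
  FCR (1.61/1.57/1.60/1.40) at the observed treatment values, and 6%
  mortality (the observed survival band). Tank noise is lognormal on the
  multiplicative growth factor and on feed intake (weights stay positive);
  the default CVs (0.08 growth, 0.05 feed) put simulated group SEs at
  roughly 5–13% of the mean, the order seen in replicated tank trials. At
  zero noise the analysis recovers the configured SGR and FCR exactly.
* `simulate_panel()` draws commodity compositions uniformly within ranges
  spanning the relevant commodity space (meals: crude protein 10–70%, ether
  extract 1–12%, methionine 0.2–2.2%, lysine 0.5–5.5%; oils: EPA 0–18,
  14:0 0–12, 16:1n-7 0–12, 16:0 5–45% of total fatty acids), so the
  microalgal ingredients are priced by interpolation in tests and
  extrapolation only when configured. Generating fixed effects act on the
  standardized scale (meal intercept 650 USD/tonne, oil 900; curvature and
  slope terms of order 30–70); residual SD defaults to 5% of the intercept.
  The generating coefficients are returned alongside the panel for recovery
  testing.
* `simulate_titration()` inverts the DH equations to the titrant volume
  that encodes a configured true DH, adds optional Gaussian dose noise, and
  emits triplicate records.

What the generators deliberately do not emulate: individual-fish growth
heterogeneity within a tank (only tank-level aggregates are modelled),
serial correlation of commodity prices across years (year effects are
exchangeable), non-Gaussian price shocks, and any dependence of composition
on time. Passing tests therefore demonstrate that the estimators recover
the parameters of *this* data-generating process — internal consistency —
not that the models are adequate for any particular real market or trial.

# Validation problem sizes and numerical choices

The test suite validates parameter recovery on 200 simulated meal panels
(12 commodities × 10 years, residual SD 5% of mean price, fixed seeds),
requiring each fixed effect's 95% interval to cover its generating value in
at least 90% of panels; bootstrap coverage on 100 standard-normal samples of
n = 200 with 10,000 replicates each; and exact (1e-6 to 1e-12) recovery on
zero-noise panels, trials and titrations. Reconstruction of the published
growth-table ANOVA is asserted to ±0.15 of the printed F (the printed
means/SEs are rounded). Tolerances on USD quantities are 0.01–0.05 on
values of order 1.

Degenerate inputs are handled explicitly rather than propagated: zero
within-group variance yields F = 0/p = 1 (all means equal) or F = ∞/p = 0
with a warning (means differ); empty diet groups, unpriced ingredients,
malformed CSV cells and out-of-range constants are errors that name the
offending element.

# Limitations

* The hedonic models price composition, not supply-demand dynamics; they
  cannot anticipate price movements as microalgae production scales.
* The published digestibility table that motivates the DH → IPD stage is
  internally inconsistent for one diet (its printed IPD does not equal the
  calibration applied to its printed DH); the package pins its behaviour to
  the calibration equation and leaves reconciling printed tables to the
  analyst.
* The ECR hypothesis test treats the median feed cost as fixed; diets whose
  cost distributions overlap heavily may show letters driven almost
  entirely by FCR differences.
* With n = 3 tanks per diet, all trial-level tests have low power; the
  machinery is correct, the design is small.
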