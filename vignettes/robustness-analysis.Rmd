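---
title: "Quantifying microbial robustness and its trade-off with performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbial robustness and its trade-off with performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Industrial microbes meet fluctuating environments — weak acids, furanic
aldehydes, osmotic stress, mixed sugars, ethanol — and a strain that grows
fastest in a benign medium is not necessarily the strain that behaves most
*consistently* across such a perturbation space. `robustpheno` separates the
two notions. **Performance** of a strain for a phenotype is its mean value
over all conditions; **robustness** is the stability of that phenotype across
conditions, quantified as a mean-normalized negative Fano factor:

$$
R_{S,i,P} \;=\; -\frac{\sigma^2}{\bar{x}} \cdot \frac{1}{m}
$$

where $\sigma^2$ and $\bar{x}$ are the sample variance (denominator $n-1$)
and mean of phenotype $i$ of strain $S$ across the perturbation set $P$, and
$m$ is the grand mean of that phenotype over **all** strains. $R$ is
dimensionless and non-positive: $0$ means perfectly stable behaviour, more
negative means less robust. Because $\sigma^2$ scales with the square of the
measurement unit and $\bar{x}\,m$ does too, $R$ is invariant to the unit in
which a phenotype is expressed — a property the test suite asserts to
`1e-12`.

Five phenotypes are tracked per well: maximum specific growth rate
($\mu_{max}$, 1/h), lag phase (h), final cell dry weight (g/L), biomass
yield (g/g consumed sugars) and ethanol yield (g/g consumed sugars). Lag
enters the statistic as measured — the statistic scores consistency, not
desirability, so no inversion is applied to "smaller-is-better" phenotypes.

## From reader curves to phenotypes

Growth curves are analysed with a sliding-window log-linear regression:
ordinary least squares of $\ln(\text{signal})$ against time on every
contiguous window (default 5 points), keeping the largest positive slope
among windows with $r^2 \ge 0.98$. Flat or erratic curves yield
$\mu_{max} = 0$ with a `no_growth` flag. The **lag** is the
tangent-intercept construction: the winning window's regression line is
extended back to the initial ln-signal baseline (the minimum of the first
three ln-signals) and the crossing time, floored at zero, is the lag.

The window default (5 points) and $r^2$ threshold (0.98) follow common
practice for plate-reader data: the window must span enough points for a
meaningful $r^2$ yet stay short against the curvature timescale
$A_{\ln}/\mu$ of the ln-curve. On noiseless curves sampled every 0.1 h these
defaults recover $\mu$ within 0.2% over $\mu \in [0.05, 0.5]$ 1/h.

Two deliberate choices deserve a note:

* **Blank handling.** The `blank` argument of `fit_mu_max()` defaults to 0,
  i.e. the signal is taken as already blank-corrected. Subtracting the
  initial signal itself (a tempting default) makes the log-slope of a pure
  exponential systematically overshoot its rate, because
  $\ln(e^{\mu t} - 1)$ has slope $> \mu$ everywhere; an explicit blank can
  be passed when the reader output contains a known medium background.
* **Lag identifiability.** The tangent construction estimates the lag
  relative to the *observed* initial level. A culture observed from
  inoculation at $t = 0$ sits
  $f(0) = A_{\ln}\exp(-e^{1 + \mu e \lambda / A_{\ln}})$ ln-units above the
  model's lower asymptote, so the geometric lag equals
  $\lambda + f(0)/\mu$. For moderate growth rates this offset is
  negligible ($< 0.01$ h at $\mu = 0.35$, $\lambda = 3$), but for very slow
  growers with short lags ($\mu \approx 0.05$ 1/h, $\lambda \approx 0$)
  $\lambda$ itself is not identifiable from the observed data by *any*
  tangent-type estimator — the reported lag is then the geometric lag of
  the observed curve. Model-based nonlinear refitting could recover
  $\lambda$ there, but is outside this package's scope.

Cell dry weight comes from the final OD through a per-strain linear
calibration, floored at zero. Yields divide by the total consumed substrate
summed over all sugars in the medium (mixed-sugar media are the norm in
hydrolysate screens); the biomass-yield numerator is the CDW *produced*
(final minus initial), while the `cdw` phenotype reports the final
concentration. Residual sugars exceeding the initial concentration by up to
5% (assay noise) are clamped; larger excesses are an error.

## Quality control

Applied in order by `qc_phenotype_table()`:

1. **Theory-based trimming.** Yields above 0.61 g/g are removed — the
   maximum theoretical ethanol yield on glucose (0.51 g/g) plus a 0.1 g/g
   experimental-error allowance — as are CDW values above 39.6 g/L, the
   biomass ceiling of the strongest medium (65 g/L glucose at the maximum
   chemostat biomass yield). Growth rate and lag have no upper bound; all
   phenotypes have lower bound 0. Bounds are *inclusive* (a value exactly at
   the bound is an admissible "maximum theoretical" value) and trimming is
   *value-level*: one bad yield does not discard the well's other
   phenotypes.
2. **Ethanol-yield exclusion.** With ethanol as the perturbing compound its
   consumption and production are confounded, so `ethanol_yield` records
   from the ethanol group are dropped.
3. **Outlier flagging.** Values strictly outside the 0.1%/99.9% quantiles
   of their phenotype (linear interpolation between order statistics) are
   flagged, never removed.
4. **Normality check.** Shapiro–Wilk per phenotype, advisory only. Above
   the test's 5000-value limit an evenly spaced subsample of the order
   statistics is used, keeping the check deterministic.

Steps 1 and 2 touch disjoint criteria, so they commute — asserted by a
property test.

## Robustness, replicates and group influence

`robustness_table()` computes $R$ per replicate over that replicate's
available conditions (missing conditions are dropped pairwise, with the
count recorded), then reports the mean across replicates with its standard
error — triplicate cultivations therefore yield an $R \pm$ SEM per strain
and phenotype. The grand means $m$ are computed once, per phenotype, on the
QC'd table (trimmed, outliers retained).

`group_influence()` asks which perturbation group drives a strain's
dispersion: robustness is recomputed with one group excluded, *reusing the
all-conditions* $m$, and the ratio $R_{\text{excluding}}/R_{\text{all}}$ is
classified — below 1, the group was degrading robustness
(`negative_impact`); at or above 1, `neutral_or_positive`; `undefined` when
$R_{\text{all}} = 0$. Keeping $m$ fixed makes the ratio a pure function of
the change in the strain's own dispersion.

## Trade-off statistics

Associations are rank-based throughout (the phenotype distributions are
skewed and multimodal, so Pearson correlation would be misleading):
Spearman's $\rho$ with average ranks for ties and two-sided p-values, no
multiple-testing correction. The per-strain summaries feed a full
performance × robustness correlation matrix across the five phenotypes; the
diagonal carries the headline performance–robustness trade-offs.

Each correlation is reported with a sample-size-based standard error

$$\mathrm{se}(r) = \frac{1 - r^2}{\sqrt{n - 1}},$$

which decreases with both $n$ and $|r|$; over a 24-strain panel a
correlation of magnitude 0.7 carries an error of about 0.1, and a weak
correlation about 0.2. Group-versus-reference comparisons of pooled
record-level values use the two-sided Wilcoxon rank-sum test with hexoses —
the benign sugar conditions — as the default reference. Regression lines in
the scatter plots are visual direction cues only, never inference.

## Culture transfer

The transfer module scores the change in $\mu_{max}$ between a first and a
second cultivation in the same medium:

$$\%P = \frac{\mu_{max,2} - \mu_{max,1}}{\mu_{max,1}} \times 100 .$$

$\%P$ is scale-invariant and bounded below by $-100$. When a strain grows
only in the second cultivation ($\mu_{max,1} = 0$, $\mu_{max,2} > 0$) the
ratio is infinite; such records carry a sentinel that
`resolve_infinities()` replaces with the dataset-wide maximum finite $\%P$
(flagged `substituted`). When both rates are zero the record carries no
improvement information and stays missing — 0/0 is not 0%. Summaries report
per-strain means across perturbations (SD over the replicate means),
per-group Spearman correlations between first and second rates, counts of
strains above configurable improvement thresholds, and the correlation of
mean $\%P$ with robustness.

## The synthetic-data generator

The generator emulates the statistical structure of a microtiter robustness
screen, with defaults matching the study design the package targets: **24
strains × 29 conditions × 3 replicates × 5 phenotypes = 10,440 records**
before QC. What it models:

* a perturbation space drawn from six groups (acids, pentoses, hexoses,
  aldehydes, NaCl, ethanol) with group-typical chemicals and g/L ranges; by
  default the space includes a 20 g/L glucose control within the hexose
  allocation (whether the reference screen counted its control among the
  conditions is not documented; including it is this package's default,
  controllable via `include_control`);
* per-strain baselines around field-typical magnitudes
  ($\mu_{max}$ 0.3 1/h, lag 3 h, CDW 4.5 g/L, $Y_x$ 0.25 g/g, $Y_p$
  0.40 g/g; 25% lognormal spread across strains);
* multiplicative condition effects and strain × condition response
  deviations — the between-condition variance that the robustness statistic
  measures;
* multiplicative lognormal replicate noise parameterized by a CV (default
  0.1, the order of triplicate scatter in plate cultivations). A lognormal
  rather than additive-normal model keeps all phenotype values positive and
  matches the right-skew of real cultivation data.

Strain × condition deviations are standardized within each strain to exact
sample moments, so the noiseless per-strain mean, variance and analytic
robustness are available in closed form (`ground_truth()`); the pipeline
reproduces them to `1e-12`, which is the backbone of the oracle tests. If
the requested spread would drive a noiseless value negative, all spreads are
rescaled jointly — ranks, and hence any embedded rank correlation, are
preserved.

`embed_tradeoff()` plants a known performance–robustness trade-off: a
Gaussian copula (Pearson $\rho_g = 2\sin(\pi\rho_s/6)$) couples the ranks of
per-strain performance with the ranks of a drawn robustness magnitude, and
the per-strain response spread is solved from
$R_s = -b_s w_s^2 / m$ so that the analytic robustness hits the drawn
values exactly. At $\rho_s = -1$ the construction is perfectly
anti-monotone and the noiseless pipeline recovers Spearman $-1$ exactly;
with noise the realized correlation attenuates, so recovery tests use
tolerance bands (median within $\pm 0.2$ at $\rho_s = -0.7$ over repeated
runs).

Growth curves use the Zwietering reparameterization of the Gompertz model
in ln-signal space,

$$\ln\frac{N_t}{N_0} = A_{\ln}\,
  \exp\!\Big(-\exp\big(\tfrac{\mu e}{A_{\ln}}(\lambda - t) + 1\big)\Big),$$

chosen because its parameters *are* the quantities of interest: the maximum
derivative equals $\mu$ and the inflection tangent crosses zero at
$t = \lambda$, giving closed-form oracles for the curve-fitting tests.

What the generator does **not** model: mechanistic metabolism (no FBA, no
inhibitor kinetics), plate-geometry effects (edge wells, evaporation),
batch effects, or condition-severity gradients within a group. Passing
recovery tests therefore demonstrates the correctness of the statistical
machinery on data with the assumed noise structure, not the biological
validity of any particular screen.

## Numerical choices and degenerate inputs

* Sample variance (denominator $n-1$) throughout: condition sets are small
  (tens of conditions) and this is the ecosystem default.
* A constant series has $R = 0$ exactly (not a tiny negative number);
  series with fewer than 2 conditions, or a non-positive mean, are reported
  missing with a reason, never silently dropped.
* Quantiles are linear-interpolation (type 7), the mainstream default.
* Spearman p-values use the t-approximation uniformly (ties make the exact
  null unavailable); n ≥ 4 complete pairs and ≥ 2 distinct values per
  vector are required, otherwise the entry is skipped with a reason.
* All randomness derives from explicit integer seeds; a fixed configuration
  reproduces every output file byte-for-byte.

## Problem sizes used in the checks

The test suite runs the oracle-equivalence check on 1,000 random small
tables, the noise-recovery check on 200 simulations of 8 strains × 29
conditions, the trade-off recovery on 200 pipeline runs per embedded
correlation (24 strains × 29 conditions × 3 replicates), and the
group-influence null on 500 simulated 30-condition series — sizes chosen to
bound Monte-Carlo error well below each tolerance while keeping the default
check fast on a laptop.

```{r, eval = FALSE}
library(robustpheno)
report <- run_pipeline(pipeline_config(
  simulation = list(tradeoff = list(phenotype = "mu_max", rho = -0.7)),
  out_dir = "robustness_run", seed = 1
))
report$tables$tradeoffs
```
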