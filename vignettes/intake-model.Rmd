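---
title: "Modelling non-dietary insecticide intake from dust and soil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-dietary insecticide intake from dust and soil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustintake)
```

## The model and its assumptions

The quantity of interest is a young child's (3–6 years) daily intake of an
insecticide through incidental ingestion of indoor dust or outdoor soil:

\[
\mathrm{DI} = \frac{\mathrm{IR} \times C \times \mathrm{CF}}{\mathrm{BW}}
\quad [\mu g/kg/day],
\]

with ingestion rate IR in mg/day, residue concentration \(C\) in µg/g,
conversion factor CF = 10⁻³ g/mg and body weight BW in kg. Intake is
expressed as percent of the Acceptable Daily Intake
(\(\%\mathrm{ADI} = 100\,\mathrm{DI} / (1000\,\mathrm{ADI})\); ADIs are
registered in mg/kg/day). Units are fixed package-wide; any other unit has to
be converted before the configuration boundary, which removes the most common
source of silent 10³ errors in this kind of model.

The model's structural assumptions:

* **All inputs are lognormal.** Dust/soil ingestion rates from
  activity-based simulation studies, residue surveys, and child growth
  charts are all strongly right-skewed and conventionally summarised as
  lognormal. A point mass (σ = 0) is the only other distribution supported,
  and only via an explicit constructor.
* **Inputs are mutually independent.** No correlation between how much dust
  a child ingests, how contaminated it is, and how much the child weighs.
* **No absorption or bioavailability factor** — the intake equation has
  none, so the estimate is ingested dose, not absorbed dose.
* **One route at a time**, with route totals formed by summing intakes
  inside each Monte Carlo iteration.

Because a product/quotient of independent lognormals is again lognormal
(`combine_product_quotient()`), every simulated scenario has an exact
closed-form answer. The Monte Carlo engine is therefore fully testable: its
quantiles must converge to the closed form, and the test suite asserts that
they do (within 1% relative error at P50–P99 and 5% at P99.9 at 10⁶ draws).

## Fitting lognormals from published evidence

Studies publish three kinds of summaries, and `fit_lognormal()` accepts all
three:

* **Arithmetic mean/SD** (`summary_moments`): exact moment matching,
  \(\sigma = \sqrt{\log(1 + (sd/mean)^2)}\),
  \(\mu = \log(mean) - \sigma^2/2\). `log1p`/`expm1` are used so the
  round trip mean/SD → (μ, σ) → mean/SD holds to 10⁻¹² relative error even
  for tiny coefficients of variation.
* **Percentile tables** (`percentile_table`): ordinary least squares of
  \(\log(value)\) on the standard-normal quantile of the probability (a
  probit plot). Two points solve exactly; three or more use the closed-form
  OLS solution — reproducible, no iterative solver, and exact (to 10⁻⁹)
  whenever the table actually comes from a lognormal. Body weight ships only
  as a seven-point growth-chart row for the combined 3–6-year range, so it
  is always fitted this way.
* **Left-censored samples** (`censored_sample`): every below-LOD entry is
  replaced by LOD/2 (`substitute_half_lod()`), then the substituted sample
  is moment-matched. Maximum-likelihood or regression-on-order-statistics
  censored estimation is deliberately out of scope: half-LOD substitution is
  the convention the packaged survey data were processed with, and the
  package mirrors it exactly.

Quantiles use `stats::qnorm`, whose accuracy (≈10⁻¹⁵) comfortably exceeds
the 10⁻⁹ needed for stable P99.9 estimates.

### Which evidence to fit from, when a table prints both

The packaged residue and ingestion-rate rows print a mean/SD pair *and*
percentiles, and nothing records how the original commercial software mapped
them to lognormal parameters. The two fits differ materially: the residue
surveys are so skewed (RSD 6.64 for chlorpyrifos in dust) that no single
lognormal matches both their moments and their printed percentiles.
The package's position:

* **moment matching is the default** (`parameterization = "moments"`) — it
  is the only evidence printed completely for every variable;
* percentile fitting is a first-class switch
  (`parameterization = "percentiles"`) so the discrepancy can be explored;
* `scenario_diagnostics()` reports fitted-vs-printed percentile ratios and
  flags large disagreements rather than correcting anything silently.

```{r diagnostics}
scenario_diagnostics("chlorpyrifos_dust")
```

This ambiguity is exactly why published upper-tail results of this kind of
study are hard to reproduce from the printed summaries alone: the P99.9 of
the intake distribution is dominated by the fitted σ of the concentration,
which differs between the two parameterizations. The package therefore
validates its engine against its own closed-form oracle, not against any
particular printed upper-tail value.

### Truncation

By default distributions are **not** truncated at the published sample
maxima: the published protocol does not mention truncation, and the fitted
lognormal tail is what the moment pair implies. Because the heavy tail
dominates P99.9, an optional per-variable upper bound is supported
(`load_scenario(..., truncate_at_maximum = TRUE)`), implemented by inverse-CDF
sampling on \((0, F(\mathrm{max}))\) so the draw count per variable is
unchanged.

## The Monte Carlo protocol

Defaults follow the study protocol: 10⁶ iterations per replicate, 30
replicates, percentile grid P50/P75/P90/P95/P97.5/P99/P99.9.

* **Percentile definition**: inverse empirical CDF (lower nearest rank,
  `quantile(type = 1)`), exact over the full replicate — deterministic and
  standard; at 10⁶ draws the difference from interpolating definitions is
  negligible.
* **Confidence intervals**: the point estimate is the mean of the 30
  per-replicate percentile estimates and the interval is
  \(\bar{x} \pm t_{0.975,\,n-1}\, s/\sqrt{n}\). The original tool's CI
  construction is undocumented; the t-interval is recorded in every report's
  metadata so the choice is auditable. Its empirical coverage of the
  closed-form quantile is checked in the test suite over 200 seeded
  meta-runs at reduced size (10⁴ iterations × 10 replicates — small enough
  to run routinely, large enough that the t-approximation is exercised), and
  CI width is checked to shrink like \(1/\sqrt{\text{replicates}}\).
* **Seeding**: each replicate's stream seed is a deterministic hash of
  (base seed, replicate index), so runs are bit-reproducible and replicates
  are order-insensitive. Identical seeds give byte-identical report CSVs.
* **Route totals** (`simulate_total()`): one body weight is drawn per
  iteration and shared across routes — one child has one body weight. The
  original protocol is silent on this; the choice is flagged in the report
  metadata and `shared_bw = FALSE` computes the independent-BW variant.
  Shared BW induces (slight) positive dependence between route intakes;
  with BW's σ ≈ 0.14 against the concentrations' σ ≈ 1.5–2 the effect on
  totals is minor.

## Sensitivity analysis

Two contribution-to-variance estimators are reported side by side, because
the conventional "contribution to variance" output of commercial Monte Carlo
tools is not defined by a published formula:

* `contribution_rank_correlation()` — normalized squared Spearman
  correlations \(100\rho_i^2/\sum_j \rho_j^2\) (midrank ties), the
  commercial convention;
* `contribution_log_variance()` — the exact decomposition for this model,
  \(100\sigma_i^2/\sum_j \sigma_j^2\), since
  \(\mathrm{Var}(\log \mathrm{DI}) = \sigma_{IR}^2 + \sigma_C^2 +
  \sigma_{BW}^2\).

```{r sensitivity}
sc <- load_scenario("chlorpyrifos_dust")
contribution_log_variance(sc)
```

Both estimators agree on the qualitative structure the test suite asserts:
concentration dominates, ingestion rate is secondary, body weight is inert
(< 1%). The two are not numerically identical — rank correlation measures
monotone dependence on the output scale — and the suite only requires them
to agree within 10 percentage points on lognormal-product scenarios.

## Synthetic data: what it emulates, what it does not

The generator produces the three input shapes the pipeline consumes, with
known ground truth:

* `generate_censored_concentrations()` — lognormal residue draws with values
  below a stated LOD flagged censored (raw values retained for oracle
  checks). The censored fraction matches the closed-form normal probability
  \(\Phi((\log \mathrm{LOD} - \mu)/\sigma)\) within binomial error.
* `generate_growth_chart()` — exact quantiles at a seven-point grid,
  noise-free, because published growth charts are smoothed; fitting them
  back recovers the truth to 10⁻⁹.
* `end_to_end_recovery()` — generate → fit → simulate → compare against the
  closed-form truth.

What the generator does **not** emulate: measurement error on
concentrations (surveys report values as exact), spatial or seasonal
structure in residues, correlation between inputs, and non-lognormal
contamination patterns (e.g. a mixture of background homes and
recently-treated homes — the most plausible reality behind the
moment/percentile inconsistency above). Passing recovery tests therefore
show the pipeline is self-consistent, not that real residue surveys are
lognormal.

Two finite-sample effects are documented rather than "fixed":

* moment matching on heavy-tailed samples (σ ≳ 1.5) is biased at realistic
  survey sizes, because the sample SD of a lognormal converges slowly; the
  recovery tests use σ = 1 truths where the estimator is well behaved;
* half-LOD substitution with a high LOD deflates the fitted mean whenever
  LOD/2 sits below the censored stratum's conditional mean (at the median
  of LN(0,1): 0.5 vs 0.523) while slightly inflating the fitted σ through
  the coefficient of variation; the test suite asserts the mean direction.

## Problem sizes and numerical choices

The test suite runs the full default protocol (4 scenarios × 10⁶ × 30) once,
uses 10⁴–10⁵ draws for convergence and property checks, 10⁶ draws for the
oracle-match and sensitivity assertions, and 200 × (10⁴ × 10) for CI
coverage — sizes chosen so each check's Monte Carlo error is several times
smaller than its tolerance. Degenerate inputs (point masses) are handled
throughout; requesting a percentile finer than 1/iterations warns rather
than fails; empty censored samples substitute to empty vectors; a scenario
whose inputs are all point masses has no defined variance decomposition and
errors accordingly.

## Known limitations

* Only the lognormal/point-mass families; no correlation structure; no
  dermal or inhalation routes; no bioavailability.
* Dietary intake percentiles are external published constants consumed for
  comparison (`build_comparison()`); the package never recomputes them.
* The published body-weight RSD of 0.086 is surfaced as a diagnostic
  (`rsd()` on the fitted spec gives ≈ 0.14 from the printed growth-chart
  row); the derivation of the smaller value is unknown and neither number
  is asserted.
* Published route-level upper-tail percentiles and the soil-route
  sensitivity split (91.4/8.5) are not reproducible from the printed input
  summaries under either parameterization; they ship as reference tables for
  comparison, not as test oracles.
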