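# dustintake

Probabilistic estimation of young children's daily intake of insecticide
residues (chlorpyrifos, cypermethrin) through **non-dietary ingestion** of
indoor dust and outdoor soil, with risk characterization against the WHO
Acceptable Daily Intake (ADI).

Young children ingest small amounts of house dust and yard soil through
hand-to-mouth and object-to-mouth behaviour. Where insecticides are applied
indoors, the residues in that dust become a non-dietary exposure route. This
package is for exposure scientists and risk assessors who want to turn
published summary statistics — a mean/SD pair for ingestion rate, a
left-censored residue survey, a growth-chart percentile row for body weight —
into a full variability distribution of daily intake.

## The model

Daily intake for one simulated child-day is

```
DI = IR × C × CF / BW        [µg/kg/day]
```

where `IR` is the dust or soil ingestion rate (mg/day), `C` the residue
concentration (µg/g), `CF = 10⁻³` g/mg the unit conversion, and `BW` the
child's body weight (kg). All three inputs are modelled as independent
lognormals, so the intake is itself lognormal — the package exploits that
closed form as an exact oracle for its Monte Carlo engine. Results are
reported as percent of the ADI (0.01 mg/kg/day for chlorpyrifos, 0.02 for
cypermethrin):

```
%ADI = 100 × DI / (1000 × ADI)
```

The Monte Carlo protocol draws 10⁶ independent (IR, C, BW) triples per
replicate and runs 30 replicates; percentiles of %ADI (P50–P99.9) are
averaged across replicates with t-based 95% confidence intervals.

Lognormal inputs are fitted from whichever evidence a study publishes:

* **moments** — exact moment matching: `σ = √log(1 + (sd/mean)²)`,
  `μ = log(mean) − σ²/2`;
* **percentile tables** — least squares of `log(value)` on the probit of
  probability (exact for two points);
* **left-censored samples** — half-LOD substitution, then moment matching.

A contribution-to-variance sensitivity analysis (normalized squared Spearman
rank correlations, cross-checked by the exact log-variance decomposition
`100·σᵢ²/Σσⱼ²`) identifies which input drives the intake variability.

## Worked example

```r
library(dustintake)

sc <- load_scenario("chlorpyrifos_dust")   # published survey inputs
set <- simulation_settings(iterations = 1e5, replicates = 3, seed = 7)
simulate_intake(sc, set)
#> Simulated %ADI percentiles: chlorpyrifos via indoor_dust
#>   100000 iterations x 3 replicates, seed 7, moments parameterization
#> P50    0.003% (0.003%, 0.003%)
#> P75    0.014% (0.013%, 0.014%)
#> P90    0.052% (0.051%, 0.054%)
#> P95    0.117% (0.111%, 0.124%)
#> P97.5  0.233% (0.220%, 0.247%)
#> P99    0.531% (0.521%, 0.541%)
#> P99.9  2.830% (2.373%, 3.287%)

sensitivity_analysis(sc, "log_variance")
#> Contribution to variance (log_variance)
#>   ir     21.65%
#>   conc   77.95%
#>   bw      0.40%
```

Reading the output: even at the 99th percentile the simulated intake stays
below 1% of the ADI — non-dietary ingestion is negligible for most children —
but the heavy upper tail of the residue concentration (RSD 6.64, against 1.37
for the ingestion rate and ~0.1 for body weight) makes the extreme
percentiles climb steeply, and the sensitivity shares confirm concentration
as the dominant driver.

A thin command-line wrapper covers the same workflow
(`exec/dustintake simulate --scenario chlorpyrifos_dust --seed 1 --out-dir out`);
see `?cli_main`.

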