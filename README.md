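# bretropy

Entropy-based analysis of real-time BRET biosensor kinetics.

## The problem

Bioluminescence resonance energy transfer (BRET) biosensors report
protein–protein proximity in live cells as a 530 nm / 470 nm emission ratio
sampled every few tens of seconds. In GPCR pharmacology they track, in real
time, events such as AT1R (angiotensin II type 1 receptor) coupling to
Gαq or β-arrestin after stimulation with the agonist AngII, the allosteric
modulator LVV-hemorphin-7, or both. Classical readouts (amplitude, EC50)
ignore the *temporal structure* of these traces. `bretropy` quantifies that
structure with two complementary information-theoretic markers:

**Sample Entropy.** For a series of length *N*, tolerance *r* and embedding
dimension *m*,

> SampEn = −ln( (A / B) · N/(N−2) )

where *B* counts pairs of length-*m* templates within Chebyshev distance
*r* of each other and *A* the corresponding length-(*m*+1) pairs
(self-matches excluded; templates of length *L* start at positions
1 … *N*−*L*). Defaults are *m* = 1 and *r* = 0.2 × SD of the series, suited
to short kinetic reads; the small-sample factor *N*/(*N*−2) inside the
logarithm can be switched off. Lower SampEn = more regular, more
predictable signaling.

**Normalized Rényi entropy spectrum.** The distribution of trace values is
estimated by a Gaussian kernel density estimate (Silverman's robust
bandwidth, support = data range, renormalized to probabilities
*p₁ … pₙ*), then

> H_α = ln( Σᵢ pᵢ^α ) / (1 − α)

is evaluated at all integer orders α from −10 to 10 plus α = ∞, with the
standard limits (α = 1 Shannon, α = 0 Hartley = ln *n*, α = ∞ min-entropy
= −ln max pᵢ) and normalized by the Hartley entropy H₀ = ln *n*. Negative
orders magnify rare, low-probability states — transient receptor
microstates invisible to Shannon entropy.

Conditions are compared with paired two-tailed t-tests
(*t* = d̄ / (s_d/√n), pairing on independent experiments with replicate
wells averaged first) and percentile bootstrap 95 % confidence intervals
(1000 resamples). A stochastic generator of BRET-like traces
(mono-exponential association plus Gaussian, AR(1), or heavy-tailed
burst-renewal noise) makes the whole pipeline testable without laboratory
data.

## Worked example

```r
library(bretropy)

run <- run_pipeline(simulation_config(seed = 42), analysis_config(seed = 42))
run$summary[run$summary$metric == "sampen", ]
#>   condition    n_experiments  mean     sem
#> 1 AngII                    3 1.18  0.0273
#> 2 AngII+LVV-H7             3 0.303 0.00742
#> 3 LVV-H7                   3 2.18  0.175
#> 4 vehicle                  3 2.24  0.136

tidy(run)[1:3, ]   # paired condition comparisons
#>   metric alpha condition_1 condition_2  mean_diff t_stat  p_value ci_low ci_high
#> 1 sampen    NA AngII       AngII+LVV-H7     0.875  27.4  0.00133   0.820   0.931
#> 2 H_norm    -5 AngII       AngII+LVV-H7    -6.35   -6.20 0.0251   -8.29   -4.82
#> 3 H_norm     1 AngII       AngII+LVV-H7     0.246  35.0  0.000816  0.234   0.259
```

Reading the numbers: the agonist+modulator combination has the lowest mean
Sample Entropy (0.30) — the modulator stabilizes receptor signaling into a
regular, predictable trajectory — while the modulator alone produces the
most irregular traces (2.18, burst-like dynamics). The paired comparison
confirms the drop from AngII alone to the combination (mean difference
0.875, t = 27.4, p = 0.0013, bootstrap 95 % CI [0.82, 0.93]). The
normalized Shannon entropy (H₁/H₀, α = 1) drops too, while the *negative*
difference at α = −5 says the combination's value distribution carries
more extreme rare-state structure here — negative orders respond to
features of the kinetic value distribution that SampEn does not measure.

`autoplot(run)` draws the mean normalized spectrum per condition across
orders; `plot_traces()`, `plot_metric_bars()` cover the raw kinetics and
per-condition bars.

### Command line

```sh
Rscript inst/cli/bretropy.R run --seed 9 --out out_dir
Rscript inst/cli/bretropy.R simulate --seed 9 --out traces.csv
Rscript inst/cli/bretropy.R analyze --traces traces.csv --out metrics
Rscript inst/cli/bretropy.R compare --metrics metrics_metrics.json --out comparisons.csv
Rscript inst/cli/bretropy.R report --metrics metrics_metrics.json --comparisons comparisons.csv --out report.md
```

YAML configuration files (field names of `simulation_config()` /
`analysis_config()`) can replace any default; `--seed` overrides the seed.

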