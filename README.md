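# cesdem

Demographic drivers of annual population change from Constant Effort Site
(CES) bird-ringing data.

CES schemes mist-net birds at fixed sites on a fixed visit schedule every
breeding season. Because effort is constant, adult recapture histories
identify apparent survival, the juvenile share of captures indexes
productivity, and adult capture counts index abundance. `cesdem` asks, for
small songbirds: **does annual adult survival or annual productivity
contribute more to year-to-year population change, and does the answer vary
with climate, migratory strategy or breeding habitat?**

The analysis has three steps, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Annual estimates per species × scheme.** A Cormack–Jolly–Seber model
   with a transience mixture,

   `L_i = (1 − τ)·1[never reseen] + τ · Π φ_t p_s^y (1−p_s)^(1−y) · χ`,

   gives annual adult survival `φ_t` (shared across a scheme's sites),
   site recapture probabilities `p_s`, and residency probability `τ`.
   Quasi-binomial and quasi-Poisson GLMs with site + year factors give the
   annual juvenile proportion `ρ_t` and the adult abundance index `x_t`.
   Robustness filters drop sites with `p̂ < 0.10` or `p̂ > 0.90`, survival
   years with SE outside `(0.01, 0.25)`, and species with quasi-dispersion
   ≥ 4.
2. **Per-population growth regression.** `r_t = log(x_{t+1}/x_t)` is
   regressed on z-scaled `φ̂_t` and `ρ̂_t` with weights
   `1/mean(SE)²`, yielding one survival and one productivity coefficient
   per population.
3. **Weighted mixed meta-models** (REML, Satterthwaite t-tests, weights
   `1/SE²`): model A `coef ~ measure + (1|scheme) + (1|species)`;
   model B `coef ~ measure * temperature + (1|species)`; model C
   `coef ~ measure * migration + measure * habitat + (1|scheme) +
   (1|species)`.

Real EuroCES capture data are access-controlled, so the package includes a
multi-scheme synthetic generator (`simulation_config()`,
`simulate_multischeme()`) with exact truth bookkeeping; all estimators are
validated by parameter recovery against that truth.

## Worked example

```r
library(cesdem)

cfg <- simulation_config(n_schemes = 3, n_species = 4, n_sites = 10,
                         n_years = 9, seed = 11)
res <- run_pipeline(pipeline_config(sim_config = cfg, n_starts = 2,
                                    seed = 5))
res$report$counts
#>        stage     n
#>        input 42312
#>     selected 42305
#>  populations    12
#>       growth    12
#>    meta_rows    24
res$meta_fits$A$coefficients
#>         parameter estimate     se    df     t      p
#> 1     (Intercept)   0.0710 0.0293  4.01 2.422 0.0725
#> 2 measuresurvival   0.0112 0.0162 17.45 0.694 0.4969
```

42,312 simulated capture events pass the CES selection filters almost
unchanged, 12 populations (4 species × 3 schemes) yield growth regressions,
and the 24 stacked coefficients feed the meta-models. In model A the
intercept (0.071) is the mean productivity coefficient across populations —
how strongly a one-SD change in annual productivity moves the annual growth
rate — and `measuresurvival` (+0.011) is the additive difference for
survival; at this small simulated size the difference is not significant
(`p = 0.50`). Models B and C (in `res$meta_fits`) add the temperature and
trait interactions.

Sensitivity variants rerun everything under altered thresholds and collect
the model-A effects side by side:

```r
sensitivity_sweep(pipeline_config(sim_config = cfg, seed = 5),
                  list(se20 = list(se_bounds = c(0.01, 0.20)),
                       se25 = list(se_bounds = c(0.01, 0.25)),
                       se30 = list(se_bounds = c(0.01, 0.30))))
```

## Package layout

- `R/capture_table.R`, `R/selection.R`, `R/histories.R` — capture-record
  data model, CSV I/O, CES selection filters, annual capture histories.
- `R/cjs.R` — transient-CJS likelihood (sufficient-statistics form), MLE
  fitting, recapture and survival-SE filters.
- `R/indices.R` — quasi-binomial productivity and quasi-Poisson abundance
  indices, Pearson dispersion, dispersion filter.
- `R/growth.R` — growth rates, z-scaling, inverse-variance weights,
  per-population weighted regression.
- `R/meta.R` — coefficient stacking, weighted LMMs A/B/C, temperature
  gradient predictions.
- `R/simulate.R`, `R/simulate_meta.R` — synthetic CES generator and direct
  coefficient-table generator, both with known truth.
- `R/pipeline.R` — end-to-end orchestration, serialization, sensitivity
  sweeps.
- `vignettes/ces-demography.Rmd` — the model, its assumptions, parameter
  conventions and design choices in detail.
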