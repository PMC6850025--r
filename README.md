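# warmgrowth

Progressive-Change BACIPS analysis of warming effects on fish body growth.

## What this package is for

Long-term whole-ecosystem warming experiments — a heated coastal basin
paired with an unheated reference area — make it possible to ask not only
*whether* elevated temperature changes fish growth, but *how the change
unfolds over decades*: as an immediate plastic response, or gradually,
through adaptation and reorganisation of the biotic environment.

`warmgrowth` implements the full inference chain for this question, for
ecologists working with paired impact/reference monitoring series:

1. **Individual-based simulation** of two-area fish populations with
   temperature- and size-dependent growth
   (`ΔL = k (L∞ − L) · exp(−((T − T_opt(L))/w)²)`, with the optimum
   temperature `T_opt(L) = θ0 − θ1·log(L/L_ref)` declining with body
   size), warming scenarios, and a realistic survey sampling protocol
   (female-only ageing, gillnet selectivity, length-stratified
   subsampling).
2. **Back-calculation** of length-at-age from operculum annuli under the
   body proportional hypothesis with a power relation `L = a·Rᵇ`, so that
   `L_i = L_c (R_i/R_c)ᵇ`.
3. **Growth statistics**: size-at-age and length-specific growth
   `G_L = (L_{t+1} − L_t)/L_t` within discrete, non-overlapping size
   classes per age; annual per-area means and heated-minus-reference
   difference series `δ_t`.
4. **Progressive-Change BACIPS**: least-squares fits of four
   impact-response curves to `δ_t` — step, linear, asymptotic
   `s/(s+γ)`, sigmoid `1/(1+e^{−(s−τ)/γ})` — compared by AICc weights
   `ω`, with the best model's `R²` and an F-test against the constant
   null, plus pre-impact stationarity and shared-warming-trend checks.
5. **Community composition**: first-night CPUE matrices, Chord-distance
   principal coordinates analysis, and BACIPS on the axis-score
   differences.

All stages read and write plain delimited tables, so any stage can be fed
real data instead of simulated output.

## Worked example

The default warming scenario: a +7 °C step in 1980 on a 16 °C reference
growth season, with the juveniles' net growth response emerging gradually
(`gradual_effect_mode`), cohorts born 1969–2003.

```r
library(warmgrowth)

cfg <- sim_config(gradual_effect_mode = TRUE, rng_seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
== Progressive-Change BACIPS pipeline report ==
seed 1, config 4134b1a6
design: 12 growth years before / 24 after onset 1980 (inclusive convention)
  individuals: 1945 heated, 1866 reference
  length-at-age estimates: 6762 heated, 6641 reference
trend difference: slope = -1.293e-16 degC/yr, F_1,24 = 0, p = 1, r^2 = 0
           response best_model weight r_squared  p_value alpha_hat stationary
1     size_at_age_1     linear  87.2%     0.920 1.12e-19      1.09       TRUE
2     size_at_age_3     linear  66.1%     0.853  6.9e-15      1.21       TRUE
3 growth_ageclass_0     linear  78.1%     0.919 1.51e-19     0.227       TRUE
4 growth_ageclass_3       step  56.9%     0.070    0.223   -0.0143       TRUE
5        cpue_perch    sigmoid  82.0%     0.539 0.000278      5.61       TRUE
6              pco1    sigmoid  47.7%     0.318   0.0246     0.273       TRUE
7              pco2     linear  53.3%     0.081    0.143   0.00502       TRUE
```

Reading the table: the size of 1-year-olds diverged **gradually** between
the areas — the linear impact model carries 87% of the AICc weight, with
`R² = 0.92` and a significant positive slope of ~1.1 mm/yr in the
difference series — and the same holds for size-at-age 3 and first-year
growth. Growth of 140–160 mm 3-year-olds shows **no significant
response** (`p = 0.22`): fish of that size sit near their thermal optimum
in the heated area. The community composition shifted **sigmoidally** on
the first ordination axis and not on the second. Pre-impact stationarity
holds for every response, and the post-onset warming-trend difference
between areas is zero by construction.

Per-response detail is available from the comparison objects:

```r
print(report$comparisons$size_at_age_1)
```

```
Progressive-Change BACIPS comparison [size_at_age_1] (n = 35)
       model k    rss   aicc delta_aicc weight
1       step 3 1832.8 145.31     71.127   0.0%
2     linear 3  240.2  74.19      0.000  87.2%
3 asymptotic 4  251.1  78.30      4.116  11.1%
4    sigmoid 5  258.8  82.09      7.902   1.7%
best: linear (R^2 = 0.920, p = 1.115e-19)
```

A thin command-line front-end wraps the same pipeline:

```sh
Rscript inst/scripts/run-pipeline.R run-all --config my-scenario.yaml \
        --seed 1 --outdir results-dir
```

## Documentation

The methods vignette (`vignettes/progressive-change-bacips.Rmd`) explains
the growth model and its parameters, the noise design, the model-selection
machinery and its measured operating characteristics (including the
anti-conservatism of select-then-test p-values), and what the simulator
does and does not emulate.
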