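# pondshift

Analysis machinery for long-term pond-breeding amphibian surveys — and, more
generally, for any patch-network census data where the questions are: *how
does local abundance relate to regional distribution, how much of the
landscape is actually available to each species, and when does a species'
regional state shift abruptly?*

The package grew out of the analysis pattern of multi-decade pond
metacommunity studies, where ~40 ponds are censused yearly for larval
densities of a dozen amphibian species, habitat availability swings with
climate (droughts dry ponds, which removes larval predators and raises pond
quality for early-breeding frogs), and a focal species can flip between a
rare, narrowly distributed state and an abundant, widespread one. Its
audience is quantitative ecologists working with occupancy-abundance data.

## What's inside

| Area | Functions |
|---|---|
| Survey I/O and preparation | `read_survey()`, `season_collapse()`, `cohort_adjust()`, `read_phylo()`, `read_ascii_grid()` |
| Habitat availability | `pond_condition()`, `available_ponds()`, `habitable_set()`, `constrained_occupancy()`, `weighted_suitability()` |
| d-a curve fitting & model selection | `fit_da()`, `fit_saturating()`, `fit_segmented()`, `da_model_suite()`, `aicc_rank()`, `cooks_outliers()`, `pic_regression()` |
| Regime shifts | `stars()`, `stars_sweep()` |
| Connectivity | `hanski_index()`, `effective_resistance()`, `compare_occupied()`, `region_resistance_summary()` |
| Time-series diagnostics | `cross_correlation()`, `tracking_metrics()`, `intraspecific_da()` |
| Synthetic metacommunities | `generate_landscape()`, `simulate_hydrology()`, `simulate_metacommunity()`, `scenario_chorus_frog()` |
| Orchestration | `run_pipeline()`, `write_report()` |

The methods at the core:

* **Sequential t-test regime detection (STARS).** A new value outside the
  current regime mean ± `diff`, with `diff = t · sqrt(2 σ_l² / l)` for
  expected regime length `l`, opens a candidate regime; the Regime Shift
  Index (RSI) cumulates normalised exceedances beyond the critical level over
  an `l`-year testing window, prorated at the series end, signed by
  direction, and invariant to affine rescaling of the series.
* **Information-theoretic d-a model selection.** Mean-only, linear,
  saturating `y = a(1 − bˣ)` and four segmented families, ranked by
  `AICc = n·ln(RSS/n) + 2K + 2K(K+1)/(n−K−1)` with `K` counting the error
  variance, plus Akaike weights and evidence ratios. Breakpoints are located
  by exhaustive midpoint search (max R²), tested by an F-test against the
  nested one-segment model, and given bootstrap confidence intervals.
* **Connectivity two ways.** The incidence-function index
  `S_i = Σ_j N_j exp(−α d_ij)` and circuit-theory effective resistance on a
  friction raster (4-neighbour lattice, edge conductance `2/(f_a+f_b)` per
  cell length, sparse Laplacian solves).
* **A drought-forced synthetic metacommunity** with density-gated dispersal,
  rescue effects and an event-level truth log, for validating every stage
  against known ground truth.

## Worked example

The package ships the published 15-year chorus frog series (ponds occupied,
and log mean larval density in occupied ponds) as `chorus_frog_series()`:

```r
library(pondshift)
cf <- chorus_frog_series()
stars(cf$occupancy, years = cf$year, l = 4, alpha = 0.05)
#> STARS regime-shift analysis (l = 4, alpha = 0.05)
#> sigma_l = 5.177, critical difference = 8.441
#> Confirmed shifts:
#>  year        rsi direction    p_between
#>  2001  1.0254531        up 1.439438e-08
#>  2010 -0.7357028      down           NA
```

The detector finds the two state transitions: the expansion (5-6 occupied
ponds through 2000, jumping to a 19-pond regime in 2001; the RSI of 1.03
measures the strength of the jump in units of the series' short-window
variability, and the Welch p-value says the regime means differ at the
1.4e-08 level) and the single-year collapse to 8 ponds in 2010, caught by the
prorated end-of-series rule. Re-ranking the published constrained d-a
model-selection table reproduces its arithmetic:

```r
aicc_rank(da_constrained_model_table())
#>                       model K  rss  aicc delta   weight evidence_ratio
#> 1                saturating 3 0.16 -48.5  0.00 0.682580           1.00
#> 2 seg_horizontal_horizontal 4 0.13 -46.9  1.63 0.301530           2.26
#> 3                    linear 3 0.32 -39.5  9.01 0.007542          90.51
#> 4    seg_sloping_horizontal 5 0.15 -39.4  9.07 0.007338          93.03
#> 5                      mean 2 0.58 -35.2 13.28 0.000894         763.35
#> 6       seg_sloping_sloping 6 0.16 -31.2 17.33 0.000118        5806.11
```

— the saturating curve is the best-supported model (weight 0.68) with the
two-horizontal-lines threshold model close behind (evidence ratio 2.3), i.e.
strong support for a decelerating, threshold-like constrained d-a
relationship. Finally, density leads occupancy by one year:

```r
cross_correlation(cf$ln_density, cf$occupancy, max_lag = 1)
#>   lag     r  n      p
#> 1  -1 0.255 14 0.3791
#> 2   0 0.439 15 0.1013
#> 3   1 0.612 14 0.0199
```

(positive lag = first series leads: the local-density shift presages the
occupancy shift, the signature of a cross-scale interaction).

A fully synthetic analogue with known ground truth:

```r
b <- scenario_chorus_frog(seed = 1)        # 37 ponds, drought 1999-2007
stars(b$yearly$n_occupied, years = b$yearly$year)$shifts
b$truth                                    # every colonisation/extinction event
```

See the vignette (`vignettes/pond-metacommunity-analysis.Rmd`) for the full
model descriptions, parameter conventions and design decisions.

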