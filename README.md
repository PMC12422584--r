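# capsakinesis

Quantitative tools for **chemokinesis** — a change in cell crawling speed
with local chemical concentration, without directional bias — in the
predatory amoeba *Capsaspora owczarzaki*, which hunts and irreversibly
attaches to schistosome sporocysts. The package serves two audiences:

* **cell-tracking analysts**, who need the exact exclusion rules and
  velocity/displacement statistics used to measure chemokinesis and
  chemotaxis from time-lapse spot-tracking tables, plus synthetic track
  generators with known ground truth to validate those pipelines; and
* **modellers**, who want the agent-based predator–prey simulation that
  asks whether a purely non-directional speed response can benefit
  predation at all.

## The core model

Cells are discrete-time persistent random walks: per step the heading turns
by a truncated-normal angle (SD σ, bound ±π) and the cell advances by an
exponentially distributed step. The mean-squared displacement obeys the
correlated-random-walk closed form

    E[R_n²] = n·m₂ + 2μ² Σ_{k=1}^{n-1} (n−k)·cᵏ,   c = E[cos θ],

(the Fürth formula in the continuum limit), which the package exposes as
`prw_msd_theory()` and uses as an analytic oracle in its tests.

Chemokinetic speed follows a Hill curve
`v(c) = v0 + (vmax − v0)·c^h/(EC50^h + c^h)` fitted to dose–response data by
bounded Levenberg–Marquardt (`fit_response_curve()`). In the simulation, a
stationary circular prey exudes a chemical that disperses by 2-D diffusion
(explicit finite differences, validated against the Green's function);
2000 predator agents crawl, speed up with local concentration when
chemokinesis is enabled, and attach irreversibly on touching the prey. The
headline statistic is the **cumulative residence time** — total attached
cell-time over a 120-minute hunt — compared between chemokinesis-on and
chemokinesis-off conditions.

Track filtering reproduces the standard assay rules: steps > 11.2 µm or
gaps > 3 frames reject a track, tracks need ≥ 3 frames, cells are selected
70–240 µm from the prey (`policy_schistosome()`); the plate-reader "mean
velocity" averages cells with total path ≤ 60 µm tracked ≥ 18 frames
(`policy_cytation()`); calcium traces use a 2.30 µm step filter and
initial-intensity normalization (`policy_fluo4()`, `normalize_fluor()`).

## Worked example

Generate synthetic tracks near a pseudo-prey, filter them with the standard
policy, and pool the chemokinesis window:

```r
library(capsakinesis)

cfg <- track_gen_config(n_cells = 80, n_frames = 60, speed = 2,
                        turn_sd = 0.3, spurious_rate = 0.003,
                        gap_rate = 0.02, arena = c(500, 500), seed = 7)
trk <- generate_tracks(cfg)
ref <- c(250, 250)                       # pseudo-prey at the arena centre

flt <- filter_tracks(trk, policy_schistosome(), ref = ref)
flt
#> <track_filter_result> kept 38 of 80 tracks
#>   rejected by rule:
#>     step: 19
#>     annulus: 23

v <- chemokinesis_window(flt$tracks, ref, r_lo = 70, r_hi = 240, t_max = 900)
round(c(n_steps = length(v), mean_velocity = mean(v)), 2)
#>       n_steps mean_velocity
#>        534.00          1.97
```

The step rule removed 19 tracks — all 8 carrying injected floating-cell
artifacts, plus 11 whose heavy-tailed exponential steps naturally exceeded
11.2 µm — and the annulus rule removed the 23 cells outside 70–240 µm; the
pooled early-window velocity recovers the generator's 2 µm/min.

Fit a dose–response curve and read off the EC50:

```r
dr <- generate_dose_response(dose_gen_config(
  doses = c(0, 0.1, 0.3, 1, 3, 10), v0 = 1, vmax = 3, ec50 = 1,
  noise_sd = 0.1, replicates = 3, seed = 2))
fit_response_curve(dr)
#> <response_curve> v0 = 1.01, vmax = 2.887 um/min; EC50 = 0.8023 mg/ml; hill = 1.06
#>   residual SD 0.115, converged: TRUE
```

Run a reduced predation comparison (the full study size is 2000 cells for
7200 s; see the vignette):

```r
on  <- run_simulation(sim_config(n_cells = 500, duration = 3600,
                                 chemokinesis = TRUE,  seeds = 1:3))
off <- run_simulation(sim_config(n_cells = 500, duration = 3600,
                                 chemokinesis = FALSE, seeds = 4:6))
compare_conditions(on, off)
#> <condition_comparison>
#>   cumulative residence on : 6.74e+04 +/- 5.49e+03 cell-s (SEM)
#>   cumulative residence off: 5.398e+04 +/- 3.42e+03 cell-s (SEM)
#>   ratio (on/off): 1.249
#>   attachment fraction on : 0.082, 0.068, 0.072
#>   attachment fraction off: 0.068, 0.070, 0.052
#>   P(on attaches earlier), one-sided rank test: 0.224
```

Even at a quarter of the study's population and half its duration, the
cumulative residence benefit is ~1.25×; the earlier-attachment rank test
needs the full-size runs (or pooled replicates) for power.

## Package layout

| file | contents |
| --- | --- |
| `R/synthetic-tracks.R`, `R/synthetic-dose.R` | generators with ground truth |
| `R/filter-policy.R`, `R/track-analysis.R` | filters and velocity statistics |
| `R/dose-response.R` | Hill fitting, speed map, serum arithmetic |
| `R/chemo-field.R` | diffusion solver, source model, burst profiles |
| `R/predation-sim.R` | agent engine, scenarios, condition comparison |
| `R/io.R` | track CSV dialect, YAML configs, run manifests |
| `vignettes/chemokinesis-model.Rmd` | model assumptions, defaults, limits |
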