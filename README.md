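# gadfly

Migratory-consistency analysis for pelagic seabirds tracked with archival
light-level geolocators (GLS), built around a tropical gadfly-petrel
system: a colony at (57.78 E, 19.85 S) whose birds breed year-round,
migrate across much of the Indian Ocean, and are repeat-tracked over
several annual cycles. The package reimplements the full analysis chain as
tested, reusable R functions, together with a synthetic-data generator so
that every stage can be validated against known ground truth.

## What it computes

* **Geolocation.** Twilight detection at a tag-specific light threshold;
  zenith-angle calibration at a known site; initial positions by the
  threshold method (longitude from the twilight midpoint, latitude from
  day length); and Bayesian refinement by MCMC with a one-sided
  log-normal twilight-error density (log-normal(meanlog 2.2, sdlog 1.0)
  minutes — shading only delays sunrises and advances sunsets), a gamma
  flight-speed prior (shape 2.0, rate 0.1 on km/h), a Gaussian
  sea-surface-temperature likelihood against a weekly 1-degree field, and
  a land mask with zero probability on land. Schedule: 2000 relaxed
  burn-in samples, 3 x 300 convergence check (split-chain R-hat < 1.1),
  then 4 chains x 3000 retained samples, summarised to median tracks with
  95% credible intervals.
* **Segmentation.** Daily ashore/at-sea states from a two-state hidden
  Markov model over three features: proportion of daytime light samples
  with interference, daily wet-count sum, and geodesic distance from the
  colony. Migration = a decoded at-sea run of at least 90 days; departure,
  arrival (days from 1 June, negative-day conversion across the origin)
  and duration follow.
* **Similarity.** Earth mover's distance (EMD) between migration point
  sets — exact optimal transport with Haversine ground cost, solved by a
  C++ network simplex — for all track pairs, plus Bhattacharyya's affinity
  (BA) between kernel utilisation distributions (h = 200 km, equal-area
  projection). Migrations are also split into 30-day periods and six equal
  stages for within-individual spatiotemporal comparisons.
* **Statistics.** Repeatability R = among / (among + residual) variance
  from Gaussian random-intercept models with 1000-iteration parametric
  bootstrap CIs; gamma/identity GLMs of EMD on the same-individual flag
  and departure-date difference (binomial/log for BA); seasonal
  variability GLMs; backwards stepwise deletion; Tukey-adjusted
  marginal-mean contrasts.

## Worked example

A complete pipeline run on a simulated population of 20 petrels tracked
for two petrel years each, with individual-specific departure phenology
(between/within SD 20/10 d) and destinations reused across years:

```r
library(gadfly)
cfg <- sim_config(n_individuals = 20, years_per_individual = 2)
res <- run_pipeline(cfg, seed = 1, n_boot = 200)

res$stats$repeatability$departure
#> Repeatability R = 0.614 [0.258, 0.822], p = 0.00148 (N_ind = 20, N_obs = 40)

w <- res$comparisons$whole
mean(w$emd_km[w$same_individual == 1])   #> 522.2 km   (within-individual)
mean(w$emd_km[w$same_individual == 0])   #> 2916.0 km  (between-individual)

res$stats$emd_glm$coefficients
#>                  estimate       se      stat             p
#> (Intercept)      2915.971 58.08005  50.20607  0.000000e+00
#> same_individual -2393.748 86.51380 -27.66897 1.650211e-168
```

All 40 simulated deployments yield a complete migration; the estimated
departure repeatability (0.61, CI covering the generator's true 0.8 at
this sample size) and the strongly negative same-individual EMD
coefficient recover the planted structure: individuals reuse their own
non-breeding areas, so within-individual migrations are far more similar
(~520 km of transport effort) than between-individual ones (~2900 km).
The run takes about four minutes on one CPU.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the packaged end-to-end analysis from scratch on a seeded
synthetic population — rendering raw logger files, re-estimating
positions, segmenting behaviour, and refitting the similarity and
repeatability models — logging the headline quantities it computed and
writing the JSON report to `--out`.
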