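# bloomsat

Satellite flowering phenology from blossom detections.

Some tropical pioneer trees — magenta-flowering *Pleroma* stands of the
Brazilian Atlantic Forest are the motivating case — bloom so synchronously and
so densely that a 10 m satellite pixel changes colour. `bloomsat` turns a time
series of 4-band (RGB + NIR) reflectance scenes into a map of where such
stands are and when each one flowers:

* **Detection.** Scenes are filtered by cloud cover (< 80%, tightened to
  < 25% outside the December–June flowering season), converted from 12-bit to
  8-bit reflectance (values capped at 2540 and divided by 10; the NIR band
  first divided by 3.937), and tiled into 136 × 136 patches whose 128 × 128
  cores define a 1280 m analysis grid (an 80 × 80 grid for a native scene).
  A small convolutional encoder — conv/pool blocks, a dense layer, dropout and
  a 2-class softmax, trained with RMSprop, class-weighted cross-entropy,
  flip-only augmentation and best-epoch selection — classifies each patch; a
  deterministic colour-rule detector serves as test oracle.
* **Phenology.** Per grid pixel, daily observation states (detected / clear /
  cloud / missing) are pooled into monthly detection fractions, cleaned and
  weighted, and fitted with the constrained three-harmonic model

  bloom(t) = bloom₀ + pow₀ · ( p₄ sin(2πt/4 + ρ₄) + p₆ sin(2πt/6 + ρ₆)
  + p₁₂ sin(2πt/12 + ρ₁₂) ),  p₄ + p₆ + p₁₂ = 1,

  solved as exact weighted *linear* least squares in the sine/cosine basis.
  The reconstructed daily curve gives the start, peak and end day of each
  flowering episode.
* **Populations and environment.** K-means on event dates, bloom values and
  down-scaled coordinates groups pixels into phenological populations, and a
  decile-class bootstrap null tests whether presence is spatially associated
  with elevation, slope, tree cover, precipitation and temperature.
* **Synthetic worlds.** A seeded generator produces ground-truth presence
  grids, per-population phenology, covariates, rendered scenes (green forest,
  clumped magenta stands, pink-soil confounders, cloud masks) and shortcut
  observation series, so the full pipeline runs and is tested without any
  satellite data.

## A worked example

One pixel whose ground truth peaks on day 80 (late March) with an 80-day
episode, observed daily for a year with 20% cloud cover and imperfect
detection:

```r
library(bloomsat)

world <- generateWorld(worldConfig(
  gridRows = 1, gridCols = 1, nPopulations = 1,
  peakDays = 80, durationDays = 80, amplitude = 0.9,
  backgroundFraction = 1,
  covariateLink = c(elevation = 0, slope = 0, treecover = 0),
  twoPeakFraction = 0, cloudProb = 0, seed = 42))

dates <- seq(as.Date("2018-01-01"), by = "day", length.out = 365)
obs <- simulateObservations(world, dates, pDetect = 0.9,
                            cloudProb = 0.2, seed = 1)
res <- fitPixelPhenology(obsStates(obs)[1, 1, ], dates)
res$fit
#> BloomFit: bloom0=3.770 pow0=9.345 p=(0.71, 0.18, 0.11) rho=(2.94, 1.71, 0.24) wR2=1.0000
res$events
#>   start_day peak_day end_day peak_value duration_days
#> 1        37       81     126    9.78986            89
```

The monthly detection fractions (`round(res$monthly$values, 2)`) were
`0 0.24 0.96 0.52 0 0 0 0 0 0 0 0`: flowering visible from February to April,
strongest in March. The fit explains them exactly (weighted R² = 1), and the
reconstructed daily curve puts the peak on day 81 — one day off the truth —
inside an episode running from day 37 to day 126.

The full eight-stage pipeline on a packaged synthetic demo (a 20 × 20-cell
world, 48 monthly scenes, a two-block detector trained on oracle-labelled
patches) runs in a few minutes:

```r
dirs <- runPipeline(demoConfig(seed = 1))
read.csv(file.path(dirs$cluster, "summary.csv"))
```

Every stage writes CSV/TIFF artifacts plus a manifest of its parameters and
input checksums; re-running a finished pipeline is a no-op. A thin shell
wrapper lives at `inst/scripts/bloomsat-pipeline.R`
(`Rscript bloomsat-pipeline.R --demo`).

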