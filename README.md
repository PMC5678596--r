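# dielpheno

Diel plant growth phenotyping from top-view VIS/NIR time-lapse imagery.

Arabidopsis rosettes are imaged from above throughout the 24-h light–dark
(diel) cycle: RGB (VIS) frames while the lights are on, near-infrared (NIR)
grayscale frames in the dark. `dielpheno` turns such a session into per-plant
growth traits:

* **VIS segmentation** by per-channel range thresholding in RGB, HSV or CIE
  Lab colour space, or by grayscale Otsu (between-class-variance maximum);
* **NIR segmentation** with a two-region Chan–Vese active contour — energy
  `E = μ·|∂Ω| + λ_in·Σ_in (I − c_in)² + λ_out·Σ_out (I − c_out)²` — seeded
  from the adjacent VIS mask and propagated frame to frame, forward (with an
  expansion bias) and in reverse from the following morning's mask (with a
  contraction bias), the two passes averaged;
* **uneven-illumination correction** for single-channel frames (robust
  quadratic trend + Gaussian-smoothed residual field);
* **stable plant identities**, numbered left-to-right automatically or from
  user-supplied seed coordinates;
* **projected rosette area** (PRA, mm² via pixel calibration) per plant per
  frame, and **relative expansion rate**
  `RER = (ln PRA₂ − ln PRA₁)/(t₂ − t₁)` (day⁻¹), both as daily values from
  light-period endpoints and as a diel series from a 10-frame
  sliding-median-smoothed PRA curve;
* a **synthetic scene generator** (growing lobed rosettes on textured soil,
  NIR radial falloff, dawn PRA dip from leaf movement, per-frame ground
  truth), which makes the whole pipeline testable without real imagery.

It is aimed at plant scientists running affordable top-view rigs who want
continuous day+night growth curves — including phenomena like the transient
PRA dip after dawn caused by epinastic leaf movement — without hand-tracing
frames.

## Worked example

Simulate one diel cycle (12:12 photoperiod, 20-min frames) of a wild-type-like
6-plant tray and run the full pipeline:

```r
library(dielpheno)

scene <- generate_session(scene_preset("wt", width = 280, height = 170,
                                       n_cols = 3, n_rows = 2, n_days = 1,
                                       rng_seed = 42))
scene$session
#> Diel session: 72 frames (36 VIS, 36 NIR), 2 periods
#>   period_index kind  first_frame last_frame n_frames
#> 1            1 light           1         36       36
#> 2            2 dark           37         72       36

cfg <- as_pipeline_config(list(calibration = list(mm_per_pixel = 0.25)))
result <- process_session(scene$session, cfg)
result
#> Diel trait set: 6 plants x 72 frames (2 periods); 0 warnings

glance(result)
#>   n_plants n_frames n_periods frac_missing final_mean_pra_mm2 mean_daily_rer
#> 1        6       72         2            0               72.6          0.206
```

Each plant started at 60 mm² and grew at r = 0.20 day⁻¹, so after one day the
pipeline's final mean PRA of 72.6 mm² (true: 60·e^0.2 ≈ 73.3) and the mean
daily RER of 0.206 day⁻¹ recover the generating conditions to within a few
percent; the daily RER is slightly above r because its endpoints span only
the light period, and the 10% dawn dip depresses frames near its start.

```r
library(dplyr)
tidy(result) |> filter(frame_index == 72) |> select(plant_id, pra_mm2)
#>   plant_id pra_mm2
#> 1        1    72.4
#> 2        2    72.3
#> 3        3    73.3
#> 4        4    73.1
#> 5        5    72.8
#> 6        6    71.8

autoplot(result)        # PRA trajectories, dark period shaded
autoplot(result$diel)   # diel RER series
```

On-disk sessions work the same way through a YAML config: `run_pipeline()`
(or the `exec/dielpheno` script with subcommands `simulate`, `segment-vis`,
`segment-nir`, `traits`, `run`) loads the images, writes labelled mask PNGs,
a `traits.csv`, daily and diel RER tables, and a run manifest.

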