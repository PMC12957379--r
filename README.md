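# mixinject

Design and diagnostics for segmented-droplet **mix-and-inject serial
femtosecond crystallography** (MISC / TR-SFX) at X-ray free-electron
lasers.

In a mix-and-inject experiment, microcrystals are mixed with a substrate a
defined time before they cross the X-ray beam, so that each diffraction
pattern is a snapshot of the reaction at time point *t_R*. Segmented
droplet injection wraps the mixed aqueous stream into oil-separated
droplets synchronized with the accelerator's pulse trains, so crystal
sample flows only when X-rays can probe it. `mixinject` is aimed at the
people who design and run such experiments — sample-delivery developers
and beamline scientists — and implements:

* **Reaction time points** — a device is three channel sections
  (mixing channel A, droplet-formation channel B, exit capillary C) with
  per-section mean velocities *v = Q/S*; the time point is
  *t_R = t_A + t_B + t_C* with the aqueous flow in A and the total flow in
  B and C. Two published Y-mixer droplet generators ship as presets
  (`preset_device("DG250-Y")`, `preset_device("DG300-Y")`).
* **Mixing** — an implicit marching solver for the parabolized laminar
  advection–diffusion equation *u(y) ∂c/∂x = D ∂²c/∂y²* in the mixing
  channel, an Einstein-relation viscosity correction for substrate
  diffusivities (*D η = D_ref η_ref*), the equimolarity mixing criterion
  (substrate concentration equal to the in-crystal protein concentration),
  and the streamline mixing-time spread Δt_m.
* **Droplets vs pulse trains** — the train-spanning condition
  *V_min = π r² v_jet n Δ* for a rod-shaped droplet in the jet, and
  droplet volumes from the flow balance *V = Q_aq / f*.
* **Synchronization** — an integrate-and-fire oscillator with a
  phase-resetting trigger capture model, synthetic detector traces, event
  detection, waterfall matrices, circular-statistics lock-in reports, and
  crystal-hit overlays.
* **Sample accounting** — indexed patterns per µL, protein mass, and
  savings versus a continuous jet at the same total flow and duration
  (*savings = 1 − Q_X/Q_T*).

Everything is data-frame-first: results come back as tibbles (with
`tidy()`/`glance()` methods on richer objects and `autoplot()` for fields
and waterfalls), so calls compose with the pipe.

## Worked example

Time point and droplet condition for the 150 µm device at its 1.2 s
operating flows:

```r
library(mixinject)

dev <- preset_device("DG300-Y")
fl  <- flow_config(Q_X = 0.5, Q_S = 0.4, Q_O = 18.3)  # uL/min
glance(residence_breakdown(dev, fl))
#> # A tibble: 1 × 5
#>   device    t_A    t_B   t_C   t_R
#>   <chr>   <dbl>  <dbl> <dbl> <dbl>
#> 1 DG300-Y 0.792 0.0200 0.378  1.19
```

The crystals spend 0.79 s mixing with substrate in section A, 0.02 s in
the droplet-formation section, and 0.38 s in the capillary: the probed
reaction time point is 1.2 s. Does a 10 Hz droplet from 0.9 µL/min of
aqueous flow span the 202-pulse train?

```r
spans_train(droplet_volume_from_flow(fl$Q_aq, 10), jet_spec(), pulse_train())
#> # A tibble: 1 × 3
#>   spans margin min_volume_pL
#>   <lgl>  <dbl>         <dbl>
#> 1 TRUE    2.14          702.
```

Yes — 1.5 nL against a ~700 pL minimum (margin 2.1). Consumption for the
two published operating points:

```r
runs <- tibble::tibble(
  t_R_s = c(0.3, 1.2), collection_time_min = c(38, 85.5),
  n_indexed = c(18794, 10992), Q_X_uL_min = c(4.9, 0.5),
  Q_T_uL_min = c(28.1, 19.2), protein_mg_mL = c(18, 25.5)
)
consumption_report(runs) |>
  dplyr::select(t_R_s, patterns_per_uL, protein_mass_mg, savings_fraction)
#> # A tibble: 2 × 4
#>   t_R_s patterns_per_uL protein_mass_mg savings_fraction
#>   <dbl>           <dbl>           <dbl>            <dbl>
#> 1   0.3             101            3.35            0.826
#> 2   1.2             257            1.09            0.974
```

101 and 257 indexed patterns per µL of crystal sample, with 83% and 97%
of the sample saved relative to a continuous jet. And a 30 s simulated
triggered run at 180 V locks immediately and stays locked:

```r
b <- make_scenario("locked_train", seed = 1, params = list(duration_s = 30))
glance(lock_in_report(b$events))
#> # A tibble: 1 × 5
#>   n_windows circular_sd_s locked_fraction longest_locked_run missing_windows
#>       <int>         <dbl>           <dbl>              <int>           <int>
#> 1       300             0               1                296               0

autoplot(fold_waterfall(b$events))  # vertical stripe at the trigger delay
```

See `vignettes/mix-and-inject-design.Rmd` for the models, their
assumptions, and the numerical choices.

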