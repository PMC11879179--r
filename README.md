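# bftforage

Visual foraging, bioenergetics and food limitation of Atlantic bluefin tuna
(*Thunnus thynnus*) larvae.

Bluefin tuna spawn in some of the warmest, most oligotrophic waters of the
ocean — for the eastern Atlantic stock, the Balearic Sea in early summer.
Their larvae are among the fastest-growing in the sea, yet zooplankton
concentrations in the mixed layer they inhabit are an order of magnitude
below those of productive coastal waters. `bftforage` asks, mechanistically,
whether that prey field can actually feed them: it couples a visual
prey-encounter model to a larval energy budget and computes the *critical
prey densities* at which a larva of a given developmental stage either covers
its metabolism (maintenance) or grows at its temperature-dependent ceiling
(ad-libitum growth). It is aimed at larval-fish ecologists and ichthyoplankton
survey groups who want to turn station tables of nauplii, cladoceran and
copepod counts into a stage-resolved food-limitation assessment.

## The model

For a larva of standard length *L* (mm) and dry weight
*W* = 0.0008·e^(0.9052·L) mg, the hourly daylight growth budget is

    SGR · W = α · Σ_prey i_prey − R_(L,T)

with assimilation efficiency α = 0.77 and routine metabolism

    R_(L,T) = 0.404 · W^0.994 · 32 · 0.88 · (12/34) · (100/45000) · 2^((T−26)/10)   [mg dw h⁻¹]

Ingestion of each prey type follows a linear clearance model,
*i* = P · β · N · W_prey, where N is prey concentration (m⁻³), W_prey the prey
dry mass, P the capture probability, and the search rate
β = ½·π·R²·V_L sweeps a half visual field at V_L = 3 body lengths s⁻¹.
The detection distance R = c·l_prey·L is proportional to prey length and to
larval length (eye development); the single optical constant *c* is
calibrated in closed form from one published threshold (a pre-flexion larva
feeding only on nauplii at 22 °C needs ≈4000 nauplii m⁻³ to grow at the
ceiling), which makes every other threshold an out-of-sample prediction.
Larvae do not feed in darkness; the daily rate accrues over a 15 h
photoperiod and is capped at the ad-libitum rate
SGR_T = 0.0418·T − 0.8355 day⁻¹. The food limitation index
FLI = realized SGR / SGR_T flags stations where food, not temperature, sets
the growth rate.

## Worked example

```r
library(bftforage)

params <- calibrate_detection()       # one-point calibration, c ≈ 7.34 mm⁻¹
stages <- default_stages(params)      # F0-F3: 4.8, 5.8, 6.7, 7.5 mm
prey   <- default_prey()              # nauplius, cladoceran, copepod

critical_density_table(stages, prey["nauplius"], c(22, 25, 28),
                       "max_growth", params)
#>    stage temperature_c critical_density_m3
#> 1     F0            22                4000
#> 2     F1            22                5589
#> 3     F2            22                8166
#> 4     F3            22               11982
#> 5     F0            25                7188
#> ...
#> 12    F3            28               31543
```

Nauplii requirements rise steeply with temperature and larval size: at 28 °C
a post-flexion larva needs ≈31 500 nauplii m⁻³ — far above anything the
surveys record (means of a few hundred m⁻³). The station-level assessment
makes the same point on (here synthetic) survey data:

```r
stations <- generate_stations(17, default_profiles()[["2020"]], seed = 42)
res <- assess_stations(stations, stages, params, prey)
aggregate(fli ~ scenario, res, function(x) round(mean(x), 3))
#>         scenario    fli
#> 1 cladocera_only  0.594
#> 2       combined  1.000
#> 3  copepods_only  1.000
#> 4   nauplii_only -0.586
```

A nauplii-only diet fails everywhere (mean FLI < 0: larvae would shrink),
while a few copepods per cubic metre release the limitation entirely — the
mechanism by which rare large prey sustain fast growth in an oligotrophic sea.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/bftforage gen-synthetic --year 2020 --n 17 --seed 42 --out-dir out
Rscript inst/scripts/bftforage assess-stations --stations out/stations_synthetic.csv --out-dir out
Rscript inst/scripts/bftforage critical-densities --temps 22,25,28 --out-dir out
```

Each run writes a manifest (seed, calibrated constant, config hash) beside
its CSV outputs.

## Documentation

The methods vignette (`vignettes/food-limitation-model.Rmd`) documents the
model assumptions, the calibration, the accounting choices, the synthetic
survey generator and known limitations.
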