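---
title: "A foraging and bioenergetics model of food limitation in bluefin tuna larvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A foraging and bioenergetics model of food limitation in bluefin tuna larvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bftforage)
```

## The question the model answers

Atlantic bluefin tuna larvae grow close to the fastest rates recorded for
marine fish larvae, in mixed-layer waters whose zooplankton standing stocks
are nominally meagre: a few hundred copepod nauplii per cubic metre, tens to
hundreds of cladocerans and 1-mm copepods. Whether such a prey field can pay
for such growth depends on three things this package models explicitly:
how much water a small visual predator can search per hour in very clear
water, how much each captured prey item is worth energetically, and how fast
metabolic costs rise with temperature. The central output is the *critical
prey density* — the single-prey concentration at which a larva of a given
stage at a given temperature exactly meets a growth target — and its
station-level counterpart, the food limitation index (FLI).

## The growth budget

A larva of standard length $L$ (mm) has dry weight
$W = a\,e^{bL}$ mg with $a = 0.0008$, $b = 0.9052$. The hourly daylight
budget is

$$\mathrm{SGR}_h \, W = \alpha \sum_{prey} i_{prey} - R_{L,T},$$

with assimilation efficiency $\alpha = 0.77$. Routine metabolism is a
near-isometric power law in mass measured as oxygen consumption at 26 °C and
converted to dry-mass units by a fixed multiplicative chain,

$$R_{L,T} = 0.404\,W^{0.994}\cdot 32 \cdot 0.88 \cdot \tfrac{12}{34}
  \cdot \tfrac{100}{45000} \cdot Q_{10}^{(T-26)/10},\qquad Q_{10}=2 .$$

The conversion factors (oxycalorific, protein, carbon and dry-weight steps)
are stored as an ordered vector in `model_params()$resp_conversions` rather
than pre-multiplied, so the chain remains auditable and each factor can be
overridden individually. Their individual biological glosses are not
load-bearing: only the product enters the model.

Ingestion of each prey type is a linear clearance process,
$i = P \,\beta\, N \,W_{prey}$: no handling time and no satiation, so the
functional response never bends. Saturation enters the model in exactly one
place — the realized daily growth is capped at the temperature-dependent
ad-libitum ceiling

$$\mathrm{SGR}_T = 0.0418\,T - 0.8355 \quad [\mathrm{day}^{-1}],$$

a line fitted to rearing experiments between 22 and 28 °C. Outside that
window the package warns rather than errors: the line extrapolates (it
crosses zero just below 20 °C, which is also roughly the lower thermal limit
for the larvae, a reassuring coincidence but still an extrapolation). A gut
state variable would be the natural refinement; it is deliberately out of
scope.

## Visual encounter

The search rate for a prey type is a half-field clearance kernel,

$$\beta = \tfrac{1}{2}\pi R^2 V_L,$$

where $V_L$ is the cruising speed (3 body lengths s⁻¹) and $R$ the visual
detection distance. The larva scans upward against the bright sea surface,
hence the factor ½. Detection is taken proportional both to prey length
(bigger targets subtend larger angles) and to larval length (a proxy for eye
growth and retinal development):

$$R = c \cdot l_{prey} \cdot L,$$

with a single optical constant $c$ (mm of detection distance per mm prey per
mm larva). A full acuity model of the larval eye would predict $R$ from
photoreceptor densities; we compress all of that into $c$ and set it by a
**one-point calibration**: `calibrate_detection()` solves, in closed form,
for the $c$ at which a pre-flexion (F0) larva feeding only on nauplii at
22 °C reaches ad-libitum growth at exactly 4000 nauplii m⁻³. With the
default constants this gives $c \approx 7.34$ mm⁻¹ — e.g. an F0 larva
detects a 0.15-mm nauplius at about 5.3 mm. Every other threshold the model
produces (other stages, other temperatures, cladocerans, copepods,
maintenance rather than maximum growth) is then an out-of-sample prediction;
the test suite checks a grid of published thresholds against them at a ±25 %
band. Night detection is zero — the larvae
do not feed in darkness — which also realizes the 15-hour feeding day below.

Because ingestion is linear in density, the critical density has the closed
form $N^* = i_{req}/(P\,\beta\,W_{prey})$, and cross-prey thresholds obey
$N^*_A/N^*_B = (W_B l_B^2)/(W_A l_A^2)$ exactly: a 3.15-µg, 0.8-mm cladoceran
is worth roughly 800 nauplii, which is why cladoceran thresholds sit three
orders of magnitude below naupliar ones. The suite verifies the closed form
against scalar root-finding on the growth budget to $10^{-9}$ relative on
random configurations.

## Capture probability

Nauplii are captured whenever encountered ($P = 1$ at all larval sizes).
For the larger, more evasive cladocerans and copepods, capture skill grows
with development; the package implements a linear ramp in larval length from
0 at first feeding (3.0 mm) to 1 at post-flexion (7.5 mm). The ramp
endpoints are a design choice — chosen so that a post-flexion larva has full
capture skill — since no measured endpoints are available.

Two modes are exposed via `model_params(capture_mode=)`:

* `"calibration"` (default): $P = 1$ for every prey and stage. The published
  cladoceran threshold for *pre-flexion* larvae (≈5 m⁻³ at 22 °C) is
  numerically consistent with full capture skill already at F0, so this mode
  is the one under which published results are reproduced.
* `"ontogenetic"`: the ramp is applied per prey type. Under this mode a
  first-feeding larva cannot meet any target on copepods alone; the critical
  density returns an `Inf` sentinel rather than an error, so tables remain
  rectangular.

Both behaviours are tested; neither is asserted to be the biologically
correct ontogeny, which the available thresholds cannot distinguish.

## Day/night accounting

The daily budget multiplies the hourly daylight rate by the 15-h photoperiod.
What happens to metabolism during the 9 dark hours is genuinely
underdetermined: the ad-libitum growth line was measured over full days in
rearing tanks and may already embed night costs. The default
(`metabolism_accounting = "daylight"`) charges metabolism only over the
feeding hours; it reproduces the published ratio of maximum-growth to
maintenance thresholds (≈2) distinctly better than full-day accrual. A
`"full_day"` mode, which additionally subtracts $(24-15)\,R/W$ from the daily
rate, is provided for sensitivity work. All limitation outputs record the
uncapped rate, the cap flag and FLI = realized/ceiling (clipped at 1), with
maintenance failure (negative realized growth) reported as its own flag.

## The synthetic survey generator

`generate_stations()` emulates the statistical structure of the two Balearic
Sea surveys summarised in `default_profiles()` (17 zooplankton stations per
year): per-variable abundance mean, SD and observed range, the number of
stations with no cladocerans or no bluefin larvae (3 and 3 in 2020, 1 and 2
in 2022), and mixed-layer temperature ranges (23.1–25.3 °C in 2020,
23.9–25.5 °C in 2022). Abundances are lognormal — the observed ranges are
far wider above the mean than below it (cladocerans 2020: range 1–7272
around a mean of 653) — clipped to the observed range; temperature is a
truncated normal; coordinates are uniform in the survey box, with no spatial
autocorrelation, because the surveys found the prey field near-homogeneous;
bluefin larvae are drawn independently of prey, as observed.

Two numerical choices matter here:

* *Location calibration.* Clipping a heavy-tailed lognormal to the observed
  range biases its mean (for the 2022 nauplii profile, by ≈12 %). The
  generator therefore keeps the lognormal shape from the target coefficient
  of variation but solves for the location at which the *post-clip*
  expectation equals the target mean (closed-form clipped mean plus
  `uniroot`); the truncated-normal temperature location is calibrated the
  same way. The SD is matched before clipping and is consequently biased
  low after it — the price of honouring both the range and the mean.
* *Zero inflation.* The printed survey means are treated as averages over
  all stations including absences, so the positive component targets
  mean/(1 − p₀). When exactly the survey-sized n = 17 is requested the
  absence count is forced; otherwise absences are Bernoulli with the
  equivalent probability.

What passing tests on synthetic stations do and do not show: they confirm
the *pipeline* (thresholds vs realistic density magnitudes, scenario
ordering, zero-inflation handling), not the field data themselves — the
generator imposes independence between variables, lognormal shapes and
homogeneity that real cruises only approximately satisfy, and it cannot
reproduce year-specific spatial patchiness (the 2022 cladoceran patchiness
is represented only through its absence count and low mean).

## Numerical choices and degenerate inputs

* Critical densities are closed-form algebra; root-finding appears only in
  test oracles and in the generator's location calibration (`uniroot`,
  tolerance 10⁻¹²).
* The calibration is exact by construction; re-calibrating from any
  model-generated threshold recovers $c$ to 10⁻⁹ relative (tested).
* Empty diets are legal and mean starvation (the budget is pure metabolic
  loss); negative densities are domain errors at the library surface, while
  the station assessor reports and skips malformed rows so one bad line
  cannot kill a survey run. Missing station temperatures fall back to a
  configured default (24.5 °C) with a warning.
* All CSV output is written at full double precision; rounding happens only
  in printed logs.

Problem sizes throughout the test suite are desk-scale by design — the
whole threshold grid is a few hundred scalar evaluations, the oracle
comparisons run 100 random configurations, and moment-recovery checks use
10⁴ synthetic stations — so the complete suite runs in seconds.

## Known limitations

No gut capacity or specific dynamic action; assimilation efficiency is
temperature-independent; swimming costs are folded into routine metabolism
rather than modulated behaviourally; light enters only as day/night, not as
intensity, turbidity or moon phase; prey quality is size and dry mass only
(no stoichiometry, pigmentation or fatty-acid value); and piscivory after
post-flexion — which likely ends the planktivorous food limitation this
package quantifies — is out of scope.
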