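---
title: "Forecasting crop evapotranspiration with remote canopy parameters and temperature forecasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting crop evapotranspiration with remote canopy parameters and temperature forecasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropet)
library(dplyr)
```

## The problem

Open-field irrigation in dry-summer climates is scheduled against the crop's
water use, and under negligible rainfall that is essentially its
evapotranspiration under standard conditions, ETc (mm/day). A useful advisory
system must forecast ETc a few days ahead, which requires two things that are
expensive to obtain operationally: up-to-date crop canopy parameters, and
forecasts of the full set of weather variables the Penman--Monteith equation
consumes. `cropet` implements a methodology that relaxes both constraints:

1. canopy parameters (leaf area index and broadband albedo) come from free
   multispectral satellite imagery and enter the Penman--Monteith equation
   *directly* (the "one-step" approach), yielding both the current ETc and an
   analytic crop coefficient $K_c$;
2. the forecast itself needs only *air temperature*, the one variable
   meteorological services broadcast freely and predict best, through a
   locally calibrated Hargreaves--Samani equation:
   $ET_c(t_0+\Delta t) = K_c(t_0)\, ET_{0\text{-HS}}(t_0+\Delta t)$,
   for lead times $\Delta t$ of 1--5 days.

The package also carries the comparison path (full Penman--Monteith on all
forecast variables), the ensemble-forecast reduction and temperature bias
correction that feed both paths, and the BIAS/RMSE verification machinery for
daily and accumulated (1/3/5-day) forecasts.

## Models and procedures

### Reference evapotranspiration (Penman--Monteith, FAO-56)

`et0_penman_monteith()` implements the standard daily reduced form for the
grass reference surface (albedo 0.23, height 0.12 m, surface resistance
70 s/m):

$$ET_0 = \frac{0.408\,\Delta (R_n - G) + \gamma \frac{900}{T+273} u_2 (e_s - e_a)}
  {\Delta + \gamma (1 + 0.34\, u_2)}$$

with $G = 0$ at the daily scale, $e_s$ the mean of the saturation vapour
pressures at the daily extremes, $e_a = (RH/100)\,e_s$, $\Delta$ evaluated at
the daily mean temperature (itself the mid-range of the extremes when not
measured), and wind converted from the 10 m measurement height by the
log-profile factor $4.87/\ln(672.58) \approx 0.75$. Net radiation is net
shortwave $(1-\alpha)R_s$ minus FAO-56 net longwave; stations report $R_s$ in
W/m², converted once internally (× 0.0864) to MJ/m²/day.

### One-step crop evapotranspiration

`etc_penman_monteith()` evaluates the full Penman--Monteith form with the
crop's own canopy parameters in place of tabulated coefficients:

$$ET_c = \frac{86400}{\lambda}\,
  \frac{\Delta (R_n - G) + \rho c_p (e_s - e_a)/r_a}
       {\Delta + \gamma (1 + r_s/r_a)}$$

* the remotely sensed albedo enters $R_n$;
* the surface resistance is the piecewise LAI rule
  $r_s = 200/\mathrm{LAI}$ for $\mathrm{LAI} \le 4$, else $50$ s/m
  (continuous at LAI 4);
* the aerodynamic resistance follows the log-profile with roughness lengths
  $0.123\,h_c$ and $0.0123\,h_c$ and displacement $\tfrac{2}{3}h_c$, with the
  crop height fixed at $h_c = 0.4$ m by default (ETc is insensitive to it
  over 0.1--0.6 m, and it is an argument everywhere).

Canopy parameters are *held constant between satellite acquisitions*
(`hold_canopy()`, a step function): no crop-growth interpolation is applied
between passes.

The internal consistency anchor of the whole construction is that the full
form with grass parameters must reproduce the reduced form: across random
valid weather the two agree within 2 % (in practice within about 0.3 %), and
the test suite enforces this over 10^4 draws.

### Canopy retrieval

`retrieve_lai()` inverts the CLAIR model,
$\mathrm{LAI} = -(1/\alpha^*) \ln(1 - \mathrm{WDVI}/\mathrm{WDVI}_\infty)$,
with $\mathrm{WDVI} = \rho_{nir} - C\,\rho_{red}$ the soil-line-corrected
vegetation index. $\alpha^* = 0.35$ is the default extinction/scattering
coefficient (validated for maize in Southern Italy);
$\mathrm{WDVI}_\infty$ is deliberately left without a default because it is a
site/sensor calibration product. Negative WDVI (bare or wet soil) clamps to
LAI 0; WDVI at or beyond the asymptote is an error, not a clamp, because it
signals reflectance inconsistent with the model. `broadband_albedo()` is the
normalised irradiance-weighted sum of band reflectances.

### Local Hargreaves--Samani calibration

`et0_hargreaves()` computes
$ET_{0\text{-HS}} = k_{HS}\, 0.0023\,(T + 17.8)\sqrt{T_{max}-T_{min}}\;0.408\,R_a$
from temperature and top-of-atmosphere radiation alone. The scaling factor is
fitted per station by `calibrate_khs()` against Penman--Monteith reference ET
over past irrigation seasons (June 1 -- September 30; four seasons, n = 488,
in the default experiment). Because $k_{HS}$ enters multiplicatively the
least-squares minimiser is closed-form regression through the origin,
$k_{HS} = \sum h_i p_i / \sum h_i^2$; the tests verify it against a dense 1-D
grid search. Only the scaling factor is calibrated -- the offset 17.8 and the
square-root exponent stay fixed.

### Ensemble forecasts and bias correction

`reduce_daily()` collapses 3-hourly ensemble output to daily site values:
median across members at each step, then the mean of the eight step medians
per lead day (the alternative order, per-member daily means first, is behind
the `order` switch since both are defensible). Daily forecast temperature
extremes are the max/min of the eight reduced steps -- a declared convention,
since nothing in the source material fixes how forecast $T_{max}/T_{min}$ for
the Hargreaves--Samani equation should be built from 3-hourly values.
`interpolate_to_site()` brings the three nearest grid nodes to the station by
barycentric interpolation on a local planar frame.

`fit_mean_bias()` estimates the mean forecast-minus-observation difference
per site, variable and lead over a reference period, and
`apply_bias_correction()` subtracts it. Only temperature is corrected in the
standard configuration (corrections of the other variables gave contrasting
results across complex terrain in the source experiments); the temperature
shift is applied to the mean and both extremes alike. On the fitting sample
the corrected mean bias is zero and
$RMSE_{corr}^2 = RMSE_{raw}^2 - bias^2$ exactly -- both asserted to 1e-9.

### Crop coefficient and forecast issue

`crop_coefficient()` computes $K_c = ET_{c\text{-PM,obs}}/ET_{0\text{-PM,obs}}$
from the day's observed weather and the held canopy state, so $K_c$ is
refreshed daily with weather and weekly-ish with imagery. Days whose
reference ET falls below 0.1 mm/day make $K_c$ undefined (error, or drop with
a warning). `forecast_etc()` then issues, per lead day, the proposed
temperature-only forecast $K_c(t_0)\,ET_{0\text{-HS}}$ on bias-corrected
forecast temperature, and the comparison full-variable Penman--Monteith
forecast with the canopy frozen at $t_0$. `accumulate_horizons()` forms the
1/3/5-day partial sums that irrigation scheduling actually consumes.

### Verification

`skill_scores()` computes BIAS and RMSE against the best estimate -- the
one-step Penman--Monteith ETc from *observed* weather -- pairing days over
the 122-day evaluation season; `summarize_over_sites()` produces the
box-plot statistics used to describe the spread across stations (linear
interpolation quartiles, Tukey fences at 1.5 IQR).

## The synthetic generator

No deposited observational or NWP data exist for this methodology, so the
`sim_*` family generates inputs with the statistical structure the study
conditions assume, and the whole pipeline is exercised on them:

* `sim_weather()` -- daily weather per station around the 18-station
  climatology of `campania_climatology()` (June--September means spanning
  coastal plains to 848 m ridges): a centred seasonal harmonic plus AR(1)
  anomalies (coefficient 0.7), Gaussian diurnal range (10 ± 2 °C), humidity
  clipped to [20, 98] %, and shortwave radiation generated as a persistent
  cloudiness fraction of the clear-sky envelope $(0.75 + 2\cdot10^{-5}z)R_a$,
  which both caps it physically and ties its mean to the climatology. The
  AR(1) coefficient and noise levels were chosen once so that mid-summer
  reference ET falls in the plausible Mediterranean 2--8 mm/day band.
* `sim_forecast_daily()` / `sim_forecast_members()` -- forecasts equal truth
  plus a systematic bias (default: −0.68 °C on temperature, none elsewhere),
  plus Gaussian noise growing +20 %/lead-day, plus (member level) ensemble
  dispersion across 16 members. The temperature noise scale (1.0 °C at lead
  1) was chosen once so the raw and corrected temperature RMSE magnitudes
  bracket the 1.70 → 1.16 °C range reported for the real system. The daily
  generator applies the noise per day and is the one used at experiment
  scale; the member generator applies it per 3-hourly step and exists to
  exercise the full reduction chain.
* `sim_canopy()` -- a maize season: normalised logistic rise reaching exactly
  `lai_max` (default 5) at flowering (default Aug 1), then a slow exponential
  decline; albedo linear in LAI from 0.15 to 0.20; acquisitions every 7 or 15
  days. Reflectances are produced by running CLAIR forward and splitting WDVI
  along the soil line, so the retrieval round-trips to 1e-9, and the green
  band is chosen to close the broadband-albedo identity exactly.

What passing on synthetic data does *not* show: the generator has no weather
fronts, no spatial error correlation between stations, no non-stationary or
non-Gaussian forecast errors, no cloud contamination or atmospheric-correction
residuals in the reflectances, and no soil-water stress (ETc is potential,
under standard conditions; precipitation is ignored throughout). Skill
numbers obtained here characterise the machinery, not any real site.

## Numerical choices

* λ fixed at 2.45 MJ/kg and the FAO-56 printed constant 0.408 in the reduced
  form; $c_p = 1.013\times10^{-3}$ MJ/kg/°C; air density from the ideal-gas
  law at virtual temperature.
* Soil heat flux G = 0 at the daily scale.
* $e_s$ from the mean of saturation pressures at the extremes, never at the
  mean temperature.
* $R_s/R_{so}$ clamped to [0.3, 1.0] in the longwave term (treated as 1 when
  $R_a = 0$) so overcast and polar-night days stay physical.
* Calm-wind floor $u_2 \ge 0.1$ m/s in **both** Penman--Monteith forms. The
  aerodynamic resistance diverges at zero wind while the reduced form's
  $0.34u_2$ term vanishes, so flooring only one of them would let the two
  formulations drift >30 % apart on dead-calm days; one uniform floor keeps
  the one-step consistency property valid over the whole weather envelope.
* Negative computed ET (rare longwave-dominated days) clamps to 0 with a
  warning.
* Kc uses the single day-$t_0$ weather; an undefined-Kc floor of 0.1 mm/day
  guards the ratio. The canopy used by a forecast is the state at $t_0$, also
  when a new image would arrive inside the horizon (within a 5-day horizon
  the difference is the canopy-freeze effect, visible in the zero-forecast-
  error experiment unless the canopy has a single acquisition).
* Quartiles by linear interpolation (R type 7), fixed for reproducibility.
* Missing data: forecast days with fewer than 8 steps are dropped; skill
  pairs with a missing side are dropped pairwise; no imputation anywhere.

## Problem sizes and determinism

`run_synthetic_experiment()` is the desk-scale replica of the regional
experiment: 18 stations × 122 evaluation days × 5 leads × 2 canopy seasons,
with calibration and bias fitting on the four preceding synthetic seasons
(488 days per station). It runs in seconds on a single core; every stage
derives its stream from one master seed and is exactly reproducible. The
property and acceptance tests use the same sizes (10^4 random weather draws
for the consistency property, 488-day calibrations, the full 18-station
replica), which keeps the whole suite well under a minute per heavy block.

## Known limitations

* The Hargreaves--Samani path inherits the equation's structural error where
  the aerodynamic term matters: at windy stations the temperature-only
  forecast is systematically poorer, exactly as the $k_{HS} > 1$ fits at the
  windiest synthetic stations suggest.
* The one-step approach assumes well-watered standard conditions; no stress
  coefficients, dual-Kc split, or soil water balance are provided.
* Sub-daily (hourly) Penman--Monteith, humidity from dew point, GRIB
  decoding, atmospheric correction of raw imagery and raster map production
  are out of scope; the package starts from surface reflectance and daily or
  3-hourly tabular weather.
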