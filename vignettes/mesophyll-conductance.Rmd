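---
title: "Modeling photosynthesis with an explicit mesophyll conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling photosynthesis with an explicit mesophyll conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmphoto)
```

## The problem

Most land surface and canopy gas-exchange models assume that the CO2
concentration available for carboxylation equals the intercellular
concentration $C_i$ — equivalently, that the conductance to CO2 transfer
inside the leaf (mesophyll conductance, $g_m$) is infinite. In reality $g_m$
is finite and draws the chloroplastic concentration $C_c$ well below $C_i$,
by its definition

$$g_m = \frac{A_n}{C_i - C_c},$$

where $A_n$ is net assimilation. Models that ignore this compensate with
*apparent* ($C_i$-based) photosynthetic capacities that are biased low.
Making $g_m$ explicit therefore requires two coupled changes: a model for
$g_m$ itself, and a re-estimation of the capacities $V_{cmax25}$, $J_{max25}$
(C3) and $V_{pmax25}$ (C4) on the $C_c$ (or, for C4, mesophyll-cytosol $C_m$)
basis. `gmphoto` implements both, plus the leaf- and canopy-level machinery
needed to quantify what the explicit treatment changes — most importantly the
sensitivity of photosynthesis to rising atmospheric CO2.

## The gm model

Effective mesophyll conductance is a PFT-specific unstressed maximum at
25 °C modulated by multiplicative environmental responses and clamped from
below:

$$g_m = \max\!\big(f_{min}\,g_{m,max25},\; g_{m,max25}\,
f_1(L)\,f_2(T_l)\,f_3(\theta)\,f_4(C_i)\,f_5(Q_a)\big)$$

* $f_1 = e^{-k_n L}$ — canopy depth profile shared with $V_{cmax}$ and
  $J_{max}$ ($k_n$ = 0.11 by default).
* $f_2$ — peaked Arrhenius temperature response normalized to 1 at 25 °C
  ($H_a$ = 49.6 kJ mol⁻¹, $H_d$ = 437.4 kJ mol⁻¹, $\Delta S$ = 1.4
  kJ mol⁻¹ K⁻¹, giving an optimum at 35.5 °C). The parameters are global
  across PFTs but editable in `inst/extdata/kinetics_params.csv`.
* $f_3 = \beta^{q}$ — soil-moisture stress on the relative plant-available
  water $\beta$, with exponents $q_m$ = 0.75 (gm), $q_s$ = 0.50 (stomata),
  $q_b$ = 0.25 (biochemistry): gm is the most drought-sensitive pathway.
  Wilting and critical points are 0.32 and 0.70 of field capacity.
* $f_4 = f_{min} + 1.5(1 - e^{-C_i/38})e^{-C_i/460}$ — empirical $C_i$
  response peaking near 100 μmol mol⁻¹ and ≈ 1 at the standardization point
  $C_i$ = 260 μmol mol⁻¹.
* $f_5 = 1 - (1 - f_{min})e^{-0.003 Q_a}$ — light response: $f_{min}$ in
  darkness, ≈ 0.8 at 500 and ≈ 1 at 1500 μmol m⁻² s⁻¹.

$f_4$ and $f_5$ are contested responses; the five model versions (`Imp`,
`Exp`, `ExpC`, `ExpL`, `ExpCL`) switch them on and off, with `Imp` the
conventional infinite-gm treatment. $f_{min}$ = 0.15 accounts for gm never
collapsing entirely even under severe stress. The clamp applies to the final
product, not per factor.

```{r}
g <- gm_effective(load_pft_registry()[["ENF"]],
                  env_state(Tl = 30, Qa = 600, theta = 0.25),
                  cumulative_lai = 1, version = "ExpL")
unlist(g)
```

## Biochemistry and coupling

C3 assimilation follows the two-state Farquhar model (Rubisco- and
RuBP-regeneration-limited, hard minimum, no TPU state, O2 fixed at
210 mmol mol⁻¹); C4 follows a reduced von Caemmerer–Furbank form with the
PEP-limited initial slope $C_m V_{pmax}/(C_m + K_p)$, the CO2-saturated
Rubisco rate, and an optional light-limited rate $J/6$. With finite gm,
substituting $C_x = C_i - A_n/g_m$ into each state's rate equation gives a
quadratic in $A_n$ (the Ethier–Livingston form) solved per state
(`solve_an_at_ci()`); the smaller root is the physical one.

Rubisco kinetics ship in an editable file with two strictly separated sets:
an apparent ($C_i$-basis) set used by `Imp` and a true ($C_c$-basis) set used
by the explicit versions, from the standard in-vivo tobacco calibrations
(`resolve_kinetics()`). Mixing bases is an error by construction.

Stomata follow the Medlyn model
$g_s = g_0 + 1.6(1 + g_1/\sqrt{D})A_n/C_a$ with $g_0$ = 0.005 mol m⁻² s⁻¹.
`solve_leaf()` iterates $A_n$, $g_s$, $g_m(C_i)$ and $C_i$ to a joint fixed
point (damping 0.5, tolerance 10⁻⁴ μmol mol⁻¹ on $C_i$, bracketed root-search
fallback after 50 iterations). The inner update of $f_4$ inside the same loop
is one faithful reading of the coupling; an outer-loop update reaches the
same fixed point, which the convergence identities in the test suite confirm.
Boundary-layer conductance and leaf energy balance are deliberately omitted:
leaf temperature is a forcing input, and transpiration is reported only as
the diagnostic $g_s D / P$.

## Apparent-to-true parameter adjustment

The package's central procedure (`adjust_c3()`, `adjust_c4()`,
`adjust_pft_table()`) converts $C_i$-based capacities to the $C_c$ basis in
three steps:

1. simulate the apparent $A_n$–$C_i$ curve with the implicit routine at
   25 °C, saturating light, no stress (gm at its unstressed maximum);
2. convert each point with Fick's law $C_c = C_i - A_n/g_m$ (gm constant, or
   varying as $f_4(C_i)/f_4(260)$ when the version carries the $C_i$
   response);
3. refit $V_{cmax25}$ and $J_{max25}$ simultaneously to the $A_n$–$C_c$
   curve with the true kinetics, by bounded Levenberg–Marquardt least squares
   (`minpack.lm`), respiration held fixed.

Numerical choices the source procedure leaves open, fixed here once:
$C_i$ grid 40–1500 μmol mol⁻¹ in 5 μmol mol⁻¹ steps, equal weights,
initialization at the apparent values, bounds (0, 10× initial value). Step 3
fits the $A_n$–$C_c$ pairs directly (predicting $A_n$ from the step-2 $C_c$),
which is deterministic and reproduces the published reference adjustment
(40/76 → 50.8/76.9 at $g_m$ = 0.1 mol m⁻² s⁻¹) to four significant figures.
Day respiration defaults to $R_l = 0.011\,V_{cmax25,Ci}$, the ratio implied
by the published reference leaf (0.44/40); it is configurable per PFT.

The adjustment inflates $V_{cmax25}$ more than $J_{max25}$ (the Rubisco
branch operates where the drawdown is largest), lowering the
$J_{max25}/V_{cmax25}$ ratio and shifting the limitation-switch point to
lower $C_i$ — consequences verified by property tests. For C4, only
$V_{pmax25}$ is affected; the refit uses a 20–150 μmol mol⁻¹ grid covering
the PEP-limited branch and holds the CO2-saturated branch at
$V_{cmax} = V_{pmax,Ci}/2$, the standard ratio between the two capacities.
With the C4-crop median gm of 0.739 mol m⁻² s⁻¹ the apparent
$V_{pmax25}$ = 60 rises to ≈ 134 μmol m⁻² s⁻¹ — "approximately 145" in the
source compilation; the exact figure is sensitive to the unstated fit range
because the apparent initial slope (60/80 = 0.75 mol m⁻² s⁻¹) exceeds gm
itself, making the refit intrinsically ill-conditioned.

A related caveat applies to the `ExpC`-style adjustment of low-gm,
high-capacity PFTs (e.g. evergreen needle-leaf): the literal $f_4$ decline
drives step-2 $C_c$ toward the compensation point at high $C_i$, so the
refitted capacities — especially $J_{max25,Cc}$ — depend strongly on the grid
ceiling. The qualitative signature (higher $J_{max25,Cc}$ than the `Exp`
adjustment) is robust and tested; the magnitudes are not, and we do not treat
them as calibrated.

```{r}
adjust_pft_table(Filter(function(p) p$pathway == "C3", load_pft_registry()))
```

## Canopy scaling and CO2 experiments

`build_profile()` divides the canopy into nine equal-LAI layers (the
default; a 90-layer refinement changes canopy assimilation by < 2%).
Capacities, respiration and gm share the nitrogen extinction profile
$e^{-k_n L}$. Radiation uses a deliberately simple sun/shade scheme — beam
extinction $k_b = 0.5/\cos\theta_z$, fixed diffuse fraction (0.3), diffuse
extinction 0.5 — rather than a full two-stream treatment; it is adequate for
the qualitative canopy contrasts the package targets, not for reproducing
site-level flux magnitudes.

`generate_forcing()` supplies synthetic half-hourly diurnal forcing
(sinusoidal light and temperature, VPD tied to temperature at fixed relative
humidity, optional dry-down, seeded Gaussian perturbations). It emulates the
shape of boreal-to-tropical fair-weather days, not weather: no clouds,
synoptic variability, or rain pulses. Passing the canopy-level sign tests on
this forcing therefore demonstrates internal model behavior, not agreement
with eddy-covariance data.

`run_paired_co2()` runs ambient and ambient + 200 μmol mol⁻¹ simulations on
identical forcing and reports relative responses of time-integrated canopy
assimilation, daytime-mean (incident PPFD > 200 μmol m⁻² s⁻¹) canopy
conductance, and intrinsic water-use efficiency. Robust behaviors the test
suite locks in:

* explicit gm raises the CO2 response of canopy assimilation under cool
  conditions and lowers it under hot conditions (the gm temperature response
  shifts where the adjustment-compensated models diverge);
* the iWUE response is version-invariant at $g_0 = 0$ — a structural
  property of the Medlyn model, which conserves $C_i/C_a$;
* C4 canopies show essentially no assimilation response but strong stomatal
  closure;
* along a gm sweep (`gm_sweep()`, capacities re-adjusted at every gm), the
  Rubisco-limited share of canopy assimilation falls as gm falls. At low
  temperatures the direct drawdown effect can mask this shift; the package
  evaluates it under temperate growing-season forcing.

## gm measurement standardization

`standardize_records()` converts literature gm measurements to
$g_{m,max25}$ by dividing out $f_2$ at the measurement temperature — and,
per model version, the $f_5$ ratio to 1500 μmol m⁻² s⁻¹ light and the $f_4$
ratio to $C_i$ = 260 μmol mol⁻¹. Records lacking a field an enabled
correction needs are dropped with a warning, never imputed.
`aggregate_pft()` reports per-PFT median, mean and a seeded-bootstrap
standard error of the median (10,000 resamples by default) — the bootstrap
is our choice where the aggregation method was unstated, being
assumption-free and reproducible. The shipped registry carries published
PFT medians; `simulate_gm_records()` generates clearly-synthetic record
tables (lognormal spread, geometric SD 1.6) for tests and examples, since
the underlying compilation is not redistributable here.

## Known limitations

* No gm acclimation to growth CO2 (deliberately excluded — observed
  responses are inconsistent), no TPU limitation, no bundle-sheath leakage
  in C4, no temperature scaling of the capacities (all calibrated
  quantities are defined at 25 °C and the headline analyses run there).
* The g1 stomatal slopes in the registry are indicative defaults; every
  quantitative result above is independent of them.
* Site- and global-scale conclusions (flux magnitudes, GPP responses)
  require observed forcing and a full land-surface host model, both outside
  this package's scope.
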