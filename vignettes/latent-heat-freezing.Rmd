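---
title: "Modelling latent-heat release during freezing of solute-laden solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling latent-heat release during freezing of solute-laden solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icecal)
```

## The problem

When a cryopreservation medium — isotonic PBS, a glycerol solution, culture
media — is cooled below its phase-change temperature, water crystallises and
releases latent heat. How much heat is released, and *when* (at which
temperature, after how much time), matters for modelling freezing in cells
and tissues and for designing cooling protocols. A differential scanning
calorimeter (DSC) measures the heat flow directly; `icecal` provides the two
models used to interpret such measurements, the thermogram processing between
the raw signal and the model inputs, and a synthetic-data generator that lets
every stage be tested end to end without instrument data.

The experimental protocol emulated throughout is the pre-nucleated
("site-saturated") constant-cooling-rate run: the sample is cooled at
5 K/min until ice nucleates (a sharp exothermic spike, typically between
−6 and −12 °C), equilibrated at the phase-change temperature so that all
nuclei exist before the measurement begins, then cooled at the chosen rate
B while the exotherm is recorded.

## The phase diagram and the separable release model

For a dilute water–NaCl solution the phase-change temperature follows
freezing-point depression,
$$T_{ph} = 273.15 - m\,c_0,$$
with $c_0$ the osmolality (Osm/L) and $m = 1.858$ K/(Osm/L). As the sample
cools below $T_{ph}$, the residual liquid sits on the liquidus and the
lever rule gives the equilibrium frozen (heat-released) fraction
$$f_{eq}(T) = 1 - \frac{m c_0}{273.15 - T}.$$

The kinetic model factorises the cumulative release into a temperature part
and a time part,
$$L(T, t) = \alpha(T)\,\beta(t), \qquad
  \alpha(T) = 1 - \frac{A}{(T_{ph}-T)+A}, \qquad
  \beta(t) = 1 - e^{-k t^n},$$
where $\beta$ is Avrami/JMAK transformation kinetics. The identity
$\alpha(T) \equiv f_{eq}(T)$ when $A = m c_0$ (because
$(T_{ph}-T) + mc_0 = 273.15 - T$) is what ties the empirical temperature
factor to the phase diagram; for isotonic saline $m c_0 = 0.53$ K. Under
constant cooling the elapsed time and temperature are linked by
$t = (T_{ph}-T)/B$, so the whole model is a function of temperature at a
given rate.

```{r model}
pbs <- solution_spec("1xPBS", 0.2853)
p <- avrami_params(A = 0.53, k = 3.3, n = 1.5, Tph = pbs$Tph)
temps <- seq(pbs$Tph, pbs$Tph - 20, by = -5)
round(cbind(equilibrium = equilibrium_release_fraction(temps, pbs),
            B1  = latent_heat_fraction(temps, p, 1),
            B20 = latent_heat_fraction(temps, p, 20)), 4)
```

The slower the cooling, the closer the curve sits to the equilibrium one;
at 20 K/min the release visibly lags.

**Time unit for $k$.** The rate constant's unit is tied to the unit of $t$;
`avrami_params()` carries an explicit `time_unit` field, default
`"minutes"`. With $k \approx 3$ in per-minute units the kinetic factor
saturates over tens of seconds, which is what produces a visible lag between
5 and 20 K/min at these parameter magnitudes; in per-second units the same
numbers would saturate within a second and all rates would collapse onto the
equilibrium curve. A `"seconds"` mode is provided; fits and forward
simulations are unit-closed, so every recovery result here is independent of
the convention.

**1×PBS osmolality.** Two presets are shipped: 0.2853 Osm/L (consistent
with $A = mc_0 = 0.53$ and $T_{ph} = 272.62$ K, the default) and the
nominal 0.3 Osm/L of 0.9 wt% NaCl (272.59 K). The 0.03 K difference is
real and is left visible rather than resolved.

## The two-stage fit

Stage one fits the single parameter $A$ to the slowest-rate curve
(nominally 1 K/min), where kinetic lag is negligible; stage two holds
$(A, T_{ph})$ fixed and fits $(k, n)$ to the faster curves — by default the
5 and 20 K/min curves *concurrently* (one pooled least-squares problem), the
"combined" fit. Both stages use bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) restarted from a coarse grid of $(k, n)$ values; ties
are broken by the lowest pooled residual, then the smallest $n$. Estimates
driven into the box bounds are flagged.

```{r fit}
curves <- lapply(c(5, 20), function(B) {
  g <- seq(pbs$Tph, pbs$Tph - 40, length.out = 100)
  release_curve(g, latent_heat_fraction(g, p, B), B)
})
fit_kinetics(curves, A = 0.53, Tph = pbs$Tph)
```

Two diagnostics accompany the fit. `avrami_linearize()` applies the
double-log transform $\ln[-\ln(1-\hat\beta)]$ vs $\ln t$ (with
$\hat\beta = L/\alpha$), on which Avrami-like data fall on a line of slope
$n$ and intercept $\ln k$; points where the transform is undefined
($t \le 0$ or $\hat\beta \notin (0,1)$) are dropped and counted, never
imputed. `r2_surface()` maps $R^2$ over a $(k, n)$ grid and masks the region
above a threshold (0.95 by convention); the combined best fit lies in the
intersection of the per-rate regions.

Numerical notes: fractions are clipped to $[0, 1-10^{-12}]$ before the
double-log transform; model curves are interpolated onto data grids linearly
in temperature; $R^2$ is $1 - SS_{res}/SS_{tot}$ about the data mean and is
an error for constant data. In double precision $\beta$ saturates to exactly
1 once $k t^n \gtrsim 37$, so linearization diagnostics are only meaningful
on the non-saturated part of a curve.

## DSC thermogram processing

A `thermogram` is the sampled record (time s, temperature °C, heat flow mW)
plus sample mass and programmed rate; exotherms are negative under the
default exo-down convention. Processing follows the instrument conventions:

* **Nucleation detection** looks for the largest exothermic excursion
  relative to a running median inside a temperature window (default
  [−12, −6] °C); broad features survive the median, sharp spikes do not.
  Ties go to the warmer sample. The prominence threshold defaults to ten
  times the median absolute excursion in the window.
* **Linear baseline**: the signal chord in time between the phase-change
  temperature and ≈ −40 °C.
* **Sigmoidal baseline** (anchors $T_{ph}$ to ≈ −22 °C): the iterative
  partial-area construction
  $b_i(t) = b_{pre}(t)(1-\phi_{i-1}(t)) + b_{post}(t)\phi_{i-1}(t)$, where
  the pre-/post-transition trends are anchored at the signal values at the
  anchor samples with Theil–Sen (median-of-pairwise) slopes — robust to the
  nucleation spike or exotherm onset clipping a trend window — and $\phi$
  is the cumulative released fraction against the previous iterate, seeded
  from the linear baseline. Convergence tolerance is $10^{-6}$ of the
  signal range between the anchors, with at most 50 iterations.
* **Integration** is trapezoidal in time (the protocol is constant-rate, so
  integrating in temperature would differ only by the factor $B$) of
  baseline − signal, divided by the sample mass: mW·s/mg = mJ/mg.
  Anchors are matched to the nearest sampled temperatures and reported.
* **Cumulative release curves** are the running integral normalised by the
  window total, so the final value is 1 by construction.

Because the saline exotherm has a $1/(T_{ph}-T)^2$ tail, the −40 °C (and
especially the −22 °C) anchor truncates ~1 % (resp. ~5 %) of the area — the
sigmoidal value sits systematically below the linear one, the same ordering
the instrument conventions produce on real data. The window normalisation
also means a release curve extracted from a thermogram is
$L(T)/L(T_{end})$, not $L(T)$: refitting kinetics through the thermogram
path carries a bias of roughly 10 % on $k$ (measured on noiseless synthetic
data), whereas fitting curves generated directly is exact to optimiser
precision. Tests assert both numbers.

## The reduced moving-boundary model

The second model resolves *why* release lags at higher rates: as ice grows,
solute is rejected at the front, enriching the adjacent liquid and
depressing its freezing point; the front can only advance as fast as solute
diffuses away. For a thin solution layer of height $H$ cooled from below at
rate $B$, non-dimensionalising with length $H$ and time $T_{ph}/B$ gives the
groups
$$\epsilon_i = \frac{B H^2}{T_{ph} D_{T,i}}, \quad
  \gamma^2 = \frac{B H^2}{T_{ph} D_c}, \quad
  St = \frac{L}{T_{ph} c_l}, \quad
  M = \frac{m c_0}{T_{ph}}, \quad k_1/k_2 .$$
$\epsilon_i$ is tiny (~$10^{-4}$) for any realistic rate, so heat conduction
is quasi-steady and the liquid temperature is simply $T(t) = T_{ph}(1-t)$;
$\gamma^2$ is not small, so the full diffusion equation is kept for the
solute. The liquid concentration at the interface is pinned to the liquidus,
$c(Z,t) = 1 + t/M$ (in units of $c_0$), and the front moves by the solute
flux balance
$$\gamma^2 \dot Z = -\frac{1}{c(Z,t)} \left.\frac{\partial c}{\partial z}\right|_{Z^+} .$$

Mapping the shrinking liquid domain $[Z(t), 1]$ onto a fixed $\delta \in
[0,1]$ and discretising ($\delta_j = jh$, $h = 1/(N+1)$) gives the scheme in
`stefan_step()`: second-order one-sided interface gradient via the ghost
value $c_{-1} = 3c_0 - 3c_1 + c_2$, explicit Euler for $Z$ and the mapping's
advection term, backward Euler for diffusion through a tridiagonal solve —
first order in time, second order in space. The far boundary is
zero-gradient via a mirror ghost $c_{N+2} = c_N$ by default; the alternative
closure $c_{N+2} = c_{N-1}$ is available as `far_ghost = "paper"`. The sign
of $\dot Z$ is fixed by the conservation law (solute rejection advances the
front, $\dot Z \ge 0$). Each step is capped by the advection CFL bound
$\Delta t \le 0.5\,h\,(1-Z)/|\dot Z|$ — the solver shortens steps adaptively
through the fast early transient. Integration stops when the liquid has
cooled 40 K below $T_{ph}$ ($t_{final} = 40/T_{ph}$), or earlier if the
front reaches $1-h$. The reported release curve is
$Z(t)/Z(t_{final})$ against $T = T_{ph}(1-t)$.

In the fast-diffusion limit the concentration is uniform at the liquidus
value and solute conservation gives the closed form
$$Z_{eq}(t) = 1 - \frac{1}{1 + t/M},$$
which is exactly the lever rule again (`mode = "equilibrium"`).

```{r stefan}
p5 <- stefan_params(cooling_rate = 5)
dimensionless_groups(p5)
res <- stefan_solve(p5, N = 100, dt = 1e-5, gamma2_scale = 2.17e-4,
                    n_records = 200)
cv <- percent_released(res)
round(cbind(T_K = cv$temperature, released = cv$fraction)[c(2, 10, 40, 200), ], 4)
```

### The solute diffusivity, and which regime the model lives in

Two internally inconsistent values for $D_c$ circulate with this model. The
Stokes–Einstein form $D_c(T) = S\,T/\mu(T)$ with the prefactor
$S = 9.17\times10^{-14}$ m²·cP/(K·min) and the Arrhenius viscosity
$\mu = 6.627\times10^{-4} e^{1.807\times10^4/(8.314\,T)}$ cP gives
$D_c \sim 10^{-11}$ m²/min and hence $\gamma^2 \approx 70\,B$: a deeply
mass-transfer-limited regime in which the front advances only a few percent
of the layer and — because $Z \propto \gamma^{-1}$ there — the *normalised*
release curves become asymptotically independent of the cooling rate. The
order-of-magnitude analysis behind the model instead takes
$D_c \sim 10^{-9}$ m²/s, i.e. $\gamma^2 \sim 10^{-2} B$
(`gamma2_scale = 2.17e-4` relative to the Stokes–Einstein value), which is
the regime in which simulated release approaches equilibrium as $B \to 0$
and is strictly lower at every temperature for faster cooling — the
qualitative behaviour the model exists to reproduce. Both are exposed
(`stokes_einstein`, `gamma2_scale`, `gamma2_mode = "temperature"/"constant"`);
the rate-ordering tests run in the second regime, and this choice is a
package decision in the face of the contradiction, not a fitted value.

### Numerical behaviour and known limitations

* **Oracle agreement.** The stepper matches an independently coded
  dense-matrix integration of the same semi-discrete system to ~$10^{-15}$
  per step (tests cover $N \le 8$, both far-ghost modes).
* **Orders.** Halving $\Delta t$ changes $Z(t_{final})$ linearly (first
  order in time); doubling $N$ changes it by well under 1 % at reference
  settings in a resolved regime.
* **Quasi-equilibrium limit.** As $\gamma^2 \to 0$ the percent-released
  curve converges to the phase-diagram curve; the sup-norm falls 0.17 →
  0.041 → 0.008 as $\gamma^2$ is scaled by $10^{-5}, 10^{-6}, 10^{-7}$.
  The early part of the equilibrium curve moves on the timescale
  $t \sim M \approx 2\times10^{-3}$, so "small $\gamma^2$" means small
  against $M$, and the residual at the smallest scale is the front-position
  resolution ($Z$ moves at most half a cell per CFL-limited step).
* **Discrete solute conservation is approximate.** $(1-Z)\langle c\rangle$
  drifts from 1 by ~$5\times10^{-3}$–$10^{-2}$ over a full resolved run at
  $N = 200$, $\Delta t = 10^{-5}$ (and by ~0.3 in the Stokes–Einstein
  regime, where the interface boundary layer is narrower than a grid cell
  while the interface concentration climbs ~75×). Two mechanisms bound it:
  the interface velocity uses the second-order one-sided gradient while the
  telescoped boundary flux of the Laplacian stencil is the first-order
  difference, and the explicit front update lags the ramping liquidus value
  by one step — at the CFL limit that alone is ~$h/2$. The drift vanishes
  under joint refinement (tested), but at fixed $N = 200$ it cannot be
  pushed below ~$10^{-3}$; the solver reports it per run in
  `diagnostics$max_conservation_drift` rather than hiding it.
* Not modelled (out of scope): the full two-phase conduction problem,
  radial/2-D effects, concentration-dependent viscosity, dendrite-scale
  structure, eutectics, front instabilities.

## The synthetic-data generator

`synth_spec()` + `generate_release_curves()` / `generate_thermogram()`
emulate the study conditions: release curves on a uniform 100-point grid
from $T_{ph}$ down 40 K with i.i.d. Gaussian noise per replicate (the
measured replicate scatter is below plot resolution, so a realistic σ is
~0.01 and no correlated-noise model is attempted; six replicates is the
experimental convention); thermograms as the full three-segment record
(5 K/min search ramp with a triangular nucleation spike — 2 s wide, 5× the
exotherm peak, purely cosmetic for detector tests —, an equilibration hold,
then the measuring ramp at B down to −50 °C) with the exotherm
$-m_s L_{tot}\,df/dt$ riding on a drifting instrument baseline.
$df/dt$ is analytic for the equilibrium and Avrami models and a finite
difference of $Z(t)$ for the moving-boundary model. The model fraction is
normalised to 1 at the end of the measuring ramp so the integrated exotherm
equals `total_latent_heat` exactly. Pure water ($c_0 = 0$) would release as
a delta function; the generator smears it into a raised-cosine step of
configurable width (0.5 K default) standing in for instrument response —
a synthetic stand-in, not a measured response function. Any noise requires
an explicit seed, and equal seeds give identical output.

What passing tests on these data do and do not show: the generator draws
from the same model families the fits assume, so recovery tests validate
the *pipeline* (transforms, baselines, optimisation, normalisation
book-keeping), not the models' adequacy for real DSC data — instrument
response, thermal lag at high rates, and correlated drift are all absent.

## Workflows and reproduction

`run_synth()`, `run_integrate()`, `run_fit()`, `run_simulate()` and
`run_compare()` execute YAML-configured workflows with deterministic
artifacts (CSV + JSON with a manifest recording seed and package version;
nothing is overwritten without `overwrite: true`), and
`inst/scripts/icecal.R` exposes them as shell subcommands.
`scripts/acceptance.R` recomputes the headline quantities (the fitted
$A$, the recovered rate constants, the minimum $R^2$ on noisy fixtures,
the pure-water enthalpy) from scratch at a given seed. Problem sizes used
there and in the tests — 100-point curves, $N = 200$ / $\Delta t = 10^{-5}$
reference solves, 10 Hz thermograms — are the package's reference
resolutions, chosen to match the study conditions while keeping any run
under a minute.
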