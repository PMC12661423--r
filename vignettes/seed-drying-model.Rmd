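---
title: "The seeddry single-seed drying model: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The seeddry single-seed drying model: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seeddry)
```

`seeddry` simulates convective drying of a single spherical seed and the
material models that close it: sorption isotherms with glassy-state
corrections, a moisture/temperature-dependent diffusivity, boundary-layer
transfer closures, a drying-curve accuracy statistic and a fluidised-bed
mixing diagnostic. This vignette is the package's record of what the model
assumes, which knobs exist and why their defaults are what they are, and how
the numerics behave at the edges.

## 1. The physical model

A hydrated seed (radius ~1 mm, initial moisture ~36.7 % wet basis) is
exposed to drying air. Four assumptions define the transport model:

1. **Uniform temperature.** The Biot number of the hydrated seed at the
   working air speed is ~0.18 (`compute_biot()`), safely below the usual
   0.4 threshold, so a single lumped temperature suffices.
2. **Perfect sphere.** Cabbage seeds are close to spherical (~2 mm
   diameter).
3. **One homogeneous material** by default; a two-material (embryo + coat)
   variant relaxes this (section 5).
4. **Ideal shrinkage.** Seed volume is the sum of component volumes (zero
   excess mixing volume); volume lost equals the volume of evaporated
   water. Thermal expansion enters only through the temperature-dependent
   component densities.

Water moves by Fickian diffusion in the co-moving (Lagrangian) frame of the
solid matrix: control volumes are attached to the solids, so the solid mass
of every shell is constant for the whole run and only water crosses shell
boundaries. Evaporation at the surface follows

$$J_{evap} = \beta_{ext}\,\frac{M_w}{R\,T_{avg}}\,\big(a_w\,p_{sat}(T) -
RH_{air}\,p_{sat}(T)\big), \qquad T_{avg} = \tfrac{1}{3}(T_{air} + 2T),$$

with both saturation pressures at the *seed* temperature (the printed form
of the flux law; `air_psat_at_air_temp = TRUE` switches the air-side term to
$p_{sat}(T_{air})$ for sensitivity studies). The surface water activity is
evaluated at the centred concentration of the outermost shell, which is an
adequate surface approximation for the shell counts used here. The lumped
heat balance is

$$\rho_{eff} c_{p,eff} V \frac{dT}{dt} = \big(h_{eff}(T_{air} - T) -
[\Delta H_{evap,0} + (c_{p,v} - c_{p,w})(T - T_0)]\,J_{evap}\big)\,A.$$

**Sign of the convective term.** The source heat balance types the
convective term as $h_{eff}(T - T_{air})$ on a positive right-hand side,
which would cool a seed below the air temperature indefinitely; every
figure-level behaviour (seed temperature relaxing toward the air
temperature after the evaporative-cooling dip) requires heat to flow from
hot air into a cooler seed. The default is therefore the physically signed
$h_{eff}(T_{air} - T)$; `sign_convention = "verbatim"` reproduces the
typeset form for comparison runs.

Boundary-layer closures are the Ranz-Marshall correlations
$Sh = 2 + 0.6\,Re^{0.5} Sc^{0.33}$, $Nu = 2 + 0.6\,Re^{0.5} Pr^{0.33}$ with
$Re = U\,2R/\nu_{air}$, $\beta_{ext} = Sh\,D_{air}/2R$, and the series
combination $h_{eff} = (1/h_{int} + 1/h_{ext})^{-1}$ with
$h_{int} = \lambda_{eff}/0.25R$ (the $0.25R$ internal length is taken
literally from the closure table) and $h_{ext} = Nu\,\lambda_{air}/2R$.

## 2. Sorption isotherms

Water activity follows Flory-Huggins theory (section "The model" of the
README gives the formulas). Three points deserve record:

**Oil exclusion.** Oil takes no part in water sorption, so the water volume
fraction entering the isotherm is computed from water and the hygroscopic
solid classes only (`water_volume_fraction()`), while the *total* water
volume fraction (oil counted with the solids) feeds the thermal
conductivity mixing rule. Component densities and specific heats are the
Choi-Okos temperature polynomials; fibre and sugar use the
complex-carbohydrate density polynomial.

**Glassy switch.** Both glassy additions are active exactly when
$T < T_g(y_w)$, with $T_g$ from the Couchman-Karasz mixing rule. Both vanish
continuously at the transition, so no blending is needed and the solver
sees a continuous (though kinked) isotherm. The derivative
$\partial T_g/\partial y_w$ in the free-volume term is analytic, keeping the
isotherm smooth for the solver; the inversion $y_w(T_g)$ used for
$\varphi_{w,T_g}$ is closed-form (the mixing rule is a ratio of linear
functions), so no root finding runs inside the time loop.

**The Leibler-Sekimoto logarithm.** The elastic addition is
$\mu_{LS} = \frac{\nu_w K_g}{R T}\ln\frac{1 - \varphi_{w,T_g}}{1 - \varphi_w}$
by default (`ls_form = "retention"`): negative in the glassy state
($\varphi_w < \varphi_{w,T_g}$), zero at the transition. The flattened
typesetting of the source equation admits the inverted ratio as well, which
is positive in the glassy state and *raises* water activity. Three
independent lines of evidence select the retention reading: (i) the narrative
the equation supports — unrelaxed drying stresses lead to *more* retained
water, with drying endpoints above the equilibrium isotherm; (ii) the fitted
modulus $K_g = 3.3\times10^9$ Pa, which can only be identified from
*elevated* final moisture contents if the term lowers $a_w$; and (iii) scale:
with $K_g = 3.3\times10^9$ Pa the prefactor $\nu_w K_g / RT \approx 24$, so
the inverted reading drives $a_w$ to order $10^2$ in the glassy state and
with it nonphysical evaporative transients. The inverted reading remains
available as `ls_form = "as_printed"` and is exercised by the test suite.

Activities above 1 (possible for $\chi_{ws} > 1$ at intermediate moisture,
including the hydrated initial state) are reported with a one-time
diagnostic, not clipped — clipping would silently alter fluxes. A
`clip_aw` flag exists for users who want the clamp.

**Fitting.** `fit_chi()` fits $\chi_{ws}$ by least squares *in moisture
content at the table's water activities* — the way isotherms are plotted and
judged — which requires one isotherm inversion per row per objective
evaluation. Only rows above the glass transition are used, matching the
protocol of fitting the bare Flory-Huggins model in its regime of validity.
`fit_kg()` fits $K_g$ the same way against final drying moisture contents in
the glassy region; a single exact point already identifies the one free
parameter, so the fit errors only when *no* glassy point is available.

## 3. Diffusivity

$D_w = (a\,\log_{10} y_w + b)\,\exp(-\frac{E_a}{R}(\frac{1}{T} -
\frac{1}{298.15}))$, clamped below at $10^{-12}$ m² s⁻¹ *after* the full
evaluation, so the Arrhenius factor cannot lift a clamped value. The clamp
reflects diffusion levelling off rather than vanishing in the glassy state.
The mutual diffusivity of the transport equation is identified with the
measured water diffusivity (a documented `multiplier`, default 1, records
the assumption). `fit_diffusivity_ab()` is a linear least-squares fit
against $\log_{10} y_w$ at the reference temperature, excluding
floor-clamped points with a warning; `fit_activation_energy()` fits $E_a$ by
least squares on the ratio $D_w(T)/D_w(T_{ref})$ with $(a, b)$ held fixed.

## 4. Numerical scheme

The sphere is divided into N equal-volume shells (default 10). Each step:

1. Geometry from masses: shell volumes $V_k = m_{s,k}/\rho_s(T) +
   m_{w,k}/\rho_w(T)$ (ideal shrinkage), outer radii from cumulative
   volumes, centroid radii $r_c = ((r_{out}^3 + r_{in}^3)/2)^{1/3}$.
2. Interface flows $Q_k = D_{if}\,(c_k - c_{k+1})/(r_{c,k+1} - r_{c,k})
   \cdot A_k$ with $D_{if}$ at the arithmetic mean of the adjacent water
   mass fractions; zero flux at the centre; $J_{evap} A_N$ at the surface.
3. Explicit Euler update of water masses and temperature.

**Time step.** Adaptive, the minimum of: 0.25 times the diffusive stability
limit $\min_k \Delta r_k^2 / 2 D_k$; a cap keeping any shell's water loss
below 10 % per step; 0.2 times the linearised thermal time constant
$\rho c_p V / (h_{lin} A)$, where $h_{lin}$ adds the evaporative sensitivity
$L\,\partial J/\partial T$ (the saturation pressure steepens ~6 %/K, which
can dominate $h_{eff}$ during the wet-bulb transient); and a 30 s ceiling so
time-varying schedules are tracked. Refining these caps changes 24-h
moisture curves by well under $10^{-3}$ MC; a negative water mass aborts the
run with a diagnostic rather than silently clamping.

**Conservation.** Internal flows cancel pairwise by construction, so
cumulative evaporation plus residual water equals the initial water to
floating-point accumulation (observed ~$10^{-14}$ relative over 24 h runs,
asserted at $10^{-8}$); solid shell masses are bit-for-bit constant.

**Verification.** In the degenerate linear regime (constant diffusivity, no
shrinkage, isothermal, surface concentration pinned to zero) the solver is
compared against the analytic Fickian-sphere series
$MR = \frac{6}{\pi^2}\sum n^{-2} e^{-n^2\pi^2 D t/R^2}$; with N = 20 the
maximum deviation over a 24-h trajectory is below 1 % (observed
~0.08 %, with ~0.8 % in the first minutes where the surface layer is
under-resolved). Equilibrium is verified by running each isotherm variant to
steady state and comparing the endpoint with the direct isotherm inversion
(agreement to ~$10^{-9}$ MC).

**Grid sensitivity.** Halving the shells from 10 to 5 shifts the early
drying knee by minutes; against an N = 20 reference on hourly samples this
costs ~0.25 percentage points of PE at N = 5 versus ~0.08 at N = 10 under
the default parameter set. The statistic concentrates in the single sample
nearest the knee and is sensitive to the glass-transition placement
(section 7), which is not a printed material constant.

**Saturation pressure** uses the Arden Buck correlation (±0.3 % over
0-60 °C, 0.05 % at 100 °C), chosen over the plain Magnus form whose ~3 %
error at the boiling point would fail steam-table cross-checks. Air-side
transport properties ($\nu_{air}, \lambda_{air}, \alpha_{air}$) are linear
fits to standard dry-air tables valid 0-80 °C; vapour diffusivity follows
the $T^{1.81}$ power law. All are evaluated at the boundary-layer average
temperature.

**Property caching.** Component densities/heat capacities are reused until
the seed temperature moves by more than 0.005 K (property change
< $10^{-5}$ relative), which roughly halves run time without measurable
effect on trajectories.

## 5. The two-material (embryo/coat) variant

The outermost shell represents the seed coat ($\chi_{ws} = 0.465$, 15 % oil
in dry matter), the inner shells the embryo ($\chi_{ws} = 1.302$, ~38 %
oil). Across dissimilar materials a concentration difference is not a
driving force, so the embryo/coat interface flow is

$$Q = \beta_{int}\,A\,\frac{c_{w,avg}}{a_{w,avg}}\,(a_{w,embryo} -
a_{w,coat}).$$

No value of $\beta_{int}$ is established for seeds. The requirement we
impose is that the two-material model with *identical* materials reproduce
the one-material solution. The naive choice $\beta_{int} = D/\Delta r$ does
not achieve this: substituting it gives a flux equal to the Fickian flux
times $d\ln a_w/d\ln c_w$, a factor ranging from ~0.25 (wet) to ~1 (dry) —
one interface would be throttled several-fold for no physical reason. The
default rule (`beta_int_rule = "matched"`) therefore sets
$\beta_{int} = \frac{D}{\Delta r}\frac{a_{w,avg}}{c_{w,avg}\,\bar s}$ with
$\bar s$ the mean isotherm slope $da_w/dc_w$ of the two adjacent shells
(numerically differentiated at fixed solids), which restores the Fickian
flux exactly to second order in the concentration difference when the
materials coincide (verified to 1 % per-flux and to $2\times10^{-4}$ MC over
full runs). The bare `"gradient"` rule remains available. Evaporation in
this mode uses the coat water activity.

## 6. Evaluation and mixing diagnostics

`percent_error()` linearly interpolates the (dense) model curve to the
experimental timestamps and applies
$PE = \frac{100}{n}\sum |MC_{exp} - MC_{model}| / MC_{model}$ — note the
model value in the denominator, making the statistic asymmetric, and making
near-zero model values dominate; an exclusion list supports dropping such
points (e.g. a 0 % RH endpoint). When inlet and outlet sensor series are
both available, `average_schedules()` builds the pointwise average, the
condition the bed actually experiences.

The mixing entropy of a bed photograph is computed from black/white pixel
fractions on a 5×5 grid:
$S = \sum_j w_j s_j / s_{max}$, $w_j = n_j/\sum n$,
$s_j = -(x_j \ln x_j + (1-x_j)\ln(1-x_j))$, $s_{max}$ the same entropy at
the overall white fraction, $0\ln 0 = 0$. This particle-count-weighted
binary form is a reconstruction of the standard formulation (the source
describes the procedure but prints no equation) and is the package's
documented contract: $S \in [0,1]$, invariant to colour relabelling,
non-increasing under grid refinement. Thresholding defaults to Otsu's
method with a fixed-threshold override; a crop box and background mask
handle frames that include apparatus.

## 7. Parameters, defaults and placeholders

| Parameter | Default | Units | Status |
|---|---|---|---|
| `chi_ws` (whole/embryo/coat) | 1.244 / 1.302 / 0.465 | — | fitted values |
| `K_g` | 3.3e9 | Pa | fitted value |
| `a`, `b` | 3e-11, 9e-11 | m² s⁻¹ | fitted values |
| `E_a` | 14.18e3 | J mol⁻¹ | fitted value |
| diffusivity floor | 1e-12 | m² s⁻¹ | stated limit |
| `N_s` | 1000 | — | polymer limit; `(1-1/N_s) ≈ 1`; configurable |
| `R0`, `MC0` | 1e-3, 0.367 | m, — | stated geometry/initial state |
| `U` | 0.235 | m s⁻¹ | stated air speed |
| `T_g,w`, `dCp_w` | 136, 1940 | K, J kg⁻¹ K⁻¹ | literature water values |
| `T_g,s`, `dCp_s` | 350, 500 | K, J kg⁻¹ K⁻¹ | **placeholder** (below) |
| `lambda_w`, `lambda_s` | 0.60, 0.20 | W m⁻¹ K⁻¹ | **placeholder** conductivities |
| compositions | see `default_composition()` | — | oil fractions stated; split **placeholder** |

The solid glass-transition parameters are not printed material constants.
The default $T_{g,s} = 350$ K, $\Delta C_{p,s} = 500$ J kg⁻¹ K⁻¹ places the
mixture glass transition at ~7.6 % MC (wet basis) at 25 °C — a typical value
for oil-rich seed tissue — and, importantly, leaves the upper humidity steps
of a desorption experiment (a_w ≳ 0.85) in the rubbery state, without which
the "fit Flory-Huggins above $T_g$" protocol has no usable data on any
sub-unity humidity grid. Quantities that hinge on the knee of the drying
curve (final MC, grid-sensitivity statistics) move noticeably with this
placement; users with measured $T_g$ curves should override `ck_params()`.

## 8. Synthetic data: what it does and does not emulate

The `gen_*()` generators produce every input class the package consumes:
humidity-step sorption tables, drying curves sampled at a balance-like
cadence with multiplicative Gaussian noise (truncated to keep MC in (0,1);
balance noise scales with signal), smoothly fluctuating measured-air
schedules, and black/white seed-bed images from segregated to fully mixed.
All are pure functions of their arguments and seed; separate fixtures use
independent streams so adding one never perturbs another.

They deliberately do **not** emulate: sorption hysteresis (sorption and
desorption branches are separate fits by design), instrument artefacts
(balance drift, sensor lag), seed-to-seed variability, non-spherical
geometry, or photographic nuisance (lighting gradients, occlusion,
apparatus in frame). Passing tests therefore demonstrate internal
correctness — conservation, convergence to the analytic sphere, parameter
recovery, equilibrium consistency — not agreement with any laboratory
measurement.

Test and verification problem sizes: property tests run 2-6 h simulations
at N = 5-10; the verification suite runs 24-h simulations at N = 5, 10 and
20 and samples hourly, the same cadence as manual moisture sampling in
drying trials.

## 9. Known limitations

- Validity is limited to drying temperatures up to ~40 °C: both the
  diffusivity law and the isotherm parameters were fitted at 25-40 °C.
- No pore mechanics: drying seeds develop internal air pockets; the model
  treats the matrix as space-filling, and the measured diffusivity is
  assumed to absorb pore effects.
- Lumped temperature rules out strong-radiation or high-Biot scenarios.
- The PE statistic is undefined where the model moisture reaches zero and
  is dominated by points where it is small; use the exclusion list.
- Placeholder constants (section 7) must be replaced with measured values
  for quantitative work on other seed lots or species.
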