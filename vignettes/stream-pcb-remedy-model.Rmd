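---
title: "Methods: linked stream PCB fate, bioaccumulation and remedy decision models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked stream PCB fate, bioaccumulation and remedy decision models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pcbfate)
```

`pcbfate` re-implements, at desk scale, the kind of linked
fate-and-transport plus food-web bioaccumulation modelling system used to
select and post-audit sediment remedies at PCB-contaminated stream sites:
a small spring-fed stream (Conard's Branch, 0.8 mile) receiving
PCB-bearing karst spring water below a landfill, joining a larger creek
(Richland Creek, 2.2 modelled miles) whose dilution sets the downstream
gradient. This vignette is the package's account of the science: the
governing relations, the parameters that matter, what the synthetic data
emulate, and the numerical and design choices.

## 1. Hydraulics

The channel is a chain of rectangular cells (default 20 per reach) on a
river-mile axis. Flows are routed quasi-steadily: boundary and lateral
inflows propagate instantaneously downstream, so flow is conserved
exactly at every cell and tributary flows add at the confluence. Depth
comes from inverting Manning's equation per cell,

$$Q = \frac{1}{n} A R^{2/3} \sqrt{S}, \qquad A = wh,\; R = \frac{wh}{w+2h},$$

solved by safeguarded Newton iteration to a relative residual below
1e-8. The full momentum equations are deliberately out of scope: in this
system the hydrodynamics exist only to supply flows, depths, velocities
and bed shear ($\tau = \rho g h S$) to the transport and food-web
stages, and a stage-discharge rating supplies those directly. The
default geometry (6 ft wide / slope 0.001 / Manning n 0.060 upstream;
15 ft / 0.0017 / 0.050 downstream) reproduces the observed base-flow
depths of about 0.6 ft and 0.9 ft and a conservative dilution factor of
about 8 for tributary water below the confluence, inside the observed
5-10 range. Dispersion coefficients (0.5 and 1.0 m^2/s) are assumptions:
no dye-test values were published.

## 2. Boundary sources

Each PCB input is a flow-stratified power rating with continuous
first-order temporal decay,

$$C(Q,t) = a_r\,(Q/Q_{ref})^{b_r}\, e^{-\lambda (t-t_0)},$$

with separate $(a_r, b_r)$ for the base-flow and storm regimes, split at
a configured flow threshold. The structure (flow-based rating plus
first-order decline) is given; the algebraic form is this package's
choice, selected as the fewest-parameter shape consistent with it. The
observed ~6 %/yr spring decline is interpreted as continuous decay,
$\lambda = 0.06\,\mathrm{yr}^{-1}$, because the six-year adjustment
factor is computed as the exponential surviving fraction
$e^{-0.36} \approx 0.70$. `fit_decay_rate()` estimates $\lambda$ by
log-linear regression with an optional log-flow covariate; on noise-free
input the recovery is exact.

Default rating values (spring: 250 ng/L at the reference base flow with
storm exponent 0.25; NSB seeps: 400 ng/L on one-tenth of the spring
flow; treatment-plant effluent: constant 50 ng/L at 450 gpm) are
assumptions scaled so the pre-remedy water column sits near 150-200 ng/L
at the upper station — the published record gives the decline rate and
the qualitative source structure, not the rating coefficients.

## 3. Fate and transport

A finite-volume cell balance of total suspended solids and total PCBs
(one lumped state, no congeners) over a two-layer sediment bed:

* water column: upwind advection, central dispersion, external loads,
  settling of the particulate fraction ($v_s f_p C_w / h$),
  volatilization of the dissolved fraction ($k_v f_d C_w / h$),
  dissolved porewater exchange $k_f (C_{pw} - f_d C_w)/h$ with
  $C_{pw} = C_{bed}/K_{p,bed}$;
* equilibrium two-phase partitioning, $f_d = 1/(1 + K_p \cdot TSS)$ with
  $K_p = K_{oc} f_{oc}$ (no third DOC phase);
* bed: deposition, excess-shear resuspension
  ($M_e \max(\tau - \tau_c, 0)$, zero below $\tau_c$), porewater
  release, bioturbation exchange between the active and deep layers
  ($D_b/\Delta z$), and burial at $v_b$; layer solids masses are held
  constant (the net solids imbalance is absorbed by the implicit deep
  supply), which keeps every PCB process first order.

Linearity is load-bearing: `apportion_sources()` runs the model once per
source (the initial bed inventory counts as a source) and relies on
exact superposition, which the acceptance tests verify to 1e-6 and the
implementation achieves to round-off. A full mass ledger (loads in,
export, volatilized, buried, storage change in water and bed) is
returned and closes to round-off; 0.5 % is the acceptance bound.

Rate defaults are literature-plausible values for total PCBs over a
rocky, armored bed, tuned only to satisfy the documented configuration
checks (settling below one percent of the upper-stream load,
volatilization a few percent): $K_{oc} = 10^6$ L/kg OC, suspended-solids
$f_{oc} = 0.05$, $v_s = 0.6$ m/d, $\tau_c = 5$ Pa (base-flow shear is
~1.8 Pa upstream and ~4.5 Pa downstream, so the armored bed does not
erode at base flow), $M_e = 0.02$ kg/m^2/d/Pa, $k_v = 0.35$ m/d,
$k_f = 0.04$ m/d, $D_b = 3\times10^{-6}$ m^2/d,
$v_b = 5\times10^{-7}$ m/d, bed $f_{oc} = 0.03$, active layer 10 cm at
1.25 kg/L dry bulk density. The calibrated site values were never
published; these stand in for them and are labelled as assumptions, not
site estimates.

## 4. Food web

Three prey compartments drive two fish species. Benthic invertebrates
equilibrate with organic-carbon-normalized bed sediment
($\beta_{soc} (C_{bed}/f_{oc}) \cdot \mathrm{lipid}$), water-column
invertebrates with the dissolved phase
($BAF_w \cdot f_d C_w \cdot \mathrm{lipid}$), and terrestrial
invertebrates are uncontaminated by definition. Fish follow the standard
bioenergetics burden balance,

$$\frac{d\nu}{dt} = k_u f_d C_w + \alpha_d I \sum_i p_i(m)\,\nu_i
  - k_e \nu - G\nu,$$

with monthly diet fractions $p_i$, growth dilution $G$ from a power
age-weight curve, feeding from the energy closure $I = (R+G)/AE$ with
$R = \alpha_R w^{-\gamma} e^{\theta T}$ on a repeating sinusoidal annual
temperature cycle, and elimination scaled inversely with the monthly
lipid fraction (which, with the seasonal diet, produces the within-year
oscillation seen in monitoring data). Fish are stationary at their
station (home ranges under ~100 m); age classes 1-3 are simulated as
cohorts with an April 1 birthday, cohorts alive at the start initialized
at their quasi-steady burden; the station value is the unweighted mean
over the sampled classes, mirroring composite sampling. $k_e$ is
supplied directly rather than derived from $K_{ow}$ to keep the
parameterization flat and testable. Kinetic and diet defaults
(creek chub $k_u = 80$ L/kg/d, $k_e = 0.01$/d, $\alpha_d = 0.9$,
$AE = 0.8$; longear sunfish slightly lower and more terrestrial) are
literature-plausible placeholders. The fillet basis at the downstream
station uses a single configurable whole-body-to-fillet ratio (0.6):
how the original fillet projections were derived was not specified.

## 5. Scenario engine

`remedy_alternative()` encodes the seven strategies: 1 removes the
treatment plant; 2 is the status quo (450 gpm plant, 85 % base-flow
capture, 99 % removal — the removal efficiency is a package assumption);
3 dredges the upper-stream bed to the 1 mg/kg cleanup criterion,
captures the NSB seeps into the plant, and relocates the outfall
downstream; 4-7 add storm storage (1 to 13 million gallons) and capacity
(600 to 1000 gpm), modelled as a fill-spill reservoir that drains
through the plant on calm days and spills when full. Captured NSB load
bypasses the capacity limit (the improved collection system was designed
for it). Projections recycle the multi-year synthetic flow record as a
repeating hydrology cycle and run ten years by default.

**Bounding calibrations.** The upper bound (less response to
remediation, higher projected concentrations) slows spring recovery
($\lambda \times 2/3$), trims NSB loads (x0.9), raises storm loads
(x1.3) and the porewater release flux (x1.5), weakens volatilization
(x0.8), and shifts diet from the terrestrial to the benthic compartment
(benthic x1.15, capped by the terrestrial fraction available that
month); the lower bound shifts each the opposite way. The published
analysis states the shift directions, not magnitudes; these defaults are
configurable assumptions chosen so every shift is monotone in projected
concentrations, which makes the lower <= base <= upper bracket hold by
construction — the bracket's purpose. Two scoping choices matter and
were made deliberately: the sediment-exchange factor multiplies the
porewater release flux only (scaling resuspension as well perturbs the
decade-scale bed trajectory instead of the sediment-to-water loading,
and can invert the bracket at undredged stations), and the diet shift
leaves the water-column fraction untouched with terrestrial as the
balancing term.

**Delay adjustment.** Projections issued years before construction are
adjusted for recovery during the delay: the water column is multiplied
by the surviving fraction $e^{-\lambda \Delta t}$ (0.70 for six years at
6 %/yr) and each fish series by
$m = 1 - (1 - e^{-\lambda\Delta t}) f_{adj}$, where $f_{adj}$ is the
fraction of that station/species burden attributable to the decaying
spring and seep sources. The default $f_{adj}$ values (0.63, 0.56, 0.36)
invert the reported multipliers 0.81, 0.83 and 0.89; multipliers are
held at full precision internally and rounded to two decimals only for
reporting.

## 6. Compliance statistics

The remedy-confirmation rule is implemented as two one-sided one-sample
Student's t-tests against the station target (2.3 / 0.9 mg/kg whole
body, 0.2 mg/kg fillet) at alpha 0.05: *success* if the mean is
significantly below the target, *failure* if significantly above,
*inconclusive* otherwise. The exact decree formulation (including
whether its tests were one- or two-sided and any explicit inconclusive
band) lives in unpublished supplementary tables; this two-one-sided
reading is documented as an interpretation, not a reproduction. The
statistical unit is the composite analysis (three fish per composite);
nondetects substitute at half the detection limit; no multiplicity
adjustment is applied across stations (each has its own clause). The
pre/post decline test is a one-sided Welch two-sample t-test. `rcc_test`
computes its t machinery directly so `stats::t.test` remains an
independent cross-check, exercised on 1000 random datasets in the
acceptance suite.

## 7. Synthetic data

The generators emulate the statistical structure the analysis assumes:
lognormal base flows (median 0.06 and 0.35 m^3/s) with Poisson storm
arrivals (22/yr) shared between the streams, truncated-lognormal peak
multipliers (spring up to x700, creek up to x90 — up to three and two
orders of magnitude above base flow) decaying over 0.3-1.2 days;
monthly routine water grabs shifted off storm days (routine monitoring
is nonstorm), multiplied by median-unbiased lognormal observation error
(CV 0.5) and censored at a 10 ng/L detection limit; and fish composites
of three individuals drawn from a lognormal with CV 0.5 around the true
station mean (60/60/54 fish per station per review round). Every
generator takes an explicit seed and restores the caller's RNG state.

They do *not* emulate: rainfall-runoff physics, flow-concentration
hysteresis, serially correlated hydrology, analytical inter-laboratory
bias, or fish movement. Passing tests therefore demonstrate internal
consistency of the pipeline under its own assumptions — parameter
recovery, mass conservation, bracketing, decision behavior — not
predictive skill on the real site, whose calibrated parameters were
never published.

## 8. Numerics

* Transport: explicit first-order upwind advection with central
  dispersion, sub-stepped so the Courant number (including the
  dispersion term) never exceeds 0.9; a user-chosen step that violates
  the condition is refused with the required step reported.
* First-order sinks and sources are integrated exactly within each
  substep (operator splitting, `m' = m e^{-r\Delta} + S(1-e^{-r\Delta})/r`),
  which keeps states non-negative at any stable step and makes the
  closed-form decay checks exact up to splitting error; the inner loop
  is compiled (Rcpp).
* Bed-derived fluxes are frozen over each day (the bed evolves on
  month-to-decade scales); the bed updates daily.
* The fish ODE uses the same exponential one-day update, so constant
  conditions hit the closed-form steady state exactly.
* A negative state aborts with a diagnostic rather than being clipped —
  clipping would silently break the linearity that apportionment needs.
* Tie-breaks and degenerate inputs: zero flow gives zero depth and
  velocity; zero-flow intervals contribute zero load; `foc = 0` with a
  contaminated bed is an error, not an NaN.

Problem sizes: tests and the acceptance script run the default 40-cell
network with daily hydrology — one-year diagnostics for budget and
apportionment checks, ten-year projections (about 3650 days, typically
200-300 transport substeps per day) for the alternative comparison and
bounding bracket, and 1000-replicate Monte Carlo for the decision
checks. These sizes were chosen to exercise every pathway at full
resolution while a complete run stays in the minutes range.

## 9. Known limitations

Quasi-steady hydraulics cannot represent wave travel or wetting/drying;
storm timing inside a day is unresolved. The single lumped PCB state
ignores congener-dependent partitioning and volatilization. Constant
bed-layer masses are inconsistent with strong net deposition (acceptable
here: both streams are armored and depositional areas intermittent).
The lipid-scaled elimination is a coarse stand-in for lipid
partitioning kinetics. The treatment-plant removal efficiency, the
post-dredge residual, and all bounding shift magnitudes are assumptions
exposed in the configuration; conclusions that depend on their absolute
values (rather than orderings and brackets) should be treated
accordingly.
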