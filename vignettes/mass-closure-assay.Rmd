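---
title: "The two-extrusion mass-closure assay: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-extrusion mass-closure assay: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiconc)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices inside the fits, what
the synthetic-data generators do and do not emulate, and the known
limitations.

## 1. The assay

An extrusion preparation starts from a weighed lipid mass $M_0$ and ends
with a main sample (volume $V_1$, concentration $C_1$) plus whatever the
rinse extrusion recovers from the filter and dead volume (total
$V_T - V_1$, concentration $C_2$). Two physical facts make the pair
solvable from two intensity readings:

1. **Shared size distribution.** Both samples passed the same filter, so
   they share $M_w$ and the form factor $P(\theta)$. In the
   dilution-corrected intensity ratio
   $\gamma = I_1 d_1 / (I_2 d_2)$ the instrument constant, contrast,
   vesicle mass and form factor all cancel, leaving $\gamma = C_1/C_2$.
   This also makes $\gamma$ instrument-independent: goniometer counts,
   Rayleigh ratios and spectrofluorimeter elastic-peak areas give the
   same $\gamma$ as long as both samples are measured identically.
2. **Mass closure.** $M_0 = C_1 V_1 + C_2 (V_T - V_1)$, which assumes
   the dead-volume solution shares the rinse concentration $C_2$ —
   i.e. lipid trapped in the extruder but not in vesicles is
   negligible. The closed form is $C_2 = \alpha/(\gamma+\upsilon)$,
   $C_1 = \alpha\gamma/(\gamma+\upsilon)$ with $\alpha = M_0/V_1$,
   $\upsilon = (V_T-V_1)/V_1$.

`solve_concentrations()` enforces the closure identity to machine
precision by construction; its `closure_residual` is a sanity check, not
a fit statistic. The solver flags two pathologies rather than guessing:
`c1_exceeds_alpha` (inputs violate mass conservation) and
`i2_below_noise` (the rinse signal is statistically indistinguishable
from zero, so $C_2$ is unconstrained).

**Dilution validity.** The intensity model $I = k M_w C P(\theta)$ holds
in the dilute regime (no structure factor). Working near 1 mg/mL before
dilution and measuring at 1:50 / 1:5 keeps the assay there; the package
does not attempt structure-factor corrections.

## 2. Error model

Intensity replicates (triplicates by default) are averaged and assigned
$SE = SD/\sqrt{n}$. First-order (delta-method) propagation through the
closed form gives $SE(C_1)$, $SE(C_2)$; masses and volumes are treated
as exact by default because they are read off a balance and a syringe
scale, but optional SEs are propagated when given. Against Monte-Carlo
draws at the same noise level the delta-method SEs agree within a
percent or two at realistic coefficients of variation (a few percent) —
the tests pin this at 5%.

A subtlety the tests document: SEs estimated from three replicates carry
only 2 degrees of freedom, so the pivot (error divided by estimated SE)
is $t$-like with roughly 4 effective degrees of freedom rather than
Gaussian. Its two-sided 2-SE coverage is about 88.6% (not 95%), and its
3-SE coverage is about 96%. The package reports plain first-order SEs
and leaves the small-sample interpretation to the user; the test suite
asserts the coverage bands actually attained by this design.

Two independent preparations are combined by
`aggregate_preparations()`: the mean, with the attributed uncertainty
being the larger of the combined measurement error
$\varepsilon_{AB} = \sqrt{\varepsilon_A^2+\varepsilon_B^2}/2$ (the SE of
a mean of two independent measurements) and the preparation spread
$\sigma_{AB} = \sqrt{\Delta x_A^2 + \Delta x_B^2}$,
$\Delta x = x - \bar x$. Scattering SEs on a single preparation can be
very small, so the spread term is what usually carries the
preparation-to-preparation variability. The formula lives in one
function so an alternative pooling convention is a one-line change.

## 3. DLS analysis

### Cumulants

`fit_cumulants()` fits the bracket (non-linearized) form
$g^{(2)}(t) = B + \beta e^{-2\bar\Gamma t}(1 + \tfrac{\mu_2}{2}t^2)^2$
by Levenberg–Marquardt with uniform weights. Choices:

* **Baseline start**: mean of $g^2$ over the last 10% of lags, refined
  inside the fit. (Correlator vendors differ in how they pin the
  baseline; refining it costs nothing and removes the dependence.)
* **Decay-rate start**: log-linear regression of
  $\ln[(g^2-B)/\beta]$ over the first decade of decay; $\mu_2$ starts
  at 0 and is constrained non-negative (a bound hit sets an `at_bound`
  flag).
* **Order**: order 1 pins $\mu_2 = 0$; order 2 is the default. Fitting
  the bracket form directly, rather than the linearized logarithm,
  matches the model exactly at the price of a nonlinear solve — which
  converges in a handful of iterations on realistic data.
* Standard errors come from the Gauss–Newton covariance
  $\hat\sigma^2 (J^\top J)^{-1}$; the polydispersity index
  $PI = \mu_2/\bar\Gamma^2$ gets a delta-method SE from the joint
  covariance.
* Intercepts $\beta < 0.05$ flag the data as low-intercept rather than
  failing: such correlograms usually mean misalignment or dust.

The Stokes–Einstein conversion $\bar D_h = k_B T q^2/(3\pi\eta\bar\Gamma)$
uses $q = (4\pi n_0/\lambda)\sin(\theta/2)$ — the solvent refractive
index belongs in $q$; the benchmark value 22.3 µm⁻¹ at 532 nm/90° only
emerges with $n_0 = 1.333$. Defaults $T = 293.15$ K and
$\eta = 1.002$ mPa·s describe water at 20 °C and are user-overridable,
as is $q$ itself (useful when comparing against a value printed at
instrument precision). With the defaults, $\bar\Gamma = 0.00240$ µs⁻¹
gives 88.8 nm and $0.00260$ µs⁻¹ gives 82.0 nm; both within the
rounding of three-significant-figure inputs of the nominal 90 nm and
83 nm.

### Regularized inversion

`invert_contin()` recovers the intensity-weighted decay-rate
distribution $G(\Gamma)$ in
$g^{(2)}(t) = B + \beta[\int G(\Gamma)e^{-\Gamma t}d\Gamma]^2$.
Numerical design:

* **Grid**: 80 log-spaced points on $[0.1/t_{max}, 10/t_{min}]$ —
  generous on both sides of the observable decay window.
* **Fit domain**: the field correlation
  $\sqrt{(g^2-B)/\beta} \approx \sum_i G_i e^{-\Gamma_i t}$, solved by
  non-negative least squares with a squared-second-difference smoothness
  penalty $\lambda \|D_2 G\|^2$.
* **Baseline**: the inversion is *very* sensitive to $B$ — an
  overestimate truncates slow modes, an underestimate invents them. A
  cumulants pre-fit is not reliable here because the cumulants model
  misfits well-separated multimodal decays and inflates $B$. Instead,
  $B$ starts at the mean of the last 5% of lags and is refined by a
  one-dimensional search (coarse scan, then golden section) minimizing
  the $g^2$-domain reconstruction residual. Grid components with
  $\Gamma < 1/t_{max}$ barely decay over the window and are degenerate
  with the baseline, so they are excluded from the refinement solve
  (not from the final one). A known baseline can be passed directly.
* **$\lambda$ selection**: `"auto"` picks the corner (maximum discrete
  curvature) of the L-curve — log residual norm against log seminorm —
  on a 20-point $\lambda$ grid spanning $10^{-6}$–$10^2$; the selected
  value is reported.
* $\beta$ only scales the weights, which are renormalized to unit sum,
  so its estimate ($\max g^2 - B$) needs no refinement.

On synthetic benchmarks this recovers an on-grid noiseless delta to
>99% of weight in one grid step, and a 10×-separated equal-weight
bimodal at $10^{-3}$ additive noise to within ~0.5 grid step per mode
with the split within a few percent. The harmonic-mean diameter
$[\sum_i G_i/D_i]^{-1}$ is the summary the mean decay rate of a
polydisperse correlogram actually estimates, which is why it (and not
the arithmetic intensity mean) is the package's distribution summary.

## 4. Thin-shell mass model and detection limit

A unilamellar vesicle is a sphere with all lipid mass in a thin shell:
$M(D) = (2\pi M_{lip}/\Delta A_{lip})D^2$ (area of both leaflets per
head group of area $\Delta A_{lip}$; 0.63 nm² for POPC). Because
$I \propto M_w C$ at fixed threshold intensity, the minimum detectable
concentration scales as $1/D^2$: 4-fold lower at 100 nm and 16-fold at
200 nm than at 50 nm. `detection_limit()` implements exactly this
scaling from a user-supplied reference point (about 0.01 mg/mL at 50 nm
on the setups this was developed for); it deliberately does not attempt
absolute Mie/Rayleigh–Gans intensity calculations.

## 5. Elastic-peak intensities

A spectrofluorimeter with $\lambda_{em} = \lambda_{ex}$ measures
elastically scattered light; the area under the elastic band is a valid
intensity measure for $\gamma$ because only ratios matter. Defaults:
integration window ±5 nm around $\lambda_{ex}$ (a few slit widths), and
a linear baseline fitted on the two flanking bands just outside the
window, which makes the area exactly invariant to constant offsets. An
explicit buffer spectrum can be subtracted instead. PMT voltage and slit
settings affect absolute areas but cancel in $\gamma$; no correction is
attempted, and areas are clipped at zero (with a warning when the
deficit exceeds roundoff).

## 6. Stewart calibration

The colorimetric cross-check fits absorbance at 485 nm against standard
concentration by weighted linear least squares (weights $1/SE^2$,
unweighted fallback when SEs are absent), over the assay's linear range
0.005–0.050 mg/mL. A straight line with a fitted intercept is the
Beer–Lambert-consistent choice; a forced-origin option exists. Inverse
prediction $C = d(A - a)/b$ propagates the absorbance SE and the full
fit covariance to first order. Matrix specificity (different
phospholipids react differently; cholesterol not at all) is handled by
fitting separate curves from matrix-matched standards — the package
stores labels but applies no reactivity correction.

## 7. What the simulators emulate

The generators produce every input the pipeline consumes, with recorded
seeds and exact ground truth, under the conditions the assay was
designed around: ~1 mg lipid extruded into ~1 mg/mL, dilutions 1:50 and
1:5, triplicate intensity readings at ~2% CV, a 532 nm/90° setup in
20 °C water, vesicle sizes 50–200 nm.

* Correlograms: the forward Laplace model (or its cumulants
  parametrization) on log-spaced lags spanning every component's decay,
  plus *additive* Gaussian noise — a reasonable stand-in for a
  well-measured correlator channel but not a photon-counting model.
* Extrusion experiments: concentrations set to satisfy closure by
  construction ($C_1 = (1-f)M_0/V_1$, $C_2 = f M_0/(V_T-V_1)$ with
  residual fraction $f$, default 0.15); intensities from
  $I = k M_w (C/d) \bar P$ with the thin-shell $M_w$ and
  $P(q) = [\sin(qR)/(qR)]^2$ averaged over the size distribution, and
  *multiplicative* Gaussian replicate noise. The form factor matters
  only for the generator's realism — it cancels in the assay.
* Emission spectra: a Gaussian elastic band of specified area on a flat
  baseline; standards: a straight line plus replicate noise.

Passing tests on these generators validates the estimators against
known truth under Gaussian noise and perfectly shared size
distributions. They do not probe: number fluctuations or afterpulsing
in the correlator, multiple scattering, imperfect distribution matching
between the two extrusions, dust, or inner-filter effects in the
spectrofluorimeter. Those failure modes are exactly what the DLS
comparison of the two samples is for, which is why the workflow runs it
first.

Simulation sizes used by the test suite and kept deliberately modest:
10,000 randomized closure checks, 500 noisy experiments for coverage,
100 correlogram fits for bias, $10^5$-draw Monte Carlos for the
delta-method checks.

## 8. Known limitations

* The assay needs the two extrusion samples to share composition and
  size distribution; it has no internal test for this beyond the DLS
  comparison it recommends. The Rayleigh-standard shortcut inherits the
  same caller-asserted similarity assumption.
* Absolute Rayleigh-ratio calibration (toluene/benzene standards) is
  out of scope; `standard_reference()` accepts whatever consistent
  intensity scale the user provides.
* Drug-loaded vesicles are handled only in the sense that the assay
  measures total particle weight concentration; partitioning the lipid
  and cargo contributions is the user's analysis.
* The inversion's $\lambda$ selection is heuristic (L-curve corner);
  for publication-grade distributions, inspect the reported $\lambda$
  and the stability of the solution across its neighborhood.
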