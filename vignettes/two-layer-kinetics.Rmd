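---
title: "Two-layer release kinetics and effective time constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer release kinetics and effective time constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdds)
```

## The physical model and its assumptions

A transdermal patch is modelled as two planar slabs in series. Layer 1
(`-la <= x <= 0`) is the vehicle: the rate-controlling membrane of a
reservoir device or the drug-loaded film of a monolithic matrix. Layer 2
(`0 <= x <= lb`) is the skin. Each layer obeys Fick's second law,

$$\frac{\partial C_i}{\partial t} = D_i \frac{\partial^2 C_i}{\partial x^2},$$

and the layers are coupled at $x = 0$ by flux continuity
($D_1\,\partial_x C_1 = D_2\,\partial_x C_2$) and by local partition
equilibrium $C_1(0,t) = k_m C_2(0,t)$. The receiver side $x = l_b$ is a
perfect sink ($C_2 = 0$): the drug is swept away as fast as it arrives,
the usual idealisation of well-stirred receptor fluid or capillary uptake.
A **reservoir** device pins $C_1(-l_a,t) = C_0$ (infinite source — the
loading is far above depletion) with both layers initially empty; a
**matrix** device is initially loaded uniformly at $C_0$ in layer 1 behind
a sealed backing ($\partial_x C_1(-l_a,t) = 0$).

The assumptions to keep in mind: one-dimensional transport, constant
diffusivities (no concentration dependence, no skin metabolism), an ideal
sink, instantaneous interfacial equilibrium, and — for the reservoir — no
donor depletion. Real skin adds follicular shunts, binding and variable
hydration; none of that is modelled here.

## Nondimensionalisation

With

$$\beta = \frac{D_2 l_a}{D_1 l_b}, \qquad p = \frac{D_1 l_b^2}{D_2 l_a^2},
\qquad \tau = \frac{D_2}{l_b^2}\,t,$$

and scaled coordinates $\chi_1 = x/l_a$, $\chi_2 = x/l_b$, the dynamics
depend only on $(\beta, p, k_m)$. $\beta$ is the ratio of layer
diffusional resistances $l_a/D_1 : l_b/D_2$; $p$ compares the equilibration
rates of the two layers on their own thicknesses. The identity
$\beta p = l_b/l_a$ holds exactly and the package's validators rely on it;
it is also what makes mass conservation emerge from the matrix transform
(below). `dimensionless_groups()` performs the reduction and carries the
time scale $l_b^2/D_2$ (for the metoprolol fixture, 65,636 s ≈ 18.2 h; for
the ATA fixture 58.1 h).

## Laplace-domain transforms

Transforming the scaled equations gives $p\,\bar U_1'' = s \bar U_1$ (plus
a particular term $1/s$ for the loaded matrix) and $\bar U_2'' = s \bar
U_2$, so layer 1 carries wavenumber $\sqrt{s/p}$ and layer 2 carries
$\sqrt{s}$. Eliminating the four integration constants against the four
boundary/interface conditions yields, for the reservoir flux ratio,

$$\frac{\bar{j}(s)}{j_{ss}} = \frac{\beta + k_m}{\sqrt{s}\left[
  k_m \sinh\sqrt{s}\cosh\sqrt{s/p}
  + \beta\sqrt{p}\,\cosh\sqrt{s}\sinh\sqrt{s/p}\right]},$$

with steady flux $j_{ss} = C_0 D_2 / (l_b (k_m + \beta))$ — the familiar
series-resistance form $C_0 / (k_m l_b/D_2 + l_a/D_1)$ — and, for the
matrix fraction released,

$$\frac{\bar M(s)}{M_\infty} = \frac{\beta p}{s^{3/2}\left[
  k_m \sinh\sqrt{s}
  + \beta\sqrt{p}\,\cosh\sqrt{s}\,\coth\sqrt{s/p}\right]},
\qquad M_\infty = A\,l_a C_0 .$$

Rather than trusting the elimination algebra, the test suite re-derives
both transforms numerically: `tdds:::two_layer_bvp_flux()` assembles the
4×4 linear system for the integration constants at each sampled $s$ and
the closed forms are checked against it to 1e-10, including the interface
residuals. For identical layers ($\beta = p = k_m = 1$) the flux ratio
collapses to the single-slab transform
$2/(\sqrt{s}\sinh 2\sqrt{s})$, which is asserted directly.

Two numerical details matter in evaluation:

* **Overflow.** Inversion contours visit $|s| \sim 10^6$, where
  $\sinh\sqrt{s}$ overflows. The products are rewritten via sum/difference
  identities and the dominant $e^{\sqrt{s} + \sqrt{s/p}}$ factored out, so
  only decaying exponentials are ever exponentiated.
* **The $s \to 0$ deficit.** The moment operator needs
  $G(s) = y_{ss}/s - \bar y(s)$, a difference of two $\mathcal O(1/|s|)$
  quantities. Each built-in transform therefore carries a series-evaluated
  deficit: the denominator is $s$ times an entire function of $s$ whose
  Taylor coefficients are accumulated iteratively (no factorials are ever
  formed), and the cancelling leading coefficient is subtracted exactly in
  coefficient space. Beyond the radius where 120 retained terms have
  converged the evaluator falls back to direct subtraction, which is
  well-conditioned there.

## The effective time constant

For a response $y(t)$ approaching $y_{ss}$, the first-moment relaxation
time is

$$t_{eff} = \frac{\int_0^\infty t\,(y_{ss} - y)\,dt}
                 {\int_0^\infty (y_{ss} - y)\,dt}
 = \lim_{s\to 0}\left[\frac{y_{ss}}{s^2} + \frac{d\bar y}{ds}\right]
   \Big/ \lim_{s\to 0}\left[\frac{y_{ss}}{s} - \bar y(s)\right].$$

For a first-order lag it returns the time constant exactly, which anchors
the convention that the response is ~63.2% complete at $t_{eff}$ and ~98%
complete at the *response time* $4\,t_{eff}$. Diffusion responses are not
first-order, so 63.2% is only nominal (the matrix fixture releases 63.2%
near $0.9\,t_{eff}$), but the 98%-at-$4 t_{eff}$ convention holds to
within half a percent for both bundled devices — that is the practical
design rule the package exposes.

Both limits are moments of the deficit: $G(s) = M_0 - M_1 s + \ldots$ with
$t_{eff} = M_1/M_0$. `effective_time_constant()` evaluates $G$ at points
$ih$ on the imaginary axis — complex-step differentiation, which is exact
for the analytic deficit and needs no subtraction — over a Richardson
ladder $h, h/4, \ldots$ (five levels, errors eliminated in powers of
$h^2$). The step is scaled as $h_0 = 0.5/\hat t$ from a pilot estimate so
the ladder stays inside the deficit's disc of convergence; with the series
deficit this reaches ~1e-7 worst-case relative accuracy over a
$250$-triple log-uniform sweep of $(\beta, p, k_m) \in [10^{-3},10^3]
\times [10^{-2},10^3] \times [10^{-2},10^2]$. A shrinking real-$s$
difference scheme was tried first and abandoned: forming $y_{ss}/s - F(s)$
in floating point loses eight or more digits for extreme triples and
cannot meet the package's 1e-6 identity contract.

The closed forms the operator is tested against are

$$\tau_{eff}^{res} = \frac{14\beta(p+3)(3p+1)k_m + [p(7p+30)+75]k_m^2
  + \beta^2[15p(5p+2)+7]}{60p(\beta+k_m)[\beta+(p+3)k_m+3\beta p]},$$

$$\tau_{eff}^{mat} = \frac{20\beta(5p+4)k_m + 120k_m^2
  + \beta^2[5p(5p+4)+16]}{20\beta p[6k_m+\beta(3p+2)]},$$

with $t_{eff} = \tau_{eff}\, l_b^2/D_2$. They are evaluated as written
(numerator/denominator grouping, no expansion); parameter ratios beyond
the sweep envelope above (e.g. $p > 10^6$) are outside the tested range.
Degenerate checks: $\tau_{eff}^{res}(1,1,1) = 7/15$ and
$\tau_{eff}^{mat}(1,1,1) = 361/220$ exactly.

## Numerical inverse Laplace transform

Full time profiles come from numerical inversion
(`invert_laplace()`), for which both device transforms are analytic off
the negative real axis. The default backend is the fixed-Talbot
deformation with 24 nodes and radius $r = 2M/(5\tau)$; the alternative
(`method = "euler"`) is Euler binomial summation of the Bromwich Fourier
series with $A = 23$, 65 evaluations. On transform pairs with known
inverses the backends reach ~1e-9 relative accuracy, and they agree with
each other to 1e-7 on the device transforms; the profile functions default
to Talbot (fewer evaluations, better plateau accuracy).

One honest limitation: any fixed-precision contour method carries an
*absolute* error floor near 1e-11 (roundoff amplified by $e^{rt}$), so
relative accuracy is unattainable once the true value is smaller than
that floor — e.g. $e^{-50} \approx 2\times10^{-22}$ for the decaying
exponential pair. The backend contract is therefore asserted at 1e-8
relative over the representable range and as an absolute bound beyond.
Device responses are $\mathcal O(1)$ where profiles are evaluated, so the
floor is irrelevant in practice. For $\tau < 10^{-6}$ the profile
functions clamp to zero rather than invert: the true response there is
transcendentally small while the $s^{-1/2}$-type transforms converge
slowly.

## The finite-difference oracle

`solve_pde()` is deliberately independent of everything above: it
discretises the *dimensional* equations with second-order central
differences and Crank–Nicolson time stepping. The interface is a
control-volume row spanning $[-h_1/2, h_2/2]$ whose unknown is $C_2(0,t)$,
with $C_1(0,t) = k_m C_2(0,t)$ substituted into the neighbouring
stencil — this enforces both interface conditions at once, keeps the
system tridiagonal and preserves second-order convergence (verified
against the single-slab analytic series and by grid-refinement tests).
Matrix devices start with the interface volume at its local partition
equilibrium, $w_0 = h_1 C_0/(h_1 k_m + h_2)$, so the discrete initial mass
equals the loaded dose.

Design choices that departed from the obvious defaults:

* **Time step.** A step bound of the form $D\,\Delta t/\Delta x^2 \le 2$
  is hopeless when the layer rates differ by a factor of ~200 (it would
  demand millions of steps for the metoprolol fixture). Crank–Nicolson is
  A-stable, so the package instead uses a fixed step count (default 4000
  over a window of $12\,t_{eff}$) and damps the startup oscillation of the
  stiff fast-layer modes with a Rannacher start: the first four steps are
  pairs of backward-Euler half-steps, which annihilate the
  $|\lambda \Delta t| \gg 1$ modes that trapezoidal stepping would carry
  at amplitude $\approx -1$.
* **Cumulative release by mass balance.** For matrix devices the released
  amount is computed as (initial mass − mass in the layers), which is
  conserved exactly by the scheme, rather than by integrating the
  boundary flux: the trapezoid-of-flux route leaves a $\mathcal O(10^{-3})$
  constant offset in $1 - M_t/M_\infty$ that makes its first moment
  diverge linearly in the window length. The flux-integral cumulative is
  still what `flux_profile(..., method = "pde")` reports for reservoirs,
  where the donor feeds mass in and balance is unbounded.
* **Row equilibration.** The interface row's mass coefficient
  $(h_1 k_m + h_2)/2$ can sit many orders below the bulk rows; rows are
  rescaled to unit maximum before factorisation.
* **Windowing.** Moment and profile windows are sized at
  $12$–$14\,t_{eff}$ using the closed-form time constant — a windowing
  convenience only; the solution itself never uses the Laplace machinery.
  The truncated tail contributes $\lesssim 10^{-4}$ to the first moment at
  $14\,t_{eff}$.

With defaults (`n1 = n2 = 120`, 4000 steps) a fixture solve takes a
fraction of a second; the three-way identity sweep in the acceptance
tests uses 100 nodes per layer and 3000 steps per triple, which keeps the
whole suite near twenty seconds while holding the discrete first moment
within 0.5% of the closed form (measured worst case ≈ 2e-4 for matrix,
2e-4 for reservoir over the sweep envelope).

## Fixtures and reproduction targets

Two literature parameter sets ship as named fixtures and define the
package's reproduction suite (`validate_reproduction()`):

* `metoprolol_tdds1` (reservoir): $\beta = 1.58\times10^{-3}$, $p = 200.6$,
  $t_{eff} = 2.148$ h, response time $8.59$ h, $j_{ss} = 79.1$
  µg/cm²/h, flux at 8.60 h $= 77.5$ µg/cm²/h.
* `ata_tdds2` (matrix): $t_{eff} = 113.7$ h, 98% released at $\approx
  455$ h, fraction at 461.4 h $= 98.1\%$.

Two source-data notes, recorded rather than resolved. The ATA study also
quotes "$\beta = 3.81$, $p = 0.41$" alongside its four printed transport
parameters; those parameters give $\beta = 0.0212$, $p = 0.4208$ under the
definitions above, and only these values are consistent with the quoted
115.3 h time constant, so the package treats the printed 3.81 as a
typographical erratum. Its quoted released amount of 49,000 µg implies an
application area near 1.79 cm² (a typical Franz-cell orifice); the fixture
leaves `A = 1` and per-area outputs. Similarly the metoprolol donor
concentration appears both as 0.036 and 0.038 g/cm³ in the sources; the
fixture uses 0.038, the value consistent with the 79.2 µg/cm²/h steady
flux. Reproduction tolerances are 1% for the reservoir quantities and 2%
for the ATA time constants (the printed parameter estimates are rounded
to 2–3 significant figures, which alone moves $t_{eff}$ by over 1%).

## What the synthetic sweeps do and do not show

The property sweeps draw $(\beta, p, k_m)$ log-uniformly over the envelope
above and realise each triple as a device with $l_b = D_2 = 1$ — exercising
the solvers across six orders of magnitude of layer asymmetry. Passing
them shows the three computational routes agree *with each other* under
the stated model; it says nothing about whether the model describes a
given formulation (constant diffusivities, ideal sink and no metabolism
are assumptions, not conclusions), and parameter values must come from
independent estimation, which is out of scope here.

## Known limitations

Planar one-dimensional geometry only; no donor depletion, binding,
metabolism, or repeated-application schedules; elasticities use the
closed forms (switch to `method = "operator"` in `time_constants()` to
cross-check); position-dependent time constants are not computed (for
these flux/fraction responses $t_{eff}$ is position-independent).
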