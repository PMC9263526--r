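---
title: "Methods: finite-bath diffusion analysis for granular biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-bath diffusion analysis for granular biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulediff)
```

## The physical model and its assumptions

`granulediff` analyses *transient uptake of a non-reactive solute*
experiments: a population of granules in a stirred vessel, a tracer dosed
into the liquid, and the bulk concentration sampled over time. The forward
model assumes:

* granules are identical spheres of the measured mean radius $R$
  (the real size distribution and modest non-sphericity enter only through
  the Monte-Carlo uncertainty analysis, not the forward model);
* granules are initially solute-free, and the whole granule volume is
  accessible with a 1:1 partition between bulk liquid and granule water
  (no partition coefficient — the model has no such term, and adding one
  would be unidentifiable from a single uptake curve);
* the bath is well mixed and *finite*: as the spheres load, the bulk
  concentration falls, giving the equilibrium ratio
  $C_{eq}/C_0 = \alpha/(1+\alpha)$ with $\alpha = V_W/V_G$;
* no external boundary-layer resistance and no consumption of the solute.

Under these assumptions the bulk ratio is the eigenfunction series evaluated
by `bulk_concentration_ratio()`, with eigenvalues $q_n$ solving
$\tan q_n = 3q_n/(3+\alpha q_n^2)$.

When the measured plateau lies *above* $\alpha/(1+\alpha)$ the full-access
assumption fails (size exclusion); the accessible volume fraction then
follows from the closed equilibrium mass balance in `accessible_fraction()`,
and no diffusivity is reported — with part of the volume excluded at an
unknown geometry, the uptake curve no longer identifies $D_e$ cleanly.

**Decision rule for the restricted-access path.** `run_fit()` estimates the
plateau from the last fifth of the samples (at least 3) and switches to the
accessibility analysis when the plateau exceeds $\alpha/(1+\alpha)$ by more
than 10 % of the expected total drop $C_0 - C_{eq}$. At the default 2 %
concentration CV this threshold is roughly three standard deviations of the
plateau estimate, so full-access experiments essentially never trip it,
while a 65 %-accessible solute at $\alpha = 4$ exceeds it by a factor of
three.

## Eigenvalue computation

Exactly one root of the eigenvalue equation lies in each interval
$(n\pi,\, n\pi + \pi/2)$: $\tan q$ rises from 0 to $+\infty$ across it
while the right-hand side is positive, bounded and decreasing. We solve by
bisection — derivative-free and guaranteed — vectorised across all brackets,
to an interval of about $10^{-14}$ relative. Residuals are verified against
$10^{-12}$; for very high-order roots ($q_n \gtrsim 10^3$) one ulp of the
argument already moves $\tan q$ by more than that, so the check is floored
at a few ulps of $q_n$. The series coefficients
$6\alpha(1+\alpha)/(9+9\alpha+q_n^2\alpha^2)$ sum to 1 (the $t=0$ identity),
converging as $1/n^2$.

## Series evaluation

Both series are truncated when a term's magnitude falls below
`series_tol` ($10^{-10}$ by default, judged at the smallest positive time
requested), with caps of 200 terms (uptake series) and 500 terms
(core-penetration series). At $t = 0$ both series converge too slowly to
evaluate naively, so the exact values (1 and 0) are returned analytically.
The core series is alternating, so its truncation error is bounded by the
first omitted term; a warning reports that bound when the cap is reached
with an unresolved tail (which happens only for dimensionless times
$D t/R^2 \lesssim 10^{-4}$). Tiny negative round-off in the core series is
clamped to 0, and the uptake ratio is clamped to
$[\alpha/(1+\alpha),\, 1]$.

## Estimating the diffusivity

`fit_diffusion()` minimises the unweighted residual sum of squares on the
concentration *ratio* $C_B(t)/C_0$, so concentration units cancel and the
estimate is invariant to rescaling the dosed mass and signal together.
$C_0$ is computed from the weighed solute mass and the liquid volume, never
from the first samples (uptake starts before the vessel is homogeneous).

The objective is one-dimensional in $D_e$, optimised on the $\log_{10}$
scale. Each of `n_starts` (default 500) starting values — drawn
log-uniformly over the default bounds $(10^{-13},\, 2\times10^{-9})$
m²/s, four decades that bracket every plausible biofilm diffusivity — seeds
a derivative-free Brent search on a two-decade bracket around the start,
expanded downhill whenever the minimiser lands on an interior bracket edge.
We chose Brent over quasi-Newton deliberately: near machine-precision
optima (noiseless data) the numerical gradient is pure round-off and
L-BFGS-type line searches abort. Log-uniform (rather than uniform) start
draws cover the four decades sensibly; with a unimodal 1-D objective far
fewer than 500 starts are needed, but the default is kept for fidelity to
the multi-start protocol. If fewer than half of the converged starts end
within 1 % of the best objective, the fit refuses to report a point
estimate and raises a multimodality diagnostic instead. An optimum at a
search bound (e.g. a flat, uptake-free series pinned at the lower bound)
triggers a misspecification warning.

**Sampling replacement.** The bench protocol replaces each withdrawn sample
with solution at the expected final concentration. The fitting model treats
this as non-perturbing, exactly as the analytical model assumes; the
synthetic generator can simulate the actual perturbation
(`replacement_mode = "expected_final"`), and the paired test shows the
resulting bias in $\hat D$ is well below the Monte-Carlo standard
deviation for the canonical design (25 × 0.5 mL from 300 mL).

## Monte-Carlo uncertainty

`monte_carlo_sd()` implements perturb-and-refit: each of `n_sims` (default
1000) simulations draws independent Gaussian relative errors on the granule
radius, the granule volume (with $\alpha$ and $C_0$ recomputed from the
fixed total volume) and every concentration, then refits $D$ by a single
bounded search started from the unperturbed optimum. The sample standard
deviation of the refitted values is the reported uncertainty. The default
CVs — radius 5 %, granule volume 10 %, concentration 2 % — are plausible
bench magnitudes, *not* validated calibrations; they are exposed as
arguments and should be overridden with instrument-specific values. With
these defaults the canonical design yields relative standard deviations of
roughly 25–35 %.

## Precision is design-limited

Two facts look contradictory at first sight: noiseless curves are recovered
to better than $10^{-6}$ relative, yet 2 % measurement noise produces
$\sim$10 % scatter in $\hat D$. The resolution is the experiment design: at
$\alpha = 4$ the entire signal is a 20 % concentration drop, and 2 %
multiplicative noise is a tenth of that. The Cramér–Rao bound for $\ln D$
under the default 25-point geometric schedule — computed in the test suite
from the model sensitivity $\partial r/\partial \ln D$ — is 12–14 % across
three decades of $D$, implying a best-case median relative error of
8–10 %. The fitted estimator sits essentially on that floor. Any tighter
claim for this design is not achievable by any estimator; substantially
better precision requires a smaller $\alpha$ (bigger drop), lower noise, or
replication.

## Temperature conversion and water viscosity

Diffusivities convert between temperatures by the Stokes–Einstein
proportionality $D\mu/T = \text{const}$, which round-trips exactly. The
water viscosity comes from the Kestin-type 0–40 °C correlation anchored at
$\mu(20\,°C) = 1.002$ mPa·s; we chose it over the simpler Vogel form
because it reproduces the standard tabulated values (1.5673, 1.3059,
1.0016, 0.8900 mPa·s at 4, 10, 20, 25 °C) to better than 0.1 %, whereas a
Vogel fit is off by >1 % at 4 °C — exactly the temperature uptake
experiments are run at to suppress biological activity. Measured
viscosities can be passed explicitly to override the correlation.

## Molecular-weight scaling and regression comparison

`fit_loglog()` is ordinary least squares of $\log_{10} D$ on
$\log_{10} MW$ — base 10 throughout, one point per solute size by default.
`compare_fits()` compares two laws coefficient-by-coefficient with
$t = |a_1-a_2| / \sqrt{SE_1^2+SE_2^2}$ on $n_1+n_2-4$ degrees of freedom
(two slopes and two intercepts estimated). The printed standard errors are
used directly, with no pooled residual variance, because the reference
law's raw data are typically literature values unavailable for pooling.
With 11 sizes per law this gives 18 degrees of freedom. Weighted regression
using per-point Monte-Carlo SDs is deliberately not offered: the weights
would be estimated from the same data and the unweighted fit is the
convention this comparison is defined for.

## Core penetration and COD fractionation

`assess_penetration()` chains law → temperature conversion → core series:
$D$ at the law's temperature, converted to the assessment temperature,
then $C/C_b$ after the contact time from the infinite-bath centre series.
The infinite-bath boundary is appropriate because during a feeding phase
the bulk is continuously replenished. Defaults (10 °C, 1 mm radius, 60 min)
describe a typical anaerobic feed of a granular-sludge reactor.

COD bookkeeping conventions in `summarize_fractions()`:

* *denominators are measured values* — shares of soluble COD divide by the
  measured < 0.45 µm concentration, never by the sum of the
  ultrafiltration classes. Serial fractionation does not always close, so
  the class sum is a different (and noisier) quantity;
* the closure residual (class sum minus measured soluble COD) is reported
  per plant and warned about above 2 mg/L — never failed on, since
  non-closure is a data property, not a user error. Of the three shipped
  influents, one (Harnaschpolder) does not close (+13 mg/L);
* particulate COD is total minus soluble (no separate measurement exists);
* cross-plant ranges round half-up to whole percent before taking min/max,
  the form such ranges are quoted in.

The VFA share of soluble COD computed from the shipped table spans
15–18 %; it is reported but carries no range assertion in the tests.

## The synthetic-data generator

`synthetic_spec()` defaults emulate the canonical bench design: 25 samples
of 0.5 mL from a 300 mL working volume, $\alpha = 4$, 4 °C, initial
concentration 1000 mg/L, geometric (dense-early) sampling over
30 s – 6 h. Choices the design leaves open were fixed once:

* *noise model*: multiplicative Gaussian with 2 % CV — refractive-index
  detection has roughly constant relative error;
* *schedule*: geometric, because the curve is steepest early and sampling
  "at irregular intervals" to capture the non-linearity is the stated
  practice; the real time points of any given lab run are not replicated;
* *restricted access*: a spec with `f_accessible < 1` generates the curve
  with effective ratio $\alpha/f$, which is exactly the finite-bath
  solution when a fraction $1-f$ of the granule volume is inert;
* *replacement*: optionally simulated by piecewise integration of the
  finite-volume oracle with the bulk state adjusted at each sampling
  instant.

Not modelled, hence not validated by passing tests: PEG polydispersity
(solutes are monodisperse), granule size distributions and aspect ratio,
external mass-transfer films, biological consumption, and any real
detector's drift. Tests on synthetic data demonstrate the *estimation
machinery* is correct and calibrated for the stated noise model; they
cannot certify accuracy on real granules beyond those assumptions.

The accessibility fixture uses a 0.2 % CV and a 24 h horizon: ±0.01 on
$f$ corresponds to ±0.2 % on $C_{eq}/C_0$
($\partial f/\partial x = -\alpha/x^2 \approx -5.4$ at $\alpha = 4$), so a
sharp check of the inversion chain needs a plateau known to that
precision, and a 10 kDa-like solute ($D \sim 5\times10^{-11}$ m²/s) needs
about ten time constants to plateau cleanly.

## The numerical oracle

`simulate_uptake_numeric()` is the independent check on the analytical
series: a conservative finite-volume discretisation of the spherical
diffusion equation, coupled to the finite bath through the outer-face flux
(the same flux leaves the bath and enters the outer shell, so mass is
conserved to solver tolerance — verified at $10^{-6}$ relative), integrated
with `deSolve`'s lsoda at $10^{-10}$ tolerances. The centre concentration
is obtained by parabolic extrapolation from the two innermost cells
(symmetry makes the profile locally parabolic). At 200 radial cells the
bulk trace agrees with the analytical series to better than $10^{-4}$
relative, and the centre trace (with a huge $\alpha$ emulating an infinite
bath) agrees with the core-penetration series to the same level. The
oracle is used in tests and for simulating the sampling-replacement
perturbation; it is never the production path.

## Problem sizes used by the test suite

Chosen as the smallest sizes that still separate signal from tolerance:
oracle cross-checks at 200 radial cells over 4–5 time points and 5
parameter sets; recovery studies over 50 seeded replicates with 8 starts
each (the 1-D objective is unimodal, so 8 starts locate the global optimum
reliably; the 500-start default is kept for protocol fidelity in
production use); Monte-Carlo checks at 20–300 simulations with the
1000-simulation default exercised through the workbench. The end-to-end
study regenerates 11 solute sizes spanning 62 Da – 10 kDa and recovers the
generating power law within two standard errors.

## Known limitations

* One fitted parameter per experiment: simultaneous multi-experiment or
  joint $(D, f)$ fitting is out of scope; a partially excluded solute
  yields $f$ only.
* The identical-spheres assumption biases $D_e$ slightly for aspherical
  granules; the forward model does not correct for it.
* Default Monte-Carlo CVs are unvalidated placeholders.
* The restricted-access generator uses the effective-$\alpha$
  approximation, exact for an inert excluded volume but not for a
  radially varying exclusion profile.
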