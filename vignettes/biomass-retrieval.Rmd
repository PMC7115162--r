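---
title: "Corn biomass retrieval from dual-polarized SAR with an optical transfer function"
author: "wcmbiomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corn biomass retrieval from dual-polarized SAR with an optical transfer function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcmbiomass)
```

## The problem

Optical satellites estimate crop biomass well but are blocked by cloud;
radar (SAR) sees through cloud but its biomass estimates sit on a different
scale. This package implements a three-part retrieval chain for corn that
makes the two sources interchangeable:

1. a semi-empirical **Water Cloud Model (WCM)** calibrated on dual-polarized
   (HH and HV) C-band backscatter, then inverted point-by-point for
   above-ground biomass and volumetric soil moisture simultaneously;
2. four empirical **vegetation-index regressions** (NDVI, RTVI, SR, SRre)
   giving biomass from optical reflectance;
3. a small **feed-forward transfer network** that maps the SAR-side biomass
   estimates onto the optical-estimate scale.

All computation operates on point-observation tables: one row per sampled
location with ground measurements (dry/wet biomass in kg m⁻², volumetric
soil moisture in m³ m⁻³) and satellite observations (HH/HV backscatter in
linear power units, incidence angle in degrees, NDVI). The packaged table
`corn_observations()` holds the 66 corn points the method was developed on;
its first 23 rows are calibration points and the remaining 43 validation
points.

## The Water Cloud Model

The canopy is modelled as a uniform cloud of water droplets above the soil:

$$\sigma^0 \;=\; A\,L^{E_1}\cos\theta\,\bigl(1 - e^{-2BL^{E_2}/\cos\theta}\bigr)
 \;+\; (C\,M_v + D)\,e^{-2BL^{E_2}/\cos\theta}$$

with biomass $L$, soil moisture $M_v$, incidence angle $\theta$, and six
coefficients per polarization. The first term is canopy volume scattering;
the second is the soil contribution attenuated by the two-way canopy
transmissivity $\tau^2 = e^{-2BL^{E_2}/\cos\theta}$. Both exponentials
divide by $\cos\theta$: the attenuation is a path-length effect, so the
slant path through the canopy scales as $1/\cos\theta$ in each term — this
is the canonical form of the model, and the package uses it consistently.
Angles are stored in degrees, as observation tables report them, and
converted to radians internally.

Either wet or dry biomass can play the role of $L$; both columns exist in
observation tables and which one enters the model is a configuration choice
(`biomass_kind`, default `"wet"`). The same choice must be used for the HH
and HV calibrations that are later inverted together.

### Calibration

`calibrate_wcm()` estimates the six coefficients per polarization by
nonlinear least squares over the calibration rows, using a damped
(Levenberg–Marquardt) iteration written for exactly the stopping semantics
the procedure prescribes: initial coefficients drawn uniformly on (0, 1),
iteration ending when the absolute SSE improvement falls below `tol`
(default $10^{-8}$) or after `max_iter` (default 100) iterations. The
literal reading "stop when the SSE reaches $10^{-8}$" cannot hold for noisy
field data, so the tolerance is applied to the *decrease* of the SSE — the
behaviour of the standard nonlinear-regression routines this mirrors.

A single random start can land in a local minimum, so by default 20
independent starts are run and the best SSE kept (`n_restarts`); every
restart's initial SSE, final SSE, iteration count and exit reason are
returned in the fit's `restarts` tibble, and identical seeds give
bit-identical fits.

One numerical property of this model matters for interpreting "the best
SSE": in the optically thin limit ($BL^{E_2}/\cos\theta \to 0$) the canopy
term degenerates to $2AB\,L^{E_1+E_2}$, so only products of coefficients are
identified and the least-squares surface contains valleys along which the
SSE keeps decreasing as parameters diverge (e.g. $A \to \infty$, $B \to 0$).
On such a valley the infimum is not attained and the "best SSE after $k$
iterations" is a property of the budget, not of the problem. Attained local
minima do exist (restarts that exit by the SSE-decrease rule rather than the
iteration cap), and at those points this implementation agrees with an
independent optimizer (`minpack.lm::nls.lm`) to well below $10^{-10}$ in
SSE; the test suite asserts optimizer equivalence there, and as a plain
multi-start comparison on noise-free synthetic data, where the global
minimum (SSE 0) is attained. Budget-limited fits are reported honestly with
`converged = FALSE`.

### Inversion

With both polarizations calibrated, each observation point yields two
equations in two unknowns. `invert_wcm()` solves
$\{\sigma^0_{HH}(L, M_v) = s_{HH},\; \sigma^0_{HV}(L, M_v) = s_{HV}\}$ by
Levenberg–Marquardt from the fixed starting point
$(L, M_v) = (1\ \mathrm{kg\,m^{-2}},\ 0.2\ \mathrm{m^3\,m^{-3}})$, stopping
when the step between iterates drops below `tol` (default $10^{-6}$) or at
400 iterations. Solutions are reported raw — not clamped to physical ranges
(the only absolute value in the whole chain is applied later, by the
transfer network). A point is flagged `converged` only when the step
criterion fired *and* the final residual norm is at most `tol`: a solver can
stall at a least-squares minimum of an inconsistent system, and that is not
a retrieval. Non-convergence is a flag, never an error.

## Vegetation-index models

Four two-coefficient forms are supported, one per index:
$a\,e^{\mathrm{NDVI}}+b$, $a\,\mathrm{RTVI}+b$, $a\ln(\mathrm{SR})+b$ and
$a\,\mathrm{SRre}+b$, each fitted separately for wet and dry biomass (eight
independent models). They are fitted with the same iterative scheme and
stopping rules as the WCM — and because every form is linear in $(a, b)$
after transforming the index, the closed-form least-squares solution exists
and the iterative fit must agree with it; the test suite asserts agreement
to $10^{-8}$ on all four forms rather than assuming it.

The source imagery supplied NDVI precomputed, so the calibration path takes
index values directly from the observation table. For users starting from
reflectance, `compute_index()` provides literature-standard band
combinations (NDVI, SR, SRre, RTVI with red-edge) with a configurable band
mapping, since red-edge index variants differ between sensors.

## The transfer network

`train_transfer()` fits a 1–10–1 feed-forward network (one hidden layer of
10 tanh units, linear output — the standard "two-layer" fitting network) by
Levenberg–Marquardt on the squared error, with identity damping
$J^\top J + \lambda I$ so the step stays defined when parameters (31)
outnumber training residuals (17). Inputs and outputs are min-max
normalized to $[-1, 1]$ and the scalings stored in the network, so a saved
network is self-contained. Of $n$ pairs, $\lceil 0.7\,n\rceil$ are used for
training — 17 of 23 under the study's convention — and the remainder is held
out purely for reporting (`holdout_mse`, on the normalized scale); there is
no early stopping. Weight initialization is seeded uniform on $(-1, 1)$;
the same seed reproduces weights bit-identically. Application is
normalize → forward pass → denormalize → **absolute value**, so adjusted
estimates are always non-negative; because tanh saturates, outputs for
inputs far outside the training range approach a finite asymptote bounded
by the output weights and scalings.

A caution the package reports rather than hides: 31 weights interpolating
17 noisy pairs can oscillate between training points, and the holdout MSE
on real calibration pairs is correspondingly large. The holdout numbers
exist precisely to make that visible.

## Synthetic observation tables

`simulate_observations()` generates tables with the statistical structure
the method assumes, so parameter recovery can be tested at any size and
noise level without real data. Defaults are the study's calibration
conditions: 23 points; wet biomass uniform on 0.04–7.1 kg m⁻²; soil
moisture uniform on 0.039–0.379 m³ m⁻³; incidence angle uniform on
21.025–31.9592°. Backscatter comes from the WCM forward model times
unit-mean multiplicative lognormal noise with configurable coefficient of
variation (default 0.05) — multiplicative because radar speckle is, and
because it keeps power strictly positive as the data invariants require.
NDVI is obtained by inverting a configurable vegetation-index model at the
drawn biomass plus small additive noise (sd 0.005), clipped to $[-1, 1]$;
dry biomass is a fixed ratio of wet (0.15, within the range the corn table
exhibits).

The generating coefficients default to values chosen for two properties,
fixed at design time: (i) they reproduce the magnitudes of the observed
channels (HH ≈ 0.07–0.6, HV ≈ 0.004–0.03 in power), and (ii) the HV channel
is canopy-dominated (small soil terms, $C = 0.01$, $D = 0.003$), matching
the physics of cross-polarized scattering and making the two-channel system
identifiable: $\sigma^0_{HV}$ pins $L$, then $\sigma^0_{HH}$ pins $M_v$.
Identifiability was verified by multi-start root scanning over the sampled
box (no point with a second root). A generator whose two channels are
near-copies of each other produces systems with genuine multiple roots —
the dual-polarization retrieval's core assumption would be violated by
construction, which is a property of a badly chosen simulation, not of the
method.

Coefficient recovery is asserted on *predictions*, not raw coefficients:
the degeneracy discussed above means different coefficient vectors can
represent the same backscatter surface, so prediction-space recovery is the
testable contract.

What the generator deliberately does not emulate: spatial correlation
between points, growth-stage time series, incidence-angle/biomass
correlation from orbit geometry, and non-lognormal speckle statistics from
multi-looking. Passing recovery tests on synthetic data therefore shows the
estimator chain is correct, not that real retrievals reach any particular
accuracy.

## Problem sizes and numerical choices in the tests

The test suite and the acceptance script run the study-sized problems
directly: 23-point calibrations with 20 random restarts, inversion of all
66 points, 17/6 network training. The noise-monotonicity property uses 10
seeds × 3 noise levels with 3 restarts each, and the end-to-end synthetic
recovery uses a 66-point table split 23/43 — sizes chosen to mirror the
study's own.

Other numerical choices, collected: Jacobians are central finite
differences with one-sided fallback at domain boundaries (biomass cannot go
negative inside a fractional power); the damping factor starts at $10^{-3}$,
divides by 10 on accepted steps and multiplies by 10 on rejected ones, with
a trial step rejected if any residual is non-finite; WCM calibration damps
with the Marquardt $\mathrm{diag}(J^\top J)$ scaling, network training with
the identity; a calibration that can no longer find any improving damped
step is treated as converged under the SSE-decrease rule (nothing smaller
than machine precision remains), while a stalled root-finder is flagged
non-converged.

## Known limitations

* The WCM coefficient vector is not identifiable from backscatter alone in
  the thin-canopy regime; compare fits by predictions or SSE, not by
  individual coefficients.
* Retrieval quality degrades where the canopy saturates the signal (large
  $L$): the soil term is attenuated to near zero and soil moisture becomes
  weakly constrained.
* The transfer network is a scale adjustment, not a physical model; it is
  only meaningful within the biomass range it was trained on, and its
  saturation outside that range is intentional.
* The package operates on extracted point values only; image processing
  (speckle filtering, geocoding, atmospheric correction) is upstream and out
  of scope.
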