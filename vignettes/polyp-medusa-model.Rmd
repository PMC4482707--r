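---
title: "A two-stage life-history model for scyphozoan population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage life-history model for scyphozoan population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scyphodyn)
```

## The model and its assumptions

Scyphozoan jellyfish alternate between a benthic polyp that multiplies
clonally and strobilates, and a pelagic medusa that reproduces
sexually through planula larvae. `scyphodyn` tracks only abundance in
the two main stages, `P(t)` polyps and `M(t)` medusae, in days:

$$\frac{dP}{dt} = \alpha(T) P + s_1 \gamma M - d_1 P - d_2 P - b_1 P^2,
\qquad
\frac{dM}{dt} = s_2 \beta(T) n P - d_3 M - d_4 M - b_2 M^2.$$

The assumptions baked into this form: planulae and ephyrae are not
tracked separately, only their survival fractions ($s_1$, $s_2$)
matter; resources are not limiting except through the intraspecific
competition terms $b_1 P^2$ (substrate space) and $b_2 M^2$; predation
acts as a constant per-capita rate $d_4$ rather than a dynamic trophic
variable; parameters are constant in time (no seasonality), with
temperature entering only through the fitted response curves
$\alpha(T)$ and $\beta(T)$; and abundances are abstract individual
counts — the model itself fixes no spatial reference area, so we treat
$P$ and $M$ as counts, the only internally consistent reading when
mixing literature-derived rates.

Substituting $a = \alpha - d_1 - d_2$, $b = s_1\gamma$,
$c = s_2\beta n$, $d = d_3 + d_4$ collapses the twelve biological
rates to the planar system

$$\frac{dP}{dt} = aP + bM - b_1 P^2, \qquad
\frac{dM}{dt} = cP - dM - b_2 M^2,$$

implemented by `reduce_params()` and `vector_field()`.

## Global dynamics

The box $\Omega = (0, l) \times (0, cl/d)$ with
$l = (|a|d + bc)/(b_1 d)$ is positively invariant
(`invariant_region()`), and a Dulac-type argument rules out periodic
orbits inside it, so every trajectory settles at an equilibrium. The
sign of the discriminant $ad + bc$ decides which one
(`classify_regime()`):

* $ad + bc < 0$: extinction $E_0 = (0,0)$ is globally asymptotically
  stable.
* $ad + bc = 0$: a degenerate saddle-node threshold. The package
  reports no attractor designation here rather than attempting a
  center-manifold analysis; the regime is measure-zero and only
  reachable by construction, so the equality tolerance defaults to
  $10^{-12}$ absolute.
* $ad + bc > 0$, $c = 0$: the polyp-only state $E_1 = (a/b_1, 0)$ is
  globally stable. $E_1$ is returned only when $a > 0$ strictly — at
  $a = 0$ it collapses into $E_0$, and the regime condition
  $ad + bc > 0$ with $c = 0$ already forces $a > 0$.
* $ad + bc > 0$, $c \neq 0$: a unique coexistence state
  $E^* = (P^*, M^*)$ is globally stable, with a heteroclinic orbit
  running from $E_0$ to $E^*$ (`heteroclinic_check()` verifies this
  numerically by seeding the unstable eigenvector of the origin).

`find_equilibria()` locates $E^*$ by eliminating $M$ through the
medusa nullcline
$M(P) = \bigl(-d + \sqrt{d^2 + 4 b_2 c P}\bigr)/(2 b_2)$ and
root-finding the polyp-nullcline residual
$g(P) = aP + bM(P) - b_1 P^2$ on $(0, l)$ with Brent's method. The
bracket $g(\varepsilon) > 0$, $g(\text{upper}) < 0$ with
$\varepsilon = 10^{-12} l$ is asserted before solving; when $b = 0$
the root coincides with $l$ itself, so the upper end is widened by
successive factors of $(1 + 2^k \cdot 10^{-12})$ until the residual is
strictly negative. With $b = 0$ the result reproduces the closed form
$P^* = a/b_1$,
$M^* = \bigl(-b_1 d + \sqrt{b_1^2 d^2 + 4 a c b_1 b_2}\bigr) /
(2 b_1 b_2)$ to near machine precision, which the test suite asserts
at $10^{-9}$ relative.

Eigenvalues of the Jacobian
$J = \begin{pmatrix} a - 2b_1 P & b \\ c & -d - 2b_2 M \end{pmatrix}$
are computed from the 2×2 characteristic polynomial rather than a
general solver — exact for the cases of interest, and it makes the
saddle/node decision transparent. Because both off-diagonal entries
are nonnegative, the discriminant of that polynomial is nonnegative
and all eigenvalues are real: the system admits no spirals, which is
why the convergence tests can demand an eventually monotone distance
to the attractor.

## Numerical choices

* Integration (`simulate_dynamics()`) uses `deSolve::lsoda`, adaptive
  and stiff-capable. The model is non-stiff at the default parameter
  scales, but $b_1$ and $b_2$ ranging over four orders of magnitude
  warrants adaptivity. Defaults: relative tolerance $10^{-8}$,
  absolute $10^{-10}$.
* States are clamped at zero on output; an interior negative excursion
  beyond $10 \times$ the absolute tolerance is treated as solver
  failure, since the model is biologically defined only on the
  nonnegative quadrant.
* Steady-state detection uses the relative criterion
  $\|F\|_\infty < 10^{-6}\,(1 + \|\text{state}\|_\infty)$, which works
  unchanged for equilibria of order $10^2$ and $10^4$.
* Degenerate inputs: `a = 0` with `c = 0` yields only $E_0$; sweeps
  flag grid values that violate a parameter invariant (for instance
  $b_1 \le 0$) and continue.

## Temperature responses

Two fitted families describe the thermal dependence of the vital
rates on the window 7–22 °C (salinity is considered fixed):

* `strobilation_response()` — a Gaussian thermal-performance curve
  $\beta(T) = 0.1430\, \exp\{-((T - 16.8108)/10.5302)^2\}$, ephyrae
  per polyp per day, peaking at 16.8 °C.
* `budding_response_printed()` — a cubic-plus-offset
  $\alpha(T) = 1.9272 T^3 - 30.3904 T^2 + 294.7234 T - 871.29 +
  0.0378$, provided verbatim. As printed it evaluates to order $10^3$
  and is monotone on the window (we verified both numerically), which
  is inconsistent with the biological budding range of 0.03–0.15 per
  day and with a mid-range polyp optimum; whether the coefficients
  carry an unprinted scale factor cannot be determined. It is
  therefore shipped for transparency only.
* `budding_response_synthetic()` — the default for temperature
  sweeps: a cubic fitted to `synthetic_budding_data()`, a synthetic
  dataset constructed once to lie in 0.03–0.15 per day with a peak
  near 12.5 °C. It is labelled synthetic throughout; no published
  quantity is computed from it.

`fit_response()` fits the Gaussian family by Levenberg–Marquardt
nonlinear least squares (`minpack.lm::nlsLM`) with moment-based
starting values (amplitude = max rate, center = argmax, width = half
the temperature range), and the cubic family by linear least squares
on the monomial basis, absorbing the additive offset into the fitted
intercept — the two are not separately identifiable from data.

`growth_stairs()` uses the per-degree relative change
$100\,(g(T{+}1) - g(T))/g(T)$, in percent. This definition reproduces
the published cold-end increments of 18.3% (7→8 °C) and 16.2%
(8→9 °C) exactly at one decimal. Averaging these stairs over 7–15 °C
gives 11.1%, not the published mean of 12.1%; the averaging convention
behind that figure is unknown, so the mean is excluded from the checks
here. Likewise the published SSE values of the original fits are
reported by `fit_response()` for the user's data but never asserted:
the underlying digitized observations are not available, and the
fixtures substitute for them structurally, not numerically.

## The synthetic-data generators

`make_rate_dataset()` emulates per-day-standardized laboratory rate
measurements: a smooth response evaluated on a temperature grid plus
additive Gaussian noise, clamped at zero because rates are
nonnegative (near-zero rates may clamp). `make_observed_trajectory()`
emulates abundance time series with multiplicative lognormal noise,
which respects positivity. Defaults follow the study conditions:
integer-degree grids on 7–22 °C, observation noise SD 0.005 per day
(about 3% of the strobilation peak — a realistic bench-scale error),
the invasion initial condition $(P, M) = (0, 2)$. One integer seed
drives a private random stream per fixture; the caller's RNG state is
untouched and identical specs give bit-identical output.

What the fixtures do not emulate: replicate structure, salinity
treatments, temperature-dependent noise, or observation error in the
temperatures themselves. Passing the recovery tests therefore shows
the estimators are correct and stable under idealized noise, not that
they are robust to every feature of real laboratory data.

## Problem sizes used in the tests

The suite verifies the oracle equivalence of the coexistence root on
200 random parameter draws against a dense-grid nullcline scan
(4000-point grid, four zoom levels), positive invariance on 100 draws,
basin convergence from 50 random starts per regime over a 5000-day
horizon, no-cycle convergence on 20 draws over 8000 days, and
Gaussian-refit recovery on 100 seeds at noise SD 0.005 (at least 95
must recover the peak within ±0.5 °C). These sizes give stable
verdicts at interactive runtimes.

## Known limitations

Somatic growth, morphology, seasonal forcing, spatial structure, and
stochastic demography are out of scope, as is any salinity dependence.
Predation is a constant per-capita rate, not a dynamic predator
population. The absence of periodic orbits is verified numerically
(eventually monotone distance to the attractor), not symbolically.
The saddle-node threshold regime is classified but its center-manifold
dynamics are not analysed. All abundances are dimensionless counts;
users mapping them to densities must supply their own reference area.
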