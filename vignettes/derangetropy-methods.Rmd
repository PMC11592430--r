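---
title: "Methods: the derangetropy transform and its numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the derangetropy transform and its numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derangetropy)
```

## The transform

For an absolutely continuous density $f$ with CDF $F$, the derangetropy
functional is

$$\rho[f](x) \;=\; \frac{24}{\pi e}\,\sin(\pi F(x))\,
F(x)^{F(x)}\,(1-F(x))^{1-F(x)}\,f(x).$$

The self-weighting term $F^F(1-F)^{1-F}$ equals $e^{-H_B(F)}$, where
$H_B$ is the Bernoulli entropy in nats of the left/right mass split at
$x$; the sine factor modulates that entropy profile periodically in the
probability level. Substituting $z = F(x)$ shows
$\int \rho[f]\,dx = \tfrac{24}{\pi e}\int_0^1 \sin(\pi z)\,z^z(1-z)^{1-z}\,dz = 1$,
so the transform of a density is again a density. A third, equivalent
expression replaces $\sin(\pi F)$ by $\pi/(\Gamma(F)\Gamma(1-F))$ through
Euler's reflection formula; the continuous factorials connect the
construction to derangements, the maximally disordered permutations.

Three conventions fix the behaviour at the boundary of the support:
$0^0 = 1$, $H_B(0) = H_B(1) = 0$, and $\rho \equiv 0$ wherever
$F \in \{0, 1\}$ (the reflection-formula form requires
$F \notin \mathbb{Z}$, so the Gamma form adopts the same limit). All
logarithms are natural: the normalising constant
$C = \log\frac{24}{\pi e}$ and $H_B$ are unit-consistent only in nats.

One typographic ambiguity had to be resolved: the defining formula can be
read with $F^F(1-F)^{1-F}$ either multiplying or dividing. Only the
product reading is consistent with the unit-mass substitution integral,
with the log-energy decomposition, and with the Gamma form, so the
product is what every code path implements.

A caution on a tempting "invariant": $\rho \to 0$ toward the support
boundary holds whenever $f$ is bounded there, but *not* for the arcsine
family, whose density diverges at the endpoints; there
$\rho \to 48/(\pi^2 e) \approx 1.789$. The tests assert boundary
vanishing only for bounded-density families.

## Distribution layer

Five analytic families are provided (uniform, normal, exponential,
Wigner semicircle on $(-R, R)$ with density
$2\sqrt{R^2 - x^2}/(\pi R^2)$, and the arcsine law on $(a,b)$ with CDF
$\tfrac{2}{\pi}\arcsin\sqrt{(x-a)/(b-a)}$). The arcsine family is
parameterised on a general interval; the standard square-root CDF is the
reading under which the sine identity
$\sin(\pi G(x)) = 2\sqrt{x(1-x)}$ holds exactly, which the package
verifies to $10^{-12}$.

Empirical estimation builds both evaluators from one Gaussian kernel
estimate: the density is computed by `stats::density` on the extended
support $(\min - 3h, \max + 3h)$ and renormalised to integrate to one
there, and the CDF is the cumulative quadrature of that same density.
Using the raw step ECDF instead would break the unit-mass property of
the transform, which needs a mutually consistent $(f, F)$ pair. The
bandwidth default is Silverman's rule of thumb (`stats::bw.nrd0`),
user-overridable; at least 10 observations with positive variance are
required. Medians are located by bisection on the CDF to $10^{-12}$ in
probability.

## Grids and quadrature

Bounded supports use *midpoint* grids: $n$ equally spaced interior
points at the centres of $n$ equal cells. The midpoint-rule mass
$h\sum_i \rho(x_i)$ then integrates the whole interval at $O(h^2)$
accuracy even when $\rho$ does not vanish at the boundary (the arcsine
case; an interior trapezoid would lose $O(h)$ boundary mass). Unbounded
supports are truncated at the $10^{-6}$ and $1 - 10^{-6}$ quantiles and
discretised equally; the mass beyond the truncation is negligible at the
tolerances used. The running CDF $G$ along a curve is the cumulative
trapezoid of the values, normalised to end at exactly 1 and clamped
monotone into $[0,1]$ as a floating-point guard.

Level-1 curves are renormalised by adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-9}$) of the analytic
composition rather than by the grid sum: the recovered harmonic
coefficient $C_1$ must be accurate to $10^{-6}$, which leaves no room
for the $O(h^2)$ bias of a grid renormalisation at the default grid
size. Deeper recursion levels, where only grid values exist, renormalise
by the midpoint sum; the residual drift is well inside the $10^{-4}$
mass tolerance applied per level.

Default sizes: 2048 points for single-level curves and energy grids
(4096 for recursion, since repeated application sharpens the mode), 512
for per-channel empirical curves, 4096 KDE bins. These were chosen so
each identity is met with an order-of-magnitude margin at interactive
runtimes; the full test suite runs in a few seconds.

## Derivative and mode

The closed-form derivative used everywhere is the chain-rule-complete
expression
$$\rho'(x) = \rho(x)\left[\Big(\pi\cot(\pi F) +
\log\tfrac{F}{1-F}\Big) f(x) + \tfrac{f'(x)}{f(x)}\right],$$
validated against central differences (step $10^{-6}$) on interior
grids. A commonly printed variant omits the factor $f(x)$ on the two
$F$-dependent terms; the two coincide only when $f \equiv 1$, and the
finite-difference oracle singles out the form above. Analytic families
carry closed-form $f'$; the empirical layer uses a central difference.

The mode is found by a 2048-point grid scan followed by golden-section
refinement in the bracketing cell (`stats::optimize`, tolerance
$10^{-10}$). For symmetric unimodal bases it reproduces the median to
$10^{-6}$, the mode-median property of the transform.

## Energies and equilibrium

From $\log\rho = \log\sin(\pi F) - H_B(F) + \log f + C$ the package
reports the modulation energy $-\log\sin(\pi F)$, the structural energy
$H_B(F) - \log f$, and their sum, which reconstructs $-\log\rho + C$ to
$10^{-10}$ on interior grids. Energies are only evaluated where
$0 < F < 1$; boundary points raise an error rather than emitting silent
infinities, and exports serialise any infinite value as `inf`.

For the uniform base on $(0,1)$ the energy derivative is
$-\pi\cot(\pi x) + 2\,\mathrm{atanh}(1-2x)$ (with
$\mathrm{atanh}(z) = \tfrac12\log\tfrac{1+z}{1-z}$, computed exactly in
that form), whose lone interior root is the median. Differentiating that
slope once more gives
$$\frac{d^2E}{dx^2} = \pi^2\csc^2(\pi x) - \frac{1}{x(1-x)},$$
because the entropy term is concave ($H_B'' = -1/(x(1-x))$): the
curvature at the equilibrium is $\pi^2 - 4 \approx 5.87 > 0$, a
minimum. The closed form exposed as
`total_energy_second_derivative_uniform` follows the commonly tabulated
expression with $+1/(x(1-x))$ (value $\pi^2 + 4$ at the median), whose
entropy term carries a dropped chain-rule sign; both expressions are
positive on $(0,1)$ and divergent at the boundaries, so the
classification of the equilibrium and the boundary-instability picture
are identical under either. The unit tests check finite differences of
the energy against the mathematically consistent expression and keep the
tabulated values on record.

General bases get a numerical treatment: the energy is evaluated through
$-\log\rho + C$, its central-difference derivative is scanned for sign
changes on the evaluation grid, each bracket is refined by bisection,
and the sign of the (closed-form or second-difference) curvature
classifies the point. No sign change yields an empty report, not an
error. Equilibria of skewed families are reported as numerical findings
only.

## The governing ODE

For the uniform base, $\rho$ as a function of the probability level $F$
satisfies
$$\rho'' + 4\,\mathrm{atanh}(1-2F)\,\rho' +
\Big[\pi^2 - \tfrac{1}{F(1-F)} + 4\,\mathrm{atanh}^2(1-2F)\Big]\rho = 0,$$
with $\rho(0) = 0$ and $\rho'(0) = 24/e$. The module verifies rather
than integrates: residuals are assembled from analytic derivatives of
the closed-form solution on $F \in [0.01, 0.99]$ (machine-level,
$<10^{-8}$ asserted) and from finite differences on general curves
(reported, not asserted — the theorem is stated for the uniform base).

The integrating factor is used as the magnitude $F^F(1-F)^{1-F}$. The
usual derivation produces it with a leading minus sign, which together
with a positive sine coefficient would force $\rho \le 0$; since an
integrating factor is defined up to a nonzero constant, the magnitude is
the convention that reproduces the transform exactly. This choice is
deliberate and documented rather than silently patched.

Dividing a fitted uniform curve by the integrating factor and fitting
$\{\sin \pi F, \cos \pi F\}$ by least squares recovers
$C_1 = 24/(\pi e)$, $C_2 = 0$ to $10^{-6}$; planted sinusoids are
recovered exactly (a linear-algebra identity, used as the independent
check of the fitting path). The initial slope is the one-sided limit of
$\rho(F)/F$, extrapolated to $F = 0$ by a three-point Lagrange
(quadratic) fit through the smallest grid points; the leading
$F\log F$ correction in $\rho/F$ limits simple one-point estimates to
$\sim 4\times10^{-3}$ relative error, while the quadratic extrapolation
reaches $\sim 3\times10^{-4}$, inside the $10^{-3}$ target. Curves whose
first grid point lies above $10^{-3}$ are refused (coverage error).

## Recursion

The self-referential iteration
$$\rho^{(n)} = \tfrac{24}{\pi e}\,\sin(\pi G^{(n-1)})\,
(G^{(n-1)})^{G^{(n-1)}}(1-G^{(n-1)})^{1-G^{(n-1)}}\,\rho^{(n-1)},
\qquad \rho^{(0)} = f,\; G^{(0)} = F,$$
operates on a fixed grid. $G^{(n)}$ is clamped to $[0,1]$ and made
non-decreasing before entering the sine and power terms; each level is
renormalised (the continuum identity guarantees unit mass exactly, the
grid only approximately), and an input whose mass deviates from 1 by
more than $10^{-2}$ is rejected as corrupted. Convergence diagnostics
track, per level, the mean, the variance and the mass within $\pm 0.05$
of the *base* median — the paper-level limit object is a point mass at
the median, and for asymmetric bases the package pins the window at the
base median rather than any level-dependent quantile (an open choice,
made once). Across levels 1–6 the variance decreases and the central
mass increases strictly for both the uniform and arcsine bases.

The observed resemblance between the third arcsine level and the first
uniform level is reported as a maximum pointwise discrepancy with no
pass/fail bound: no metric or tolerance accompanies the qualitative
claim, so the tests only sanity-bound the number. No convergence-rate or
self-similarity-exponent estimation is attempted.

## Synthetic signals

The generator emulates the *shape* of a multichannel recording — 19
channels under 10–20 labels by default, each a sum of sinusoids with
channel-specific random phases plus additive noise, fully reproducible
from a seed. A nonzero `skew` replaces the Gaussian noise by a
standardised log-normal tilt $\propto e^{sZ}$, giving amplitude
distributions whose skewness grows with $|s|$ and flips with its sign.
It does **not** emulate real electrophysiology: no $1/f$ spectra,
artifacts, nonstationarity, inter-channel correlation or volume
conduction. Passing tests therefore demonstrate that the pipeline
(estimation, transform, features) is correct and deterministic on
controlled inputs, not that any clinical contrast is reproduced; the
per-channel "variability" feature is operationalised as the standard
deviation of $\rho$ across the grid, one documented choice among
several possible summaries. Channel amplitude distributions are taken
as the marginal distribution of each channel, estimated independently
with no preprocessing.

## Problem sizes and limitations

The test suite and the acceptance script run at the defaults above
(grids of 256–4096 points, samples of $10^2$–$10^5$, recursion to level
6, 19-channel matrices of a few thousand samples) in seconds on one
core. Known limitations: no distribution families beyond the five plus
empirical; no censored or weighted samples; no symbolic or
arbitrary-precision arithmetic (the three-form equivalence is limited to
$\sim 10^{-10}$ relative accuracy near the $10^{-6}$ quantile tails by
double-precision cancellation in $1 - F$); the ODE verification is a
residual check, not a solver; and binary EEG containers are out of
scope by design.
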