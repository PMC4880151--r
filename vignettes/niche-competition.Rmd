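---
title: "Modelling competition between healthy and leukaemic haematopoiesis in the bone-marrow niche"
author: "hscniche package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competition between healthy and leukaemic haematopoiesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscniche)
```

## The models

`hscniche` implements two deterministic competition models of acute
myeloid leukaemia in the haematopoietic stem-cell niche. Five cellular
species interact: haematopoietic stem cells $S$, healthy progenitor
cells $A$, terminally differentiated blood cells $D$, leukaemia stem
cells $L$, and terminally differentiated leukaemia cells $T$. Two niches
impose crowding: the stem-cell niche with occupancy $Z_1 = S$ and
capacity $K_1$, and a shared progenitor/leukaemia niche with occupancy
$Z_2 = A + L$ and capacity $K_2$. Crowding down-regulates proliferation
linearly through $(K - Z)$ factors, in the Lotka–Volterra tradition.

Model I is
$$
\begin{aligned}
\dot S &= \rho_S S (K_1 - Z_1) - \delta_S S \\
\dot A &= \delta_S S + \rho_A A (K_2 - Z_2) - \delta_A A \\
\dot D &= \delta_A A - \mu_D D \\
\dot L &= \rho_L L (K_2 - Z_2) - \delta_L L \\
\dot T &= \delta_L L - \mu_T T
\end{aligned}
$$
with proliferation rates $\rho_i$, differentiation rates $\delta_i$ and
migration (clearance into the blood) rates $\mu_D$, $\mu_T$, all in
units of 1/time. Model II adds a negative feedback of differentiated
blood cells on progenitor differentiation: the $A \to D$ flux
$\delta_A A$ is replaced by $\delta_A A / (1 + D)$ in both $\dot A$ and
$\dot D$. Accumulating differentiated cells thereby delay progenitor
differentiation — a demand-adaptation mechanism that turns out to
benefit the healthy lineage. The S, L and T equations are identical
between the models, and at $D = 0$ the models coincide.

Only $A$ and $L$ are niche effectors; the leukaemia population competes
with healthy *progenitors*, not with stem cells, so leukaemia affects
the stem-cell pool only indirectly. Populations are scaled so that
$K_1 = K_2 = 1$ by default; all state variables are dimensionless
occupancy fractions (values above 1 are possible for $D$ and $T$, which
live outside the niches).

The assumptions worth keeping in mind: crowding feedback is linear and
proportional to total occupancy; the models are mean-field (no spatial
structure, no stochasticity, no delays, no age structure); and the
leukaemia parameters are constants, i.e. incidence and transformation
are outside the scope.

## Parameters and defaults

`model_params()` holds the ten parameters. The fixed reference values
used throughout are $\mu_D = 0.275$, $\mu_T = 0.3$ (leukaemia progeny
slightly shorter-lived), $\rho_L = 0.27$, $\delta_L = 0.2$ (compensated
by leukaemia proliferation above its differentiation rate). The four
healthy-lineage rates $(\rho_S, \delta_S, \rho_A, \delta_A)$ are the
analysis axes and are varied over $[0.1, 0.5]$, a region of rich
dynamical behaviour; the default point $(0.5, 0.43, 0.14, 0.44)$ is a
reference example discussed below. Rates of order $0.1$–$0.5$ per time
unit imply relaxation times of order 10–100 time units, which motivates
the numerical defaults.

## Steady states and critical values

Model I has a unique interior fixed point in closed form
(`fixed_point_model1()`):
$$
S^\* = 1 - \tfrac{\delta_S}{\rho_S},\qquad
A^\* = \frac{-\delta_S S^\*}{\rho_A \delta_L/\rho_L - \delta_A},\qquad
D^\* = \tfrac{\delta_A}{\mu_D} A^\*,\qquad
L^\* = 1 - A^\* - \tfrac{\delta_L}{\rho_L},\qquad
T^\* = \tfrac{\delta_L}{\mu_T} L^\*.
$$
The $L$ equation pins the niche occupancy $A^\* + L^\* = 1 -
\delta_L/\rho_L$ whenever leukaemia persists. $A^\*$ has a pole at
$\delta_{A,\mathrm{asymp}} = \rho_A \delta_L / \rho_L$; the package
treats a guard band of $10^{-9}$ around it as singular and the sweep
machinery logs such points as indeterminate rather than evaluating them.

For Model II, $S^\*$, and the $L^\*$, $T^\*$ expressions given $A^\*$,
carry over, while $(A^\*, D^\*)$ solve the balance relation
$A^\* = \mu_D D^\*(1 + D^\*)/\delta_A$ together with a quadratic in
$D^\*$, yielding a *minus* and a *plus* branch
(`fixed_points_model2()`, reported in that order as the first and
second solution). When the discriminant is negative both branches are
complex; the package flags them `is_real = FALSE` and reports no state
rather than a fabricated real part. The plus branch is the one that
admits biologically meaningful coexistence, and only in a narrow regime
(small stem-cell influx $\delta_S S^\*$, $\delta_A \rho_L$ close to
$\rho_A \delta_L$).

`critical_values()` returns the parameter values at which species'
steady states cross zero or diverge — the boundaries of the coexistence
region. These were re-derived from the steady-state expressions rather
than transcribed, because inline typography for such formulas is easy to
misgroup; with $\phi = 1 - \delta_L/\rho_L$ and
$d = \rho_A \delta_L/\rho_L - \delta_A$, setting $L^\* = 0$ gives the
quadratic $\delta_S^2 - \rho_S \delta_S - \rho_S \phi d = 0$ and hence
$\xi^2 = \rho_S^2/4 + \rho_S \phi d$, $\delta_{S,\mathrm{crit}} =
\rho_S/2 + \xi$. Every returned value is contractually a root of the
corresponding steady-state curve, and the test suite verifies each
against an independent Brent root-finder on that curve. Undefined values
(e.g. $\xi$ when $\xi^2 < 0$) are returned as `NA` with a flag, never as
an error, so sweeps can proceed.

A small but robust structural fact: $A^\*$ and $D^\*$ are maximised over
$\delta_S$ at $\delta_S = \rho_S/2$, independent of all other
parameters — stem cells best support the progenitor pool when they
proliferate at twice their differentiation rate.

## Numerical integration

`integrate_to_steady_state()` integrates either model with the LSODA
stiff/non-stiff switching solver (via `deSolve::lsodar`), with the
right-hand sides compiled in C. Steady state is declared from the
residual norm $\lVert f(x) \rVert_\infty <$ `convergence_norm_tol`
($10^{-9}$ by default), monitored continuously by the solver's
root-finding machinery so the integration stops at the first instant the
criterion is met. A residual criterion is used instead of
state-difference between checks because slow transients can make
successive states nearly equal long before equilibrium.

Defaults: initial state $(0.01, 0.01, 0.01, 0.01, 0.01)$ — a small equal
seeding that lets either lineage invade; horizon $t_{\max} = 10^4$;
solver tolerances `rtol` $= 10^{-8}$, `atol` $= 10^{-10}$. Components
more negative than $-\mathtt{atol}$ are never produced by these
tolerances; overshoot within $(-\mathtt{atol}, 0)$ is clamped to zero.
The stopping state locates the equilibrium to about
`convergence_norm_tol` divided by the slowest local decay rate, i.e.
$\approx 10^{-8}$ for rates of order $0.1$; reproducibility across
solver-tolerance changes is therefore at the $10^{-8}$–$10^{-7}$ level,
not at `atol` itself.

## Linear stability and the stable-fraction study

`assess_stability()` evaluates the analytic Jacobian
(`model_jacobian()`, hand-derived; finite-difference agreement is a
mandatory test) at a real fixed point and classifies it stable iff every
eigenvalue real part lies below $-10^{-9}$. "Negative eigenvalues" is
read as negative real parts — the standard criterion, since complex
pairs occur in this 5×5 system — and marginal cases are conservatively
classified unstable.

`stable_fraction_in_coexistence()` samples the four varied rates iid
uniform on $[0.1, 0.5]^4$ (fixed leukaemia parameters), keeps the draws
whose chosen analytic fixed point is real with $A^\* > \varepsilon$ and
$L^\* > \varepsilon$, and reports the fraction of those that are
linearly stable. With 10,000 draws the package obtains approximately
0.86 for Model I, 0.43 for the Model II minus branch, and exactly zero
stable points on the plus branch. The zero-stable plus branch matches
the originally reported behaviour; the other two fractions do not (0.359
and 0.115 were reported). We examined the obvious protocol variants —
sampling all eight rates, counting stable-and-coexistent over all draws,
requiring real negative eigenvalues, requiring full-state
nonnegativity, alternative fixed leukaemia parameters — and none
reproduces both reported fractions; the package therefore reports its
own computation, whose Jacobians are verified against finite differences
and whose stability calls are verified by perturbation-and-return
integration, and records the disagreement rather than forcing it.

## Sweep engines and the classification protocol

`run_sweep()` classifies every parameter set of a `sweep_design()` by
three features: progenitor survival ($A^\* > \varepsilon$), leukaemia
survival ($L^\* > \varepsilon$), and coexistence (both), plus dominance
($A^\* \gtrless L^\*$) within coexistence. The positivity threshold
$\varepsilon = 10^{-6}$ is far above solver tolerance and far below any
meaningful population fraction. Dominance is reported as the joint
probabilities $P(A^\*>L^\* \wedge \text{coexistence})$ and
$P(L^\*>A^\* \wedge \text{coexistence})$, which sum to the coexistence
probability up to ties (ties within $\varepsilon$ set neither flag and
are measure-zero under both engines).

Two engines are provided, and their relationship is the methodological
heart of the package:

* **analytic** — the exact $t \to \infty$ attractor. For Model I the
  stem-cell equation is autonomous and relaxes to
  $S_\infty = \max(0, 1 - \delta_S/\rho_S)$. Given $S_\infty > 0$, the
  interior fixed point is the attractor precisely when it is coexistent;
  otherwise the trajectory settles on the healthy-only boundary root of
  $\delta_S S_\infty + \rho_A A(1 - A) - \delta_A A = 0$ (one can show
  leukaemia can invade that root exactly when the interior $L^\*$ is
  positive, so the two characterisations agree). When $S_\infty = 0$ the
  $(A, L)$ pair reduces to two-species competitive exclusion decided by
  the smaller $\delta/\rho$ ratio. This engine is vectorised and runs a
  full-scale grid in under a second. For Model II, where branch
  multiplicity and basins make a closed-form attractor unavailable, the
  analytic engine classifies a point by its real nonnegative branches (a
  documented over-approximation, used only for cross-checks).
* **integration** — LSODA from the default initial condition,
  classifying the final state. With `on_nonconverged = "exclude"`,
  points that fail the residual criterion by $t_{\max}$ are reported
  indeterminate and excluded; in this mode the two engines agree within
  0.02 on every summary probability over a $10^4$-point random design,
  and pointwise everywhere except within about 0.01 of a critical
  boundary. With `on_nonconverged = "classify"` the state at $t_{\max}$
  is classified as-is.

The distinction matters because the losing species near an exclusion
boundary decays at a rate proportional to its distance from the
boundary, so arbitrarily slow transients exist and any finite-horizon
simulation counts some of them as coexistent. The reported
survival/coexistence probabilities for these models were measured by
finite-time LSODA simulation, and the package reproduces them in
`"classify"` mode with the default protocol (equal 0.01 seeding,
$t_{\max} = 10^4$, $\varepsilon = 10^{-6}$): at 21 points per axis,
Model I gives $(0.675, 0.435, 0.110, 0.055, 0.055)$ against the
reported $(0.683, 0.466, 0.148, 0.087, 0.061)$, and at 12 points per
axis Model II gives $(0.722, 0.350, 0.071)$ against $(0.719, 0.344,
0.063)$ for the first three columns. The exact $t \to \infty$
classification gives a noticeably lower Model I coexistence probability
(about 0.08): roughly a third of the reported "coexistence" mass is
slow-transient, a fact worth knowing when interpreting such probability
tables. The directional effect of feedback — Model II gains progenitor
survival and loses leukaemia survival and coexistence — holds under
both engines and at every design size we tried.

Grid designs are endpoint-inclusive and evenly spaced; the full-scale
resolution is 42 points per axis ($42^4 \approx 3.1$ million
combinations), configurable and recorded in the output metadata, and
the acceptance/test runs use 21 (Model I) and 12 (Model II) points per
axis to keep a laptop-scale runtime — the methodology is unchanged by
resolution beyond sampling noise. Uniform random designs require an
explicit seed and are exactly reproducible from it.

## The reference point discrepancy

At $(\rho_S, \rho_A, \delta_S, \delta_A) = (0.5, 0.43, 0.14, 0.44)$
with the package's fixed leukaemia parameters, the Model I fixed point
is $S^\* = 0.72$, $A^\* \approx 0.830$, $L^\* \approx -0.570$: not
coexistent. The study this point is drawn from describes it as lying in
the coexistence region with a stable coexistent state, but does not
state the leukaemia parameters used there; under, e.g.,
$\rho_L = 0.4$, $\delta_L = 0.2$ the same healthy-lineage rates do give
a coexistent point. The package evaluates and reports the conflict (see
`test-acceptance.R`) and does not attempt to force agreement.

## Limitations

The synthetic parameter ensembles emulate the study design — uniform
boxes and grids over the four healthy-lineage rates with leukaemia
rates fixed — not biological parameter uncertainty; probabilities
computed from them are properties of that design, not of AML. Finite-
horizon classification inherits a protocol dependence (horizon, initial
condition, threshold) that the engine-concordance machinery makes
explicit but cannot remove. The models themselves are mean-field ODEs
with linear crowding; spatial niche structure, stochastic extinction at
small population sizes, and cancer incidence are all outside scope. No
limit-cycle or global-stability analysis is attempted: classification
is by fixed points and simulated attractors only.
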