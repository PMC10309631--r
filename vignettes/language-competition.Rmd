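---
title: "Bilingual competition dynamics and threshold-triggered sliding-mode control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilingual competition dynamics and threshold-triggered sliding-mode control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingslide)
```

## The model

Two languages A and B compete inside one well-mixed population that also
contains bilinguals. The state is a point on the 2-simplex: proportions
$x_A$ (monolingual A), $x_B$ (monolingual B) and $w = 1 - x_A - x_B$
(bilingual). Monolinguals never convert directly into the other
monolingual group; every shift passes through the bilingual pool. Four
transfer rates drive the flows, each proportional to the *status* $s$ of
the attracting language (a socio-economic weight) and to that language's
speaker share raised to an *attractiveness exponent* $a$:

$$
P_{w \to A} = I_{wA}\, s_A\, x_A^a, \qquad
P_{A \to w} = I_{Aw}\, s_B\, x_B^a, \qquad
P_{w \to B} = I_{wB}\, s_B\, x_B^a, \qquad
P_{B \to w} = I_{Bw}\, s_A\, x_A^a,
$$

where the $I$ are direction-specific interaction values. With a turnover
rate $\mu$ weighting the bilingual-to-monolingual flow, the monolingual
proportions obey

$$
\frac{dx_A}{dt} = \mu\, w\, P_{w\to A} - (1-\mu)\, x_A\, P_{A \to w},
\qquad
\frac{dx_B}{dt} = \mu\, w\, P_{w\to B} - (1-\mu)\, x_B\, P_{B \to w},
$$

and $w$ follows by conservation. Substituting the transfer rates collapses
everything into four positive coefficients,

$$
a_1 = \mu I_{wA} s_A,\quad a_2 = (1-\mu) I_{Aw} s_B,\quad
a_3 = \mu I_{wB} s_B,\quad a_4 = (1-\mu) I_{Bw} s_A,
$$

giving the planar system implemented by `rhs_reduced()`:

$$
\dot x_A = a_1 (1 - x_A - x_B)\, x_A^a - a_2\, x_A x_B^a, \qquad
\dot x_B = a_3 (1 - x_A - x_B)\, x_B^a - a_4\, x_B x_A^a .
$$

`model_params()` holds the full parameterization, `reduced_coefficients()`
performs the collapse, and the identity between the full and reduced
fields is enforced by a property test. Two modelling stances deserve
explicit mention:

* $\mu$ is treated purely as the coefficient it is in the equations above.
  It is sometimes glossed as a mortality or generational-turnover rate,
  but it multiplies the bilingual-to-monolingual flow, so no demographic
  interpretation is attached; the constraint $0 < \mu < 1$ is exactly what
  makes all four reduced coefficients positive.
* Absolute population counts are out of scope. The model operates on
  proportions only, which is why $w$ is stored redundantly and validated
  against $1 - x_A - x_B$ instead of being integrated.

## Parameters that matter

| parameter | meaning | typical value | why |
|---|---|---|---|
| $\mu$ | turnover weight on bilingual-to-monolingual flow | 0.02 | losing a language across generations is much slower than learning one within a life |
| $a$ | attractiveness exponent | 1.31 (time-series scenarios), 1 (policy scenarios) | cross-cultural estimates cluster at $1.31 \pm 0.25$; the closed-form analysis is cleanest at $a = 1$ |
| $s_A, s_B$ | language statuses | complementary pairs (0.8/0.2, 0.6/0.4, ...) | statuses act as relative weights; complements keep one degree of freedom |
| $I_{wA}, I_{wB}$ | bilingual-to-monolingual interaction | 1 (10 when one language is strongly favoured) | re-monolingualization is the default-strength flow |
| $I_{Aw}, I_{Bw}$ | monolingual-to-bilingual interaction | 0.03-0.06 in the policy scenarios | adults acquire a second language far more slowly |
| ET | endangerment threshold | 0.3 | the $x_B$ level at which intervention parameters replace the free ones |

`s_A + s_B = 1` is *not* enforced - nothing in the dynamics requires it -
but a warning is issued when statuses are not complementary, since every
worked scenario uses complements. Likewise $a < 1$ (sublinear
attractiveness) is allowed and flagged: the classification theory below
assumes $a \ge 1$.

The time-series scenarios state $a = 1.31$ once, for the first example
only; this package applies it to all five of them, reading the single
statement as the section-wide setting. The policy scenarios state $a = 1$
but not $\mu$; $\mu = 0.02$ is adopted there too, a choice confirmed by
exact reproduction of their interior-equilibrium coordinates.

## Equilibria and stability

The boundary points $E_0(0,0)$, $E_1(0,1)$, $E_2(1,0)$ are equilibria for
every parameterization. Dividing the two interior stationarity conditions
gives the ratio identity $(x_A^*/x_B^*)^{2a-1} = a_2 a_3/(a_1 a_4)$, from
which `interior_equilibrium()` computes the unique interior point in
closed form; at $a = 1$ it reduces to the rational expressions
$x_A^* = a_2 a_3 / D$, $x_B^* = a_1 a_4 / D$ with
$D = a_1 a_4 + a_2 a_3 + a_2 a_4$. Both forms are kept and checked against
each other and against an independent nested-bisection oracle in the
tests. The exponent $a = 1/2$ is refused (the ratio exponent vanishes);
this is the one genuinely unsupported value.

Stability uses the trace-determinant plane: $p = -\mathrm{tr}\,J$,
$q = \det J$ of the analytic Jacobian (`jacobian_reduced()`, cross-checked
against central finite differences). The taxonomy implemented by
`classify_equilibrium()` is: $q < 0$ saddle; $q > 0, p > 0$ stable (node
if $p^2 \ge 4q$, focus otherwise); $q > 0, p < 0$ unstable likewise;
$q > 0, p = 0$ center-like degenerate; $p = q = 0$ degenerate /
non-hyperbolic. The boundary terms $x^{a-1}$ use the one-sided limits
$0^0 = 1$ ($a = 1$) and $0$ ($a > 1$); for $a < 1$ the Jacobian diverges
on the boundary and evaluation is refused there.

Two classification facts the package verifies rather than assumes:

* $E_1$ and $E_2$ are always stable *nodes*, never foci: their
  discriminants are the perfect squares $(a_2 - a_3)^2$ and
  $(a_1 - a_4)^2$.
* The interior point always has $q < 0$: coexistence in the uncontrolled
  model is a saddle, so it is never observed.

At $E_0$ with $a > 1$ the linearization is the zero matrix and says
nothing. Rather than asserting instability, `classify_equilibrium()`
reports "degenerate/non-hyperbolic" and runs a perturbation probe:
trajectories from eight starts at distance $10^{-4}$ are integrated, and
escape beyond ten times that distance sets `numerically_unstable`. The
analytic label and the numeric probe are kept separate on purpose.

One derived quantity differs knowingly from how it is sometimes quoted:
the closed form of $p$ at the interior saddle ($a = 1$). From the Jacobian
one gets $p = a_1 x_A^* + a_3 x_B^* = a_1 a_3 (a_2 + a_4)/D$, confirmed by
finite differences; a circulating variant, $a_2 a_3(a_1 + a_4)/D$, does
not match the Jacobian and is not used. The sign conclusions are identical
either way.

`boundary_inflow_check()` turns the positive-invariance argument into an
executable check: on each edge of the triangle the field's outward
component is sampled and its worst value reported. The tests sweep this
over a thousand random parameterizations and $a \in \{1, 1.31, 2\}$.

## Simulation

`integrate_smooth()` integrates the planar field with `deSolve` at
`rtol = 1e-9`, `atol = 1e-12`, emitting at least 500 evenly spaced
samples. The `vode` stepper is used for plain runs: `lsoda`'s automatic
stiffness switching can abort with a spurious interpolation error after a
coordinate has decayed to numerical underflow near a monolingual
equilibrium, which these trajectories routinely do; `lsodar` (the only
root-finding stepper) is reserved for event detection in the hybrid
integrator, whose pieces are short. Coordinates are clamped to zero below
$-10^{-12}$ before exponentiation so fractional powers never see
integrator overshoot, and endpoint states are projected back onto the
simplex before residual evaluation.

Initial triples that do not sum to one - one worked scenario lists
proportions summing to 0.99 - are renormalized with a warning rather than
rejected. `attractor_of()` integrates in restartable chunks (length 2000,
budget $2 \times 10^5$) until the field residual falls below $10^{-10}$
and the per-chunk displacement below $10^{-8}$, then matches the limit
against the known equilibria within $10^{-4}$. "Extinction" of a language
is operationalized as its proportion first crossing 0.01
(`first_passage_time()`, linear interpolation between samples); the
threshold is configurable since the underlying curves only approach zero
asymptotically.

Two behaviours of the worked time-series scenarios deserve flagging,
because the dynamics contradict the prose that originally accompanied
them (the package reports what the equations yield; the scenario `notes`
carry the flags):

* The first scenario (statuses 0.4/0.6, bilingual-to-A interaction 10) is
  announced as ending in $E_1(0,1,0)$; integrating its stated equations -
  confirmed with an independent integrator - gives $E_2(1,0,0)$. The
  swapped-status variant, the interaction sweep, and the
  heterogeneous-start scenario (which genuinely reaches $E_1$) all match
  their announcements.
* In the status sweep with $s_B = 1 - s_A$, language B goes extinct only
  for $s_A \in \{0.5, 0.7, 0.95\}$ (with monotonically decreasing
  extinction times, as announced); at $s_A \in \{0.1, 0.3\}$ B wins
  instead, so no extinction time exists there.

## Sliding-mode control

The controlled model swaps in post-intervention parameters whenever
$x_B < ET$. This creates a piecewise-smooth system with switching line
$\Sigma = \{x_B = ET\}$; `filippov_model()` holds the two coefficient
sets. On $\Sigma$ the signs of the two regimes' normal components
$\sigma_{\mathrm{free}}, \sigma_{\mathrm{ctrl}}$ classify each point
(`classify_sigma_point()`); where both fields point at the line
($\sigma_{\mathrm{free}} < 0 < \sigma_{\mathrm{ctrl}}$) motion is
constrained to it. The sliding dynamics follow Filippov's convex
combination - the unique convention for a planar system with a scalar
switching function that keeps the combined field tangent to $\Sigma$:

$$
\lambda = \frac{\sigma_{\mathrm{ctrl}}}{\sigma_{\mathrm{ctrl}} -
\sigma_{\mathrm{free}}}, \qquad
\dot x_A = \lambda f_A^{\mathrm{free}} + (1-\lambda) f_A^{\mathrm{ctrl}},
$$

with $\lambda \in (0,1)$ guaranteed by the sliding sign pattern. A
*pseudo-equilibrium* is a zero of this field inside a sliding segment: a
stationary state of the controlled system that is an equilibrium of
neither smooth regime - stable coexistence of the two languages, with
language B pinned at the threshold. `pseudo_equilibrium()` finds segment
endpoints and field roots by bracketed scans polished to $10^{-12}$; at
$a = 1$ the root condition is an exact quadratic, which the tests exploit
as an independent oracle (three-point polynomial fit plus `polyroot`).

The three intervention strengths behave qualitatively differently, and
the package reproduces all three: status-only raises a sliding segment
whose motion exits at the right endpoint (no pseudo-equilibrium);
interaction-only produces no sliding segment at all; the combined
intervention yields the pseudo-equilibrium $(0.1289, 0.3, 0.5711)$ with
$\lambda \approx 0.027$.

`integrate_hybrid()` performs event-detected integration: the active
regime runs under `lsodar` with a root function on $x_B - ET$; each hit
is classified; crossings switch regimes (with a $10^{-11}$ nudge off the
line so the root function does not re-fire at the junction), sliding hits
continue as a one-dimensional integration along $\Sigma$ with root
functions at the segment endpoints. Sliding ends either in convergence at
the pseudo-equilibrium or at a tangency endpoint, where the continuation
regime is the one whose field points away from the line (the sign of
$\sigma_{\mathrm{free}} + \sigma_{\mathrm{ctrl}}$ decides). A chattering
guard aborts after $10^4$ switches; none of the worked scenarios comes
close. Exactly on $\Sigma$, regime attribution is governed by the sliding
classification, not by the $x_B \ge ET$ inequality.

A point worth stating because it is easy to over-read: the
pseudo-equilibrium is *locally* attracting - on-line starts inside the
segment and controlled-region starts beneath it converge to it - but its
basin is limited. From the uniform-ish start $(0.33, 0.33, 0.34)$ the
free flow crosses $\Sigma$ at $x_A \approx 0.35$, right of the sliding
window $(0.102, 0.129)$, and the controlled regime then carries the state
to monolingual A. The threshold policy guarantees coexistence only for
histories that approach the endangerment threshold in the right region;
the tests assert both the local attraction and this global limitation.

## Phase portraits and scenarios

`nullclines()` solves the nontrivial factor of each field component per
grid column by bracketed root search (the axes are returned as labelled
trivial branches); every emitted vertex is verified to satisfy its
stationarity condition to $10^{-10}$, and the nontrivial branches
intersect at the interior equilibrium. `vector_field_grid()` samples unit
directions on a barycentric lattice - chosen over a clipped square grid so
that fractional exponents are never evaluated outside the simplex - with
magnitudes stored separately and zero-field points flagged as equilibrium
candidates.

The scenario registry (`list_scenarios()`, `load_scenario()`,
`run_scenario()`) encodes the worked parameter tables: five time-series
scenarios (two single runs, a high-status variant, two sweeps, one
heterogeneous start) and four policy studies (uncontrolled baseline plus
the three interventions at $ET = 0.3$). Scenarios round-trip through flat
`key = value` config files (`write_scenario_config()` /
`read_scenario_config()`), and every written output carries a provenance
header echoing the full parameterization. A thin command-line front-end
is installed under the package's `exec` directory.

## Problem sizes and tolerances

The package's own test and reproduction runs use: closed-form equilibria
(instantaneous); sliding analyses with 1024-point bracketing scans
(milliseconds); trajectory integrations to horizons of 300-5000 model-time
units with 500-4000 output samples; property sweeps over 1000 random
parameterizations for boundary-invariance and saddle checks. All
assertions use fixed seeds. Display rounding follows the 4-decimal
convention of the analyses these scenarios reproduce (2 decimals for the
pseudo-equilibrium's headline coordinates).

## Known limitations

* Exactly two languages plus a bilingual pool; no three-language
  extension, no spatial structure, no age structure, no stochasticity.
* Proportions only - absolute counts and demography are out of scope.
* The classification theory covers $a \ge 1$; sublinear attractiveness is
  integrable but flagged, and boundary Jacobians are undefined there.
* Sliding analysis beyond the planar/scalar-switching setting
  (higher-order sliding, equivalent-control variants, chattering
  smoothing, control-parameter optimization) is not implemented.
* The scenario registry reproduces desk-scale analyses; nothing here fits
  the model to census or survey data.
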