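---
title: "Methods: ESS resource allocation and mating-system evolution in hermaphroditic perennials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ESS resource allocation and mating-system evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essalloc)
```

## The life history and its assumptions

The model describes a hermaphroditic perennial with discrete breeding
seasons and overlapping generations. Each adult holds a unit resource
budget per season and splits it three ways: a proportion `M` to pollen
production, `F` to seed production, and `1 - (M + F)` to its own survival.
We work in the equivalent coordinates `E = M + F` (reproductive allocation)
and `r = M/E` (sex allocation). The budget is normalized to 1 throughout:
an absolute budget would cancel from every first-order condition, so `M`,
`F` and `E` are proportions.

Key simplifications, inherited by everything downstream:

* no age or stage structure — adults do not change their parameters with
  age, and juveniles mature in one season;
* no density dependence in either offspring production or adult survival;
* no pollen limitation and no reproductive assurance — a plant's ovules are
  always fertilized, a fraction `s` by self pollen;
* inbreeding depression acts through survivorship only, with a juvenile
  fraction `delta_j` and an adult fraction `delta_a`; the relative
  survivorships are `w_j = 1 - delta_j` and `w_a = 1 - delta_a`, always
  derived rather than stored.

## Mutant fitness

A rare mutant `(E', r', s')` in a resident population fixed for
`(E, r, s)` is scored by its expected genetic contribution to the next
generation:

$$W = P_a(E')\,\bigl(1 - S(s')\,\delta_a\bigr)
 + P_j\Bigl[\,s' w_j f(F') + \tfrac12 (1-s') f(F')
 + \tfrac12 (1-s)\, f(F)\, \frac{m(M')}{m(M)}\Bigr].$$

The genetic-share weights encode the automatic transmission advantage of
selfing: a selfed seed carries two of its parent's gene copies and counts
with weight 1, an outcrossed seed with weight 1/2. The adult term is the
mutant's own survival discounted by the adult inbreeding mortality of its
selfed fraction `S(s')`; evaluating `S` at the mutant's own selfing rate is
what makes the adult term contribute `-P_a \gamma \delta_a` to the selfing
gradient, which the mating-system threshold requires. The siring term
competes the mutant's pollen against the resident pollen pool for the
resident's outcrossed ovules; pollen number only ever enters through the
ratio `m(M')/m(M)`, so the scale `m_max` cancels identically (a tested
invariance).

`female_fitness()` and `male_fitness()` split `W` into seed-parent and
pollen-parent components. Two conventions are involved that affect only the
split, never `W` itself: a selfed offspring contributes 1/2 to each
component, and the adult-survival term is divided half and half. The
decomposition `W_f + W_m = W` holds to machine precision by construction
and is asserted as such.

## Gain curves

The four resource-to-fitness maps are pluggable (`gain_set()`), each
carrying its value and, optionally, analytic derivatives. The defaults:

| curve | form | default parameters | why |
|---|---|---|---|
| adult survival | `Pa(E) = Pa_max (1-E)^beta` | `Pa_max = 0.9`, `beta = 0.5` | strictly decreasing and strictly concave, guaranteeing an interior optimum in `E` and a closed form for tests; the shape is otherwise unconstrained by the theory, so it is replaceable |
| female gain | `f(F) = f_max F` | `f_max = 10` | linearity is exactly the condition under which the `E` and `r` problems decouple |
| male gain | `m(M) = m_max M^eta` | `m_max = 100`, `eta = 0.8` | diminishing returns on pollen (`eta < 1`) are what keep the sex allocation interior; `eta = 1` degenerates (see below) |
| selfed-adult fraction | `S(s) = gamma s` | `gamma = 0.5` | `gamma`, the growth rate of self-fertilized adults, is treated purely as this slope; `0 < gamma < 1` keeps `S < 1` |

The power exponent of the male curve has no established symbol; the package
names it `eta` and defaults to 0.8, a mid-range value for diminishing male
returns. `constant_curve()` and `fixed_gains()` build deliberately
degenerate curves (fixed `Pa` and `f` values) for threshold evaluation;
they skip the `f(0) = 0` style validation and must not be used to solve
allocation optima.

## Closed-form ESS and its consequences

With the default curves, stationarity of `W` in the mutant's `(M', F')` at
mutant = resident gives

$$-P_a'(E)\,(1 - s\gamma\delta_a) = \frac{P_j f_{\max}}{2}\,
  \bigl(1 + s(2w_j - 1)\bigr), \qquad
  r^* = \frac{\eta(1-s)}{\eta(1-s) + 1 + s(2w_j-1)}.$$

The `E` condition contains no `r` (a consequence of the linear female
gain — asserted numerically by locating the root of the finite-differenced
survival-vs-female condition at several resident sex allocations) and the
`r` condition contains no `E`, `f_max`, `m_max` or `delta_a`. Under the
default survival curve the `E` root is explicit:
`E* = 1 - (Pa_max beta / K)^(1/(1-beta))` with
`K = (P_j f_max/2)(1 + s(2w_j-1))/(1 - s gamma delta_a)`; roots outside
`[0, 1]` are clipped with an explicit boundary flag rather than rejected,
since only interior optima carry the stationarity interpretation.

The direction of `E*` in `s` is governed by the ratio
`w_j / (1 - gamma + gamma w_a)` against 1/2 (`classify_dE_ds()`). Ties are
labelled `independent` within an absolute tolerance of `1e-9` on the ratio,
because the knife-edge is a genuinely distinct regime (constant `E*`), not
a rounding artifact. Note one subtlety the ratio makes explicit: even
cost-free selfing (`delta_j = delta_a = 0`) gives ratio 1 > 1/2, so `E*`
rises with `s` through the transmission advantage alone, although
resident-total fitness is then independent of `s`.

The slope of `r*` in `s` is `-2 eta w_j / (eta(1-s) + 1 + s(2w_j-1))^2`:
strictly negative whenever `w_j > 0`, independent of `delta_a` and `gamma`,
vanishing only in the degenerate case `w_j = 0`.

## The numerical oracle

`solve_ess_numeric()` exists to check every closed form against a route
that shares none of its algebra: best-response iteration on the raw fitness
function. Against the current resident, the mutant optimum over
`(E', r')` is found by nested Brent/golden-section maximization
(`stats::optimize`, tolerance `1e-9`) on the unit square; the resident is
then moved toward the best response and the loop repeats until the best
response is within `1e-8` of the resident.

Two numerical choices matter here:

* **Damping.** The undamped map two-cycles: a resident investing little in
  pollen makes the pollen pool cheap to monopolize, so the best-response
  sex allocation overshoots, the harder the closer `eta` is to 1 (the
  best-response exponent is `1/(eta-1)`). Each component therefore carries
  its own relaxation factor, halved when that component's successive
  displacements reverse sign and grown by 1.2x while they agree (floor
  `1e-3`). Fixed points are unchanged; convergence is still declared on the
  undamped displacement.
* **Boundaries.** When the best-response `E'` pins to ~0 (e.g. a vanishing
  reproductive payoff), fitness is flat in `r'` and the sex allocation
  carries no signal; convergence is then judged on `E` alone and the
  result flagged as a boundary solution. `eta = 1` is excluded from oracle
  comparisons: the fitness is linear in `r'` there, the best response is
  bang-bang, and the second-derivative matrix is exactly singular (the
  second-order check reports `indeterminate` rather than failing).

Start point `(0.5, 0.5)`, iteration cap 500, no random numbers anywhere in
the solvers. Non-convergence raises a classed condition carrying the full
trajectory for diagnosis.

Finite differences use central steps `1e-5 * max(1, |x|)` for first
derivatives (shrunk near boundaries rather than silently switching to
one-sided differences — a boundary resident is an error for the allocation
gradient), `1e-4` for the second-derivative matrix, and `1e-6` for the
selfing gradient, whose one-sided fallback at `s = 0` or `1` reports which
side was used. The second-order check tests negative definiteness through
both leading minors with tolerances scaled by the matrix norm
(`1e-6 * scale` on `H[1,1]`, `1e-5 * scale^2` on the determinant); inside
those tolerances it reports `indeterminate` instead of guessing. Arithmetic
identities are asserted at `1e-9` or tighter; solver outputs at `1e-6`.

## Mating-system evolution

Holding the allocation at its ESS and letting the selfing rate vary, the
selection gradient on a mutant selfing rate is

$$\frac{\partial W}{\partial s'} = P_j f(F)\,(\tfrac12 - \delta_j)
  - P_a(E)\, S'(s)\, \delta_a,$$

constant in `s'` under the linear default `S`. Selection is therefore
directional: writing `tau = delta_a P_a gamma / (P_j f)`, the gradient is
positive — complete selfing invades and is the ESS — exactly when
`delta_j < 1/2 - tau`, and negative — complete outcrossing — when
`delta_j > 1/2 - tau`. With no adult inbreeding depression the boundary is
the classical `delta_j = 1/2`. `classify_mating_ess()` computes the
gradient both analytically and by finite differences and requires the two
routes, and the `delta_j` rule, to agree; a disagreement is an internal
error (a tripwire for the implementation), not a user error.

`tau` is printed as a number but `P_a` and `f` are functions of the
strategy. The package's default is to evaluate them at the allocation ESS
for the resident selfing rate (anchor `s = 0` unless specified), with fixed
numeric overrides available — both interpretations are supported because
the choice genuinely matters: `tau` drifts as the allocation re-equilibrates
along `s`, so a parameter set near the boundary can change regime between
low and high resident selfing rates. The bundled regime scenarios are
chosen to sit on one side of the boundary across the whole `s` range.
`find_deltaj_boundary()` bisects the gradient zero in `delta_j`
(tolerance `1e-8`), re-solving the allocation ESS at each trial value so
the recovered boundary equals `1/2 - tau` self-consistently; when the
gradient has one sign on all of `[0, 1]` it returns a no-boundary result
with the uniform regime. With a nonlinear user-supplied `S(s')` the
gradient can cross zero in `s'`; the root is located and labelled
`interior_singular`, an extension beyond the linear model and marked as
such.

`pairwise_invasibility()` renders the same content as an invasion-sign
grid over resident and mutant selfing rates (allocation at the resident's
ESS, diagonal exactly zero), serializable as a coordinate-framed CSV.

## Scenarios, sweeps and the CLI

`scenarios()` bundles six parameter sets landing clearly inside each
qualitative regime: the three directions of `E*`-versus-`s`, a family of
`w_j` values for the `r*` decline, and both mating-system regimes. These
are *regime witnesses*, not reproductions of any particular published
curve — the analysis never fixes the parameter values behind plotted lines,
so sweeps are checked for signs, monotonicity and boundary locations only.
Sweeps and the CLI (`run_cli()`; subcommands `solve`, `classify`, `sweep`,
`pip`, `scenarios`) write deterministic CSV/JSON with 12 significant
digits: identical configurations give byte-identical outputs.

## What the tests do and do not establish

The test suite verifies internal identities (decomposition, scale
invariance, coordinate-change equivalence), agreement between independent
routes (closed forms vs best-response iteration on 100 random parameter
sets; analytic vs finite-difference gradients on 100 more; slope sign on
1000 sampled sets — sizes chosen to exercise the parameter space densely
while keeping the default run fast), and the threshold locations by
bisection. Passing says the implementation is a faithful, self-consistent
rendering of the model. It does not say the model describes any particular
plant: inbreeding depression that varies with density or age, pollen
limitation, plasticity in allocation, or correlated evolution of `(E, r)`
with `s` are all outside the model, and the mating-system analysis treats
the allocation as instantaneously equilibrated at each selfing rate rather
than coevolving.

## Known limitations

* Closed forms require the default curve family; arbitrary curves are
  served by the numeric oracle only, and nothing symbolic is attempted.
* `eta = 1` (linear male gain) makes the sex-allocation problem degenerate
  for the oracle and the curvature test, as described above.
* The selfing-rate analysis evaluates one trait at a time; joint
  three-trait adaptive dynamics (branching, convergence stability beyond
  the second-order check) is out of scope.
* Boundary allocation optima are reported with a flag but their stability
  is not analyzed beyond first order.
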