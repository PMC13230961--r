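---
title: "Methods: delayed CSC dynamics under radioimmunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed CSC dynamics under radioimmunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemrit)
```

## Scope

`stemrit` couples three model layers: a delayed dynamical system for a
tumor driven by cancer stem cell (CSC) plasticity; a linear-quadratic
(LQ) radiobiology stack for protracted irradiation by internally
administered radionuclides; and a two-dimensional oxygen
reaction–diffusion field supplying the hypoxia modifier.  A local
one-at-a-time (OAT) sensitivity layer ranks parameter influence on any
scalar output.  This vignette documents the model assumptions, the
numerical choices, and the design decisions taken where the underlying
formulation left genuine freedom.

## The dynamical tumor model

Four concentrations evolve in years: CSCs $S$, differentiated cancer
cells (DCs) $D$, Wnt-$\beta$-catenin pathway proteins $a$, and
microRNAs $m$.

$$
\begin{aligned}
\dot S &= (2p(D,a)-1)\,\varepsilon S + q(m(t-\tau))\,D(t-\tau)
          - \upsilon R_{\mathrm{imm}} S\\
\dot D &= 2(1-p(D,a))\,\varepsilon S - (d + q(m))\,D
          - \theta R_{\mathrm{imm}} D\\
\dot a &= a\!\left(\beta S \frac{a}{1+a} - \alpha\right)\\
\dot m &= \gamma e^{-S/S_0} - \alpha m
\end{aligned}
$$

with $p(D,a) = \eta a/((1+\eta a)(1+\psi D))$ and
$q(m) = \tfrac{q_0}{2}(1+\tanh((m-m_0)/\sigma))$.

Assumptions worth making explicit:

* **Asymmetric delay.**  The dedifferentiation influx into the stem pool
  uses the *delayed* pair $q(m(t-\tau))D(t-\tau)$ — DCs stimulated by
  microRNAs need a conversion time $\tau$ — while the outflux in the DC
  equation uses the instantaneous $q(m)$.  The asymmetry is part of the
  model and is preserved, not symmetrized.
* **Space-free cells.**  Only oxygen diffuses; the cell populations are
  well mixed.
* **$a = 0$ is invariant.**  A tumor whose Wnt signal is exactly zero
  never reactivates it; the implementation preserves this exactly (the
  $a$ equation is multiplied through by $a$).

### Parameters

Defaults (units as in `model_params()`): $\eta = 1$, $\psi = 0.5$,
$\varepsilon = 1\,\mathrm{y^{-1}}$, $m_0 = \sigma = 0.05$,
$\upsilon = 25\,\mathrm{y^{-1}}$, $\theta = 50\,\mathrm{y^{-1}}$
($\theta > \upsilon$: CSCs are the more radioresistant pool),
$\alpha = 0.3$, $\beta = 1$, $\gamma = 1$, $S_0 = 0.038$,
$\tau = 8.8964\,\mathrm{y}$.  Two parameters are only constrained, not
fixed, by the source formulation: the DC death rate is given as a range
$d \in [36.5, 109.5]\,\mathrm{y^{-1}}$ and the maximal dedifferentiation
rate only as $q_0 > d$.  We fix $d = 36.5$ (the lower end: the most
conservative DC turnover) and $q_0 = 40$ (just above $d$, so that
dedifferentiation can outpace DC death without dominating the dynamics).
These are study conditions, set once; both are ordinary arguments of
`model_params()`.

### Initial data

The defining publication of this model family defers its initial
conditions to earlier work; they are not derivable from the parameter
tables.  `default_initial_state()` therefore places the system at a
small perturbation of the Wnt-inactive controlled branch:
$S(0) = S_0 = 0.038$, $D(0) = S(0)/d$, $a(0) = 0.01$, and the microRNA
level at its quasi-stationary value
$m(0) = (\gamma/\alpha)e^{-S(0)/S_0}$.  The history on $[-\tau, 0]$ is
constant at this state.

**Consequence.**  Under these initial data the CSC burden grows from
0.038 to a flat plateau near 0.042 cell mm⁻³ (the drift of the plateau
tracks the slow decay of the Wnt signal), peaks at the therapy switch-on
boundary, and declines monotonically once the kill terms act.  Reported
transient *repopulation* — a hump rising for some 40 days *after*
therapy onset — depends on the unpublished initial data and does not
occur here: we verified that with any history consistent with the
controlled branch the kill terms dominate immediately at the dose rates
of interest.  Absolute concentration values at quoted time points are
therefore not comparable; the package asserts the reproducible
signature instead — growth into the onset, peak at the onset boundary,
monotone post-onset decline, the published percent reductions
(recomputed from the published concentration pairs via
`percent_reduction()`), and the radionuclide ordering (²²⁵Ac most
effective).

### Therapy coupling

`therapy_schedule()` computes $R_{\mathrm{imm}} = \alpha_c \cdot
\mathrm{BED}$ from the LQ stack and switches it on as a *time-constant*
multiplier at `t_start` (default: the delay $\tau$, as in the standard
scenario; the two are distinct concepts and independently settable).
The constant-coupling reading matches a formulation in which a single
scalar multiplies the kill terms.  A time-resolved alternative
(`mode = "dose-rate"`, kill $\propto \alpha_c r(t-t_\text{start})
\mathrm{RE}$) is provided for exploration but is not the canonical
behavior.

## The linear-quadratic stack

All radiobiology runs in days.  The single unit bridge
(`years_to_days()`, `r0_per_day()`; factor 365, configurable to 365.25)
converts scenario dose rates given in Gy/year.  Internally every dose
rate is Gy/day; a Gy/year input divided by 365 and a Gy/day input give
bit-identical downstream results (tested).

* Effective half-times: $T_e = T_pT_b/(T_p+T_b)$,
  $T_{eu} = T_pT_u/(T_p+T_u)$, $\tau_e = T_e - T_{eu} > 0$ (requires
  $T_b > T_u$, validated at construction).
* Dose rate $r(t) = r_0(2^{-t/T_e} - 2^{-t/T_{eu}})$; total dose
  $\mathcal D = r_0\tau_e/\ln 2$ (equals the quadrature of $r$ to
  $10^{-6}$ relative, tested).
* Protraction factor $\Lambda$: the printed three-term closed form.  We
  verified it against the LQ dose-protraction double integral
  $\frac{2}{\mathcal D(\alpha_c/\beta_c)}\int_0^\infty r(t)\int_0^t
  r(t')e^{-(\ln 2/T_\mu)(t-t')}\,dt'\,dt$ by quadrature: agreement is
  $\sim 10^{-9}$ relative for all four radionuclides, so the closed form
  is canonical.
* **RE convention.**  Two inconsistent forms of the relative
  effectiveness circulate: $1 + \frac{r_0}{\ln 2}\Lambda$ (dimensionally
  odd) and $1 + \frac{r_0\Lambda}{\ln 2 (\alpha_c/\beta_c)\,
  \mathrm{OER}}$.  The package's canonical `relative_effectiveness()`
  uses the second — it is the standard LQ protraction correction and
  carries correct units ($\Lambda$ in days, $r_0$ in Gy/day,
  $\alpha_c/\beta_c$ in Gy).  The bare form is available via
  `convention = "plain"`.
* Repopulation: the $-\ln 2 (T-T_k)/(\alpha_c T_d)$ subtraction is OFF
  by default (no kick-off/doubling times are fixed by the source
  parameter set); supply `repop_params()` to enable it.
* $\mathrm{SF} = e^{-\alpha_c \mathrm{BED}}$, $\mathrm{TCP} =
  e^{-N\,\mathrm{SF}}$ with $N = \varsigma V$.  The oxygen-pressure
  density $f(P_o)$ in the averaged surviving fraction is unspecified
  upstream; `surviving_fraction()` defaults to a point mass at a given
  $P_o$ and accepts either a pdf function or the empirical histogram
  exported by `field_summaries()`.  The capillary-density label
  $\nu_c$ never enters a formula and is not carried.
* "TCP reaches 1" on a response curve is operationalized by
  `tcp_crossing()`: the smallest grid $r_0$ with
  $\mathrm{TCP} \ge 1-10^{-3}$ (threshold configurable), since no
  crossing criterion is stated upstream.  Published crossing doses could
  not be reconstructed from the stated formulas under any branch we
  tried and are reported as informational only by `reproduce_tables()`.
* The published peak dose *rates* at $r_0 = 2$ Gy/day are reproduced to
  better than 0.1 % by the closed-form maximizer; two of the published
  peak *times* (1.939 d and 2.061 d) differ from the maximizer of the
  printed dose-rate curve (2.004 d and 2.103 d) and appear to be
  figure read-offs; the package asserts the rates only.

Physical half-lives use the rounded nominal values (8 d for ¹³¹I, 10 d
for ²²⁵Ac, 64.1 h for ⁹⁰Y with 24 h/day exactly) because they reproduce
the published peak dose rates to <0.1 %; exact isotope half-lives are
available via `radionuclide_registry(exact_half_lives = TRUE)`.

## The delay integrator

`simulate_csc()` implements the method of steps: fixed-step classical
RK4 with cubic Hermite dense output (value and derivative at the step
endpoints) from which the delayed values $D(t-\tau)$, $m(t-\tau)$ are
read; for $t-\tau \le t_0$ the history function is used.  Choices:

* **Step.**  $\Delta t = 0.01$ y by default.  A warning fires when
  $\Delta t > \tau/2$ (delay under-resolved); in that regime node-exact
  lookups bypass interpolation and incomplete intervals fall back to the
  last complete one.
* **Discontinuity handling.**  Therapy is constant over each step, using
  the regime of the step's start node; the kill switch therefore enters
  exactly at the first step boundary at/after `t_start` without
  contaminating the preceding step.  This keeps the observed RK4
  convergence at order 4 (halving the step reduces closed-form subcase
  errors by ≈16×, tested) and lets the integrator agree with an
  independent adaptive DDE solver to $\sim 10^{-7}$ on therapy scenarios.
* **Positivity.**  Stage states are clamped at zero before evaluating
  the right-hand side (the model is undefined for negative
  concentrations); accepted steps are not clamped, and an excursion
  below $-10^{-12}$ raises a warning as an integrator-failure signal.
* $\tau = 0$ degrades to plain RK4 on the ordinary system, and with
  $q_0 = 0$ (delay term absent) a delayed run reproduces the undelayed
  one exactly (tested).

## Equilibria

`equilibria()` returns the three therapy-free branches with residual
annotations.  Two conventions needed fixing:

* $E^{(1)} = (0,0,0,m_1)$: $m_1$ is arbitrary for the first three
  equations; the default $m_1 = \gamma/\alpha$ also zeroes the microRNA
  equation.
* $E^{(2)} = (S_2, S_2/d, 0, m_2)$ with
  $S_2 = -S_0\ln(\alpha m_2/\gamma)$: the branch is an exact equilibrium
  only where $q(m_2) = \varepsilon d$; the default $m_2$ solves this
  balance (possible iff $q_0 > \varepsilon d$ — the origin of the
  $q_0 > d$ condition).  Any $m_2 < \gamma/\alpha$ may be supplied; the
  validity flag reports a non-positive $S_2$.
* $E^{(3)}$: the closed form for $a_3$ assumes the
  dedifferentiation-silent regime $q(m_3)\approx 0$; residuals are
  reported for its defining balances ($2p = 1$, Wnt balance, DC balance
  with $q \to 0$, microRNA balance) plus the full right-hand-side norm
  separately, which retains the neglected influx.  With the default
  $q_0 = 40$ that influx is *not* small, so $E^{(3)}$ is exact only as
  the solution of its defining system — the annotation makes the
  distinction visible rather than hiding it.

## The oxygen field

Explicit RK4 (forward Euler selectable) on the 5-point Laplacian,
101×101 nodes over a 20 mm domain ($\Delta x = 0.2$ mm),
$\Delta t = 0.01$ s, diffusion number $5\times10^{-4}$ — far inside the
0.25 stability bound, which is enforced at construction.  The Dirichlet
ring (40 mmHg capillary pressure) is re-imposed after every stage.

* **Initial condition.**  The published perturbation expression has
  unbalanced parentheses; two readings exist.  The canonical reading is
  additive, $40 + 0.1\cos((x^2+y^2-55)\pi) - 0.01\sin((x^2+y^2+91)\pi)$
  on centered coordinates $[-10, 10]^2$ (the radially symmetric argument
  produces the circular depletion patterns); the nested reading is
  available via `reading = "nested"`.  The two differ by at most the
  sine amplitude, 0.01–0.11 mmHg.
* **Coupling.**  The cell density $S+D$ is a scalar per run (1 for the
  sensitivity scenario, 0.001 for slow-depletion illustrations); a
  per-node density matrix is accepted for future coupling, but the
  canonical runs are uncoupled.
* **Verification.**  In the consumption-dominated regime the center node
  obeys the implicit 0-D law $k\ln P + P = k\ln P_0 + P_0 - C_{max}t$;
  the solver matches its bisection solution to $\sim10^{-12}$ relative
  at $t = 2$ s (tested at 0.5 % tolerance), preserves the zero-density
  steady state exactly, and is insensitive to grid refinement at the
  center to $<0.1\,\%$.

`field_summaries()` reports the interior mean (excluding the Dirichlet
ring) as its primary statistic, plus the boundary-inclusive mean, the
OER histogram in both orientations (the published histogram's axis
mapping is ambiguous), and the unit-normalized empirical pressure
density for `surviving_fraction()`.

## Sensitivity analysis

`oat_sensitivity()` uses forward differences with $\delta = +0.1\,\%$
(central differences selectable), reporting the normalized elasticity
$((Y(p(1+\delta)) - Y(p))/Y(p))/\delta$, ranked by absolute value with
an alphabetical tie-break.  Zero-valued nominals are skipped with a
message; non-finite perturbed outputs are flagged and excluded.

* **Dynamics scenario** (`csc_sensitivity_scenario()`): output is the
  final CSC concentration $S(16\,\mathrm y)$ with therapy from
  $t = \tau = 8.8964$ y at $r_0 = 50$ Gy/year.  The parameter vector
  lists both the pharmacokinetic roots ($T_p, T_b, T_u$) and the derived
  effective times ($T_e, T_{eu}$) as separate rows: a perturbed root
  propagates through the harmonic combination, while a directly
  perturbed derived time bypasses the propagation (detected by
  comparison with the nominal derived value — exact under OAT).  This
  dual treatment is a documented choice; it is the only way separate
  rows for roots and derived times can coexist without double counting.
  The reference table never names its radionuclide; we use ²²⁵Ac, the
  focal agent.  The signs of the leading indices ($T_e$ −, $T_{eu}$ +,
  $q_0$ +, $r_0$ −, $\upsilon$ −) are asserted; absolute values depend
  on the unpublished initial data and are not.
* **Oxygen scenario** (`oxygen_sensitivity_scenario()`): output is the
  mean tumor oxygen pressure at $t = 2$ s, density 1 cell mm⁻³.  The
  published index set (−1.7261 for $C_{max}$, +0.1629 for $k$, +0.0034
  for $D_{O_2}$) is reproduced to ≈0.3 % when the domain mean *includes*
  the Dirichlet boundary ring; the interior-only mean gives the same
  signs and ranking but a larger $C_{max}$ magnitude (≈−1.94).  The
  scenario therefore defaults to the boundary-inclusive mean
  (`output = "mean_all"`), with interior-only and center-node variants
  available.  Tests assert signs and ranking, which hold under every
  variant.

## Problem sizes and fixtures

The test suite runs entirely on programmatically generated inputs: the
toy configurations of `toy_params()` (21×21 oxygen grid, pure-decay
dynamical submodel, hand-checkable LQ set), full-resolution single runs
where the verification target demands it (the 101×101 oxygen oracle
check, the four 16-year therapy trajectories, a 6-elasticity dynamics
sensitivity), and closed-form or quadrature oracles computed in the
tests themselves.  The whole suite completes in well under a minute on
one core.  What passing tests show: internal consistency of the
formulas, order-4 convergence of the integrator, agreement with
independent numerical oracles, and reproduction of the published
checkable surface (peak dose rates, percent reductions, orderings,
sensitivity patterns).  What they cannot show: agreement with the
unpublished absolute trajectories, or fidelity of the biology itself.

## Known limitations

* No vascular geometry, perfusion heterogeneity, nutrient gradients or
  pH in the oxygen model; diffusion–consumption only.
* No decay-chain dosimetry for ²²⁵Ac daughters and no LET
  microdosimetry; radiation quality enters only through
  $\alpha_c, \beta_c$.
* The recurrence time $\tau_c = 11.8964$ y is treated as a scenario
  constant, not a computed quantity (no defining criterion is stated
  for it upstream).
* Local OAT sensitivity cannot capture parameter interactions; a global
  method is out of scope.
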