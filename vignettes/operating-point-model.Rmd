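---
title: "The operating-point model of body-fat regulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The operating-point model of body-fat regulation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatop)
```

## The model and its assumptions

`fatop` implements a minimal feedback model of body-fat regulation on the
timescale of days to weeks (not the meal timescale). Fat mass $F$ gains
from food intake $u$ at conversion rate $a_F$ and is lost to its own
maintenance cost $\gamma_F F$ and to the body's other energy costs
$\gamma_E$:

$$\frac{dF}{dt} = a_F u - \gamma_E - \gamma_F F.$$

Leptin $L$ is produced by fat in proportion to *recent food intake*
($a_L F u$) and cleared at rate $\gamma_L$; leptin suppresses intake
through a Hill function with half-effect $K_L$ (which rises with leptin
resistance), steepness $n$, and a ceiling $u_{max}$ (maximal "satiety"
intake):

$$\frac{dL}{dt} = a_L F u - \gamma_L L, \qquad
  u = \frac{u_{max}}{1 + (L/K_L)^n}.$$

Three consequences organise the whole package:

1. **Diet line.** At fixed intake, $dF/dt = 0$ gives
   $u = (\gamma_F F + \gamma_E)/a_F$ — rising.
2. **Appetite line.** Leptin clears fast (half-life tens of minutes), so
   $L \approx (a_L/\gamma_L) F u$; substituting into the intake rule gives
   $F = (\gamma_L K_L / a_L)\, u^{-1} (u_{max}/u - 1)^{1/n}$ — falling.
3. **Quadratic leptin line.** Composing the quasi-steady leptin with the
   diet line gives $L = \frac{a_L}{\gamma_L a_F} F(\gamma_F F + \gamma_E)$,
   i.e. an approximately quadratic leptin–fat relation across a
   population. This is a direct consequence of leptin production
   depending on intake as well as fat; a fat-only production term would
   predict a linear relation.

The operating point is the intersection of lines 1 and 2. In the steep
limit $n \to \infty$ it is closed-form in two regimes: *above-critical*
($K_L \le K_{crit}$), where $F^*$ is the positive root of
$\gamma_F F^2 + \gamma_E F - a_F K_L \gamma_L / a_L = 0$, intake is
$K_L \gamma_L/(a_L F^*)$ and $L^* = K_L$ exactly; and *satiety-capped*
($K_L > K_{crit}$), where $u^* = u_{max}$ exactly and
$F^* = (a_F u_{max} - \gamma_E)/\gamma_F$. The boundary $K_L = K_{crit}$
is assigned to the above-critical regime (a closed-interval convention;
the two solutions coincide there, which the tests assert). The published
closed forms for the above-critical root print a denominator that does
not follow from equating the two lines, so the package derives the root
from the intersection and cross-validates every solution against an
independent bisection oracle (`operating_point_numeric()`, relative
tolerance $10^{-8}$, enabled by default) rather than transcribing a
printed expression.

## Parameters, units and presets

All quantities are in the source analyses' arbitrary units (fat mass,
intake mass/day, leptin concentration); time is a dimensionless model
unit. The published unit note ties time to leptin turnover but is
ambiguous, and every in-scope result is unit-free, so the package treats
time as dimensionless and leaves any minutes-per-unit conversion to the
user. The default set is `aF = 0.02`, `gammaF = 0.025`,
`gammaE = 0.00625`, `aL = gammaL = 1`, `KL = 0.5`, `umax = 2`, with
$n = \infty$ for closed-form analysis. `op_preset()` ships every column
of the published parameter table by figure label, keeping swept
parameters as `[lo, hi]` ranges expanded on demand. One shipped value is
internally inconsistent in the source: the `fig5F` column lists
`KL = 3.6` although the stated rule "twice the critical resistance"
yields a different number for every reading of that column; the preset
records the printed 3.6.

Two further constructions are the package's own:

* `harris_like` — a *synthetic calibration* in fold-of-control units
  emulating the rat refeeding experiment: operating point at $(1,1)$,
  diet-line groups $a_F/\gamma_F = 1.5$ and $\gamma_E/\gamma_F = 0.5$, a
  20-day fat time constant (so a 40%-fed group ends a 20-day controlled
  phase near 0.43 of control fat, as the rats did), ceiling
  $u_{max} = 1.38$ and steepness $n = 7.1$ as estimated from that
  experiment, with $K_L$ pinned by requiring the appetite line to pass
  through $(1,1)$.
* `with_fast_leptin()` — multiplies $a_L$ and $\gamma_L$ by a common
  factor (default 25). This leaves the quasi-steady leptin level, both
  lines and the operating point *exactly* unchanged and only speeds the
  fast variable. With the dimensionless defaults ($\gamma_L = 1$ per
  time unit) leptin turns over on the same timescale as a one-day output
  step, which contradicts the model's own quasi-steady premise; the
  rescaling restores the physiological separation (leptin half-life of
  tens of minutes against a one-day grid) wherever a test or measurement
  relies on intake having reached the appetite line "within the first
  day".

## Dynamics

`simulate_dynamics()` integrates the two-state system with `deSolve`
(lsoda; `rtol = 1e-8`, `atol = 1e-10`) at finite steepness
`n_dynamics = 100` — steep enough to track the $n\to\infty$ analysis while
keeping the right-hand side smooth. Leptin starts at its quasi-steady
level for the initial $(F, u)$ unless overridden, since the recovery
protocols start from a maintained feeding state; a `quasi-steady` mode
eliminates leptin algebraically, which puts intake exactly on the
appetite line at every step. The Hill power is evaluated in log space
with the exponent capped at 700, so very steep terms saturate to a huge
finite number instead of overflowing.

`detect_transient()` classifies the intake course relative to its final
value, oriented by the pre-perturbation intake: approaching from below,
an excursion above the final value beyond `eps_rel = 0.01` is an
overshoot; from above, below it, an undershoot. The threshold is far
below the ~80% overshoots the model produces and far above integrator
noise. A trajectory whose intake still moves by more than $10^{-4}$
(relative) over the last 10% of the horizon is reported `inconclusive`,
never guessed. The default horizon is 50 time units (the published
simulation length), but the slowest mode of the default set relaxes at
about $0.06$/unit, so ~4% of an initial deviation remains at 50 units;
classification and convergence checks therefore use a 400-unit horizon,
where trajectories reach the operating point to well under 1%.

## The intervention rule engine

`line_membership()` assigns $a_F, \gamma_F, \gamma_E$ to the diet line
and $a_L, \gamma_L, K_L, u_{max}, n$ to the appetite line. $a_L$ and
$\gamma_L$ also scale the leptin line, but leptin is not an axis of the
(fat, intake) portrait, so they are classified where they act on feeding.
`classify_intervention()` computes operating points before and after a
change at the *same finite steepness* as the confirming simulation (so
the initial state is exactly a fixed point of the pre-change dynamics),
predicts the transient from whether the old operating point lies on the
new appetite line (relative tolerance $10^{-6}$), confirms by simulation,
and raises any prediction/simulation disagreement or breach of the
structural rules as a diagnostic warning rather than resolving it
silently.

The battery runs at steepness $n = 7$, the value fitted to rat refeeding
data, not the display default 100. The reason is scientific rather than
numerical: at $n = 100$ the appetite line is indistinguishable from the
$n\to\infty$ hyperbola, on which $u_{max}$ does not move the operating
point in the leptin-sensitive regime at all — yet the satiety-ceiling
interventions (dietary fibre, gastric bypass, diet variety) demonstrably
move fat and intake in rodents. The finite empirical steepness is what
gives those rows their direction. In the satiety-capped regime
appetite-parameter changes genuinely leave the operating point unmoved;
the engine reports both directions as 0 and flags the regime explicitly
rather than calling it a rule breach.

## Fitting pipelines

**Normalization.** Growing animals gain weight throughout an experiment,
and tube feeding itself is aversive; expressing every series as a
fold-change of the interpolated control removes both (the generator's
growth trend is multiplicative for exactly this reason — it provably
cancels). Series are linearly interpolated onto an integer-day grid
before division; a control that does not cover a group's days is an
error naming the gap.

**Phase points.** One diet point per controlled group: the phase-mean
relative intake (tube-fed intake is constant, so the mean is the
delivered fraction) against the final controlled-day relative fat. The
control group contributes $(1,1)$ by construction. Appetite points pool
every recovery day across all groups (the published point count is
consistent with pooling); no weighting is applied.

**Estimators.** Both lines are fitted with fat as the response, matching
the printed equation forms: the diet line by OLS ($F = a u - b$; with
only two points the SDs are flagged unavailable, as in the original
analysis), the
appetite line by bounded Levenberg–Marquardt on
$F = c\,u^{-1}(u_{max}/u - 1)^{1/n}$, multi-started over
$n_0 \in \{2, 5, 10, 20\}$ with $c > 0$, $n \ge 1$ and $u_{max}$ above
the largest observed intake. The leptin–fat fit compares the
no-intercept quadratic $L = a_q F^2 + b_q F$ against the linear $L = cF$
using the Gaussian-RSS AIC, $N\log(RSS/N) + 2k$, without the additive
constant — only AIC *differences* are meaningful under this convention,
so the report always prints $\Delta$AIC, and absolute published AIC
values are matched only up to convention. Pearson $r^2$ is computed on
$L$ (not $\log L$). The preference is invariant to rescaling both axes,
which the tests assert directly.

## Sensitivity analysis

For each steady-state variable the other two are eliminated
algebraically, leaving one characteristic residual whose root is that
variable's steady state; the roots agree with the line intersection to
$10^{-8}$. Log-sensitivities
$\partial \log X^* / \partial \log p$ come from the implicit function
theorem, with both partials of the residual taken by central differences
at relative step $10^{-6}$ — the printed closed-form derivative is long
and typo-prone, and its structure is validated instead by an independent
finite-difference oracle: re-solving the steady state at
$p(1 \pm 10^{-4})$ and differencing the logs. The two routes agree to
better than $10^{-4}$ relative everywhere on the default grid
$n \in \{2, 4, 7, 10, 20, 50, 100\}$ in both regimes (baseline, and
"high-resistance" with $K_L$ replaced by $2K_{crit}$); agreement is
assessed relative to the larger magnitude with a $10^{-6}$ absolute floor
for sensitivities that vanish identically (in the satiety-capped regime
several partials underflow to exact zeros). At $n = 100$ the profiles
reproduce the analytic steep-limit patterns: leptin tracks $K_L$ with
unit log-sensitivity and intake is insensitive to $u_{max}$ in the
baseline regime; the roles swap in the high-resistance regime.

## Earlier leptin-based models

For structural comparison, `tam_lines()` and `jacquier_lines()` derive
diet and appetite curves from two earlier model families: a
brain-leptin-transport model (saturable plus linear entry into the brain,
leptin-amplified expenditure, constant fat-free mass) and a
body-composition model (Forbes-type fat/fat-free-mass coupling, Hill
leptin-receptor response with fixed receptor density). Their original
calibrated parameter tables are not reprinted in the source analyses, so
the shipped defaults are *representative synthetic sets* chosen to
exercise the structural claims — rising diet curve, falling appetite
curve, a unique intersection, correct algebraic limits — and every test
on these curves is structural, never value-exact. Both constructors
accept full overrides so calibrated values can be supplied. Neither
model makes leptin production depend on recent intake, so neither
reproduces the quadratic leptin–fat relation; the package makes no claim
otherwise.

## The synthetic-data generator

`generate_feeding_experiment()` emulates the tube-feeding protocol: one
group per feeding fraction (defaults 0.4, 1.0, 1.6 of control intake;
the fraction-1 group *is* the control, so tube-feeding artefacts cancel
under normalization), a 20-day controlled phase, 30 days of ad-libitum
recovery, a shared multiplicative growth trend (default 1.005/day, a
realistic juvenile-rat growth rate; any positive rate cancels exactly
under normalization), and lognormal measurement noise (default
$\sigma = 0.05$, positivity-preserving, on intake and fat). Fat can
optionally be emitted only on sparse measurement days, mimicking real
body-composition sampling. Recovery intake is simulated in quasi-steady
leptin mode — daily sampling cannot resolve the sub-day leptin transient
— at steepness `hill_n = 7.1`, the value estimated from the rat data.
That choice matters: at steepness 100 the simulated appetite relation is
effectively the limiting hyperbola, whose fit parameters $(u_{max}, n)$
lie on a flat likelihood ridge, and the generator would produce data
from which the analysis pipeline cannot recover its own parameters.

Each experiment carries its exact zero-noise ground truth as an
attribute: the fold-change appetite-line parameters (exact at any phase
length) and the diet-line slope/intercept both asymptotically and at the
finite phase — after $T_c$ days of controlled feeding the end-of-phase
fat has completed only $1 - e^{-\gamma_F T_c}$ of its relaxation, so the
measured diet points are exactly affine in intake but with a shrunken
slope (`a_phase`). This is a property of the protocol, not a pipeline
artefact, and the recovery tests compare estimates against it.

**What passing tests do and do not show.** Under the default preset, the
noiseless pipeline recovers every line parameter to $10^{-6}$, and across
100 noisy replicates the diet-line parameters and the appetite scale $c$
are recovered without detectable bias, with reported SDs bracketing the
truth at their $t$-based nominal coverage (three diet points leave one
residual degree of freedom, for which 3-SD coverage is 90.5%, not 99.7%).
The satiety ceiling $u_{max}$, however, is *not identified* under these
study conditions: the default ceiling sits at 2.07 times steady intake
and the protocol's fat excursions never push relative intake near it, so
per-replicate estimates are heavy-tailed along the ridge (medians far
above the truth), even though the estimator shows no bias beyond its —
enormous — Monte-Carlo error and is exact in the noiseless limit.
Emulating the real experiment's deep depletion instead (the
`harris_like` calibration) places recovery points on the near-vertical
branch of the appetite line, where 5% intake noise acquires unbounded
leverage in a fat-response fit and degrades $c$/$u_{max}$ coverage in a
different way. Tight ceiling estimates of the published kind therefore
require data that graze the ceiling without dwelling on the vertical
branch; neither failure mode is hidden by the tests, and the steepness
$n$ shares the same ridge (its published SD, more than half its value,
says as much). Real data differ from the generator in further ways the
tests cannot probe: measurement error on intake is likely
autocorrelated, fat is measured sparsely and destructively in real
designs, and fat-free mass dynamics are absent from the model.

`generate_leptin_population()` draws one parameter per individual
(default: $K_L$, lognormal $\sigma = 0.5$, giving roughly the 2.5-fold
95% fat range seen in population scatters), solves each operating point
in closed form, and adds lognormal measurement noise ($\sigma = 0.1$) to
leptin. When only appetite-line parameters vary, every operating point
lies exactly on the quadratic leptin line, so the zero-noise scatter
traces it perfectly — the package's route to the population quadratic;
varying diet-line parameters scatters points orthogonally to the curve.
Infeasible draws (no positive steady state) are skipped with a reported
count.

## Numerical choices

* Finite-steepness appetite inversion: bracketed root-finding on
  $(10^{-12} u_{max},\, u_{max}]$, tolerance $10^{-10} u_{max}$; the
  fixed-point map is monotone, so the root is unique.
* Operating-point bisection bracket: $(\sim 0,\ (a_F u_{max} -
  \gamma_E)/\gamma_F]$, the largest fat any feasible steady state can
  sustain; infeasibility ($a_F u_{max} \le \gamma_E$) is an explicit
  error at construction and solve time.
* Steady-state residual brackets extend to the exact regime endpoints
  ($u_{max}$ itself for intake), because in the satiety-capped regime the
  root sits within machine precision of the endpoint.
* Infinite steepness is an explicit flag (`n = Inf`), never a huge float;
  the fat line at $L = K_L$ takes the high branch (same closed-interval
  convention as the regime boundary).
* Negative fat-line values are returned as-is and flagged
  ("diminished fat stores") rather than clipped: the negative branch is a
  mathematically valid solution describing lean-mass breakdown.
* Problem sizes in the test suite were chosen to keep the full run around
  half a minute: 1000 random parameter draws for the oracle-equivalence
  property, 100 synthetic replicates for recovery, 50-draw spot checks
  elsewhere.

## Known limitations

The model omits fat-free-mass dynamics, adaptive thermogenesis and any
mechanism of tube-feeding aversion (handled only via control
normalization); intake units are abstract, so gram/calorie conversion
under food-composition changes is left to the user. The legacy-model
parameter sets are synthetic stand-ins, and value-level reproduction of
the corresponding published curves is out of scope. The sensitivity
analysis is local (log-derivatives at a point), not variance-based.
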