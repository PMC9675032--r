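---
title: "Mechanics of the Ndc80-microtubule link: models, estimator, and validation"
author: "ndc80link authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of the Ndc80-microtubule link}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndc80link)
```

This vignette is the package's account of its science: the estimator
and the elastic models it implements, the assumptions behind them, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was
genuinely open.  Every number quoted here is computed by the package's
own tests or scripts; nothing is asserted that the code does not
reproduce.

## 1. The measurement model: interval-wise equipartition

A bead of friction coefficient $\gamma$ held in an optical trap of
stiffness $c_\mathrm{trap}$ and coupled to a microtubule (MT) tip
through an elastic link fluctuates about its mechanical equilibrium
with variance $k_BT/c_\mathrm{tot}$, where $c_\mathrm{tot}$ is the
total restoring stiffness at the operating point.  When the MT
depolymerises, the equilibrium position itself drifts, so a plain
variance over any long window conflates drift with fluctuation.  The
estimator therefore cuts the 10-kHz trace $x(t)$ into intervals of
$\Delta t = 0.1$ s (1000 samples each; a trailing partial interval is
dropped so every interval has the same weight), fits a straight line
$f_k(t)$ to each interval as a local model of the quasi-equilibrium
drift, and inverts the residual variance:

$$c_k = \frac{k_BT}{\langle (x_k(t) - f_k(t))^2 \rangle}, \qquad
  F_k = c_\mathrm{trap}\,\langle x_k \rangle .$$

*Assumptions.* (i) The bead relaxation time $\tau = \gamma/c$ is
0.1–1 ms, so a 0.1-s interval holds $\sim \Delta t/2\tau \approx$
100–1000 independent displacement samples — long enough for a usable
variance, short enough to resolve the force ramp.  (ii) Drift within an
interval is approximately linear; the linear detrend removes any
deterministic ramp *exactly* (a property test adds ramps of 25 and
−300 nm/s and requires the $c_k$ to change by $<10^{-9}$ relative).
(iii) The trap force calibration is linear, which holds only within
200 nm of the trap centre — hence the excursion exclusion.

The mean squared residual uses divisor $N$ (the plain mean), not
$N-2$: at $N = 1000$ the difference is below 0.2%, far beneath the
statistical scatter of a single interval.

*Exclusions and state labels.* Intervals with
$|\langle x_k\rangle| > 200$ nm are flagged `excursion`.  Detachment is
detected as an abrupt (one-interval) return of
$\langle x_k \rangle$ from beyond 50 nm to within
$2\sqrt{k_BT/c_\mathrm{trap}}$ of the centre; all later intervals are
labelled `detached` (they measure the bare trap).  MT states are
assigned from the trend slope, smoothed by a 5-interval running median:
shrinking above $+v_\mathrm{stall}$, growing below $-v_\mathrm{stall}$,
stalled in between, with $v_\mathrm{stall} = 5$ nm/s.  No published
rule exists for this classification; the threshold and window are this
package's choice, and the per-interval slope noise sets its accuracy —
at stall stiffness $\sim$0.25 pN/nm the smoothed slope scatter
misclassifies only a few percent of stalled intervals (tested), but at
0.1 pN/nm the same threshold would misclassify a substantial fraction,
so state-resolved results at low stiffness deserve caution.

## 2. Elastic elements

Each element implements the same contract: extension $z(F)$ (nm) and
differential stiffness $c(F) = (dz/dF)^{-1}$ (pN/nm), mutually
consistent to $10^{-3}$ relative or better (tested by central
differencing for every element).

### 2.1 Ndc80 as a confined two-bond freely jointed chain

The complex is two stiff arms, $a = 40$ nm (bead side) and $b = 16$ nm
(MT side), meeting at a free hinge.  The micron-sized bead is modelled
as a plane that confines the chain to a half-space: the hinge height
$z_a$ and the total extension $z = z_a + z_b$ must both be positive.
The only energy is $-F(a\cos\theta_a + b\cos\theta_b)$.  The natural
120° cap on the inter-arm angle is deliberately not enforced: under
confinement plus tension the chain is already biased to small angles,
and dropping the cap is what makes a closed form possible.

Writing $f = F/k_BT$, the angular integrals collapse to
$Z \propto D(f)/f^2$ with
$D = 2e^{fa}\sinh(fb) - e^{fb} - fb + 1$, and $z(F)$ and $c(F)$ follow
from the first two logarithmic derivatives of $Z$.  Numerically the
closed form is evaluated in two regimes:

* $f(a+b) \ge 0.02$: all exponentials are rescaled by $e^{-f(a+b)}$ so
  that every term decays — stable to arbitrarily large force (no
  overflow guard needed; tested to $10^4$ pN).
* $f(a+b) < 0.02$: $D/f^2$ is an indeterminate $0/0$; a fifth-order
  Taylor expansion of $g(f) = D/f^2$ takes over.  The two branches
  agree to better than $10^{-3}$ relative at the switch (tested).

Anchors: the crossover force $k_BT/b = 0.256$ pN; the strong-force laws
$z = a + b - 2k_BT/F$ and $c = F^2/2k_BT$ (within 1% at 10 pN); and the
Boltzmann-averaged inter-arm angle at 1 pN, $43.9^\circ \pm 23.7^\circ$
by 3-D Gauss–Legendre quadrature, which rounds to the $44^\circ \pm
23^\circ$ the model is known for.  An exact Monte Carlo sampler
(`sample_fjc()`, inverse-CDF draws from the tilted marginals plus a
single rejection for the coupled constraint) provides the independent
cross-check for all of these, including the fluctuation identity
$c = k_BT/\mathrm{Var}(z)$.

### 2.2 Microtubule as an entropic worm-like chain

For forces far above $k_BT/L_p \sim 10^{-6}$ pN the WLC extension is
$z/L = 1 - \sqrt{k_BT/4FL_p}$, giving
$c_\mathrm{MT} = (4/L)\sqrt{L_p/k_BT}\,F^{3/2}$ — an exact 3/2
stiffening exponent.  The persistence length of a grafted MT is length
dependent, $L_p = L_{p\infty}/(1 + L_0^2/L^2)$ with $L_{p\infty} =
6.3$ mm and $L_0 = 21\ \mu$m, which makes $c_\mathrm{MT}$ nearly
length independent for $L \ll L_0$ (3 µm vs 10 µm differ by under
10%); $L = 10\ \mu$m is the package default.  Forces below
$10^{-3}$ pN are rejected as outside the model's validity.  Mechanical
(enthalpic) stretching and unbending of the MT are far stiffer than
anything measured here and are not modelled.

### 2.3 Protofilament flare as an elastica

A protofilament peeling off the MT tip has spontaneous curvature
$\varphi$ (20° per 8-nm dimer $= 0.0436$ rad/nm — this conversion is
what makes the closed-form stiffness dimensionally consistent and
reproduces the expected force scale $\alpha/s_0^2 \sim 0.3$–2 pN) and
bending stiffness $\alpha = k_BT L_p$ with $L_p = 200$ nm.  An Ndc80
complex attached at arc position $s_0$ (20 or 50 nm; $s_0$ must not
exceed the 10–80 nm flare length) pulls along the MT axis, and the
energy-minimising shape solves the pendulum equation
$\ddot\theta = (F/\alpha)\sin\theta$ with $\theta(0) = 0$,
$\dot\theta(s_0) = \varphi$.  Thermal fluctuations of the flare are
neglected: bending and stretching energies dominate at these forces.

The boundary-value problem is solved by shooting on the unknown base
curvature $\dot\theta(0)$ with fixed-step RK4 (400 steps).  Two
numerical points matter:

* **Branch selection.** The pendulum equation admits over-the-top
  solutions that also satisfy the boundary conditions; naive
  bracketing finds them (at 30 pN one lands on a branch with
  $\theta(s_0) \approx 6.5$ rad and a stiffness wrong by two orders of
  magnitude).  The solver instead scans candidate base curvatures
  upward from zero on a log grid and bisects the *first* sign change,
  which is the minimal-bending physical branch; a direct numerical
  minimisation of the discretised energy functional confirms the
  choice (energies agree to $10^{-4}$ relative, tested).
* **Log-space root finding.** The physical root scales as
  $\varphi/\cosh(s_0\sqrt{F/\alpha})$ and falls below $10^{-17}$ at a
  few hundred pN, beyond the absolute tolerance of a linear bisection;
  the bisection therefore runs in $\log \dot\theta(0)$.

The deflection is $z_0 = \int_0^{s_0}\cos\theta\,ds$ (Simpson on the
RK grid) and $c_\mathrm{PF}$ is its inverse central-difference
derivative (relative step $10^{-3}$).  In the strong-force limit the
linearised equation gives
$c_\mathrm{PF} \approx 8F^{5/2}/3\varphi^2\alpha^{3/2}$; the shooting
solution matches this within 0.5% at 30 pN and its local log–log slope
is $2.50 \pm 0.01$ there.

### 2.4 PEG tether as a two-state extended FJC

Each PEG monomer switches between a short helical (0.28 nm) and a long
planar (0.358 nm) conformer; tension tilts the free-energy gap
$\Delta G(F) = \Delta G_0 - F\,\Delta L$ with $\Delta G_0 = 3\,k_BT$.
The chain extension combines the Boltzmann-weighted effective segment
length, a Langevin-function orientation factor, and a serial backbone
elasticity of 150 N/m per segment; PEG-2000 has $N_S = 45$ monomers.
The published parameter set fixes everything except the Kuhn length in
the orientation factor; using the monomer length itself gives a
force-free stiffness of 3.4 pN/nm, incompatible with the 1.38 pN/nm the
model is anchored to, whereas the PEG literature value of 0.7 nm
reproduces it ($c(0) = 1.376$, printing as 1.38).  The package adopts
0.7 nm, fixed once.  Since even the force-free value is an order of
magnitude above any measured link stiffness, the PEG (and the yet
stiffer PLL backbone it hangs from) is omitted from the default
composite; the element exists to demonstrate exactly that.

## 3. Composition and the attachment-number envelope

Elements in series share tension, so compliances add; $n$ parallel
linker chains share force equally, $c_n(F) = n\,\tilde c(F/n)$.  For a
power-law linker $\tilde c \propto F^m$ this equals
$\tilde c(F)\,n^{1-m}$: parallel attachment *softens* the link whenever
$m > 1$, which both the Ndc80 chain ($m = 2$) and the flare
($m = 5/2$) satisfy.  The measured total is
$c_\mathrm{tot}(F) = c_\mathrm{trap} + \big(1/n\tilde c(F/n) +
1/c_\mathrm{MT}(F)\big)^{-1}$, the trap acting in parallel because it
holds the bead from the opposite side; its force dependence is
negligible and it is treated as constant.  The unquantified
Ndc80–MT bond stiffness is representable as a rigid placeholder so the
architecture is complete without inventing numbers.

`envelope_nmin()` minimises the trap-free stiffness over integer
$n \in [1, 50]$ for each force on a grid over 0.5–6 pN — the force
window of the stall experiments; the grid is a package constant, kept
configurable because the examined range is not sharply defined.  Ties
break toward smaller $n$.  For the $s_0 = 50$ nm composite the
minimiser grows from 1 to 12 across the window, non-decreasing and
approximately linear ($R^2 > 0.99$) — a linearly increasing $n(F)$ is
the quasi-static signature of a catch bond, and by
$F/n(F) = \mathrm{const}$ it converts any linker exponent into overall
*linear* stiffening.  A decreasing (slip-bond) $n(F)$ does the
opposite: `slip_bond_exponent()` verifies that $n \propto 1/F$ with a
quadratic linker yields an effective exponent of 3.  For efficiency the
exhaustive search evaluates the single-chain stiffness through a
monotone log–log spline on 80 nodes (interpolation error $\sim
10^{-6}$; a direct-evaluation mode exists and is tested to agree).

## 4. Semiflexible arms

`wormlike_stiffness()` relaxes the rigid-arm idealisation: each arm
becomes a discrete WLC of 8 segments with bending constant
$k_BT L_p^\mathrm{arm}/\ell$ per joint, free hinge between arms, same
half-space constraints, tension $F$.  The Metropolis move set mixes
local segment-cone proposals with a Gibbs rotation of a whole arm whose
new global orientation is drawn *exactly* from the tilted Boltzmann
marginal of the arm's end-to-end vector — this move is rejection-free
apart from the half-space constraints and is what keeps the chain
mixing in the stiff-arm limit, where small random rotations freeze.
100 replicas run in parallel (60 000 retained samples at the default
settings); the stiffness comes from $c = k_BT/\mathrm{Var}(z)$ with a
between-replica standard error, and a Geweke-style diagnostic on the
replica-mean trajectory warns if equilibration is suspect.

In the rigid limit ($L_p^\mathrm{arm} = 10^4$ nm) the sampler agrees
with the closed-form FJC stiffness within 5% (tested across seeds; the
residual scatter is sampling error, not bias).  At coiled-coil-like
$L_p^\mathrm{arm} = 150$ nm the stiffness at 1 pN moves by well under
10% — semiflexibility of the arms is a minor correction, which is why
the rigid two-bond chain is an adequate model of the complex.  The
30% tolerance used in the corresponding test is deliberately loose; it
encodes "minor effect", not a precise prediction.

## 5. The synthetic-trace generator

`simulate_trace()` emulates the recordings the estimator was designed
for: a bead with Stokes friction $\gamma = 8.4\times10^{-6}$ pN·s/nm
(1-µm bead in water) in a trap of 0.02–0.04 pN/nm, connected to an MT
tip through the composite link, sampled at 10 kHz.  The link enters
through its force–extension table, built by integrating the composite
compliance on a 400-node log grid up to the largest force the schedule
can reach plus a thermal margin, with a linear slack ramp to zero force
(a tether cannot push).  The tip follows a schedule: shrink at
$v_\mathrm{shrink}$ (default 25 nm/s), stall when the link force
reaches the commanded stall force, rescue/catastrophe/detachment at
configured times or forces.  Two implementation details matter and are
worth stating plainly:

* **Integrator.** Each 1-µs substep advances the *locally linearised*
  dynamics with the exact Ornstein–Uhlenbeck update (exponential
  integrator) rather than plain Euler–Maruyama.  EM at this step size
  biases the stationary variance by $+c\,\delta t/2\gamma \approx 2\%$
  at the stall operating point — a bias the equipartition estimator
  would faithfully report, corrupting the very validation the
  simulator exists for.  The exponential update is unconditionally
  stable and variance-unbiased; its only approximation is freezing the
  link slope across one substep (the bead moves $\sim$1 nm per
  substep, over which the tabulated slope is effectively constant).
  The step-stability bound $\delta t \le 0.1\gamma/c_\mathrm{max}$ is
  still enforced, now as a guard on linearisation quality.
* **Force triggers are filtered.** The instantaneous link force
  fluctuates thermally by $\sim$1 pN; a stall threshold on the raw
  force fires seconds early.  Stall and force-detachment triggers
  therefore act on an exponential moving average with a 10-ms time
  constant, giving commanded forces their quasi-static meaning.

The detector model defaults to instantaneous decimation to 10 kHz.  A
boxcar window is available and follows the exact OU attenuation factor
$(2/r^2)(r - 1 + e^{-r})$, $r = T_\mathrm{avg}/\tau$ (tested to 1%):
a full-sample-period boxcar already costs several percent of the
variance once the corner frequency is within an order of magnitude of
the Nyquist frequency, so an integrating-detector assumption is *not*
innocuous — decimation is the faithful default for a fast quadrant
detector.  Optional additive white noise emulates the detector floor;
it is a free knob, not a calibration, since the original instrument's
noise floor is unknown.

The attachment count $n$ is constant within a trace, consistent with
the observation that stiffness–force relations coincide before and
after a rescue.  `make_experiment_set()` varies stall forces and
schedules across traces to echo the four canonical single-experiment
behaviours (stall then detach, early detach, stall then rescue, and
non-stiffening lateral attachment, the last modelled by a
constant-stiffness link), with child seeds derived deterministically
from one master seed.

*What the generator does not emulate:* 3-D bead motion and rotation,
QPD voltage nonlinearity, trap anharmonicity, protofilament ensemble
kinetics, force-velocity coupling of depolymerisation (stall is a
velocity clamp, not a mechanochemical model), instrument drift, and
any force dependence of attachment number within a trace.  Passing the
recovery tests therefore shows that the *estimator* is faithful to the
modelled physics; it cannot certify robustness to instrument
artefacts absent from the model.

## 6. What the estimator measures, exactly

For a *linear* link the stationary bead variance is $k_BT/c_\mathrm{tot}$
and the interval estimator recovers $c_\mathrm{tot}$ directly (tested
against the exact OU recursion: 100 intervals recover 0.10 pN/nm
within 5%).  For a *stiffening* link the bead fluctuates in an
anharmonic well, and the exact ensemble stiffness
$k_BT/\mathrm{Var}(x)$ lies a few percent *below* the tangent
stiffness $c_\mathrm{tot}(\bar F)$ — thermal excursions sample the
soft side of the well more compliantly.  The package exposes this
quantity as `equipartition_stiffness()`, a direct Boltzmann integral
over the bead coordinate, independent of any simulation.  The headline
validation — a 30-s shrink-to-stall experiment at $\sim$4 pN,
estimator bins vs model — holds to within 2 SEM per 1-pN bin against
this ensemble stiffness, and within 5% against the tangent curve.
Conflating the two would produce an apparent several-SEM "bias" at the
stall bin that is in fact physics: variance-based stiffness estimates
are systematically soft for stiffening springs, one reason such
measurements tend to undershoot model predictions.

## 7. Robust power-law characterisation

Measured relations are summarised by $c(F) = aF^m + c_0$, fitted by
minimising the Huber loss so that sporadic gross outliers (e.g.
transient multi-linker events) do not drag the exponent: with 10%
outliers at 10× stiffness the Huber fit recovers $m$ within 0.1 while
least squares misses by four times as much (tested).  Numerically, for
each candidate $m$ the linear parameters $(a, c_0)$ are profiled out
exactly — IRLS with the Huber weights, active-set clamping at the
bounds — and the profiled loss is minimised over $m$ alone, bracketed
by a start grid $\{0.5, 1, 1.5, 2, 3\}$; this makes noiseless recovery
exact to ~10 significant digits and the fit scale-equivariant.  The
Huber threshold is $1.345 \times 1.4826\,\mathrm{MAD}$ of the
residuals, iterated once on the robust fit's own residuals; when the
scale collapses (noiseless data) the fit falls back to plain least
squares, and when no residual exceeds the threshold the two coincide
(a property test constructs bounded noise to verify this).  Bounds:
$a > 0$, $0 < m \le 5$, $0 \le c_0 \le 0.05$ pN/nm — the offset
absorbs the trap stiffness.

Per-experiment exponents require $\ge 10$ usable intervals ($\ge 1$ s
attached) and, optionally (default on), a one-sided Spearman screen
($p < 0.05$) that drops experiments without recognisable stiffening —
the published analyses excluded laterally attached, non-stiffening
recordings, but stated no criterion, so this screen is a stand-in and
can be switched off.

## 8. Problem sizes and determinism

The test suite and acceptance script run, by design, at sizes a
laptop handles in minutes: quadratures at 200–300 nodes per dimension
($10^{-8}$-level convergence), $2\times10^5$–$10^6$ Monte Carlo
samples, Metropolis runs of $1.8\times10^6$ total moves, Langevin
traces of 6–30 s at 1-µs substeps, experiment sets of 3–11 traces.
Every stochastic path is seeded: identical seeds give bit-identical
traces, sample streams and experiment sets (tested), and the
acceptance script consumes a single `--seed` for all of its
randomness.

## 9. Known limitations

* The Ndc80–MT *bond* stiffness is structurally present but
  unquantified (rigid by default); absolute composite stiffnesses are
  therefore upper bounds.
* The estimator's state classification is a threshold rule, not an
  inference; near the stall threshold its labels are noisy at low
  stiffness (§1), and no hand-annotation path is provided.
* The envelope treats $n$ quasi-statically; no kinetic attachment /
  detachment model is included.
* The PF model is deterministic (no thermal flare fluctuations) and
  assumes a point attachment at fixed $s_0$.
* The WLC microtubule formula is the strong-force expansion; it is not
  valid below $\sim10^{-3}$ pN and the code refuses to evaluate it
  there.
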