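# ndc80link

Stiffness time-tracing and structure-based elastic models of the
Ndc80–microtubule link.

## The problem

In the mitotic spindle, chromosomes are coupled to dynamic microtubule
(MT) ends by Ndc80 complexes — ~56 nm rod-like proteins with a flexible
kink that splits them into a 40-nm and a 16-nm arm.  In optical-trap
assays, an Ndc80-coated bead tracks a depolymerising MT end against the
trap load; the elastic stiffness of the bead–MT link, and how it grows
with tension (*strain stiffening*), reports directly on the molecular
architecture of the attachment.

`ndc80link` is for biophysicists analysing such bead traces and for
modellers asking what link stiffness the known structures predict.  It
provides:

* **Stiffness time-tracing** — an interval-wise equipartition estimator
  that turns a 10-kHz bead-position trace `x(t)` into a time series of
  (force, stiffness) pairs:
  the trace is cut into intervals of Δt = 0.1 s, each interval is
  detrended with a linear fit `f_k(t)` to follow the slowly moving
  quasi-equilibrium position, and

  c_k = k_BT / ⟨(x_k(t) − f_k(t))²⟩,  F_k = c_trap ⟨x_k⟩.

  Exclusion rules (±200 nm excursions, detachment detection) and
  shrinking/stalled/growing state labels follow the assay conventions.
* **Elastic element models**, each exposing extension `z(F)` and
  stiffness `c(F) = (dz/dF)⁻¹`:
  * the Ndc80 complex as a two-bond freely jointed chain (arms a = 40,
    b = 16 nm) confined to a half-space by the bead — closed-form
    partition function, extension, stiffness; stiffens as
    `c = βF²/2` above the crossover `k_BT/b = 0.256 pN`;
  * the MT as an entropic worm-like chain with length-dependent
    persistence length `L_p = L_p∞ / (1 + L_0²/L²)` — exact `F^{3/2}`
    stiffening;
  * the flaring protofilament (PF) as an elastica with spontaneous
    curvature (20° per 8-nm dimer), solved by shooting — `F^{5/2}`
    stiffening;
  * the PEG bead coating as a two-state extended freely jointed chain
    (force-free stiffness 1.38 pN/nm — too stiff to matter).
* **Composition** — serial/parallel spring algebra with equal force
  sharing (`c_n(F) = n c(F/n)`, which *softens* super-linear
  stiffeners), the total measured stiffness
  `c_tot = c_trap + (1/(n c̃(F/n)) + 1/c_MT)⁻¹`, and the envelope
  `n_min(F)` of attachment numbers that minimises the link stiffness —
  the quasi-static signature of a catch bond.
* **Monte Carlo** — an exact sampler of the confined chain and a
  Metropolis sampler with semiflexible (worm-like) arms, linked to the
  models by the fluctuation identity `c = k_BT / Var(z)`.
* **A seeded Langevin simulator** of the whole experiment (trap +
  nonlinear link + tip schedule with stall, rescue, catastrophe,
  detachment) that generates ground-truthed synthetic traces for
  validating the estimator end to end.

All quantities are in pN, nm and s; `k_BT = 4.1 pN nm` by default.

## Worked example

Simulate a 30-s experiment in which the MT shrinks until the link
tension stalls it at ~4 pN, then re-estimate the stiffness–force
relation from the synthetic trace alone:

```r
library(ndc80link)

link <- composite_link(list(fjc_ndc80(), pf_flare(s0 = 50)),
                       mt = mt_wlc(length = 1e4), n = 3,
                       trap_stiffness = 0.025)
cfg  <- sim_config(duration = 30, link = link, trap_stiffness = 0.025,
                   stall_force = 4)
sim  <- simulate_trace(cfg, seed = 11)
sim
#> <simulated_trace 'sim'> 30 s; events: stall@7.21

series <- trace_stiffness(sim$trace, dt = 0.1, kbt = 4.1)
table(series$state)
#> shrinking   stalled
#>        66       234

use <- !series$excluded & series$state != "detached"
fit_power_law(series$force[use], series$stiffness[use])
#> c(F) = 0.01522 F^1.908 + 0.05  [pN/nm; 300 points, loss 0.0163]

bin_stiffness(series$force[use], series$stiffness[use])[, c(1, 3, 5, 7)]
#>   bin_lo mean_force mean_stiffness   n
#> 1      0     0.7538         0.0585  14
#> 2      1     1.4907         0.0848  23
#> 3      2     2.5031         0.1378  20
#> 4      3     3.8256         0.2472 243
```

The 300 intervals trace the link from ~0.6 to ~4 pN; the binned means
agree with the configured model's ensemble (equipartition) stiffness
`equipartition_stiffness(link, F)` — 0.0580, 0.0824, 0.1364,
0.2492 pN/nm at the four bin centres — within their standard errors,
and the robust power-law fit recovers a stiffening exponent near 2 with
an offset absorbing the trap stiffness (here saturating its 0.05 pN/nm
bound because the softest bin already sits above it).

Model-side quantities come straight from the elements:

```r
fjc_stiffness(1)                    # one Ndc80 complex at 1 pN: 0.1239 pN/nm
fjc_interarm_angle(1)               # mean 43.9 deg, sd 23.7 deg
envelope_nmin(link, seq(0.5, 6, 0.25))   # n_min grows 1 -> 12
```

A thin command-line wrapper around the same functions lives at
`inst/cli/ndc80link.R`
(`simulate | estimate | fit | models | compose | mc`).

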