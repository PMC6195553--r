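---
title: "Binding-enhanced diffusion in reversibly crosslinked gels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-enhanced diffusion in reversibly crosslinked gels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geldiff)
```

## The scientific problem

A particle larger than the mesh size of a polymer gel cannot passively pass
through it: the surrounding strands cage it.  Yet some biological barriers
(the nuclear pore complex being the canonical example) let selected large
macromolecules through while rejecting others of the same size.  `geldiff`
implements a coarse-grained model of one equilibrium mechanism that achieves
this: a particle that binds *competitively* to the gel's crosslink binding
sites can catalyse crosslink exchange in its neighbourhood, transiently
opening the cage around it, and thereby diffuses *because* it binds --
while a chemically identical non-binding particle stays caged.

## The three-state site model

Each polymer strand end carries a binding site that is in one of three
states: **free**, **crosslinked** (paired with a complementary strand end),
or **bound** (attached to a binding particle).  A site can never be
crosslinked and bound at the same time (competitive binding), and the
crosslinked and bound states are connected directly (direct bond exchange),
so a crosslink can hand its site over to a particle without ever passing
through the free state.

The kinetics are controlled by two state energies $E_c$, $E_b$ (the free
state defines the zero) and three transition-state energies $T_{fc}$,
$T_{cb}$, $T_{bf}$, all in units of $k_BT$.  Transition rates follow the
Arrhenius form

$$k_{\mu\nu} = \omega_0\, e^{-(T_{\mu\nu} - E_\mu)/k_BT},$$

which satisfies detailed balance around the cycle,
$k_{fc}k_{cb}k_{bf} = k_{fb}k_{bc}k_{cf}$ — the mechanism operates in
thermodynamic equilibrium and consumes no energy.  `energy_model()`
validates the physical constraint that each transition-state energy is at
least as large as both adjoining state energies; `rates_from_energies()`
produces the six rates.

With dimensionless local activities $c_{G'}$ (complementary sites) and
$c_P$ (binding particles), the equilibrium occupancy of a site is

$$P_{\text{cross}} =
  \frac{c_{G'} k_{fc}}{k_{cf} + c_{G'} k_{fc} + c_P k_{cf} k_{fb}/k_{bf}},
  \qquad
  P_{\text{free}} = \frac{k_{cf}}{\text{same denominator}},$$

and the mean lifetime of the crosslinked state is
$\tau_{\text{cross}} = 1/(k_{cf} + c_P\,k_{cb})$: a nearby binding particle
shortens crosslink lifetimes without changing how many crosslinks there are.
That asymmetry — lifetime down, occupancy (almost) unchanged — is the heart
of the mechanism.  These closed forms are implemented in
`equilibrium_probabilities()` and `crosslink_lifetime()` and serve as the
analytic oracle for the stochastic engine; `stationary_distribution()`
solves the explicitly constructed three-state generator as an independent
cross-check.  In that generator both crosslink-forming channels
(free→crosslinked and bound→crosslinked) carry the activity $c_{G'}$, and
both particle-binding channels carry $c_P$; this is the unique assignment
under which the closed forms above coincide with the stationary
distribution for arbitrary activities.

The mean-field activities $c_{G'}$, $c_P$ are emergent properties of the
spatial dynamics and are never assigned numeric values by the simulation;
they enter only the closed-form module, where they are free inputs.

## Mechanical model

The gel is built from star polymers: a core monomer with arms of two
monomers each, 4 arms in 2D (9 beads) and, as this package's documented
choice for the 3D architecture, 6 arms along the axes in 3D (13 beads).
Monomers are disks (spheres) of radius $R_m = 0.5$; tracers have
$R_p = 1$ in 2D.  Interactions (`pair_energy()`):

$$V_H(r_{ij}, b_{ij}) = \tfrac{k_H}{2} s_{ij}^2 \times
  \begin{cases} 1 & s_{ij} \le 0 \\ b_{ij} & s_{ij} > 0,\end{cases}
  \qquad s_{ij} = r_{ij} - (R_i + R_j),$$

a two-sided harmonic bond when the bond variable $b_{ij} = 1$ and a
one-sided contact repulsion otherwise.  The two branches coincide for
$s_{ij}\le 0$, so flipping a bond while the disks overlap leaves the energy
continuous — this is why the stochastic engine only allows bond changes for
overlapping pairs.  Strand stiffness comes from a bond-bending term on each
consecutive triple along a strand (core–arm–end; triples spanning two arms
across the core are excluded, so arms stay straight but can pivot):

$$V_{BB}(\theta) = \tfrac{k_{BB}}{2}(\cos\theta - 1).$$

Dynamics are overdamped Langevin (`simulate_gel()`),
$\dot{\mathbf r}_i = \mathbf F_i/\gamma_i + \sqrt{2k_BT/\gamma_i}\,
\boldsymbol\eta_i(t)$ with $\gamma_i = 2d\pi\eta R_i$, integrated by
Euler–Maruyama at fixed $\Delta t$.  Default parameters: $k_H = 400$,
$k_{BB} = 200$, $\eta = 1$, $k_BT = 1$, $\Delta t = 0.005$.

Between consecutive BD steps the bond topology evolves by an exact
Gillespie simulation over the frozen configuration, terminating at
$\Delta t$: eligible transitions are enumerated (overlap-gated, including
the two atomic exchange moves), a waiting time is drawn from the total
rate, one event fires proportionally to its rate, and the list is rebuilt.
The waiting-time clock is redrawn after every event (standard SSA); for
exponential clocks this is statistically equivalent to pre-sampling.

## Gel construction and geometry defaults

`build_gel()` places stars on a periodic square (cubic) lattice whose
lattice constant makes facing strand ends of neighbouring stars overlap by
`overlap = 0.2 R_m` at rest, so `saturate_crosslinks()` can pair every end:
the production gel has *zero* free binding sites.  Saturation matters
because in the high-affinity regime a free site is a trap — a particle that
binds it has no exchange partner to hand it back to.

Sizes are package choices (the mechanism does not fix them): tracer MSD
experiments default to $4\times4$--$5\times5$ stars, and the shell
filtering demonstration trims a $16\times16$ lattice to a two-star-thick
square ring with a wide interior cavity (low particle density per unit of
fence length); these sizes keep a full acceptance run on a single
desk-scale CPU while leaving several cage layers around the tracer.  Two consequences of small
boxes are handled explicitly:

* **Network drift.** The whole periodic gel diffuses freely with
  $D_{\text{com}} \approx k_BT/\sum_i\gamma_i$, which for a few hundred
  beads is comparable to the hopping diffusivity being measured.  The
  engine records the gel's centre-of-mass displacement and `compute_msd()`
  measures tracer motion relative to it by default.
* **Shell geometry.** `trim_to_shell()` deletes whole stars outside a
  radial band (never severing permanent bonds — that would be polymer
  degradation, which the reversible mechanism deliberately avoids).  On a
  coarse lattice a *circular* band leaves a 45° staircase of dangling arms
  whose openings line up into steric channels, so the filtering
  demonstration uses the Chebyshev metric: a square ring whose four sides
  are sealed, bulk-like crosslinked fence lines.  Dangling boundary ends
  that cannot be paired are deactivated (they keep their excluded volume
  but produce no binding events); otherwise they would act as traps.
  Because the free-floating ring both drifts and flexes (stars have no
  cross-arm angular stiffness), interior/shell/exterior classification is
  topological rather than radial: `fence_loops()` extracts the closed
  inner and outer fence chains once from the rest geometry, and
  `count_fence_regions()` tests each particle against the instantaneous
  fence polygons frame by frame (`run_filter_demo()` wires this up).
  The demonstration also builds the shell with *typed* binding sites
  (`build_gel(two_species = TRUE)`: `G` on positive-axis arms, `G'` on
  negative, particles bind `G` only).  With self-complementary sites and
  ten binding particles working a small fence simultaneously, two
  concurrently freed ends can crosslink *each other*, leaving their former
  partners permanently particle-bound and the fence permanently holed — a
  multi-particle topology rearrangement specific to the high-affinity
  limit.  Typed sites forbid that move, so every opening heals; the
  single-tracer mechanism is identical in both modes.

## Measurement choices

* **MSD and $D$.** `compute_msd()` averages over all time origins and
  replicate runs; `estimate_diffusion()` fits the last decade of lags by
  default and reports an $R^2$ linearity diagnostic ($R^2 < 0.98$ flags a
  plateau or sub-diffusive window).  Uncertainties come from the spread of
  per-replicate slopes.
* **$D_0$.** Ratios $D/D_0$ use a *measured* free-particle $D_0$
  (`measure_free_diffusion()`), which is fitted over short lags where
  time-averaged MSD estimates are most precise; the analytic
  $k_BT/(2d\pi\eta R_p)$ is a cross-check, and for a free particle the
  Euler–Maruyama update is bias-free at any $\Delta t$.
* **Equipartition checks** run at $\Delta t = 5\times10^{-4}$: plain
  Euler–Maruyama inflates the stationary variance of a harmonic mode by
  $1/(1-\theta\Delta t/2)$ with $\theta = k_H/\gamma$, about 19% for
  monomer pairs at the production step.  This inflation affects bond-length
  fluctuations at production settings (a known property of the scheme, kept
  because the fixed-step explicit update is the standard choice for
  overdamped dynamics at this coarse-graining), not the free diffusion.
* **Crosslink lifetimes.** `measure_crosslink_lifetime()` replays the
  bond-event log into completed formation→breaking intervals (intervals
  open at the start or end of a run are censored and dropped).  Because
  breaking is overlap-gated and a thermalised lattice leaves crosslinked
  pairs overlapping only part of the time (the built-in prestress
  redistributes over the strand bonds), in-gel lifetimes exceed the ungated
  $1/(k_{cf}+c_Pk_{cb})$ by the inverse overlap fraction; the closed form
  is recovered exactly when the pair is held overlapping.  Proximity
  stratification uses the distance to the nearest binding particle recorded
  at the formation and breaking events.

## The two regimes

**High affinity (perfect filtering).** `high_affinity_model()` sets
$E_c = -150.5$, $E_b = T_{cb} = -150$, $T_{fc} = T_{bf} = 0$: spontaneous
crosslink breaking is suppressed by $e^{-150}$, so a non-binding tracer is
caged indefinitely (its relative MSD plateaus at the cage-rattle scale,
about 2 in these units), while a binding tracer hops from cage to cage by
the crosslinked↔bound exchange and shows linear MSD.  Because the exchange
conserves the total bond count exactly, the gel never degrades.
`sweep_high_affinity()` maps $D/D_0$ over the two parameters that matter in
this limit, $E_b - E_c$ and $T_{cb} - \max(E_c, E_b)$; diffusion is fastest
when the three deep energies are roughly equal, and the package's
desk-scale sweep (3×3 grid, 3 replicates × $1.5\times10^6$ steps per
point, $4\times4$ gel) reproduces a maximum $D/D_0$ in the few-percent
range.

**Moderate affinity (reversible gel).** `moderate_affinity_model()` sets
$E_c = 2E_b = -10$ with every transition state at the larger adjoining
state energy.  All three states are accessible; crosslinks spontaneously
break and re-form, so even the non-binding tracer diffuses on the gel's
self-healing time scale, and the binding tracer diffuses faster by using
the additional exchange pathways.  At short lags the binding tracer is
*slower* (it spends time bound); the enhancement is a long-time property.
The separation of scales here is extreme — $1/k_{cf} \approx 2\times10^4$
time units — so non-binding diffusivities at this landscape require runs of
order $10^5$ time units; the acceptance checks for this regime use the run
lengths stated in the test code and report replicate-spread uncertainties.

## What the synthetic gels do and do not capture

The lattice generator produces exactly the conditions the model analyses:
monodisperse stars, a defect-free saturated network, no entanglement, one
or few tracers.  Real gels have polydispersity, dangling ends, entanglement
and many-particle crowding; none of these is represented, so passing tests
here validates the mechanism and its implementation, not quantitative
transport in any experimental system.  In particular the enhancement ratio
$D_b/D_{nb}$ depends strongly on cage geometry and network prestress,
which in a real gel are set by chemistry, not by a lattice constant.

## Numerical and degenerate-input choices

* Attempt frequency $\omega_0 = 1$ in simulation time units (exposed as
  `prefactor`); only the product of rates with $\Delta t$ matters for the
  coupling.
* Particle binding capacity defaults to one concurrent bond
  (`sim_config(capacity = )`); a bound site released by exchange may
  re-crosslink with *any* overlapping free end, not only its former
  partner.
* Integration is declared unstable and aborted if any per-step
  displacement exceeds `max_step_disp` (default 0.5, ten monomer-radius
  tenths); with the default $k_H\Delta t/\gamma_{\min} \approx 0.64$ the
  scheme is stable but close to its limit — raising $k_H$ or $\Delta t$
  much further trips the guard.
* Coincident bead centres exert no pair force (the direction is
  undefined); bond-bending on a degenerate (zero-length) bond raises an
  error.
* The RNG is a counter-seeded xoshiro256++ stream per run; identical
  configuration and seed reproduce trajectories and event logs bit for
  bit.

## Reproducing the headline numbers

`scripts/acceptance.R` (repository root) rebuilds everything from scratch:
it measures $D_0$, runs the high-affinity sweep and reports its grid
maximum of $D/D_0$, and runs the shell filtering demonstration and reports
how many non-binding particles remain in the interior cavity.  See the
README for invocation.
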