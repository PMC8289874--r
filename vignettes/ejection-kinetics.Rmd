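---
title: "Kinetics of polymer ejection through a nanopore: model, theory and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of polymer ejection through a nanopore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ejectr)
library(dplyr)
```

# The problem

A polymer confined in a small cavity escapes spontaneously through a narrow
pore because confinement raises its free energy: no external force is
needed. This is the physics of a bacteriophage ejecting its genome, and of
any release of a chain from a trap through a channel. `ejectr` implements
the quasi-two-dimensional version of this problem — a disk-like cavity
embedded in a slit, connected by a short cylindrical pore to an open slit
"semi-space" — in three coupled layers:

1. a coarse-grained bead-spring Langevin dynamics engine (`load_chain()`,
   `equilibrate()`, `run_ejection()`, `run_ensemble()`),
2. a d-dimensional scaling theory of the kinetics (`predicted_exponents()`,
   `speed_model()`, `build_landscape()`, `entering_time()`,
   `stage_time_predictions()`), and
3. an event-series analysis pipeline (`waiting_times()`, `detect_Nstar()`,
   `decompose_stages()`, `fit_power_law()`, ...),

plus a synthetic event-series generator (`fixture_spec()`,
`generate_event_series()`) that samples the theory kinetics directly, so
every analysis operation can be exercised in milliseconds without molecular
dynamics.

All quantities are in reduced units: the monomer diameter $\sigma$, the
interaction strength $\varepsilon$, the bead mass, and the time unit
$t_u = \sigma\sqrt{m/\varepsilon}$ are all 1.

# State variables and stages

With $N$ monomers in total, $m$ counts those still in the cavity, $s$ those
that have arrived in the semi-space, and the pore holds $m_p = \ell_p/\sigma$
of them, so $N = m + m_p + s$ at every instant. A process passes through:

* **entering** ($-m_p \le s \le 0$): the head monomer traverses the pore
  against the chemical-potential difference $\Delta\mu_{cp}$ — a Kramers
  first-passage problem;
* **main ejection**, split at the critical number
  $N_* = (D/\sigma)^{1/\nu}$ into a **confined** stage ($m > N_*$, the
  cavity compresses the chain out) and a **non-confined** stage, itself
  split into **thermal escape** ($m > s$, uphill in free energy) and
  **entropic pulling** ($m < s$, the outer segment pulls);
* **leaving**: the tail traverses the pore, driven by
  $\Delta\mu_{ps} < 0$.

`build_landscape()` assembles the corresponding piecewise free energy
$F(s)$ and labels it with one of four regimes (I: monotone descent when
$\phi_0 \ge \phi_p$; II: entering barrier only; III: a second barrier in the
non-confined stage when $N_* < N - m_p < 2N_*$; IV: both barriers merged
when $N - m_p < N_*$):

```{r landscape}
land <- build_landscape(N = 128, D = 10,
                        params = theory_params(dmu_cp = 1))
attr(land, "regime")
head(as.data.frame(land), 3)
```

# The kinetics and its exponents

Balancing the free-energy release against dissipation at the pore gives
$\dot m = -(1/\eta\sigma^2)\,dF/dm$. With the blob free energy
$F \sim k_BT (m/N_*)^{z_1+1}$ in the confined stage and the tethered-chain
entropy beyond, the ejection speed $V_{ej}(m) = \sigma/W(m)$ scales as
$m^{z_1}$ while confined and $m^{-z_{2P}}$ while pulled, with every exponent
fixed by the Flory exponent $\nu = 3/(d+2)$:

```{r exponents}
predicted_exponents(d = 2)
```

$z_1 = 1/(d\nu - 1)$, the friction exponent $x_1 = 1/d$ (the $\sim D$-sized
moving segment near the pore contributes $\sim m^{1/d} + (N-m)^{1/d}$
monomer frictions), $z_{2P} = 2\nu$, and the closed-form decay exponents
$\zeta_1 = 1/(z_1 - 1)$, $\zeta_2 = 1/(z_{2P} + 1)$. The whole-process
speed model (`speed_model()`) combines both branches plus a second-virial
correction $B_2$ responsible for the up-turn of the speed near $m = N$ in
dense starts.

Two conventions deserve a note, because the scaling relations only fix
structure up to order-one constants. The confined kinetics carries a
prefactor $z_1 + 1$ when derived directly from the blob free energy; the
stage-time prediction table uses the unit-prefactor convention. Both are
exposed through the `prefactor` argument of `kinetics_rhs()` and
`m_of_t_confined()`, with the regime default documented on each function;
the closed forms and the ODE solutions agree under either convention, and
the tests verify that. Similarly, friction is $\eta_0 N^{x_1}$ in the
confined stage but $\eta_0 m^{y_{2P}}$ in the pulling stage — each kinetics
equation uses its own local convention.

First-passage times (the entering stage, and the thermal-escape stage) are
computed by the standard double-integral mean-first-passage quadrature over
the relevant landscape segment (`entering_time()`,
`stage_time_predictions()`), not from closed asymptotic forms; the
quadrature reproduces the diffusive limit $\eta\ell_p^2/(2 k_BT)$ exactly
and the Arrhenius and drift limits asymptotically. The trapezoid grid
(default 4001 points) is converged to well below 0.1%. The chemical
potential differences $\Delta\mu_{cp}$ and $\Delta\mu_{ps}$ are free input
parameters: the theory relates them to osmotic pressure differences but
provides no microscopic formula, so they are supplied by the user (regime
classification uses $\phi_0$ versus $\phi_p = \sigma^2/(6 r_p^2)$ instead).

# The simulation model

Beads interact by a WCA (shifted-truncated LJ 12-6) pair potential,
harmonic bonds ($k = 600\,\varepsilon/\sigma^2$, $b_0 = \sigma$), and an
LJ 9-3 wall potential ($\varepsilon_w = 3\varepsilon$) truncated and
shifted to zero at its minimum, which makes it purely repulsive and reach
$k_BT$ at $0.76\sigma$ — an effective wall thickness of $0.26\sigma$ per
face. The cavity wall therefore sits on a sphere of diameter $D + 0.52$ and
the pore wall on a cylinder of diameter $d_p + 0.52$, producing effective
dimensions $D$ and $d_p = 1.5\sigma$ (single-file). The slit gap is
$H = 1.5\sigma$, so the initial volume fraction obeys
$\phi_0 = N(\sigma/D)^2 \cdot 2\sigma/(3H[1 - (H/D)^2/3])$
(`volume_fraction()`, inverted by `diameter_for_generation()` on the
$0.3\times 2^{-g}$ generation grid).

Choices the model statement leaves open, and how this package resolves
them:

* **Wall geometry at the sphere–cylinder junction.** The accessible space
  is the union of the cavity sphere, the pore cylinder (reaching
  $1.5\sigma$ into the cavity), and the outer slit; a bead interacts with
  the union boundary through the largest of the signed inside-distances.
  This makes the wall energy continuous everywhere — naive per-region rules
  put beads abruptly deep inside a neighbouring wall's potential at region
  boundaries, which is both unphysical and numerically explosive. The
  cylinder's reach is the smallest that leaves no spurious barrier on the
  pore axis.
* **Integrator.** BAOAB splitting of underdamped Langevin dynamics with
  friction $\gamma = m/\mathrm{damp}$ ($\mathrm{damp} = 1\,t_u$); it
  reduces to velocity Verlet at $\gamma = 0$ and reproduces Boltzmann
  velocity statistics, both verified in the tests. The default time step
  $dt = 0.005\,t_u$ is set by the bond vibration period
  ($\approx 0.26\,t_u$ at $k = 600$).
* **Loading.** The contract is only "self-avoiding chain confined in the
  cavity, head at the pore entrance". `load_chain()` places the chain
  deterministically on an Archimedean spiral (alternating small z-offsets
  let dense chains stagger between the plates), then relaxes it in two
  steps: an overdamped zero-temperature quench with capped forces, then
  plain thermal dynamics. Densities above the close-pack bound
  $\phi_0^{cl} = \frac{\pi}{2\sqrt3}\cdot\frac{2\sigma}{3H} \approx 0.403$
  are rejected; the spiral loader handles up to $\phi_0 \approx 0.3$ (the
  densest condition studied here). A pumping-style loader would satisfy
  the same contract; the spiral is used because it is deterministic and
  budget-free.
* **Equilibration** runs with the head monomer frozen at the entrance for
  $\max(100, 10\,N^2\mathrm{damp}/(3\pi^2 T))\,t_u$ by default (a
  ten-Rouse-times heuristic), configurable.
* **Ejection** frees the head, activates a reflective wall at the entrance
  acting on the head only (so the chain cannot retract entirely), and
  records $(t, m, s)$ whenever the region counts change; counts are
  recomputed every step from the entrance/exit planes, which makes
  $m + \text{pore} + s = N$ an identity. Runs exceeding the step budget
  (default $5\times 10^7$) are flagged censored and excluded from means;
  censoring is logged per run.

# Analysis conventions

`waiting_times()` uses *residence* semantics — $W(m)$ is the total time at
state $m$, re-crossings included — because that matches the definition of
the waiting-time function. Stage boundaries instead need first-passage
semantics: `state_series()` monotonizes each run by assigning every level
its *last* downward crossing, and `decompose_stages()` reads the five stage
times off that timeline ($\tau_{ent}$ is the first arrival of $s = 1$).
Both conventions are exercised against crafted series in the tests.

`detect_Nstar()` smooths $\log V(m)$ with a centred moving mean (window 5)
before taking the interior argmin; an argmin at the profile edge is flagged
`no_minimum` (the translocation limit $D = \infty$). The smoothing choice
is ours — on a kinked V-shape it biases the detected minimum about two
states toward the shallow side, which matters only when $N_*$ is small.
Scaling fits use the standard windows $0.01 < m/N < 0.5$ (pulling) and
$0.5 < m/N < 0.95$ (confined/escape); `fit_power_law()` reports the
log-log least-squares slope with its 1-sigma standard error, and
`fit_entering_exponential()` fits $a_n e^{b_n \ell_p}$ by nonlinear least
squares seeded from the log-linear fit.

# What the synthetic fixtures do and do not show

`generate_event_series()` draws per-state dwell times with mean
$\sigma/V(m)$ from the theory speed model — exponential by default (the
minimal memoryless model for a Markovian state description; the dwell
statistics of the underlying dynamics are not specified by the theory),
gamma for over-dispersion, or deterministic. The default `piecewise` speed
model switches from the confined branch to the pulling branch exactly at
$N_*$, so the speed minimum of a fixture sits at $N_*$ by construction;
the `combined` model (the single-equation fit) has its minimum where its
two terms balance, which scales as $D^{2z_1/(z_1+z_{2P})} = D^{8/7}$
rather than $D^{1/\nu}$ — a property of that approximation, not of the
kinetics. Fixtures emulate event series only: they contain no spatial
coordinates, no re-crossing noise beyond the dwell model, and no
correlation between states, so passing the recovery tests shows the
*analysis pipeline* is correct, not that the simulator reproduces the
theory. That cross-check is the simulator test suite's job, at small N.

# Problem sizes and what the test suite runs

The test suite is sized for a single CPU: thermostat checks use one bead
over $10^6$ steps; the Flory-exponent check uses free chains of 16–64
beads; the physics gate runs a 50-run translocation ensemble at $N = 16$
and fixture ensembles of 200 runs at $N \le 512$. The fitted simulation
exponents of the full-scale study (chains to $N = 1024$, 500 runs per
condition) are far outside desk scale; `scripts/overnight_exponents.R`
reruns that campaign at reduced size ($N \le 64$, ~100 runs), and the
acceptance tests include its cheapest pieces ($\tau_{ent}$ and
$\tau_{leav}$ versus pore length at $N = 32$, and the translocation
profile exponents at $N = 32$). At these sizes finite-chain corrections
are visible, and two conditions are out of reach by construction: the
densest condition $\phi_0 = 0.4$ exceeds what the spiral loader can place
(it is within 1% of close pack), and $N_*(D)$ detection needs $N \gg N_*$
chains. Where a reduced-size estimate disagrees with the full-scale value,
the tests report the measured number rather than masking it.

# Known limitations

* Implicit solvent only: no hydrodynamic interactions, so absolute time
  scales are Rouse-like.
* The quasi-2D geometry is the only simulator geometry; the theory layer
  supports $d = 3$ analytically but no spherical-cavity engine is built.
* $\Delta\mu_{cp}$, $\Delta\mu_{ps}$ and all order-one kinetic prefactors
  are inputs, not predictions.
* The loader's spiral placement caps the reachable density slightly below
  the close-pack bound.
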