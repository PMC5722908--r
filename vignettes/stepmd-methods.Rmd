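---
title: "Enhanced and adaptive sampling on a toy domain-docking system"
author: "stepmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhanced and adaptive sampling on a toy domain-docking system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(stepmd)
library(ggplot2)
```

## The scientific problem

A recurring situation in molecular simulation is a mobile protein domain
that must find and dock onto a distant reaction site — the paradigm case
being a nuclease domain closing onto the backbone phosphate it cleaves,
a transition of roughly 10 Å gated by a metal cofactor. Plain
("conventional") molecular dynamics rarely crosses such barriers in
accessible wall time, so practitioners reach for *enhanced sampling*:
either bias potentials that flatten or steer the landscape, or adaptive
protocols that concentrate unbiased simulation effort where progress is
being made.

`stepmd` implements three such strategies **in full**, together with the
trajectory-analysis protocol used to interpret them, but runs them on
**small synthetic bead systems** with designed, analytically known
properties. That inversion — real algorithms, toy physics — is the whole
point: every claim the package makes about its machinery can be checked
against a closed form, a brute-force enumeration, or a designed value.

The three strategies are:

1. **Accelerated MD (aMD) boost.** When a boosted energy channel $V$
   falls below a threshold $E$, the bias
   $$\Delta V = \frac{(E-V)^2}{\alpha + (E-V)}$$
   is added, producing the modified potential
   $V^\* = E - \alpha(E-V)/(\alpha + E - V) \in (E-\alpha,\,E]$, monotone
   in $V$, with force scale $\alpha^2/(\alpha+E-V)^2 \in (0,1]$,
   continuous at $V=E$. Basins are lifted, barriers above $E$ untouched.
   In *dual* mode both an internal-coordinate channel (the toy analog of
   a dihedral term) and the total potential are boosted independently
   and the recorded $\Delta V$ is their sum.
2. **Targeted MD (tMD) steering.** A harmonic penalty
   $$U = \tfrac12 \frac{k}{N}\,\bigl[\mathrm{RMSD}(t) -
   \mathrm{RMSD}^{*}(t)\bigr]^2$$
   on the gap between the instantaneous best-fit RMSD from a target
   structure and a reference that decreases linearly over the schedule;
   the spring constant is scaled down by the number $N$ of targeted
   atoms, and weak positional restraints are available for untargeted
   atoms.
3. **Step-by-step adaptive ensembles.** Cycles of unbiased replica runs
   where each cycle is reseeded from the saved snapshot minimising a
   *progress metric* — the geometric mean of the distances from a
   scissile-site bead to two catalytic-site beads, with smaller values
   meaning closer to the docked (catalytic-like) state. No artificial
   forces ever act on the system; the bias is purely in where computing
   time is spent.

## The synthetic systems

### Analytic landscapes

`make_analytic_landscape()` provides a single particle on either a 1D
quartic double well $V(x) = a(x^2-b)^2$ (wells at $\pm\sqrt b$, barrier
$a b^2$, exact Boltzmann density exposed for oracles) or the standard
Müller–Brown surface with its three minima. These are the stand-ins for
a rugged biomolecular landscape wherever a method's statistical claims
need an exact reference — e.g. that dual-boost aMD plus exponential
reweighting recovers the double-well free-energy profile.

### The domain-docking fixture

`make_domain_docking_model()` builds a 14–15 bead system:

* a **scaffold** of 8 tethered beads carrying the scissile-site bead and
  two label sites (`fretA`, `fretC`) — the analog of the protein body
  plus nucleic-acid frame that the mobile domain docks against;
* a **mobile domain** of 6 beads (anchor, two catalytic-site beads
  `cat1`/`cat2`, label site `fretB`, two fillers) held quasi-rigid by
  stiff bonds, attached to the scaffold by two near-slack linkers, and
  free to translate along the docking coordinate;
* a quartic double well on the anchor's docking coordinate placing the
  **undocked** pose at progress metric 9.5 length units and the
  **docked** pose at 6 — mirroring the experimental scale of the
  transition (≈9 Å down to ≈6 Å);
* an optional **ion bead** pinned at the reaction interface (the
  centroid of the scissile and catalytic sites in the docked pose — the
  interface placement is our choice, as no standard convention exists)
  whose short-range Gaussian attraction to the catalytic beads deepens
  the docked minimum by a designed, exactly bookkept amount
  (`design$ion_depth`). Removing the ion restores a symmetric double
  well, so docking loses its thermodynamic advantage — the toy analog of
  the metal cofactor being required for a stable catalytic state;
* purely repulsive excluded-volume walls between the scissile and
  catalytic beads just inside the designed contact distance. Real
  domains cannot compress below van-der-Waals contact; without the
  walls, the minimum-over-frames statistic that drives adaptive
  reseeding ratchets into unphysical compressed outliers.

Defaults were fixed once, from these physical considerations (docked
basin stiff enough that metric fluctuations are ≈0.15 length units;
barrier 3.5 thermal units so that a 60-time-unit replica crosses with
probability ≈0.3): they are the package's study conditions, not tuning
knobs.

```{r fixture}
sys <- make_domain_docking_model()
sys
progress_metric(sys$poses$undocked, sys)
progress_metric(sys$poses$docked, sys)
```

## The engine

Dynamics are integrated with the BAOAB splitting of Langevin dynamics,
chosen for its accurate configurational sampling at moderate time steps;
with zero friction and temperature it reduces to velocity Verlet and
conserves energy to first order in $\mathrm{d}t^2$. Temperature is
specified as a *thermal energy* ($k_BT$), making the engine
unit-agnostic: reduced units ($k_B = 1$, mass 1) for toy work, kcal/mol
and Ångström (with `thermal_energy(310.15)` ≈ 0.616 kcal/mol) for
paper-facing arithmetic. There are no constraints and no barostat — the
toy systems are unconstrained NVT by design.

Randomness policy: every run takes one integer seed; replica streams in
campaigns are derived as a deterministic hash of (master seed, cycle,
replica), so entire campaigns are bit-reproducible. Velocities at
reseeding are redrawn from the Maxwell–Boltzmann distribution rather
than copied, so one replica's momenta never propagate to a whole cycle.

A potential energy exceeding a configurable bound aborts the run with an
error naming the step — the diagnostic signature of a time step too
large for the stiffest term.

## Design choices in the biasing module

* **Dual-boost composition.** The two channels are boosted
  independently and summed:
  $\Delta V = \Delta V_{\mathrm{dih}}(V_{\mathrm{dih}}) +
  \Delta V_{\mathrm{tot}}(V_{\mathrm{tot}})$, with biased force
  $f_{\mathrm{tot}}F_{\mathrm{tot}} + (f_{\mathrm{dih}}-1)
  F_{\mathrm{dih}}$. Published aMD variants differ in how the second
  boost nests; independent channels are the simplest composition with
  the required limits, and the one we document and test.
* **Parameter recipe.** `estimate_amd_params()` uses the standard
  two-coefficient shape $E = \langle V\rangle + c_E\,\mathrm{size}$,
  $\alpha = c_\alpha\,\mathrm{size}$ per channel. The classic protein
  coefficients (3.5 and 0.7 per residue for the dihedral channel, 0.175
  per atom for the total) are defaults; for the 1D toy, coefficients of
  order the barrier and the thermal energy ($c_E = 1$,
  $c_\alpha = 0.25$ on the internal channel) put $E$ just above the
  barrier top and make the flattened surface diffusive, which is what
  the PMF-recovery demonstration uses.
* **Reweighting estimator.** Exponential reweighting
  $F(\mathrm{bin}) = -k_BT\,\log\sum e^{\Delta V/k_BT}$ is the default;
  a second-order cumulant variant is selectable. On the 1D double well
  at the demonstrated sampling the exponential estimator recovers the
  barrier within ~10%; the boost on the *total* channel feeds
  confinement-energy fluctuations through the exponential, which is the
  dominant residual error and grows with boost strength — the reason the
  total-channel boost defaults gentle. Empty bins are `NA`, never zero.
* **tMD gradient.** Only the explicit coordinate dependence after the
  optimal superposition is kept; the rotation- and translation-gradient
  terms vanish at the fit optimum, so the force is exact at the best-fit
  point. When steering must move a domain *rigidly* (best-fit RMSD over
  the moving set alone would absorb the motion), `tmd_params()` accepts
  a separate `fit_indices` selection — align on the scaffold, steer the
  domain — mirroring how partial steering is set up in practice. With a
  fixed external fit the retained gradient is exact everywhere.
* **Schedule clamping.** Before `t_start` the reference holds the
  initial RMSD, after `t_end` the final value, so a steered run can be
  followed by relaxation against a constant target.

## Design choices in the adaptive module

* **Selection scope.** The literal protocol reseeds from the previous
  cycle (`previous_cycle`, the default); `best_so_far` reselects over
  all history and makes the per-cycle minimum series non-increasing by
  construction. Both are offered because the protocol's plain
  description does not fix the scope.
* **Convergence rule.** Relative change of the per-cycle minimum below
  5% over 2 consecutive cycles. Published campaign traces show a
  plateau but state no rule; this one is ours and configurable.
* **Failure policy.** A replica whose integration fails is logged and
  dropped; a cycle aborts only when every replica fails.

## What the demonstrations do and do not show

The bundled problem sizes (chosen once as the package's study
conditions) are: campaigns of up to 8 cycles × 10 replicas × 6000 steps
at $\mathrm{d}t = 0.01$, friction 1, $k_BT = 1$ on the docking fixture;
a 150 000-step dual-boost run on the double well; and 20 000-step
steered runs covering a 100-ns schedule in physical units with friction
0.2 ns⁻¹ — strong friction makes the collective drag $N\gamma$
overwhelm the per-atom spring, so the default keeps the steered
coordinate lightly damped and averages duplicate runs when a rate is
quoted.

Passing these demonstrations shows that the *machinery* is correct: the
bias formulas match their closed forms and finite-difference gradients,
reweighting undoes a known boost on a known landscape, the adaptive
protocol converges onto a designed basin and beats equal-budget naive
ensembles, and the analysis stack separates designed states. It does
**not** show anything about real biomolecules: the fixtures have no
solvent, no electrostatics, no internal flexibility worth the name, and
their noise statistics are far tamer than a protein's. The toy steered
run also reproduces a known practical feature of scheduled steering:
the measured RMSD trails the reference by a lag (here ≈1 Å, matching
the ~0.8 Å terminal gap typical of such runs), so the fitted decrease
rate sits a few percent below the scheduled one.

## A worked example

A small campaign (scaled down from the defaults to keep this vignette
quick):

```{r campaign}
eng <- engine_params(dt = 0.01, temperature = 1, friction = 1,
                     n_steps = 1, save_interval = 20, seed = 1)
spec <- campaign_spec(n_cycles = 4, n_replicas = 4, run_length = 3000,
                      selection_scope = "best_so_far", master_seed = 7)
camp <- run_stepwise_campaign(sys, eng, spec,
                              initial = sys$poses$undocked)
tidy(camp)
glance(camp)
autoplot(camp)
```

And the analysis protocol on the campaign's final cycle — align on the
scaffold, PCA over the mobile domain, label-pair distances:

```{r analysis}
traj <- camp$trajectories[[length(camp$trajectories)]][[1]]
aligned <- fit_superpose_series(traj, sys$poses$docked,
                                fit_selection = "scaffold")
pca <- pca_modes(aligned, selection = "mobile_domain")
glance(pca)
head(distance_pairs_series(traj, list(c("fretA", "fretB"))))
```

## Known limitations

* The engine is pure R and deliberately small: simple cutoffs, no
  neighbour lists, no periodic boundaries, no constraints. It is sized
  for tens of beads, not thousands.
* Exponential reweighting is variance-limited; boosts much larger than
  a few $k_BT$ per frame need the cumulant estimator or more sampling.
* The clustering step (average linkage on pairwise best-fit RMSD, cut
  at a threshold, medoid representative) is a documented analog of
  common practice, not a reproduction of any specific published
  configuration.
* The coordination-geometry check classifies center–ligand angle pairs
  as cis/trans at 135° and applies a ±15° default tolerance — a typical
  screen, configurable where stricter geometry is wanted.
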