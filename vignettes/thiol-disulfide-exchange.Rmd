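---
title: "Simulating force-activated thiol-disulfide exchange with dsxchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating force-activated thiol-disulfide exchange with dsxchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsxchange)
```

## The problem

A disulfide bond under mechanical tension can be attacked by a free thiol
within the same protein: an S\(_N\)2 substitution at one of the two bonded
sulfurs forms a new disulfide and releases the other sulfur as a thiol.
In the mutated titin immunoglobulin domain I27\* — 89 residues, five
cysteines (24, 32, 47, 55, 63), one engineered 24–55 disulfide — single-
molecule force-clamp experiments observed this isomerization to be highly
specific: essentially only 32Cys attacks, with a measurable preference
between the two sulfurs of the bond.

`dsxchange` implements a hybrid Monte Carlo / Langevin dynamics scheme for
this process on a coarse-grained (CG) model of the domain:

1. **Force-clamp dynamics.** Overdamped Langevin dynamics of a
   one-bead-per-residue chain, one terminus restrained, a constant force
   (default 480 pN) pulling the other along a fixed axis.
2. **First-passage detection.** After every integration step, the distance
   from each free thiol sulfur to each disulfide sulfur is tested against a
   cutoff (default 0.5 nm).  Only the first crossing counts: tension makes
   the reaction effectively irreversible.
3. **Swap move.** Either the first sub-cutoff approach is accepted outright
   (distance criterion), or a Metropolis decision is made on locally
   minimized reactant/product energies (energy criterion): the crosslink is
   rewired to the attacker–target pair, both conformations are relaxed by
   steepest descent with only residues within 0.5 nm of the three reactive
   cysteines mobile, and the proposal is accepted with probability
   \(\min(1, e^{-\Delta E / k_B T})\).  A rejected proposal lets the
   dynamics continue and is re-proposed at subsequent steps.

The analysis layer computes everything downstream: sulfur–sulfur distance
distributions, regioselectivity \(N_{55}/N_{24}\) with bootstrap errors,
attack-angle survival curves \(P(\theta > \theta_0)\), unfolding
statistics, PCA of the disulfide-enclosed loop, and Shrake–Rupley SASA
with a Kolmogorov–Smirnov comparison of reactive conformation groups.

## The coarse-grained model

Units are GROMACS-style throughout: nm, ps, kJ/mol; forces in pN are
converted via 1 pN·nm = 0.602214 kJ/mol, and \(k_BT = 2.494\) kJ/mol at
300 K.

One bead sits at each C\(\alpha\) position; cysteine beads double as
sulfur positions, so the criteria — which depend only on S–S distances and
angles — act directly on bead geometry.  Thiol protonation is a
bookkeeping flag, not a particle.  The energy is

* harmonic bonds, \(r_0 = 0.38\) nm (C\(\alpha\)–C\(\alpha\) spacing),
  \(k = 10^4\) kJ/mol/nm\(^2\);
* a mild harmonic bending term (\(k_\theta = 10\) kJ/mol/rad\(^2\) about
  \(\theta_0 = \pi\)), giving the unfolded chain a persistence length of
  roughly 1.5 nm so the disulfide-enclosed loop stays disordered;
* excluded volume: truncated 12-6 Lennard-Jones, \(\sigma = 0.47\) nm,
  \(\epsilon = 1\) kJ/mol, 1 nm cutoff, with first and second backbone
  neighbors excluded;
* a **softcore sulfur–sulfur interaction** (below);
* a stiff harmonic disulfide crosslink, \(r_0 = 0.39\) nm;
* Gaussian **native-contact wells** (below) that emulate the folded state;
* the pulling work term
  \(-F\,(\mathbf{r}_\mathrm{pulled}-\mathbf{r}_\mathrm{fixed})\cdot\hat{u}\).

### Why the plateau lands near 23 nm

The taut path of the unfolded, natively bonded chain is residues 1–24, the
crosslink, and residues 55–89: 57 bonds plus 0.39 nm, i.e. 22.05 nm at
rest length.  Two corrections act in opposite directions and were budgeted
analytically when the bond stiffness was chosen, before any simulation was
run: enthalpic bond stretching adds \(F/k \approx 0.029\) nm per bond
(+1.65 nm at 480 pN), while thermal transverse fluctuations contract the
chain by the discrete freely-jointed-chain factor
\(\coth(Fb/k_BT) - k_BT/Fb \approx 0.977\).  Together they predict a
plateau of about 23 nm — the same value the all-atom system reaches —
which the simulations reproduce (23.2–23.4 nm averaged over seeds).  This
is a genuine property of the chosen stiffnesses, not a fitted number: with
rigid bonds the same chain would plateau near 21.5 nm.

### The softcore sulfur–sulfur potential

At sub-σ separations the plain LJ wall would produce enormous forces in
exactly the conformations the method cares about (attack geometries at
0.25–0.5 nm).  The sulfur–sulfur interaction is therefore softcore:
**identical to the plain LJ form at and beyond 0.35 nm** and bounded
below it.  The implemented core is piecewise-\(C^1\): for
\(r < r_c = 0.35\),

\[ V(r) = V_\mathrm{LJ}(r_c) + \frac{V'_\mathrm{LJ}(r_c)}{2 r_c}\,
   (r^2 - r_c^2), \]

which matches the LJ value and slope at the crossover, has a finite value
(≈ 869 kJ/mol at contact for the default parameters) and a force that
decreases linearly to zero at \(r = 0\).  The conventional free-energy-
perturbation softcore parameters (\(\alpha = 0.3\), \(\lambda = 0.9\),
\(p = 1\)) are stored and reported for provenance, but the standard FEP
formula with \(\lambda = 0.9\) does *not* reduce to plain LJ at 0.35 nm,
so the crossover-identity contract — the physically meaningful statement —
is honored by construction instead.  `softcore_table()` (or the
`dump-table` CLI subcommand) writes the tabulated \((r, V, -dV/dr)\)
curve for inspection.

### The folded stand-in and the native-contact term

The starting conformation is a seeded compact self-avoiding collapse,
relaxed under restraints that reproduce the folded domain's printed
geometry: the 24–55 crosslink closed at 0.39 nm, and the free thiols 32,
47, 63 held at their folded-state mean distances from the bond (1.2, 2.2
and 2.1 nm respectively).  It is a stand-in, not the native fold: an
import path for real PDB structures (`read_structure()`, SSBOND records
honored) covers users with actual coordinates.

A bare compact blob, however, is liquid-like: thiols would wander into
attack range within picoseconds, which the real folded domain — whose
β-sandwich locks the cysteines in place until force unravels it — never
allows.  The model therefore adds a standard structure-based (Gō-type)
term: every bead pair at least three residues apart that sits within
0.8 nm in the built conformation contributes a Gaussian well of depth
4 kJ/mol (≈ 1.6 \(k_BT\)) and width 0.05 nm at its native distance.  The
depth was set by a thermal argument, not by fitting: wells of ~1.5
\(k_BT\) break and reform thermally, so the loop is disordered after
unfolding (as required), while the cooperative network still holds the
fold together at zero force; each individual contact resists only
≈ 80 pN, far below the 480 pN clamp, so unfolding proceeds in tens to
hundreds of picoseconds.

### Dynamics

Euler–Maruyama overdamped Langevin integration:
\(\Delta x = F/\gamma\,\Delta t + \sqrt{2 k_B T \Delta t/\gamma}\,\xi\),
with \(\gamma = 100\) kJ·ps/mol/nm\(^2\) and \(\Delta t = 10^{-3}\) ps
(the stiffest term then has \(k\Delta t/\gamma = 0.1\), well inside the
stability margin).  A per-step displacement cap of 0.05 nm guards against
the rare steep excluded-volume overlap in freshly built conformations; in
equilibrated chains it is essentially never active.  The fixed terminus is
restrained harmonically (\(10^4\) kJ/mol/nm\(^2\)) rather than frozen, so
its thermal width is part of the model.  The integrator draws its noise
from a fast internal generator seeded from R's RNG, so every trajectory is
bit-reproducible from `set.seed()`-style seeds; dynamics and Metropolis
decisions use separate derived sub-streams, which is why a hybrid run with
swapping disabled is bit-identical to a plain force-clamp run at the same
seed.

The CG time unit does not map one-to-one onto the all-atom nanosecond:
with an implicit solvent and soft potentials the chain explores
conformations orders of magnitude faster.  The default 700 ps run
(7 × 10\(^5\) steps) plays the role of an all-atom-scale 100 ns trajectory:
unfolding completes within 250–350 ps and the remainder samples the
unfolded, disulfide-bonded state.

## The swap protocols

With the **distance criterion**, detection runs in-stream after every
integration step (strictly more sensitive than scanning stored frames at
the output stride), and the first crossing is the counted event — at most
one per trajectory, the earliest across the six thiol/sulfur pairs, with
the nearer sulfur as target when both are in range.  In the campaign this
criterion is applied *virtually*: events are counted but the bond is not
rewired, and the trajectory continues to full length, mirroring the
protocol in which plain force-clamp runs are scanned for reactive
geometries.  With the **Metropolis criterion** the bond actually moves.
The frozen-environment contract is strict: beads outside the 0.5 nm relax
radius are bit-identical before and after the local minimization, which
also makes the mobile-subsystem \(\Delta E\) exactly equal to the
full-system \(\Delta E\) (frozen–frozen terms cancel); the subsystem
energy is used for numerical hygiene.  The attack-angle filter exists
(`angle_min`) but is off by default: angles are an analysis, not part of
the headline protocol.

## What the generator does and does not emulate

The synthetic fixture reproduces the *stated conditions* of the study:
89 residues, cysteines 24/32/47/55/63, the 24–55 bond, 480 pN, 300 K, a
folded start whose thiol–bond distances match the printed folded-state
averages, and unfolding to the ~23 nm plateau with the loop protected from
stretching.  Passing tests on this fixture demonstrate the machinery —
detection, swapping, statistics — not all-atom biology.  Known, deliberate
limitations:

* **The chain is a homopolymer.**  The residue map \(i \mapsto 79 - i\)
  maps 32↔47 and 24↔55 onto each other, so at CG resolution the
  32-versus-47 specificity can only arise kinetically (32 starts closer to
  the bond and the loop's native contacts preserve that bias), not from
  sequence-specific loop propensities as in the real domain.  In practice
  32 is the most frequent attacker and samples attack-range distances
  several-fold more often than 47, but 47 still contributes a minority of
  events — the right ordering, for a coarser reason and with weaker
  contrast than the all-atom system shows.
* **63Cys can attack during the unraveling transient.**  Residue 63 is
  only eight bonds from 55 along the chain; while the C-terminal tail
  peels, it can transiently pass within 0.5 nm of the bond.  The all-atom
  unfolding pathway keeps it away.  A fraction of CG events therefore
  carries attacker 63; they are reported, not filtered.
* **The 55-versus-24 preference does not reproduce.**  The experimental
  and all-atom preference for 55 (ratio 1.5–2.5) rests on which loop
  conformations are compatible with each approach — information encoded in
  side chains and sequence.  The CG kinetics instead slightly favor the
  sulfur nearer in sequence to the attacker (24 for attacker 32), so the
  CG \(N_{55}/N_{24}\) ratio is at or below 1.  For the same reason the
  SASA contrast between the two reactive conformation groups is weak and
  direction-unstable at CG resolution: approaching either sulfur of a
  0.39 nm bond perturbs the loop's compactness almost equally.  The
  package reports whatever the model produces; the regioselectivity
  *arithmetic* (counts, ratio, bootstrap) is tested against the printed
  18/12 → 1.5 example instead.
* The folded-state end-to-end distance of the construct (7 nm in the
  experimental geometry) is not reproduced by a compact collapse (~1–2
  nm); the unfolding *increment* and plateau are the modeled quantities.
* The printed all-atom numbers that depend on the explicit-solvent
  ensemble — 73% unfolding within 10 µs, ≈50% PCA variance in two modes,
  SASA p < 0.001 — are targets of *qualitative* analogy only.

One further note on error bars: the bootstrap standard error of a count
ratio at \(n = 30\) events (sd of the resampled ratio ≈ 0.72 for the
18/12 example) is systematically larger than the first-order delta-method
approximation (0.56), because the ratio's resampling distribution is
heavily right-skewed at this sample size.  The package reports the honest
bootstrap sd; the tests pin it against an exact enumeration of the
resampling distribution.

## Numerical choices

* Steepest descent minimizer: GROMACS-style adaptive step (accept → ×1.2,
  reject → ×0.2), convergence when the maximum mobile-bead force drops
  below `minimizer_tol` (10 kJ/mol/nm); non-convergence within
  `minimizer_max_steps` rejects the proposal with a diagnostic rather than
  trusting an unconverged energy.
* Tie-break at detection: when both disulfide sulfurs are within the
  cutoff, the nearer one is the target.
* Rejected Metropolis proposals are re-tested every subsequent step with
  no cooldown.
* Shrake–Rupley SASA uses a deterministic 960-point Fibonacci sphere per
  bead, probe 0.14 nm, bead radius σ/2 ≈ 0.235 nm; a bead exactly
  coincident with an earlier one contributes no area.  Rotation
  invariance holds to the lattice resolution (~0.5%), translation
  invariance exactly.
* The KS comparison subsamples each SASA series at its empirical
  autocorrelation zero-crossing (the CG analogue of sampling every 2 ns of
  all-atom time) and uses the exact two-sample D with asymptotic p
  (`stats::ks.test`).
* Loop PCA (residues 24–55) superposes iteratively onto the running mean
  (Kabsch/SVD) before the covariance eigendecomposition; trajectories that
  never unfold are discarded, and the folded prefix of each trajectory
  (end-to-end < 20 nm) is dropped.
* The 0.5 nm swap cutoff and the 0.6 nm "reactive conformation" coloring
  cutoff used for SASA/PCA grouping are distinct, both configurable.
* Replicate counts: the full campaign default is 100 seeded replicates
  (the study-scale protocol).  The shipped test suite and acceptance
  script exercise 10–24 replicates, a problem size chosen so the whole
  analysis reruns comfortably on a laptop; all qualitative conclusions
  reported by the tests are stable across these sizes.

## A short example

```{r example, eval = FALSE}
fx <- build_i27_star(seed = 1)
tr <- run_force_clamp(fx$frame, fx$topology, potential_params(),
                      simulation_config(seed = 1))
plot(tr$times, end_to_end(tr), type = "l",
     xlab = "time (ps)", ylab = "end-to-end (nm)")

hy <- run_hybrid(fx$frame, fx$topology, potential_params(),
                 simulation_config(seed = 1),
                 swap_criterion("metropolis"))
events_table(hy$events)

rep <- campaign(run_config(replicates = 24))
print(rep)
```

## Discrepancies recorded while implementing

The source study states the distance-criterion regioselectivity both as
1.5 (from the counts 18 and 12) and as 1.7 in a later summary of the same
quantity; the implementation reports the counts-derived value and treats
the ratio as defined by `n55 / n24`.  A figure caption's "67Cys" is read
as 63Cys.  Whether the Metropolis comparison used full-system or
subsystem energies is unstated; under the frozen-environment contract the
two are identical, which the tests assert.
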