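---
title: "Modeling two-state protein transitions with pathcg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling two-state protein transitions with pathcg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Many proteins adopt two (or more) experimentally resolved
conformations, and the biology often lives in the transition between
them: which contacts break first, which residues gate the motion, what
the high-energy state near the barrier looks like.  Crystal and cryo-EM
structures only show the endpoints.  `pathcg` models the path between
them with a deliberately simple, fully reproducible stack:

1. a **dual-basin C-alpha structure-based (Go-type) model** built from
   the two endpoint structures,
2. **Langevin dynamics with well-tempered metadynamics** over the two
   collective variables (RMSD to state A, RMSD to state B), giving a
   2D free-energy surface,
3. a **two-round pathway search** on that surface (nudged elastic band
   from random bead placements, plus Metropolis-accepted stochastic
   grid walks), whose lowest-barrier path defines the transition
   pathway and whose maximum defines the transition (high-energy)
   state,
4. a **residual CNN** that learns to predict the high-energy-state
   distance matrix directly from the two endpoint matrices (and, in
   its three-head form, two flanking intermediates, from which the
   whole pathway is interpolated),
5. **restrained simulated annealing** that turns a predicted distance
   matrix back into C-alpha coordinates.

Everything operates on C-alpha coordinates in nm; energies are kJ/mol,
times ps, temperatures K, with kB = 0.008314 kJ mol^-1 K^-1.

# Dataset rules and contact statistics

The curation module implements the dataset rules for deciding whether
two depositions are two states of one protein: sequence identity
> 90% (global alignment, identity matrix, affine gaps 10/0.5),
superposition RMSD > 0.5 nm with terminal loops excluded, longest
alignment gap < 21 residues, sequence length > 50.  Terminal-loop
trimming is operationalized as stripping the leading/trailing runs
that are coil in both states — the source procedure names no
algorithm, so the simplest deterministic reading is used.  Clusters of
more than five structures whose largest pairwise RMSD is below 0.2 nm
are single-state; the shortest member represents them.

Transitions are classified by secondary-structure changes over mapped
residues: more than five helix/strand swaps is a global fold change
(Category IV, checked first); more than five helix-or-strand to loop
changes is local unfolding (III); otherwise inter- versus intra-domain
motion (I versus II) is decided by a rigid-block heuristic — complete-
linkage clustering of the |d_A - d_B| distance-difference matrix at
0.2 nm, Category I when at least two blocks of 30+ residues move
relative to each other.  The original procedure used visual
inspection; the heuristic makes the choice reproducible, and both
thresholds are arguments.

Contact-type statistics cover the 210 unordered residue-type pairs.
For protein i, F_pq = N_pq / (N_p N_q) with N_pq counting C-alpha
pairs separated by 0.3-1.0 nm; dataset frequencies average over
proteins, and the multi-state enrichment ratio is
R_pq = 2 F^MS / (F^MS + F^SS) in [0, 2] (types absent everywhere are
NA, not 0).  Changed-contact frequencies count pairs whose C-alpha
distance moves by at least 0.5 nm between the states, normalized the
same way — the source renders that normalization only as an image, so
it is mirrored from the main frequency formula, and pairs' two states
are averaged where a whole pair enters the plain frequency count.

# The coarse-grained model

`build_dual_basin()` takes bonds, angles and dihedrals from the
state-A geometry; native contacts are C-alpha pairs with |i - j| >= 4
closer than 0.8 nm (a cutoff map — the all-atom shadow-map definition
needs atoms we do not carry; the cutoff is an argument).  Contacts are
partitioned into common (both states; equilibrium distance the mean of
the two native distances), unique-A and unique-B; each is a 12-10 well
of depth epsilon = 1 kJ/mol, the uniform contact strength of the
source protocol.  Non-contact pairs repel as a truncated-shifted
r^-12 with sigma = 0.4 nm, cut at 0.75 nm so that native non-contact
pairs (>= 0.8 nm by construction) feel exactly zero force at either
endpoint.  Dihedral strength is halved (configurable to exclusion)
where the two states' secondary structure differs — the original
dual-basin mixing recipe is in an upstream method we do not reproduce,
so the package makes the simplest choice that de-emphasizes conflicting
torsions.  Averaging common-contact distances means endpoints with
*differing* common-contact geometry are slightly strained; on fixtures
whose common contacts are rigid this vanishes identically.

Dynamics is BAOAB Langevin; with friction 0 the O-step is the identity
and the integrator reduces to energy-conserving velocity Verlet
(measured drift ~1e-6 kJ/mol per 10^3 steps at dt = 0.0005 ps).
Defaults: dt 0.0005 ps, friction 0.1-1 ps^-1 (the low-friction limit;
the basin-stability tests use higher friction purely to thermalize
quickly), mass 1 per bead.  The simulation temperature is not stated
in the source; with epsilon = 1, kB T = 1 (T = 120 K) sits slightly
below the toy systems' folding temperature and is the package default.

Well-tempered metadynamics deposits a Gaussian every 500 steps with
initial height 1 kJ/mol, width 0.05 (CV units), bias factor 50; the
deposited height is damped by exp(-V_bias / kB dT), dT = 49 T.  The
bias force enters through the analytic best-fit-RMSD gradient
(rotation and centroid derivatives vanish at the Kabsch optimum).  The
free-energy estimate is F = -(gamma/(gamma-1)) V_bias on a grid,
shifted to min 0.  Desk-scale runs here are 10^5-10^6 steps —
the source used 4x10^8 per protein — so single-run surfaces carry an
irreducible noise of order kB T; two-seed agreement on the toy fixture
is a few kB T RMS after removing the arbitrary additive constant, and
barrier measurements below always compare like with like.

# Pathway search

Round one: 7 beads, endpoints pinned at the two basins, interior beads
placed uniformly at random, 1000 iterations of gradient descent under
the bilinear-interpolated landscape force perpendicular to the path
plus plain spring forces (plain, not tangent-projected, so kinked
paths straighten on flat regions); step size 0.25 grid cells, decaying
linearly over the second half of the iterations so beads settle.  One
hundred restarts for each spring constant 0.3, 0.6, 0.9, 1.2 (treated
as dimensionless relative weights).  Round two: from the start cell, a
uniformly chosen 4-neighbor is accepted with min(1, exp(-dG/kBT)) —
acceptance sampling, which has the correct all-accept limit on flat
landscapes — until the end cell is reached; failed walks are reseeded
so exactly 50 succeed.  That gives 450 candidates (400 NEB + 50
walks); the lowest barrier wins, ties broken by shorter arc length
then lower mean free energy, and the winner's maximum-F node is the
transition state.  Walk paths are loop-pruned during the walk.

The search is validated against an exact, exhaustive widest-path
(minimax) oracle: binary search over grid levels with 4-connected
flood fill.  On 20 random smooth 40x40 landscapes the two-round best
barrier matches the oracle within one grid cell's F-range in 20/20
cases.  The walk temperature on those landscapes is kB T = 3,
commensurate with their +-6 kJ/mol amplitude; at kB T = 1 walks cannot
cross the tallest ones in any reasonable proposal budget.

The transition-state ensemble is the set of trajectory frames whose
CVs fall within +-0.08 nm of the transition state on both axes; its
mean pairwise distance matrix feeds the featurization.

# Features, network, loss

Distances map to features by D(r) = 1 - (1 + e^(1-r))^-1: strictly
decreasing, D = 0.5 exactly at r = 1 nm (the contact definition),
D(0) = 1 - 1/(1+e) ~ 0.731.  The transform is applied after ensemble
averaging of distances.  A contact is D >= 0.5; unique contacts exist
in exactly one state; pairs with |i - j| < 3 are excluded from the
masks (trivially near; configurable).

The predictor stacks the two endpoint features as L x L x 2, applies a
3x3 convolution to 64 channels, 8 residual blocks (conv-ReLU-conv +
identity, ReLU), and a per-position head of 64 cells implemented as a
1x1 convolution stack 64 -> 64 -> 1, matching the L x L x 64 ->
L x L x 1 shape contract.  The raw output is averaged with its
transpose — summing would double the scale — and clamped to [0, 1) at
prediction time (training uses the unclamped symmetric output; targets
live in (0, 0.732), so the clamp rarely binds).  The loss is squared
error weighted 5:1 between unique and non-unique pairs, normalized by
the number of included pairs; the ratio is the substance, the
normalization keeps plain SGD at learning rate 0.001 well-scaled for
any L.  Optimization is one SGD update per example, shuffled each
epoch, with best-validation checkpointing.  Two numerical choices
matter: single-precision arithmetic (the convolutions are im2col +
GEMM), and zero-initializing each block's second convolution so the
untrained network is the identity on top of its stem — without that
the 8-block stack amplifies activations and SGD diverges.

The three-head variant predicts states 2, 3 (high-energy) and 4
simultaneously with a shared backbone and summed per-head losses; the
full pathway is an elementwise piecewise-linear interpolation through
[A, s2, s3, s4, B], so 5 points return exactly the anchors.

# Reconstruction

A predicted matrix becomes coordinates by restrained simulated
annealing: a single-basin model of the reference state has its
contacts inside the declared changing regions removed and replaced by
flat-bottom harmonic restraints (strength 2.0 kJ/mol, half-width
0.05 nm) at r0 obtained by inverting the sigmoid at the predicted D
(>= 0.5 pairs only) — the inversion uses the full prediction rather
than pinning every restraint at 1 nm.  Ten runs (default) cool
linearly from 100 K to 10 K over 3x10^6 steps; the structure with the
smallest mean squared restraint violation is selected, and all runs
are kept.  Bond lengths are checked to remain within 10% of the
reference.

# Synthetic fixtures, and what passing them shows

The generators live in the package as first-class, tested code.

The **toy two-state hinge** is two ideal helical arms (0.38 nm bonds)
joined by a four-residue linker; the closed form packs the arms
antiparallel with ~45 inter-arm contacts, and the open form rotates
the second arm by `hinge_angle` about the axis through the last two
linker residues, so bonds and angles are bitwise identical between
states and only hinge dihedrals differ.  At 90 degrees the RMSD is
1.3 nm.  Ground truth (RMSD, unique-contact sets, the hinge residues
with the largest contact change) is computed by brute-force scans at
generation time.  The fixture emulates a Category I/II two-domain
opening with a clean contact signature; it does not emulate real
residue-type statistics, irregular loop geometry, fold switching, or
the all-atom packing a shadow contact map would see — so tests passing
on it validate the machinery, not accuracy on real proteins.

**Analytic landscapes** (flat, quasi-1D double well with barrier b
exactly, a walled channel with a single Gaussian saddle, and random
sums of Gaussians) provide closed-form saddles for the search; the
**minimax oracle** is exact on any grid.  The **synthetic corpus**
draws pairs of random compact chains, featurizes them, and sets the
transition-state target by a known rule (elementwise min, geometric
mean, or midpoint on unique pairs, midpoint elsewhere).  A model that
recovers the elementwise-min rule on held-out examples (r = 0.98 here)
demonstrates the architecture can learn deterministic contact-map
maps; the overfit harness uses the smooth midpoint rule because the
min rule's jump at the contact threshold puts an error floor under any
smooth network, which is a property of the rule, not of the trainer.

# Problem sizes used by the test suite

Metadynamics on the 40-residue toy runs 3-6x10^5 steps (the quasi-1D
double-well fixture 8x10^5 at T = 200 K); path searches use 40-50
cell grids; training uses L = 32 corpora of 20 (overfit) and 200+50
(rule recovery) examples for 2000-3000 SGD steps; annealing uses 2-6
runs of 1.5-3x10^5 steps.  These sizes were chosen so each stage's
behavior is measurable and stable under its stated tolerance.

# Known limitations

- C-alpha only; no side chains, no all-atom back-mapping.
- RMSD collective variables cannot separate intermediates that happen
  to be equidistant from both endpoints; the source notes the same
  limit.
- Desk-scale metadynamics leaves kB-T-scale noise in the surfaces;
  barriers are best read from projections or minimax crossings, not
  single grid cells.
- The I-versus-II rigid-block heuristic replaces human inspection and
  is scale-sensitive (its 30-residue block minimum is meaningless for
  chains much shorter than 100 residues).
- The dual-basin mixing of conflicting dihedrals (halving) is one
  defensible choice among several; the true recipe of the upstream
  method is not public in the text we implement from.
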