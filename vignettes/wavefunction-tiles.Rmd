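---
title: "Wavefunction tiles by dynamic Voronoi Metropolis sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefunction tiles by dynamic Voronoi Metropolis sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An N-electron spatial wavefunction lives in 3N dimensions and is
antisymmetric under exchange of like-spin electrons.  Relabelling the
N&alpha; alpha electrons (or the N&beta; beta electrons) among themselves
maps the wavefunction onto itself up to a sign, so configuration space
decomposes into N&alpha;!&middot;N&beta;! equivalent regions -- *tiles* --
each containing all of the wavefunction's information.  This package
realises the tiles as Voronoi cells: a reference point `x̄` (the *site*)
defines a cell consisting of all configurations closer to `x̄` than to any
of its like-spin permutation images.  The site is required to be
self-consistent,

    x̄ = ∫_R x Ψ²(x) dx / ∫_R Ψ²(x) dx ,

i.e. the |Ψ|²-centroid of its own cell `R`.  Because Metropolis walkers
sample |Ψ|² directly, the centroid is estimated by a plain average of
walker positions folded into the cell, and the *dynamic* iteration
alternates sampling blocks with centroid updates until the site stops
moving (`run_dvms`).

Wavefunctions are CAS-CI expansions Ψ = Σᵢ cᵢ ψᵢ over spin-factored Slater
determinants of Gaussian-basis molecular orbitals (`read_molden`,
`read_civec`, `psi_value`).  Truncating the expansion after the leading
configurations (by |cᵢ|, degenerate groups kept whole, `truncate_ci`)
interrogates the effect of electron correlation; the *completeness* of a
truncation is its cumulative squared coefficient weight
(`ci_completeness`).

## Sampling

Walkers all start from one configuration, typically a local maximum of
|Ψ| located by BFGS ascent on log|Ψ| from a Lewis-like electron
arrangement (`find_psi_maximum`, `lewis_guess_benzene`).  Each Metropolis
step sweeps the electrons in order and proposes, for one electron at a
time, an isotropic Gaussian displacement with variance 0.2 bohr² per
dimension, accepted with probability min(1, Ψ'²/Ψ²).  Steps that change
the sign of Ψ are always rejected, confining each walker to the nodal
pocket it started in.

A design note on the proposal: the stated step variance together with
*whole-configuration* joint moves would multiply ~126 independent
per-dimension penalties into a Metropolis ratio of order e⁻⁵⁰, so a joint
chain simply never moves (we measured acceptance exactly 0 across four
orders of magnitude of step variance).  Single-electron trials at the
same per-dimension variance give 40--50% acceptance and are the standard
proposal in electron-configuration Monte Carlo; the package therefore
moves one electron per trial.  Two step-counting conventions are
offered (`scheme` in `run_walk`): `"sweep"` tries every electron once
per step (fast mixing; the default for site location, where only the
stationary distribution matters *and* for the occupancy protocol) and
`"single"` tries one uniformly chosen electron per step.  The
granularity matters only for time-dependent quantities: under sweeps
the benzene occupancy traces equilibrate within ~30 steps, so the
conventional discard of steps 1--500 is safely conservative, whereas
under single-trial counting the same physical relaxation stretches
over many hundreds of steps and the 501--2000 averaging window is
still transient-contaminated.  Occupancies therefore use sweeps.  The
*rates* extracted from a trace, however, are per *step*, and a
per-step rate is only comparable across codes once the number of
elementary trials per step is fixed -- a genuine ambiguity discussed
under limitations.  Ratios are evaluated incrementally with the
Sherman--Morrison update of the reference-determinant inverse plus the
determinant lemma for the excited configurations, and walker state is
rebuilt from scratch every 100 sweeps to stop floating-point drift; the
incremental route is cross-checked against direct determinant evaluation
in the test suite.

Walkers that wander out of the reference cell are *folded* back by the
optimal like-spin relabelling, found per spin as a linear-assignment
problem with squared-distance costs (`best_fold`); minimising the squared
distance over permutations is exactly nearest-site Voronoi classification
among the permutation images.  The permutation parity is tracked: an
odd fold lands on the opposite-signed copy of the tile, and the count of
odd folds is reported as a diagnostic rather than silently accepted,
because the tiling literature is ambiguous about whether cells should be
restricted to even permutation images.

## The benzene experiment

The shipped fixtures hold an RHF/6-31G(d) single determinant (cartesian
6d), an all-&pi; (6,6) CAS-CI and a valence (30,18) CAS-CI (15 valence
occupied + 3 lowest virtual orbitals, leading 400 of 665,856
determinants) for an ideal D6h benzene with r(C--C) = 1.397 Å and
r(C--H) = 1.087 Å.  The exact geometry used in the original analysis is
unpublished; these are standard DFT-quality bond lengths, and the
occupancy results are symmetry properties only weakly sensitive to them.
The fixtures were computed with the small self-contained RHF/CAS-CI
engine in `inst/engine` (validated against literature energies:
RHF/6-31G(d) benzene gives -230.70184 hartree) and every stored quantity
is re-checked in the tests against engine-evaluated reference values.

A single-determinant DVMS run converges to a Kekulé-like site: per spin,
six core electrons, six C--H bond electrons, and alternating one/two
electron C--C bonds (banana pairs above and below the plane), verified by
`bond_electron_counts` giving 2-1-2-1-2-1.  Rotating the nine C--C
bonding electrons of either or both spin sets by 60° about the C6 axis
yields the four reference sites (`build_reference_sites`): two
*eclipsed* structures (both spins in the same Kekulé pattern) and two
*staggered* ones (alternate patterns, three electrons per C--C bond).
The spec-level description speaks of rotating "the C--C bonding electron
spin sets"; a Kekulé spin set has 3 double-bond pairs + 3 single-bond
electrons = 9 electrons, and all nine move under the rotation.

With the (6,6) CAS-CI truncated to 7, 11 or 21 configurations, 500
walkers start at an eclipsed site and are classified among the four
sites at every step.  Equilibrium class means over steps 501--2000 carry
a decorrelation-corrected standard error: the per-step standard
deviation is divided by sqrt(n/200), the conventional 200-step
decorrelation allowance of this protocol (`equilibrium_occupancy`).
Under sweep counting the measured cell-assignment decorrelation is
considerably shorter, so this deflation overstates the error if
anything.  Block means over 501--1000 / 1001--1500 / 1501--2000 are
compared by z-tests (`block_stationarity`).  Because a trace started from a single
structure shows a nucleation lag before the first cell crossings -- a
sigmoidal onset no pure exponential can represent -- `fit_kinetics`
starts its exponential fit at the first step that has covered 20% of
the distance to the plateau; on lag-free synthetic traces this changes
nothing (tested), while on the benzene transients it removes a
several-fold downward bias in the rate.  The single-determinant wavefunction is
multiplicatively separable in the spins and shows no staggered/eclipsed
preference (verified as a null test); correlation introduces a small
(~3%) class asymmetry.

A finding worth stating plainly: the *direction* of that small
asymmetry is delicate.  Truncated CI expansions are not invariant under
rotations within degenerate orbital pairs (benzene's e1g HOMOs and e2u
LUMOs), so the fixtures canonicalise every degenerate pair by symmetry
adaptation (mirror-plane even/odd components, signs fixed); the
degenerate coefficient groups are then exact -- boundaries at 1, 3, 5,
7, 11, ..., 21 configurations -- and truncations keeping whole groups
are frame-independent, fully symmetric states (adapting to the
atom-plane or the bond-plane mirror gives identical spectra and
occupancies).  With that canonical choice the shipped (6,6) expansions
show a slight *eclipsed* preference at equilibrium, while
symmetry-broken orbital sets (raw eigensolver output, or orbitals at a
slightly distorted geometry) can invert the preference to staggered at
the same magnitude.  Readers comparing against external analyses of
this system should keep this sensitivity in mind.  Every validation
layer of the package supports the computed numbers: an independent
Slater--Condon recomputation of the fixture expansion's energy, a
bit-exact replay of the sampling kernel against direct wavefunction
evaluation, the unbiased single-determinant null, and textbook
real-space left-right correlation recovered for H2 FCI by the same
machinery.

The staged protocol (`staged_truncation_run`) enlarges the (30,18)
expansion group by group, restarts walkers of an eclipsed and a
staggered lineage at their previous sites, re-centres each site with a
sampling block (first 25% discarded as the start-up transient), and
records |Ψ| at both sites.  The crossing stage is defined
persistently -- the first stage from which the staggered lineage's |Ψ|
stays above the eclipsed one's -- because at very short truncations the
two sites are symmetry-equivalent images and single-stage comparisons
are pure noise.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `step_variance` | 0.2 bohr² | per-dimension Gaussian trial variance for the moved electron |
| `n_walkers` | 500 (occupancy), 100--200 (DVMS) | ensemble size |
| `block_steps` | 2000 | sweeps per DVMS cycle |
| `tol` | 0.05 bohr | max-norm site displacement, averaged over `settle` = 3 cycles |
| `burn_frac` | 0.25 | block fraction excluded from centroids |
| `decorrelation` | 200 steps | error deflation for occupancy means |
| `degeneracy_tol` | 1e-6 | coefficient-magnitude tie tolerance in truncation |

The convergence criterion (0.05 bohr averaged over three consecutive
cycles) is a robustness choice: single-cycle displacements at practical
walker counts are Monte-Carlo noisy, and averaging three cycles makes
the test insensitive to single outliers.  The degeneracy tolerance is
appropriate for point-group-exact degeneracies computed at solver
precision.

## Toy systems and what the tests show

`make_toy` provides analytic systems built from the same Gaussian
machinery: `two_electron_triplet` (two same-spin electrons, node exactly
at x₁ = x₂, tile centroids known by quadrature), `two_plus_two` (the
separable 4-electron product), and `double_well_ci` (one electron, two
configurations whose coefficient ratio tunes two-cell occupancy -- the
minimal analogue of the eclipsed/staggered competition).  Every analytic
reference is re-derived in the test suite by deterministic grid
quadrature (`tile_quadrature`), never trusted from constants.

These toys exercise every pipeline stage in low dimension, where
quadrature ground truth exists.  What passing them does *not* show is
accuracy for real correlated molecules beyond the shipped benzene
wavefunctions: the fixtures freeze one geometry, one orbital set and one
CI solver tolerance, and degenerate-orbital rotations or another
geometry would change individual coefficients (though not the symmetry
conclusions).

## Numerical choices and degenerate inputs

* Truncated expansions are **not** renormalised: the Metropolis ratio is
  scale-invariant, so occupancies are unaffected (tested).
* Classification ties (exactly equidistant sites) break towards the
  lowest site index; this is a measure-zero event under sampling.
* Walkers may not start on a node (|Ψ| = 0 start is an error with
  guidance), and a singular reference determinant mid-run aborts rather
  than silently degrading.
* Proposed moves whose reference-determinant ratio underflows are
  treated as node-crossings and rejected.
* Cube files are written in bohr with z-fastest ordering; XYZ files in
  Å.  Both round-trip bit-stably through the package's own readers.

## Problem sizes

Default analysis runs use 500 walkers × 2000 sweeps per truncation for
occupancies, 150 walkers × 800-sweep blocks for locating the
single-determinant site, and 80 walkers × 300-sweep blocks per stage of
the staged (30,18) protocol; the test suite uses proportionally reduced
ensembles with correspondingly widened Monte-Carlo intervals.  These
sizes were chosen so the full analysis reproduces the reference
occupancies within their quoted 2σ errors.

## Known limitations

* No importance-sampled, force-biased or parallel-tempered moves; deep
  nodal pockets are explored only through the plain Metropolis kernel.
* Kinetics are summarised by a symmetric two-state model; the single
  reported rate is interpreted as the per-direction crossing rate, which
  differs from the relaxation rate by a factor ~2 near 50/50 occupancy.
  More fundamentally, a per-step rate depends on how many elementary
  electron trials one "step" contains: the same physical dynamics gives
  a ~40x higher per-step rate under full sweeps than under one-trial
  steps.  Equilibrium occupancies, completeness and the crossing stage
  are unaffected by this convention; only absolute per-step rates (and
  the decorrelation length expressed in steps) carry it.
* The Molden reader supports cartesian (6d) files only; spherical [5D]
  inputs are rejected with a message.
* The in-repo engine regenerating the fixtures is a minimal RHF/CAS-CI
  code (no symmetry, no DFT, dense/Davidson CI only) intended for
  reproducibility, not production electronic structure.
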