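---
title: "Models and methods behind conformscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind conformscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

conformscape characterises the conformational space of a G
protein-coupled receptor — concretely, the angiotensin II type 2
receptor (AT2R), whose helix 8 packs atypically into the transmembrane
bundle in the inactive state — from molecular dynamics output. This
vignette explains each model the package implements, the parameters that
matter, what the synthetic generators emulate, and the numerical choices
made where the design was genuinely open.

## Collective variables

Two internal coordinates summarise the intracellular conformation:

* **distance sum** — the Cα distance 2.40–5.63 plus 2.40–6.25
  (Ballesteros–Weinstein numbering). TM2 is conformationally stable, so
  the two legs report the openness of intracellular TM5 and TM6.
* **helix-8 dihedral** — the torsion over the Cα atoms of 8.54, 7.56,
  7.54 and 7.47, describing the swing of helix 8 between the membrane
  plane and the bundle core.

Ballesteros–Weinstein resolution is pure arithmetic within a helix,
`residue(x.n) = anchor(x) + (n − 50)`; positions outside the helix's
residue range are rejected rather than extrapolated, because the scheme
is undefined beyond the helix. `at2r_bw_map()` pins the anchors from
published position labels (e.g. P271 at 6.50, N315 at 7.50).

The dihedral is the IUPAC signed torsion mapped into [0°, 360°). The
wrapped scale is deliberate: the inactive-like helix-8 orientation sits
above 200°, which a (−180°, 180°] convention would split across the
discontinuity. All dihedral comparisons in the tests are made on the
circle (difference wrapped to (−180°, 180°]).

Both observables are functions of internal geometry only, so they are
invariant under rigid rotation and translation; the suite asserts this
to 10⁻⁹ over random rigid motions.

## Fluctuation, mode and correlation analysis

RMSF, principal components and the dynamic cross-correlation matrix
(DCCM) all start from the same superposition: every frame is fitted
onto the mean structure by the optimal least-squares (Kabsch) rotation,
and the mean is re-estimated once and the fit repeated. Iterating
twice is the default of the common trajectory tools; the superposition
can be disabled for pre-aligned input.

With maximum-likelihood normalisation (divisor `n_frames`) the PCA
eigenvalues partition the same total variance the RMSF measures:
`sum(rmsf²) = sum(eigenvalues)`, asserted on toy data. DCCM entries are
normalised displacement covariances; a residue with zero displacement
variance has *undefined* correlation, reported `NA` rather than 0 —
a zero would wrongly claim "uncorrelated". The 0.3 display mask only
affects plots and exports, never stored values.

Ligand contacts count a residue as contacting in a frame when any of
its atoms (Cα in the reduced representation used here) lies within 4 Å
of any ligand atom; residues in contact in at least 60% of frames form
the highly-contacting set. Both thresholds are exposed as arguments.

## Free-energy landscapes

The landscape is Boltzmann inversion of the 2-D histogram over the two
collective variables: `F(bin) = −kT ln(n_bin / n_max)`, so the modal
bin sits at zero and every other occupied bin is a positive free
energy. Empty bins are `NA` — an unvisited region carries no estimate,
and writing 0 there would fabricate a deep basin. Defaults: 100×100
bins over the observed range padded 2%, kcal/mol at 300 K (the usual
simulation temperature), with a kT-units switch. Bin assignment is
half-open `[lo, hi)`: a point exactly on an interior edge belongs to
the higher bin. The deepest-basin normalisation makes free-energy
*differences* invariant under duplicating the sample set, which the
suite asserts; an additive count offset is **not** an invariance of
Boltzmann inversion.

## Markov state model

The MSM stage mirrors standard practice: z-score the two collective
variables (they live on incommensurate unit scales — angstrom versus
degree — so unscaled k-means would be dominated by the dihedral),
cluster into microstates with k-means (default k = 500, reduced to
`frames/10` when data are scarce; for large frame counts the clustering
is fitted on a 20,000-frame subsample and all frames assigned to the
nearest fitted centre), count sliding-window transitions at a lag
(never across trajectory boundaries), and row-normalise.

The default estimator symmetrises the counts, `(C + Cᵀ)/2`, giving a
reversible chain whose stationary distribution is proportional to the
symmetrised row sums and which satisfies detailed balance exactly.
This was preferred over iterative maximum-likelihood reversible
estimation because it is deterministic, closed-form, and adequate at
this scale; the naive row-normalised estimator is retained because it
is the correct object to compare against a generating matrix in
oracle tests. Disconnected count graphs are restricted to the largest
connected set with a warning.

Implied timescales are `tᵢ = −τ / ln λᵢ`. The Markovian lag is chosen
as the smallest lag from which the slowest timescale varies by less
than 10% (relative) across all larger scanned lags; when no lag
qualifies the scan is flagged non-Markovian. In the acceptance checks,
"flat within 10%" is measured as every `t₂(lag)` lying within ±10% of
the mean over lags 1–10 — a tolerance band around the central value.

Macrostates come from PCCA+: the rows of the first `n` right
eigenvectors of the reversible transition matrix lie in an
`n`-vertex simplex; vertices are located by the inner-simplex
(maximal-spread) construction, fuzzy memberships are the barycentric
coordinates, and crisp states take the membership argmax. The
subsequent objective optimisation of full PCCA+ is omitted — on
well-separated metastable states the simplex construction already
recovers the blocks, which is what the tests assert. Macrostate
proportions are exported both π-weighted and raw-count-weighted; on
converged sampling the two agree.

Transition "times" between macrostates are mean first passage times:
the committor solves its linear system (0 on the source, 1 on the
sink), the passage times solve the first-passage system with the sink
absorbing, and the MFPT averages the source states weighted by the
stationary distribution restricted to the source, in physical units of
`lag × frame_interval`. An unreachable sink yields an infinite MFPT
marker, not an error.

Representative conformations maximise the total similarity
`S = exp(−d / d_scale)` over a macrostate's candidate frames, where
`d_scale` is the (sample) standard deviation of the pairwise distances.
Distances are RMSD between snapshots when coordinates are available and
Euclidean distance in the z-scored collective-variable space otherwise.
Ties break to the lowest frame index, and an all-zero distance matrix
returns the first frame.

## Statistical coupling analysis

Conservation at a position is the relative entropy between the dominant
residue's observed frequency `f` and a background frequency `q`:
`D = f ln(f/q) + (1−f) ln((1−f)/(1−q))`. The background defaults to the
uniform `q = 0.05`; a named per-residue table can be supplied. One
all-gap row is appended to every alignment before any frequency is
computed — with it no frequency reaches exactly 1, keeping `D` and its
derivative finite (the zero-frequency guard).

The coupling matrix uses the analytic slope
`∂D/∂f = ln[f(1−q) / (q(1−f))]`:
`C_ij = ∂D/∂f(i) · ∂D/∂f(j) · |f_ij − f_i f_j|`, with `f_ij` the joint
frequency of both dominant residues. Exactly independent columns give
0; duplicated columns give `(∂D/∂f)² f(1−f)`. Dominance ties break
alphabetically; gaps are never dominant but do inflate denominators.

Sectors come from the eigenvectors of the coupling matrix with the
diagonal zeroed (so sectors reflect coupling, not self-conservation; a
switch restores the diagonal). The first mode is dropped as the global
signal. "Weight" is read as the signed loading, with each eigenvector's
sign fixed so its largest-magnitude component is positive — without a
sign convention the red/blue rules are not reproducible, and the
negative-threshold branch of the blue rule would be vacuous under an
absolute-value reading. Red positions satisfy `v₂ > v₄` and `v₂ > ε`;
blue positions satisfy `(v₂ < v₄ and v₂ < −ε)` or
`(v₄ > v₂ and v₄ > ε)`; ε defaults to 0.05.

Domain summaries report mean ± sample standard deviation of the
conservation score over residue ranges; composite rows (ICLs, "All
loops", "All TMD") pool their member ranges before averaging.

## Nudged elastic band

A band of replicas linearly interpolated between two fixed endpoints is
relaxed so that the true force acts only perpendicular to the local
tangent and the spring force only parallel to it. The tangent is the
energy-weighted upwind tangent: forward difference going uphill,
backward difference going downhill, and at local extrema a blend of
both differences with the larger energy jump weighting the
higher-energy side; the blend reduces to the monotone cases when the
two jumps are equal. The tangent is normalised to unit length because
the projections need a direction, and when the energy weights cancel
(a transiently disordered band during annealing) the central difference
`R_{i+1} − R_{i−1}` is used as a fallback before declaring degeneracy.

The spring force magnitude is `k(|R_{i+1}−R_i| − |R_i−R_{i−1}|)` along
the tangent — the canonical choice consistent with a pure parallel
projection. Note it is norm-based: a self-crossing of the band is
invisible to it, which is why annealing noise must stay small (see
below).

Relaxation follows an annealing schedule whose phases mirror the usual
protocol — heat with a soft spring (k = 10), equilibrate with the
production spring (k = 50), a hot anneal cooling to zero, then a
zero-temperature quench — expressed in optimizer steps, since the
package relaxes analytic surfaces rather than solvated proteins. Phase
temperatures are in the surface's energy units and should be kept small
against `k · spacing²`; the default 0.01 satisfies this for the
built-in benchmarks. The final quench uses FIRE (fast inertial
relaxation), the standard accelerated minimiser for elastic bands;
convergence requires the perpendicular true force *and* the projected
spring force to drop below the tolerance (default 10⁻³), i.e. the band
lies on the minimum-energy path with equilibrated spacing. On the
analytic benchmark surfaces the tests run the quench alone
(temperature 0): thermal phases exist to shake a band off bad initial
geometry on rugged landscapes and add nothing on smooth two-well
surfaces, while their noise can transiently cross replicas.

On the 1-D double well `x⁴ − 2x²` the perpendicular force vanishes
identically, so the relaxed band is the uniformly spaced chain between
the minima; with 52 interior replicas the replica nearest the barrier
top sits at |x| = half the spacing ≈ 0.019. On the Müller–Brown
surface the band passes within grid accuracy of both saddle points
located by an independent dense grid search.

Replica post-processing: `align_replicas()` removes rigid-body
differences by sequential Kabsch superposition (proper rotations
enforced); `select_diverse_replicas()` picks maximally different
replicas by greedy max–min distance with the endpoints always included
(deterministic low-index tie-break), with an adjacent-gap mode as the
alternative reading of "most different".

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage can be verified against known
ground truth without multi-microsecond trajectory archives.

**Brownian collective-variable trajectories.** The default surface
places three inverted-Gaussian wells at the receptor's reported basin
coordinates — active-like (54 Å, 105°), intermediate (53.5 Å, 188°),
inactive-like (55.5 Å, 216°) — with depths 3.2/4.4/4.1 kT chosen to
give distinct equilibrium weights (≈ 0.25/0.38/0.37, comparable to the
reported macrostate proportions) and barriers low enough that a
10 × 50,000-step run hops between basins hundreds of times. A soft
quadratic wall (centres ± 2 widths, length scale half the smallest
width) bounds the landscape, as the physical variables are bounded by
the fold and the dihedral period; without it the flat plateau would
carry unbounded Boltzmann mass. The integrator is Euler–Maruyama,
`x ← x − μ ∇V dt + √(2 μ kT dt) ξ`, with per-axis mobilities (5, 300):
the two coordinates live on incommensurate unit scales, and an
isotropic mobility in Å/degree units would manufacture an artificial
slow diffusive mode along one axis (during design this exact artifact
made the spectral lumping split the plateau instead of the basins).
Trajectories start round-robin at the well centres, mimicking
production runs seeded from structures spread along a transition path.
Every 20th step is saved as a frame. Ground-truth labels are
nearest-well in width-scaled coordinates.

What this does *not* emulate: the atomistic origin of the collective
variables (no roughness on the surface, no multiscale friction, no
memory effects from projecting out thousands of degrees of freedom),
metastable states outside the chosen wells, and the far slower
transition rates of the real receptor. Passing tests show the analysis
stack recovers the kinetics and thermodynamics of a system that *is*
Markovian in the collective variables; they cannot show that two
collective variables suffice for any particular receptor.

**Markov-chain label sequences** are seeded categorical samples from a
given row-stochastic matrix — the oracle source for timescale and
first-passage tests.

**Synthetic alignments** draw positions independently from a uniform
background except for: conserved positions (a designated residue at a
target frequency); coupled groups sharing a per-sequence hidden binary
state, each member copying the state residue with probability
`coupling`; and a global latent state touching every position with
probability 0.5, standing in for the shared phylogenetic signal of real
alignments. The global strength is deliberately large enough that the
leading eigenvector of the coupling matrix is the global mode even when
a tightly coupled sector is planted — which is precisely why the sector
rules drop the first mode. The model has analytically checkable limits
(coupling 0 → independence; coupling 1 → duplicated columns) but no
phylogenetic tree structure, so it cannot test tree-aware reweighting
(out of scope).

**The toy helix bundle** is an idealised four-helix PDB fixture (3.6
residues/turn, 1.5 Å rise, 2.3 Å helix radius, bundle radius 6 Å) with
a pseudo-ligand at the centre and a matching Ballesteros–Weinstein map
whose anchors are the helix midpoints — enough to exercise parsing,
featurization and contact analysis end to end.

## Problem sizes and numerical notes

The shipped checks use 10 × 50,000-step Brownian runs (25,000 saved
frames), 500 microstates, lags 1–10; 500-sequence × 100-position
alignments over 20 replicate seeds; 52-interior-replica bands. The
Müller–Brown quench uses step 10⁻⁴ against gradients of order 10³; the
double-well quench uses 2 × 10⁻³, keeping the spring chain
(stability bound `h < 2/(4k)`) well inside its stable regime. k-means
uses a fixed seed everywhere; all generators are pure functions of
(spec, seed). Eigen-decompositions of reversible transition matrices go
through the symmetric similarity transform `D^{1/2} T D^{−1/2}`, so the
spectrum is real by construction rather than by truncation.

The worked example on the deposited AT2R crystal structures (the
antagonist-bound and agonist-bound entries) requires downloading those
coordinates with `fetch_at2r_structures()`; they are not redistributed
with the package. Expect the recomputed collective variables to land
within about 1 Å / 5° of the published values — the residual reflects
structure-preparation differences (capping, back-mutation) upstream of
featurization.

## Known limitations

* The reversible estimator ties the stationary distribution to the
  empirical state visitation; severely out-of-equilibrium ensembles
  need longer sampling rather than estimator corrections.
* PCCA+ here is the simplex-vertex construction without the follow-up
  membership optimisation; for weakly separated states the crisp
  boundaries can wander.
* The norm-based spring force cannot detect band self-crossings;
  anneal gently or quench from a sensible interpolation.
* Contact analysis in reduced mode sees only Cα atoms, which
  understates contact fractions relative to all-heavy-atom counting.
* No MBAR/WHAM reweighting, no Bayesian MSM uncertainty, no hidden
  Markov models, no climbing-image band variant.
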