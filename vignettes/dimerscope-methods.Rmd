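---
title: "Methods: models, parameters and design choices in dimerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in dimerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

dimerscope characterizes weak, transient protein homodimers. This vignette
is the package's own account of the models it implements, the parameters
that matter, the numerical choices behind them, and what the synthetic-data
generators do and do not emulate.

# The setting

Membrane-anchored small GTPases such as K-Ras form homodimers whose
protein–protein interfaces are so weak (millimolar dissociation constants)
that the complexes are essentially invisible in solution and become
populated only when membrane binding concentrates the protomers in two
dimensions. Characterizing such dimers computationally means (i) proposing
candidate interfaces by symmetric docking, (ii) discarding candidates that
are incompatible with the protein's biology, (iii) quantifying the surviving
interfaces, (iv) estimating their thermodynamic stability from free-energy
profiles, and (v) connecting the predictions to spatial-clustering readouts
from electron microscopy. dimerscope implements each of these layers behind
a small, testable surface, with synthetic generators providing ground truth
for every input class.

# Structures and geometry

Structures are read from PDB via bio3d and stored with coordinates in nm
(PDB Å are converted on input; a single internal unit prevents cutoff
mistakes). Alternate locations resolve to the highest-occupancy conformer;
waters and hetero groups are dropped unless requested. Author residue
numbering is preserved so that biologically meaningful residue ids (94, 95,
101, 107, ...) can be used directly in selections and filters.

Superposition is the Kabsch algorithm (SVD of the cross-covariance with the
determinant correction, so the result is always a proper rotation). It is
cross-checked in the test suite against bio3d's independent implementation.

Secondary structure is assigned from backbone dihedral windows — helix:
$\varphi \in [-120,-30]$, $\psi \in [-80,0]$ in runs of at least 4; strand:
$\varphi \le -90$ or $\ge 150$ with $\psi \ge 90$ or $\le -150$ in runs of
at least 3; otherwise coil — because the only distinction the viability
filters need is "regular structure vs flexible loop". A full DSSP
reimplementation would add hydrogen-bond bookkeeping without changing any
downstream decision; a user-supplied assignment can override the dihedral
call. Terminal residues are judged on their single defined dihedral.

# Solvent-accessible surface area

SASA uses the Shrake–Rupley construction: each atom's radius is expanded by
the probe (default 0.14 nm, the conventional water probe) and the exposed
fraction of a point lattice on that sphere is counted. The lattice is a
deterministic golden-section spiral, so results are bit-reproducible at a
given density; `n_sphere_points` defaults to 960 (relative error against
the analytic two-intersecting-spheres formula is below 0.1% there). Because
an occluded lattice point in the dimer is necessarily occluded in the
monomer, the buried area
$\Delta SASA = SASA(A) + SASA(B) - SASA(AB)$ is non-negative for *every*
geometry at *every* lattice density — an exact property, which the tests
exercise on a thousand random rigid arrangements.

Heavy atoms carry united-atom van der Waals radii (C 0.170, N 0.155,
O 0.152, S 0.180, H 0.120, P 0.180 nm), so structures without hydrogens —
the normal situation for docking output — are handled directly.

A residue is *interfacial* when it buries more than 0.01 nm², which is the
noise floor of the point sampling at the default density. Relative exposure
divides a residue's area by a reference maximum computed self-consistently:
the residue's SASA at the centre of an extended Gly-X-Gly tripeptide built
by the package's own geometry with the same radii and probe. Literature
all-atom Gly-X-Gly tables assume hydrogens and different radii and would
make the ratio scale-inconsistent with this engine. The exposure threshold
(0.25, inclusive) is the conventional exposed/buried boundary.

One caveat of quadrature by indicator functions: the *pointwise* error at a
fixed geometry does not shrink monotonically with lattice density (the
boundary crosses cells discretely). The error averaged over geometries
does, and that is the form the convergence test asserts.

# Interface descriptors

The five standard descriptors are computed per frame and summarized over
conformer ensembles (mean ± sd, plus a centred running average whose window
is configurable):

- **Hydrogen bonds**: donor–acceptor heavy-atom distance ≤ 0.30 nm and,
  when the donor carries hydrogens, deviation from donor–H–acceptor
  linearity ≤ 20°. Without hydrogens the angle term cannot be evaluated;
  the detector falls back to the distance-only criterion and flags the
  fact in its output rather than silently changing definition.
- **Hydrophobic contacts**: the number of carbon atoms in monomer A with at
  least one monomer B carbon within 0.38 nm. This atom-level count is
  asymmetric in the labels by definition; a symmetric variant is exposed by
  flag.
- **d_COM**: mass-weighted centre-of-mass distance between the monomers.
- **Relative orientation δ**: monomer A is superposed onto a reference
  arrangement; δ is the axis-angle magnitude
  $\arccos((\mathrm{tr}\,R - 1)/2)$ of the residual rotation taking monomer
  B onto the reference's monomer B. The reference defaults to the first
  frame. This is a deliberate, documented stand-in: axis-angle magnitude is
  the canonical scalar summary of a relative rotation, vanishes at the
  reference, and is invariant to global rigid motion.
- **ΔSASA**, as above.

Salt bridges are basic/acidic residue pairs with any charged-group N–O
distance ≤ 0.4 nm (Lys NZ; Arg NE/NH1/NH2; Asp OD1/OD2; Glu OE1/OE2;
His ND1/NE2 only when flagged protonated — neutral His is the default
because the assay pH is near neutral). π-stacks are aromatic ring pairs
with centroid distance ≤ 0.55 nm, classified parallel below 45° of
inter-normal angle and t-shaped above; ring normals come from an SVD plane
fit, so incomplete rings are skipped with a warning rather than fitted
badly.

Quasi-symmetry of a homodimer interface is the Jaccard overlap of the
residue-id sets each monomer contributes to the interface: 1 for an exact
two-fold interface, 0 for disjoint contributions. Note that a translated
copy of a monomer is *not* two-fold symmetric — only a 180° rotation about
the inter-monomer axis is — and the score reflects that.

# Docked-pose clustering and viability filters

Pose distance is interface Cα RMSD: superpose monomer A, measure over
monomer B, minimized over the two label assignments (a homodimer pose and
its label swap are the same physical object). Clustering is greedy-leader:
leaders in descending neighbourhood-density order, each absorbing all
unassigned poses within the radius (default 0.4 nm — comfortably below the
≥ 1 nm separation of genuinely distinct binding modes and above docking
jitter). The published algorithms behind docking packages' own clustering
are not reproduced; leader clustering with an explicit radius is
deterministic, auditable, and monotone (tightening the radius never merges
clusters). Clusters under 5% enrichment are flagged minor and eliminated,
mirroring the conventional cluster-size cutoff; a minor cluster can be
promoted explicitly, which represents the manual judgement call of keeping
a small cluster supported by independent evidence.

The three filters act on cluster representatives (the member minimizing
summed intra-cluster RMSD; ties to the lowest index for determinism):

1. **Interface composition** — the interfacial residue set must intersect
   the reactive set (co-evolution hotspots and/or probe-predicted reactive
   surfaces, supplied as residue lists) *and* contain at least one
   helix/strand residue. Interfaces made up solely of flexible loops are
   rejected.
2. **Effector-loop exposure** — the mean relative SASA of the
   effector-binding loop, evaluated in the dimer context, must be at least
   0.25 for *both* protomers. The loop range is configuration (default
   25–40, the switch I region); nothing in the geometry depends on the
   specific numbering.
3. **Membrane competence** — both protomers' anchor-residue Cα must lie in
   the same half-space of the best-fit plane through the dimer's Cα cloud
   (least-variance SVD direction) and be solvent exposed. This is a
   geometric proxy for "both lipid anchors can insert into one membrane".

Every cluster gets an audit row with each verdict and a reason string, so a
run is reviewable after the fact.

# Binding thermodynamics from a PMF

The mean force $F(r)$ sampled along d_COM is integrated by the trapezoid
rule from the outer grid edge inward, $W(r) = -\int F\,dr$, and shifted so
the mean of $W$ over the reference window vanishes. The unbound reference
is d_COM > 4.6 nm by default; the estimator refuses to proceed when the
reference window is not flat (max |W| ≥ 0.2 kcal/mol), since K_d is
meaningless without a defined unbound state. Pointwise PMF error
accumulates per-segment variances $(\Delta r/2)^2(s_k^2+s_{k+1}^2)$ from
the reference edge, hence grows toward small r.

The association constant is the one-dimensional radial configurational
integral
$$K_a = \frac{1}{V^\circ} \int_{bound} 4\pi r^2 e^{-W(r)/RT}\, dr,
\qquad V^\circ = 1.661\ \mathrm{nm}^3,$$
the volume per molecule at 1 M. The $4\pi r^2$ Jacobian is the standard
choice for a radial coordinate; a no-Jacobian variant is exposed by flag
for comparison. The bound window defaults to the grid start up to the first
point past the principal minimum where $W \ge -RT$ — the thermal boundary
of the well — and is configurable because the window is a physical
modelling decision, not a numerical one.

Two conventions deserve emphasis. First, $\Delta G_{bind} = RT\ln(K_d/1\,M)$:
this is the convention under which the canonical weak-dimer reference pairs
round-trip (5 mM ↔ −3.16 ≈ −3.1 kcal/mol and 107 mM ↔ −1.33 ≈ −1.3
kcal/mol at 300 K; R = 1.9872×10⁻³ kcal/(mol·K)). The inverted form
$K_d = e^{-\Delta G/RT}$ sometimes seen in print is inconsistent with those
numbers. Second, uncertainty: the reported K_d standard error is obtained
by *parametric resampling* — force noise is redrawn from the stated
standard errors, re-integrated, re-referenced, re-windowed and
re-integrated to K_d (200 replicates, internally seeded). A first-order
delta-method propagation was tried and rejected: it cannot see the
sensitivity of the bound-window selection to noise and undercovers
(93/100 within 2 SE versus 97/100 for the resampling scheme, at a force
noise of 0.5 kcal mol⁻¹ nm⁻¹ on a 0.02 nm grid). Only the K_d/ΔG pair is
reported: on- and off-rates individually are not constrained by a PMF and
are deliberately not computed.

Minima are reported with prominence-style depths (the lower of the two
flanking barriers minus the well bottom), so shallow corrugations are
separated from genuine wells by a depth threshold.

# Alanine scanning

Each interfacial residue is truncated to alanine (side chain beyond Cβ
removed, backbone untouched; Gly/Pro skipped with a reason, Ala a no-op)
with no conformational relaxation, and the change in inter-monomer
interaction energy ΔΔE = E_mut − E_wt is reported, positive for
stabilizing residues. The energy is a transparent fixed-parameter pairwise
sum: Coulomb with formal ±1 e charges spread over charged-group terminal
atoms and a distance-dependent dielectric ε = 4r (r in Å), plus 12-6
Lennard-Jones with per-element well depths and r_min equal to the sum of
the united-atom radii, all switched smoothly to zero between 1.0 and
1.2 nm. The deliverable is the *ranking* of residues, which is robust to
the absolute scale of such a schematic energy; absolute ΔΔG physics
(rotamer relaxation, desolvation, entropy) is explicitly out of scope.

# Co-evolution scoring

Column-pair mutual information is computed from sequence-weighted
frequencies (weights 1/neighbourhood size at 80% identity; pseudocount
λ = 0.5 per symbol over the 21-letter alphabet including the gap), columns
with > 50% gaps are masked, the average-product correction
$APC_{ij} = \overline{MI_i}\,\overline{MI_j}/\overline{MI}$ removes the
phylogenetic/entropy background, and the corrected scores are standardized
to z-scores over all unmasked pairs. The z-scale is what makes a fixed
hotspot threshold (score > 2.0, strict) meaningful across alignments; the
threshold itself is configurable because externally computed coupling
scores (which the package reads from three-column tables, symmetrizing and
rejecting conflicting duplicates) live on their own scales. A residue is a
hotspot when its best pair score exceeds the threshold *and* it is solvent
exposed (relative SASA ≥ 0.25) — buried covarying positions are structural,
not interfacial, signals. Column-to-residue mapping uses an ungapped
consensus match with ≤ 5% mismatches, or an explicit offset.

# Spatial statistics

Ripley's K uses the isotropic edge correction: each pair is weighted by the
reciprocal fraction of the circle of radius $d_{ij}$ centred on point i
that lies inside the rectangular window (closed-form arcs for edges with
corner-overlap subtraction, valid to half the shorter side). The estimator
is $\hat K(r) = \frac{A}{n(n-1)}\sum_{i\ne j} w_{ij}\,1[d_{ij}\le r]$; the
$n(n-1)$ denominator makes it exactly unbiased under complete spatial
randomness conditionally on n, which the tests verify to within 2 standard
errors over 200 simulated patterns at every grid radius. The r grid
defaults to 1–240 nm in 1 nm steps (the EM-scale convention), truncated to
a quarter of the shorter window side. $L(r)-r = \sqrt{K/\pi}-r$ is the
clustering summary; group curves are combined as weighted means with
weights proportional to pattern point counts (the natural choice when
patterns differ in labelling density), and the group statistic is the
maximum of the weighted-mean curve.

The bootstrap comparison resamples pattern labels across the pooled set
(group sizes preserved) and reports a two-sided p-value
$(1+\#\{|T^*|\ge|T|\})/(n_{boot}+1)$, floored at $1/(n_{boot}+1)$. Null
calibration is part of the acceptance suite: split halves of CSR replicate
sets reject at 5% no more than 10% of the time over 20 meta-replicates.

Simulators: homogeneous Poisson (CSR) and the Thomas cluster process
(Poisson parents simulated in a window expanded by 4σ to avoid edge bias;
Poisson(μ) offspring displaced by an isotropic Gaussian). Both are pure
functions of their seed.

# What the synthetic data emulate — and what they do not

The generators produce every input class with planted, recoverable truth:

- **Helical homodimers**: two ideal α-helices (φ = −57°, ψ = −47°, 0.15 nm
  rise) built by internal-coordinate chaining, at a planned axis separation
  and crossing angle. Side chains are schematic stubs; planted salt-bridge
  side chains are stretched so the charged termini sit exactly 0.32 nm
  apart at the interface midline, planted π-stack rings are placed with
  exact centroid gap and inter-normal angle, and all other long side chains
  point away from the partner so the planted contacts are the only
  engineered ones. The default sequence places His94/His95, Arg97, Glu98,
  Lys101, Arg102, Glu107 and Tyr137 on a helix numbered 86–137, so planted
  bridges (101→107, 98→97) read like their biological counterparts. An
  optional coil tail numbered 25–40 stands in for the effector loop, and a
  schematic exposed anchor residue (id 140, offset along +y) for the
  lipid-anchor attachment.
- **Pose ensembles**: rigid placements of monomer B around a fixed monomer
  A — four viable parallel placements, one hotspot-avoiding z-shifted
  antiparallel placement (fails the composition filter by construction) and
  one anchor-flipped antiparallel placement (fails the membrane filter) —
  with small rigid jitter inside clusters and uniform scatter elsewhere.
  The default fractions (20/16/14/12/10/8% plus a 4% minor cluster) mirror
  a realistic docking outcome in which six major clusters pass the 5% rule
  and two of them fail the biology filters, leaving four viable models.
- **MSAs**: i.i.d. background columns from a standard amino-acid frequency
  vector with planted pairs drawn from a two-state coupled distribution
  (E↔K / D↔R) at coupling 0.9 by default — strong but imperfect
  covariation, the regime where ranking is meaningful.
- **Mean-force profiles**: a Gaussian well
  $W(r) = -\mathrm{depth}\cdot e^{-(r-c)^2/2\sigma^2}$ (c = 3.6 nm,
  σ = 0.15 nm, grid 2.6–6.0 nm at 0.02 nm) whose analytic derivative gives
  the sampled force, plus i.i.d. Gaussian noise at the stated standard
  error (0.5 kcal mol⁻¹ nm⁻¹ in the noisy tests). The *true* K_d is
  computed from the analytic profile by adaptive quadrature under the same
  windowing convention, and the well depth for a target K_d (e.g. 5 mM)
  is found by bisection.

What passing tests on these fixtures shows is that the *estimators and
decision rules* are correct: detectors recover exactly what was planted,
the thermodynamic chain inverts its own construction with calibrated
uncertainties, clustering partitions what was generated. What it does not
show is anything about real conformational ensembles: ideal helices have
no rotamer disorder, no backbone flexibility, no solvent; synthetic MSAs
have no phylogeny (the sequence-weighting machinery is exercised, not
stressed); Gaussian wells have no barrier anharmonicity; simulated point
patterns have no detection noise or antibody-linker displacement. Claims
about real systems require real trajectories, alignments and micrographs
run through the same interfaces.

# Problem sizes and determinism

The test and acceptance workloads are sized for interactive iteration:
100-pose ensembles, 500 × 60 alignments over 20 seeds, 171-point force
grids over 100 noise seeds, 200 CSR patterns of ~400 points, 20 bootstrap
meta-replicates at 199 resamples, SASA property sweeps at 240-point
lattices with oracle comparisons at 960–3840. Every stochastic component
takes an explicit seed, is restored-state isolated (callers' RNG streams
are untouched), and produces byte-identical output on repeat; the pipeline
writes its config, seed and a config hash alongside its outputs so a run
directory is self-describing.

# Known limitations

- Secondary structure is a dihedral-window classifier, not DSSP; unusual
  geometries (π-helices, bulged strands) will read as coil.
- The hydrogen-bond angle term silently degrades to distance-only when
  hydrogens are absent (flagged per bond, but still a different
  criterion).
- The alanine-scan energy is schematic; only rankings should be
  interpreted.
- The relative-orientation δ is one reasonable scalarization of a relative
  rotation; other conventions (e.g. per-axis Euler decompositions) are not
  provided.
- K_d assumes a one-dimensional reaction coordinate along d_COM; slow
  orthogonal degrees of freedom would require higher-dimensional PMFs.
- Ripley analysis assumes a rectangular observation window; irregular
  windows are out of scope.
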