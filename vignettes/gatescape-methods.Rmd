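---
title: "Methods: gating geometry, permeation pathways and proton electrostatics"
author: "gatescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating geometry, permeation pathways and proton electrostatics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescape)
```

# Scope

Secondary transporters of the major facilitator superfamily (MFS)
work by alternating access: a central substrate site is exposed to the
two sides of the membrane in turn, and a cytoplasmic and a periplasmic
gate must never be open at the same time, or the proton gradient that
drives transport would leak away.  Deciding whether a given
conformation — a crystal structure, a homology model, or a frame of a
simulated transition — is cytoplasmically open, periplasmically open,
occluded, or leaky is therefore the central analytical question, and
no single measure answers it.  `gatescape` implements the battery of
complementary analyses used to make that call: geometric gate order
parameters, pore-radius profiles, water-density pathways, a continuum
electrostatic free-energy landscape for a solvated proton, predicted
DEER spin-label distance distributions, and conformational clustering.

All coordinates and distances are in Angstrom, energies in kJ/mol
(the kcal-to-kJ factor 4.184 enters exactly once, at the Born-equation
boundary), and cluster cutoffs in nm, following the conventions of
each analysis's community.

# Gate order parameters

The periplasmic gate of an MFS transporter is the packing of
transmembrane helices 1 and 7; the cytoplasmic gate is the packing of
helices 4 and 10.  `derive_gate_pair()` computes the full
C$\alpha$–C$\alpha$ cross-distance matrix between two helices on a
reference structure and freezes the closest-contact residue pair; the
order parameter for every subsequent frame is simply the
C$\alpha$–C$\alpha$ distance of that fixed pair (`gate_distance()`,
`order_parameter_trace()`).  Freezing the pair on a reference — rather
than re-minimising per frame — keeps traces continuous; ties in the
minimisation are broken toward lower residue numbers so degenerate
fixtures are deterministic.  For LacY the canonical anchors are
Ile32–Asn245 (periplasmic, frozen from the cytoplasmic-open crystal
structure) and Glu126–Cys333 (cytoplasmic, frozen from the
periplasmic-open model); the pairs for twelve MFS transporters ship in
`mfs_gate_table()`.

`classify_state()` partitions the order-parameter plane with two
thresholds, defaulting to 13 Å (cytoplasmic) and 8 Å (periplasmic):
below both is `occluded`, at-or-above exactly one is
`cytoplasmic_open` / `periplasmic_open`, and at-or-above both is
`leak`.  The thresholds describe where occluded-state ensembles have
been observed to sit rather than sharp physical boundaries, so they
are exposed as configuration (`state_thresholds()`); the `leak` label
makes the classifier total — it marks the quadrant a functioning
transporter must avoid.  Multi-chain structures use the chain given in
the helix ranges; when nothing is specified the first protein chain is
the default.  The bundled LacY helix ranges
(`lacy_helix_table()`) are approximate reconstructions from topology
annotations and are intended to be overridden.

# Pore profiles

`pore_radius_at()` reports, for a plane at height $z$ along the
membrane normal, the largest clearance sphere that can be centred in
that plane: the maximum over in-plane centres $c$ of
$\min_i(\lVert (c, z) - x_i \rVert - r_i^{vdW})$ over atoms within a
slab $z \pm 3$ Å (so spheres intruding into the plane are counted).
The maximisation runs Nelder–Mead refinements from a 5 × 5 grid of
starts inside a search box (half-width 5 Å by default — cavity scale;
a wider box reports a boundary-limited maximum when the clearance is
unbounded outward, and an empty slab returns an `Inf` sentinel).  This
is deliberately simpler than a path-following probe with simulated
annealing: it is deterministic and testable, and for straight
transporter bores gives the same profile; for strongly kinked pathways
whose centreline leaves the plane the per-plane maximum can differ,
which is the main caveat when comparing against path-following tools.
`pore_profile()` aggregates per-frame radii into a mean and a
population standard deviation per $z$ bin — the descriptive spread of
the ensemble, which for two alternating frames of radius 3 and 5 gives
exactly mean 4, SD 1.

# Water density and pathway connectivity

`water_density()` bins water positions into voxels per frame and
reports the time-averaged number density relative to bulk; the bundled
bulk reference is SPC water at 0.970 g/cm³, i.e.
$0.970 / 18.0154 \times N_A \approx 0.0324$ Å⁻³
(`spc_bulk_number_density()`).  Out-of-grid waters are dropped and
counted, so voxel counts plus dropped always equals waters × frames.
`pathway_connected()` thresholds the relative density and asks whether
one connected component of at-or-above-threshold voxels touches two
query boxes (cavity and a bulk compartment); 26-connectivity is the
default, 6-connectivity the stricter option.  A functionally occluded
conformation is one whose cavity component reaches neither bulk phase:
dehydrated constrictions block protons even where a purely steric
profile might not.

# Proton electrostatics

The free energy of moving a solvated proton from bulk water to a
position $r$ in the protein/membrane system is computed in the Born
approximation: the proton is a cavity of radius $a$ and charge $+1$ in
a dielectric continuum.  The radius comes from the Born equation

$$a = \frac{-166\ \text{Å kcal mol}^{-1}\, q^2}{\Delta G^*_{solv}}
\left(1 - \tfrac{1}{80}\right),$$

with the experimental oxonium hydration free energy
$\Delta G^*_{solv} = -110.4$ kcal/mol giving $a = 1.4848$ Å
(`born_radius()`).  The landscape is

$$W(r) = G_{\text{protein+ion}(r)} - G_{\text{protein}} -
G_{\text{ion, bulk}},$$

evaluated with a linearized Poisson–Boltzmann (LPB) model
(`born_landscape()`).  By linearity the protein self-energy cancels
exactly and $W(r)$ reduces to an ion desolvation difference — the
ion's reaction-field energy in its environment minus in bulk water,
both computed on identical ion-centred grids so grid self-energies
cancel by construction — plus the interaction term $q\,\phi_P(r)$ with
the protein's potential.  The ion's cavity is carved into the
dielectric map for the ion solves; the protein solve omits it, a
standard and quantitatively negligible inconsistency for cavity-sized
ions.  Points whose unperturbed environment is below the water
dielectric are flagged as desolvation-regime values.

The dielectric model (`dielectric_model()`) assigns, in precedence
order: water-accessible voxels 80, protein interior 10 (within vdW +
1.4 Å probe of an atom — the probe criterion is our documented
assumption), head-group slabs 20 (6.5 Å thick), hydrophobic core 2
(33.5 Å thick), bulk water 80.  The membrane slabs are hard shells;
smooth dielectric tapers belong to implicit-solvent dynamics models,
not to this analysis.  Mobile-ion screening (100 mM 1:1 salt at
298.15 K; Debye length ≈ 9.7 Å) acts only in water-dielectric voxels,
since mobile ions cannot enter protein or membrane.
`cavity_points()` enumerates water-accessible interior positions on a
1 Å lattice (probe 1.4 Å) both as landscape evaluation points and as
the `solvent_points` that reclaim interior voxels to ε = 80.

## The FD-LPB solver

`solve_lpb()` discretises $\nabla\!\cdot\!(\varepsilon\nabla\phi) -
\bar\kappa^2\phi = -4\pi C \rho$ with a 7-point stencil, harmonic
averaging of ε on face midpoints, trilinear assignment of point
charges, and Dirichlet boundary values from a Debye–Hückel monopole;
the symmetric positive-definite system is solved by
Jacobi-preconditioned conjugate gradients to a relative residual of
1e-6 (cap 20,000 iterations; non-convergence is an error, never a
silent result).  `solve_lpb_focused()` chains levels of a
`focusing_schedule()`: each finer box takes boundary values (and its
initial guess) interpolated from the previous level.  The default
desk-scale schedule is (120 Å, 65³) → (60 Å, 65³) → (30 Å, 65³); the
larger-system schedule (250, 129³) → (100, 129³) → (50, 129³) is
selected with `scale = "paper"`.  The desk scale keeps a full
Born-validation or membrane-barrier profile within minutes on one CPU
while leaving the finest spacing (0.47 Å) a factor ~3 below the proton
cavity radius.

One numerical choice matters more than the rest: the ion cavity
surface is anti-aliased by harmonic volume-fraction averaging over one
grid spacing.  With a hard staircase assignment the effective cavity
radius is quantized to the grid and Born energies oscillate rather
than converge under refinement; with the smoothed surface the analytic
Born energy is recovered with an error of about 4 % at the desk-scale
schedule, decreasing systematically (observed order ≈ 2) as the final
level is refined — both properties are checked by the test suite, and
`analysis/04_proton_electrostatics.R` prints the numbers.

# DEER distance distributions

Spin-label flexibility is convolved into predicted distance
distributions in four steps (`attach_rotamers()`, `clash_filter()`,
`pair_distribution()`, `ensemble_distribution()`).  A rotamer library
in a canonical side-chain frame is mapped rigidly onto each labelled
site via the right-handed orthonormal triad built from backbone N,
C$\alpha$, C (origin at C$\alpha$, x toward N); rotamers with any atom
within the clash cutoff of a non-excluded protein heavy atom are
discarded (2.0 Å default; 1.5 Å for tightly packed sites), surviving
weights renormalised, and all inter-site rotamer pairs histogrammed
with product weights into 1 Å bins over 0–80 Å.  The spin position is
the midpoint of the two reporter atoms (the nitroxide N and O of an
MTSL-like label); the labelled residue's own atoms are excluded from
the clash test, since the site is conceptually mutated to the label,
and hydrogens are ignored because the reference structures lack them.
Ensembles average per-frame distributions with equal weight; frames
where a site loses every rotamer are skipped and counted, and a
fully empty result is flagged rather than thrown.  Library weights are
treated as independent of the backbone (product weights), the simplest
defensible convention.  `make_rotamer_library()` generates synthetic
weighted libraries — articulated arms with Dirichlet weights — so all
of this is testable without the published MTSL library;
`read_rotamer_library()`/`write_rotamer_library()` define the
plain-text interchange format.

# Clustering and contacts

`pairwise_rmsd()` reports nm after optimal rigid superposition
(Kabsch, unit weights — no mass weighting) and requires at least three
atoms; raw RMSD is available for translation-sensitive questions.
`daura_cluster()` implements greedy neighbour-count clustering: the
frame with the most neighbours within the cutoff (default 0.25 nm)
becomes a centre, its neighbourhood is removed, and the procedure
repeats; ties break toward the lowest frame index, and clusters are
ordered by decreasing size.  Because neighbour counts are integers,
ties are common in small ensembles, and relabelling the frames can
then legitimately change the partition — the documented tie rule makes
any single run deterministic, which is what the tests pin down.
`contains_frame()` answers the standard "is the final frame in the
dominant cluster" question.  `residue_min_distance_trace()` reports
the per-frame minimum cross-pair distance between two atom groups;
for a salt bridge the default groups are the arginine side-chain
nitrogens against the glutamate carboxylate oxygens
(`salt_bridge_groups()`), and the group-minimum convention (rather
than a fixed atom pair) is flagged in the output metadata.

# Synthetic study systems

`make_bundle()` generates the geometry every stage is exercised on: a
two-domain bundle of idealised helices around the z axis (the membrane
normal, midplane z = 0), with the two domains occupying half-rings
that meet at a seam.  Each membrane half responds only to its own gate
fraction: at fraction 0 the helix ends pinch radially inward by up to
5 Å, sealing the bore at that face below the 1.4 Å radius of a water
molecule; at fraction 1 they splay 8 Å away from the opposite domain,
giving inter-domain gate distances well above the open thresholds.
Gate anchors — the terminal C$\alpha$ of each domain's seam helix at
each face — are recorded in the structure and recovered by
`bundle_gate_pairs()`.  A small fixed-amplitude jitter (0.05 Å, drawn
once from the seed before the gate displacements) keeps fixtures
non-degenerate without breaking the independence of the two gates.

The generator emulates the features the analyses rely on — two-domain
architecture, independently tunable gates, a solvated central cavity,
realistic length scales — and nothing else: no side chains, no
realistic helix packing, no lipids, no forces.  Green tests therefore
demonstrate that the analyses measure what they claim on geometry with
known ground truth; they do not demonstrate force-field-level realism,
and quantitative values from simulated ensembles of real transporters
(salt-bridge averages, experimental DEER peak positions, occupancy
regions of order-parameter space) are out of reach at this scale.
`make_transition()` (linear interpolation plus Gaussian noise) stands
in for transition trajectories, and `fill_cavity_waters()` Poisson-
samples waters at a target density with a 2.6 Å hard-sphere exclusion
— a fixture rule, not a physical model.

`soft_ratchet_sample()` is a deliberately minimal analogue of biased
transition sampling: Brownian proposals are accepted when they do not
increase the progress variable $\varphi$ (best-fit RMSD of chosen
atoms to the target) and with probability $\exp(-\delta/\Delta\varphi)$
when they increase it by $\delta$.  The published bias magnitudes
$\Delta\varphi = 10^{-4}$ Å and $10^{-6}$ Å map onto a soft and a
nearly hard ratchet, preserving the qualitative contrast between
full-transition and single-gate-closure protocols; the sampler refits
the target at every evaluation rather than on a fixed cadence, a
documented divergence from MD-engine practice.  Atomistic biased MD
itself is out of scope.

# Problem sizes and degenerate inputs

The test suite and the analysis scripts run at desk scale by choice:
65³ focusing grids, 40-frame ensembles, 8-frame clustering matrices
against brute-force oracles, bundles of ~2,000 atoms.  Degenerate
inputs have defined behaviour rather than errors where a value is
still meaningful: empty pore slabs return an `Inf` sentinel, empty
rotamer sets are flagged all-zero distributions, out-of-grid waters
are dropped and counted; genuinely unanswerable requests (missing
anchor atoms, mismatched topologies, underdetermined superpositions,
non-converged solves) raise errors that name the offending entity.

# Known limitations

Pore profiles are per-plane maxima, not curved-path radii.  The
electrostatic model is linear-response continuum theory with hard
dielectric shells and a spherical proton — no explicit hydration
structures, no nonlinear PB, no pKa machinery.  DEER predictions
assume backbone-independent rotamer weights and heavy-atom clash
tests.  The synthetic generator's defaults were chosen once to emulate
transporter-scale geometry and are not tuned per analysis.  Real
trajectory formats beyond multi-model PDB are out of scope; structures
arrive through `read_structure()`, `read_ensemble()` and
`read_pqr()`.
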