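# gatescape

Functional-state analysis of major facilitator superfamily (MFS)
transporter conformations.

MFS transporters such as the lactose permease LacY move substrates by
alternating access: a cytoplasmic and a periplasmic gate open and
close in turn, and the transition is thought to pass through an
*occluded* intermediate with both gates shut — the state that keeps
the proton gradient from leaking.  Given a structure or a
conformational ensemble, `gatescape` answers the question *"which
functional state is this, and is it really sealed?"* with a battery of
complementary analyses:

- **Gate order parameters** — the Cα–Cα distance of the
  closest-contact residue pair on helices TM1/TM7 (periplasmic gate)
  and TM4/TM10 (cytoplasmic gate), frozen on a reference structure and
  tracked per frame.  A conformation with cytoplasmic order parameter
  d_cyt < 13 Å **and** periplasmic order parameter d_peri < 8 Å is
  classified `occluded`; the other quadrants are `cytoplasmic_open`,
  `periplasmic_open` and `leak`.  Anchor pairs for 12 MFS transporters
  (LacY: Ile32–Asn245 and Glu126–Cys333) are bundled.
- **Pore profiles** — a simplified HOLE-style profiler: per height z,
  the largest clearance sphere max_c min_i(|(c,z) − x_i| − r_i^vdW),
  with ensemble mean ± SD.  Radii below ~1.4 Å (a water molecule)
  mean a dehydrated, sealed constriction.
- **Water pathways** — voxel water densities relative to SPC bulk
  (0.970 g/cm³ ≈ 0.0324 Å⁻³) and connected-component tests of whether
  any aqueous pathway joins the central cavity to either bulk phase.
- **Proton electrostatics** — the position-resolved Born free energy
  W(r) = G(protein+ion at r) − G(protein) − G(ion in bulk) of a
  solvated proton (Born radius a = −166·q²/ΔG*_solv·(1−1/80) =
  1.4848 Å from the oxonium hydration free energy −110.4 kcal/mol),
  from an in-package finite-difference linearized Poisson–Boltzmann
  solver with three-level focusing, an implicit membrane (ε = 2 core,
  33.5 Å; ε = 20 head groups, 6.5 Å; ε = 10 protein; ε = 80 water) and
  100 mM Debye screening in water.
- **DEER predictions** — spin–spin distance distributions from
  weighted rotamer libraries: rigid attachment onto the backbone
  N/Cα/C triad, steric clash filtering (2.0 Å cutoff, 1.5 Å for tight
  sites), product-weighted pair histograms over structures and
  ensembles.
- **Conformational clustering** — Daura neighbour-count clustering at
  0.25 nm on all-atom superposed RMSD, plus salt-bridge-style
  group-minimum distance traces.

A synthetic-structure module (`make_bundle()` and friends) generates
two-domain helical bundles with independently tunable gates, transition
ensembles, rotamer libraries and cavity waters, so the entire pipeline
is exercisable and testable without downloading any structure.

## Worked example

```r
library(gatescape)

# a closed two-domain bundle, and its recorded gate anchors
b  <- make_bundle(bundle_spec(gate_cyt = 0, gate_peri = 0, seed = 3))
gp <- bundle_gate_pairs(b)
gate_distance(b, gp$cyt)   # 0.95 A
gate_distance(b, gp$peri)  # 2.45 A
classify_state(gate_distance(b, gp$cyt), gate_distance(b, gp$peri))
#> [1] "occluded"

# is it sterically sealed?  pore radii at the two gate bands:
prof <- pore_profile(b, seq(-14, 14, by = 2))
min(prof$mean_radius[prof$z <= -10])  # 0.49 A  (cytoplasmic gate)
min(prof$mean_radius[prof$z >=  10])  # 0.58 A  (periplasmic gate)
# both far below the 1.4 A radius of a water molecule

# the proton's Born radius and the membrane barrier
born_radius(1, -110.4, 80)
#> [1] 1.484828
ion  <- born_ion(1, born_radius(1, -110.4, 80))
prof <- membrane_barrier_profile(ion, z_points = c(35, 0))
prof$W   # 0.03 kJ/mol in bulk, 224.9 kJ/mol at the core centre
```

The numbers read exactly as the science expects: both gate order
parameters are deep inside the occluded quadrant, both constrictions
are too narrow for water, and the protein-free implicit membrane is a
>100 kJ/mol electrostatic barrier for the proton while bulk water is
the zero of the landscape.

The numbered scripts under `analysis/` run the full study on the
synthetic systems — `01` builds structures and ensembles, `02` gate
order parameters, `03` pore/water pathways, `04` proton
electrostatics, `05` DEER distributions, `06` clustering — each
writing tab-separated tables under `results/` and printing a one-line
narrative of what it found (for example, `03` reports the occluded
bundle's cavity connected to *neither* bulk phase, and the
cytoplasmic-open bundle connected to the cytoplasm only).

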