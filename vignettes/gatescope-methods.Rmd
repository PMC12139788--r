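---
title: "Methods: gate-state, hydration, ion-site and probe-accessibility analysis"
author: "gatescope"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: gate-state, hydration, ion-site and probe-accessibility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

gatescope analyses molecular-dynamics trajectory ensembles of LeuT-fold
neurotransmitter:sodium symporters (NSS), the family that includes the
serotonin transporter (SERT). These transporters alternate between outward-
and inward-facing states; an extracellular "gate" salt bridge between a
conserved TM1 arginine (Arg104 in SERT numbering) and a TM10 acidic residue
(Glu493), and the arginine's alternative contact with a chloride-sensing
glutamine (Gln332), are central reporters of that cycle, together with ion
occupancy of the Na1/Na2/Cl− sites, hydration of the bundle interior, and
the accessibility of extracellular-pathway residues such as Tyr107 to bulky
cysteine-modifying reagents (MTSET, in SCAM experiments).

The data model is deliberately small: a `Topology` (ordered atom table with
author residue numbering, never re-indexed, and Bondi van der Waals radii —
C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å, default 1.70 Å for
unknown elements) and a `Trajectory` (an `n_atoms x 3 x n_frames` array in
Å sharing one topology). PDB and DCD reading are delegated to bio3d; a
minimal CHARMM-format DCD writer and a fixed-width (multi-model) PDB writer
are provided for the synthetic generators. Coordinates are assumed already
imaged (wrapped, protein-centred); no minimum-image correction is applied,
and the synthetic data are non-periodic by construction. Hydrogens are kept
on reading, but every distance-criterion analysis uses heavy atoms only,
and the surface-area calculation excludes them by default.

# Gate-state classification

A contact is scored purely by heavy-atom donor–acceptor distance: present
if and only if the minimum distance over the donor set × acceptor set is
strictly below the cutoff (default 3.2 Å). No angle term and no explicit
hydrogens enter the criterion. Donors default to the gate arginine's NE,
NH1, NH2. The glutamine acceptor is the side-chain carbonyl oxygen (OE1);
the glutamate acceptors are both carboxylate oxygens (OE1/OE2). Glutamate
carboxylate oxygens are conventionally labelled Oε1/Oε2; where source
material uses Oδ labels (aspartate convention) for this residue, the
implementation maps to the carboxylate oxygens regardless of label.

Each frame falls in exactly one of four categories — `GLN_ONLY`,
`GLU_ONLY`, `BOTH`, `NEITHER` — so per-trajectory fractions sum to 1
exactly. Ensemble statistics are computed per trajectory first, then
averaged, with the sample standard deviation (denominator n−1) taken
across replica trajectories; frames are never pooled before the SD, because
replicas, not frames, are the independent units. A single trajectory yields
SD 0 with a warning. Whether an ensemble's fractions should use every saved
frame or a stride is configurable (`stride`, default 1).

# Rotamer dihedrals

Torsions follow the signed IUPAC convention, in degrees on the half-open
interval (−180, 180], with the anti-planar case mapped to +180 so the
branch cut has a single representation. χ1/χ2 atom quadruples come from an
embedded table for the 20 canonical residues (χ1: N–CA–CB–{CG|CG1|OG|OG1|SG},
χ2: CA–CB–G–{CD|CD1|OD1|ND1|SD}); residues lacking the requested χ raise a
definition error. Rotamer classes are the standard thirds centred on +60°
(gauche+, (0, 120]), 180° (trans, (120, 180] ∪ (−180, −120]) and −60°
(gauche−, (−120, 0]); the bins are a field convention, not a fitted
quantity. No smoothing is applied to angle series before classification.

# Hydration occupancy maps

The map is an axis-aligned cubic-voxel grid (default spacing 1.0 Å) of edge
2×radius (default radius 20 Å) centred on the centroid of a reference
selection. "Occupancy" means the fraction of frames in which at least one
selected atom centre (default: water oxygens) lies inside the voxel —
atom-centre binning with no Gaussian smearing, mirroring the occupancy map
type of standard visualisation tools. Every frame is first rigid-body
superposed onto the reference frame over an alignment selection, so maps
live in a common protein frame; because the original wrapping/centring
selection of any given trajectory set is generally unknown, the alignment
selection is a user parameter defaulting to all Cα atoms. Frames pooled
across trajectories enter with equal weight; per-trajectory maps can also
be emitted, preserving the per-replica alternative where weighting matters.
Grids are written in an OpenDX scalar-field dialect whose data block is
laid out in the grid array's own x-fastest linear order (stated in the
header docs; the package's reader round-trips it within 1e−6).

# Ion sites

The Na1, Na2 and Cl− sites are defined by coordinating-atom lists with
inclusive distance cutoffs of 2.5 Å (Na+) and 3.5 Å (Cl−) and a minimum
coordination number of 2; "bound" in a frame means at least that many
coordinating atoms within the cutoff. These criteria are adopted from the
restraint-style site definitions conventional for this family (Na1: Ala96
O, Asn101 OD1, Ser336 O/OG, Asn368 OD1; Na2: Gly94 O, Val97 O, Leu434 O,
Ser438 OG; Cl−: Asn101 ND2, Tyr121 OH, Gln332 NE2, Ser336 OG, Ser372 OG).
Dwell segments are the run-length encoding of the bound flag, and unbinding
is reported as the first unbound segment persisting at least a
persistence window (default 25 frames, i.e. 100 ps at 4 ps output), an
explicit operational stand-in for "the ion left the site": a lasting event,
not single-frame flicker. With persistence window 1 and noiseless input,
segments reconstruct the generator's ground truth exactly.

# Probe accessibility (Shrake–Rupley)

The solvent-accessible surface area uses Shrake–Rupley quadrature: for each
atom, points on its expanded sphere (r_atom + probe) are tested against all
neighbours' expanded spheres, and the exposed fraction scales the expanded
sphere's area. The point set is a deterministic golden-spiral lattice
(default 960 points) — no RNG in the main algorithm, so results are
bit-reproducible; neighbour pruning at r_i + r_j + 2·probe is exact, so the
pruned computation equals the all-pairs one. The probe defaults to 1.4 Å
(water); 3.0 Å approximates the bulky MTSET reagent. A residue's
accessibility is the sum over all of its atoms (side-chain-only by flag),
averaged over frames within each trajectory, with the headline ensemble
mean and SD taken over the per-trajectory means; frame-level SDs are also
emitted because either convention appears in the literature.

Validation uses an independent Monte-Carlo rejection oracle (uniform random
points per expanded sphere, binomial standard errors). The validation
clusters are 20 atoms (C/N/O/S) sampled at ≥ 7 Å minimum separation in a
20 Å box: moderate sphere overlap with no fully buried atoms. This design
keeps the comparison well-conditioned — for a nearly buried atom both the
relative tolerance and the binomial SE collapse toward zero while any fixed
quadrature remains quantized at one point's worth of area, so agreement
there tests arithmetic luck, not correctness.

# Inactivation kinetics

Cysteine-modification rates are extracted from concentration–response data
at fixed exposure time t under the standard pseudo-first-order SCAM
relation A(c) = exp(−k c t), giving k = ln 2 / (c_half · t); the package
states this model openly as its own choice, since assay write-ups usually
cite it from prior work rather than printing it. Activities are normalized
to the within-plate untreated control per replicate, and replicates are fit
jointly (never averaged first, preserving the error structure). The fit is
least squares on the activity scale, initialized from the log-linear
regression of −ln A on c·t and polished by Newton steps on the exact
gradient, so noiseless data recover k to machine precision. Confidence
half-widths come from the local quadratic (Gauss–Newton) approximation at
the optimum; no bootstrap. Data are rejected when no control is present,
when activity does not decrease with concentration (Spearman trend > 0), or
when all treated activities are ≈ 0 (saturated, k unidentifiable). Only the
concentration-series design is implemented; time-course data at fixed
concentration would require reinterpreting the abscissa and is out of
scope. The percent-of-maximal normalization,
100·(k_condition − k_reference)/(k_full − k_reference), preserves sign and
is reported unclipped.

# Synthetic data: what it emulates, and what it does not

The generators provide ground truth for every analysis stage at desk scale:

* **Toy transporter** — a deterministic miniature system carrying the
  residues the analyses address by role (gate arginine, glutamine,
  glutamate, the Na1-coordinating aspartate with χ1 built at +60°, the
  extracellular tyrosine, the three ion-site atom sets, ions at their site
  centres, filler scaffold Cα atoms). Its geometry is schematic: the two
  acceptor groups sit 20 Å apart so an emission near one can never satisfy
  the criterion at the other, making label recovery provable rather than
  probable.
* **Markov gate ensembles** — a hidden four-state Markov chain (initial
  state from its stationary distribution, eigen-solved) emits
  donor–acceptor distances uniformly from [2.7, 3.1] Å when a contact is
  on and [4.0, 8.0] Å when off; the gap around 3.2 Å guarantees noiseless
  emissions classify back to the generating label exactly. Only the
  arginine donor pseudo-atoms move. The default transition matrix is the
  sticky chain P = 0.9·I + 0.1·1πᵀ with π = (0.55, 0.12, 0.08, 0.25),
  whose stationary salt-bridge occupancy (GLU_ONLY + BOTH) is 0.20 —
  an outward-open-like ensemble in which the gate salt bridge is formed
  about 20% of the time. Defaults of 8 replicas × 2,000 frames (10,000 in
  the validation runs) keep ensembles tractable; replica r uses seed + r.
* **Ion dwells** — alternating bound/unbound segments with continuous
  exponential lengths rounded up to whole frames (frames are the native
  analysis unit), bound geometry at the toy site centre, unbound displaced
  10 Å.
* **Hydration** — a homogeneous Poisson point process of water-oxygen
  pseudo-atoms inside a sphere, so the expected voxel occupancy has the
  closed form 1 − exp(−ρ·spacing³).
* **Assays** — A(c) = exp(−k c t) times mean-one lognormal noise. The
  default design emulates a 96-well plate: triplicate untreated control
  wells plus six concentrations bracketing c_half. Triplicate controls
  matter: with a single noisy control well, the normalized fit's variance
  is dominated by the control, which no real plate design tolerates.

What the synthetic data do **not** emulate: real protein geometry, force
fields, correlated solvent structure, periodic boundaries, angle-dependent
hydrogen bonding, or reagent chemistry. Passing the ground-truth tests
therefore demonstrates that the analysis layer measures what it claims to
measure on data whose truth is known — not that any particular biological
number is reproduced. Headline ensemble quantities from half-microsecond
production simulations (state fractions, 363–410 Å² tyrosine
accessibilities) require the original trajectories and are out of desk
scale by design.

# Numerical choices and degenerate inputs

* Strict `<` at the hydrogen-bond cutoff (a pair at exactly 3.2 Å is
  absent); inclusive `≤` at ion-site cutoffs. Ties in minimum-distance
  searches break toward the lowest atom indices; altloc occupancy ties
  break toward label "A".
* Superposition is closed-form Kabsch (SVD with the proper-rotation sign
  fix); fewer than 3 selected atoms or a collinear selection is a
  degenerate-geometry error. Empty selections always raise rather than
  silently analysing nothing — except the occupancy map's species
  selection, where an absent species is a legitimate all-zero map and
  warns instead.
* Problem sizes in the validation suite (10,000-frame ensembles, 400-frame
  hydration runs, 10⁵ Monte-Carlo samples per atom, 100 assay replicates)
  were chosen so each statistical comparison has comfortable power at a
  3-SE band while completing in seconds; for the sticky default chain the
  binomial SE is inflated by the integrated autocorrelation time
  (1+λ)/(1−λ) = 19.
* All stochastic paths take a single integer seed and restore the caller's
  RNG state; the deterministic paths (classification, quadrature SASA,
  grids, fits) contain no RNG at all, which is what makes byte-identical
  re-runs of a configuration a testable contract.

# Known limitations

No periodic-image reconstruction, no mmCIF writer, no topology/bond
perception, no angle-dependent H-bond definitions, no hidden-Markov
smoothing of state series, no χ3/χ4 or rotamer-library scoring, no
analytic (power-diagram) SASA or Connolly surfaces, no free-energy or
affinity estimates for the ion sites, and no mechanistic model of reagent
hydrolysis. The orchestrator (`runAnalysis`) provides per-trajectory
independence but no parallel-execution guarantees.
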