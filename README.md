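# gatescope

Trajectory-ensemble analysis for LeuT-fold neurotransmitter:sodium
symporters (NSS) — the transporter family of the serotonin transporter
(SERT). In these proteins an extracellular "gate" salt bridge between a
conserved TM1 arginine (Arg104 in SERT numbering) and a TM10 glutamate
(Glu493), the arginine's alternative contact with a chloride-sensing
glutamine (Gln332), the occupancy of the Na1/Na2/Cl⁻ ion sites, hydration
of the helix bundle, and the accessibility of extracellular-pathway
residues (e.g. Tyr107) to bulky cysteine reagents all report on the
conformational cycle that couples ion binding to substrate transport.
gatescope turns those reporters into reproducible computations for people
who have trajectory ensembles (or assay plates) and want numbers with
error bars:

* **Gate states** — per-frame classification of the arginine network into
  `GLN_ONLY` / `GLU_ONLY` / `BOTH` / `NEITHER` under the heavy-atom
  distance criterion *d*min < 3.2 Å (strict), with per-trajectory
  fractions and across-replica mean ± SD.
* **Rotamers** — signed IUPAC χ1/χ2 torsions in (−180°, 180°] and
  gauche+/trans/gauche− classes on the standard thirds.
* **Hydration maps** — voxel occupancy (fraction of frames with ≥ 1 water
  oxygen in the voxel) on a grid around a reference residue, frames
  superposed to a common protein frame, written as OpenDX.
* **Ion sites** — coordination counts against the embedded Na1/Na2/Cl⁻
  coordinating-atom sets (cutoffs ≤ 2.5 Å Na⁺ / ≤ 3.5 Å Cl⁻, minimum
  coordination 2), dwell segments and lasting-unbinding detection.
* **Probe accessibility** — Shrake–Rupley SASA on a deterministic
  golden-spiral quadrature with a configurable probe (3.0 Å mimics the
  MTSET reagent), per-residue attribution and per-trajectory averaging,
  plus an independent Monte-Carlo oracle.
* **Kinetics** — substituted-cysteine accessibility (SCAM) rate constants
  from inactivation plates: *A(c) = exp(−k c t)*, *k = ln 2 / (c_half t)*,
  and the percent-of-maximal normalization
  100·(k_cond − k_ref)/(k_full − k_ref).
* **Synthetic data** — generators with known ground truth (Markov gate
  ensembles, exponential ion dwells, Poisson hydration, noisy assay
  plates) so every stage is testable without multi-gigabyte trajectories.

The package is S4 throughout (`Topology`, `Trajectory`,
`GateStateSeries`, `StateFractions`, `OccupancyGrid`, `BindingTrace`,
`RateConstantFit`), reads PDB/DCD via bio3d, and is orchestrated either
from the functions below or from a single YAML config via `runAnalysis()`.

## Worked example

Simulate an 8-replica gate ensemble whose hidden Markov chain has a known
stationary distribution, classify every frame, and summarise:

```r
library(gatescope)

spec   <- gateMarkovSpec(nFrames = 2000L, nTrajectories = 8L, seed = 1L)
sim    <- simulateGateTrajectories(spec)
series <- lapply(sim$trajectories, classifyGateStates)
stateFractions(series)
#> StateFractions over 8 trajectories
#>      GLN_ONLY GLU_ONLY   BOTH NEITHER
#> mean   0.5372   0.1457 0.0824  0.2347
#> sd     0.0509   0.0411 0.0303  0.0558
```

The means sit near the chain's stationary distribution
(0.55, 0.12, 0.08, 0.25); the SD row is the across-replica spread, the
error bar convention for ensemble state fractions. The salt-bridge
occupancy of this ensemble is `GLU_ONLY + BOTH` ≈ 0.23 of simulation
time. Accessibility of the extracellular tyrosine to a 3 Å reagent-sized
probe, on the toy system:

```r
toy <- makeToyTransporter()
res <- sasa(toy$frame, toy$topology, sasaParameters(probeRadius = 3))
subset(res$perResidue, resid == 107)
#>   resid resname chain     area
#> 3   107     TYR     A 553.1371
```

and a rate constant from a noisy synthetic inactivation plate (true
k = 500 M⁻¹min⁻¹):

```r
d <- simulateInactivationAssay(assaySpec(kTrue = 500, cv = 0.05, seed = 1))
fitInactivation(d)
#> RateConstantFit: k = 517.7 M^-1 min^-1 (95% CI +/- 38.1),
#>                  c_half = 0.0006695 M, t = 2 min
```

The fitted k lands within the quoted confidence interval of the generating
value, and `k · c_half · t = ln 2` holds exactly by construction.

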