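Package: gatescope
Title: Gate-State, Hydration, Ion-Site and Probe-Accessibility Analysis of
    Transporter Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectory ensembles of
    neurotransmitter:sodium symporters (LeuT-fold transporters such as the
    serotonin transporter). Classifies the extracellular Arg-centred gate
    network into four hydrogen-bond states under a heavy-atom distance
    criterion and summarises state fractions across replica trajectories;
    computes side-chain chi1/chi2 dihedral series and gauche/trans rotamer
    classes; builds volumetric water-occupancy maps around a reference
    residue; traces ion-site coordination, dwell times and unbinding for the
    Na1, Na2 and Cl- sites; computes Shrake-Rupley solvent-accessible surface
    area with a configurable (reagent-mimetic, 3 Angstrom) probe together
    with a Monte-Carlo validation oracle; and fits second-order cysteine
    modification rate constants from inactivation assays. A synthetic-data
    module generates toy topologies, Markov-switching gate ensembles,
    exponential ion-dwell traces, Poisson hydration fields and noisy assay
    data with known ground truth, so every analysis stage is testable
    without large trajectory archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
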