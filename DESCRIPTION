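Package: onebpa
Title: One-Bead-Per-Amino-Acid Simulation of Arginine-Rich Dipeptide
    Repeats Binding Nuclear Transport Components
Version: 0.1.0
Authors@R:
    person("onebpa", "maintainers", email = "onebpa@example.org",
           role = c("aut", "cre"))
Description: Residue-scale (one bead per amino acid, Calpha-centred)
    implicit-solvent molecular simulation and analysis of the direct binding
    between poly(proline-arginine) dipeptide repeat proteins and folded
    nuclear transport components. Provides coarse-grained model construction
    from PDB/FASTA inputs (elastic networks for folded cores, disordered
    regions from missing density or low per-residue confidence), the full
    nonbonded force field (piecewise 8-6 hydrophobic potential, screened
    Coulomb electrostatics with a distance-dependent dielectric, 8-6
    cation-pi potentials between arginine/lysine and aromatic residues,
    excluded volume), a Langevin dynamics engine with periodic boundaries,
    inter-molecular contact statistics with block-averaged errors,
    binding-site overlap counts, and the charge-parameter (NCPR - f*M/Rg)
    correlation fit with optimisation of the dipole weight f. A synthetic
    data module generates toy folded components with controlled net charge
    and dipole moment so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
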