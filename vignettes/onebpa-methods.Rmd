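---
title: "Methods: residue-scale simulation of polyPR binding to nuclear transport components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-scale simulation of polyPR binding to nuclear transport components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onebpa)
```

## The scientific problem

Arginine-rich dipeptide repeat proteins (R-DPRs) translated from the C9orf72
G4C2 hexanucleotide expansion — in particular poly(proline–arginine),
polyPR — disrupt nucleocytoplasmic transport in ALS/FTD models. One candidate
mechanism is *direct* binding of polyPR to the soluble machinery of the
transport cycle: importin-α adaptors, the Ran system (Ran, RanGAP, RanGEF,
NTF2), and the exporters of importin-α. `onebpa` implements a
one-bead-per-amino-acid (1BPA) implicit-solvent model to quantify that
binding: each residue is a single bead at the Cα position, folded cores are
held by stiff elastic networks, and polyPR is a fully disordered chain of
alternating P and R beads carrying one positive charge per repeat.

The package covers the full pipeline: model construction from structure and
sequence, the complete nonbonded/bonded force field, Langevin dynamics in a
periodic box, contact statistics against binding-site annotations, and the
charge-parameter correlation

$$ \mathrm{NCPR} - f\,M/R_g $$

against which normalized contact numbers are linearly regressed, with the
dimensionless dipole weight $f$ optimized by quality of fit.

## The model

### Bead properties

Each bead carries a charge ($-1$ e for D/E, $+1$ e for K/R, 0 otherwise —
histidine is neutral at pH 7.4 but the assignment is configurable), a
relative hydrophobic strength $\epsilon_i \in (0,1)$, and an aromatic flag
(F, Y, W). Charges are side-chain based only; termini are not charged,
consistent with a strictly per-residue parameterization.

The per-amino-acid hydrophobic strengths belong to the force field's
published supplementary material, which is not bundled here. The shipped
table (`inst/extdata/hydropathy_1bpa_synthetic.tsv`) is a clearly labelled
stand-in: a min–max normalized Kyte–Doolittle scale mapped into $(0,1)$,
with the four charged residues raised by $+0.10$ (the reference
parameterization notes that charged-residue strengths were slightly
increased). It is an *input*, swappable via `read_hydropathy(path)`, and no
quantitative acceptance target depends on it: the analytic force-field
targets use fixed constants, and hydrophobic mixing plays a minor role in
the electrostatically dominated binding studied here.

### Interaction potentials

All potentials act between bead centres, in kJ/mol with distances in nm.

* **Hydrophobic/hydrophilic 8–6 potential** (`phi_hp`), for pairs within
  disordered chains (intra-polyPR; pairs with both residues inside a
  disordered region of one component):
  $$\phi_{hp}(r) = \begin{cases}
   \epsilon_{rep}(\sigma/r)^8 - \epsilon_{ij}\big[\tfrac43(\sigma/r)^6 -
   \tfrac13\big] & r \le \sigma \\
   (\epsilon_{rep}-\epsilon_{ij})(\sigma/r)^8 & r \ge \sigma
  \end{cases}$$
  with $\epsilon_{ij} = \epsilon_{hp}(\epsilon_i\epsilon_j)^{0.27}$,
  $\epsilon_{hp} = 13$, $\epsilon_{rep} = 10$ kJ/mol, $\sigma = 0.6$ nm. The
  two branches agree in value and first derivative at $\sigma$.
  Setting $\epsilon_{ij} = 10$ kJ/mol gives the purely repulsive excluded
  volume used for every polyPR/component pair that is neither electrostatic
  nor cation–π — it vanishes identically for $r \ge 0.6$ nm.

* **Screened electrostatics** (`phi_elec`) between all charged bead pairs:
  $$\phi_{elec}(r) = \frac{q_iq_j}{4\pi\varepsilon_0\,\epsilon_r(r)\,r}
    e^{-\kappa r}, \qquad
    \epsilon_r(r) = S_s\Big[1 - \frac{r^2}{z^2}
    \frac{e^{r/z}}{(e^{r/z}-1)^2}\Big]$$
  with $S_s = 80$, $z = 0.25$ nm, and Debye screening $\kappa = 1.0$
  nm$^{-1}$ at 100 mM, $1.5$ nm$^{-1}$ at 200 mM monovalent salt. Near
  $r = 0$ the dielectric is evaluated by series expansion
  ($\epsilon_r \to S_s x^2/12$, $x = r/z$), avoiding the 0/0 of the closed
  form; it rises monotonically to $S_s$ at large separation.

* **Cation–π 8–6 potential** (`phi_cp`) replaces $\phi_{hp}$ for polyPR
  cations (R; the K entries support polyGR/GK variants) against component
  aromatics (F/Y/W):
  $$\phi_{cp}(r) = \epsilon_{cp}\big[3(r_m/r)^8 - 4(r_m/r)^6\big]$$
  with its minimum of exactly $-\epsilon_{cp}$ at $r_m = 0.45$ nm and pair
  depths (kJ/mol) RF 4.30, RY 5, RW 6.7, KF 1.79, KY 3.13, KW 4.26.

* **Elastic network / backbone bonds** (`phi_network`),
  $\phi = K(r-b)^2$ with $K = 8000$ kJ/mol/nm$^2$: every pair of structured
  beads closer than 1.4 nm (strict) in the reference structure is bonded at
  its crystal distance; disordered chains are held by backbone bonds at
  $b = 0.38$ nm. Bonded pairs are excluded from all nonbonded terms.

### Pair classification

The classification is deterministic and symmetric (`classify_pair`):
polyPR×component pairs are electrostatic (when both beads are charged) plus
either cation–π (R/K vs F/Y/W) or excluded volume; intra-polyPR and
intra-disordered-region pairs use the full 1BPA $\phi_{hp}+\phi_{elec}$;
structured intra-component pairs are network-bonded. Two cases the source
model leaves open are resolved as follows and are deliberate choices of
this package:

* *structured–structured intra-component pairs beyond the network cutoff*,
  and *structured–disordered cross pairs within one component*, get
  excluded volume plus electrostatics — electrostatics draws no
  structured/disordered distinction anywhere in the model, and a folded
  core without self-excluded-volume could be threaded by its own tails;
* *electrostatics between polyPR and charged residues inside structured
  regions* is evaluated (same reasoning).

Since the elastic network bonds every structured pair closer than 1.4 nm,
no non-bonded structured pair can start inside the 0.6 nm excluded-volume
core, so these additional terms are numerically gentle.

The bonded terms of disordered chains beyond the backbone bond
(angle/dihedral potentials of the parent disordered-protein force field)
are not restated in the source material; the default stand-in is the
harmonic backbone bond alone, with the network stiffness. This makes
disordered chains locally more flexible than the parent model — a
documented limitation that does not affect the contact-driven observables
this package targets, and the bond table is swappable per model.

## Numerical choices

* **Truncation.** No cutoff is stated for the nonbonded potentials; they
  are short-ranged by construction ($r^{-8}$, or screened with
  $\kappa^{-1} \le 1$ nm). We truncate at 2.5 nm (configurable) and shift
  each pair energy to zero at the cutoff, preserving energy-conservation
  diagnostics; forces are left unshifted (the discontinuity at 2.5 nm is
  $\lesssim 0.06$ kJ/mol/nm and invisible to the NVE drift test at reduced
  timestep).
* **Integrator.** The source protocol names only "Langevin dynamics" with
  $T = 300$ K, $\Delta t = 0.02$ ps, $\gamma = 0.02$ ps$^{-1}$. We use the
  BAOAB splitting (velocity-Verlet kicks/drifts around an exact
  Ornstein–Uhlenbeck step), which reduces to plain velocity Verlet at
  $\gamma = 0$ — used by the NVE and free-flight tests.
* **Masses.** Uniform 110 g/mol (average amino-acid weight). Masses only
  affect kinetics, and every analysed observable is a configurational
  equilibrium average, so this is benign.
* **Coulomb prefactor.** $1/(4\pi\varepsilon_0) = 138.935458$
  kJ·nm/mol/e².
* **Neighbour list.** Verlet list with a 0.3 nm skin, rebuilt when any bead
  moves half the skin; contact analysis uses a periodic cell list. Both are
  tested for exact equality against brute-force $O(N^2)$ oracles.
* **Reproducibility.** All stochastic kernels draw from R's RNG;
  trajectories are bitwise reproducible for a given (seed, config) on one
  platform.
* **Blow-up guard.** The integrator aborts with the step index if the
  energy turns non-finite or any force component exceeds $10^7$
  kJ/mol/nm.

## Model construction from structures

`parse_structure` reads Cα atoms (model 1, altloc "A" preferred) from PDB
text, converts Å to nm, and keeps residues that are present in the sequence
(SEQRES or an explicit `sequence`) but missing from the coordinates as
unresolved beads. `mark_disordered` declares a residue disordered when it
is unresolved *or* its per-residue confidence score (e.g. pLDDT) is below
70; unresolved always wins, even over a high score — missing crystal
density is direct evidence of disorder in the deposited state.
`place_unresolved` grows missing stretches from the nearest resolved
anchor at 0.38 nm per step, biased away from the fold's centre, then
relaxes only the placed beads by short steepest descent; the source
material does not state a placement procedure, and only the relaxed
ensemble matters because these regions are governed by the disordered-chain
force field during dynamics. A multi-chain crystal unit (e.g. the NTF2
homodimer) is one molecule: network bonds may join its chains.

## Descriptors and the charge-parameter fit

`compute_descriptors` returns NCPR (total charge / length), the
time-averaged dipole magnitude $M = \langle|\sum_i q_i(r_i - r_0)|\rangle$
and radius of gyration $R_g$. For net-charged molecules $M$ depends on the
origin $r_0$; we use the centre of mass (uniform masses, so identical to
the centre of geometry — both options are exposed), applied consistently to
every molecule. Without a trajectory, single-conformation values are
returned and labelled as such.

`optimize_f` maximizes fit quality of `ct_normalized` against
$\mathrm{NCPR} - f M/R_g$ jointly over the PR20 and PR50 datasets (and
both salt concentrations when present). The combination rule is not stated
in the source; the default aggregate is the *mean* $R^2$ across groups,
with `min` and a pooled regression selectable — for well-behaved synthetic
data all three agree to within the grid resolution. The search is a dense
grid on $[0, 0.1]$ with step $10^{-5}$, followed by golden-section
refinement when the grid optimum is interior; ties take the smallest $f$,
so data that depend on NCPR alone return exactly $f = 0$. Fits with
$R^2$ below a configurable threshold (default 0.8, between the retained
0.83–0.89 and the dropped 0.59–0.70 fits of the reference analysis) are
flagged `low_r2` but never hidden. $R^2$ at the optimum can never fall
below $R^2$ at $f=0$ because $f=0$ is in the search domain.

## What the synthetic data emulate — and what they do not

`gen_toy_component` builds compact folds as jittered cubic-lattice
serpentines with 0.38 nm spacing: consecutive and lattice-neighbour beads
fall inside the 1.4 nm network cutoff, so the generated fold carries a
dense elastic network like a real folded domain. The sequence is composed
to hit the target net charge exactly (E/K for charges, F for aromatics, S
filler); the dipole moment is controlled *spatially* — charge is a 3-D
property of the fold, so segregating negative residues to one side
(`segregate = TRUE`) produces a high-dipole "RanGAP-like" extreme, while
scattering them uniformly gives a low-dipole "Ran-like" case (measured
dipole below ~3 e nm at 100 residues). `gen_correlation_dataset` draws
(NCPR, $M$, $R_g$) from ranges spanning the realistic spread of folded
transport components (NCPR $\in [-0.25, 0.05]$ e, $M \in [5, 120]$ e nm,
$R_g \in [2, 3.5]$ nm) and embeds a known linear law with group-specific
slopes (steeper at 100 mM and for PR50) and Gaussian noise
(default sd 0.01 on the normalized contact number, giving $R^2 \approx
0.95$, comparable to the retained reference fits).

A green test on this world establishes that the machinery is correct —
potentials, sampling, counting, fitting — not that any real transport
component binds polyPR with a particular $C_t$: toy folds are geometric
templates, not physical structures, their $R_g$ (~0.7 nm at 100 residues)
is smaller than real components', and desk-scale runs (0.1–1 ns here
versus ≥2.5 μs production in the reference study) only support directional
comparisons. Accordingly the end-to-end acceptance check asserts *sign
only*: the charged high-dipole toy must out-bind the neutral low-dipole toy
under identical configs, with the chain placed within diffusive reach of
the component (a box-scale diffusive search would need tens of
nanoseconds).

## Known limitations

* The hydropathy table is a stand-in (above); swap in the measured scale
  for quantitative hydrophobic effects.
* Disordered-chain bonded terms are backbone bonds only (above).
* No binary trajectory format ships; `write_trajectory` emits a portable
  JSON + TSV pair instead.
* Simulations are NVT single-box; no replica exchange, constant pressure,
  or explicit ions.
* Kinetic observables (diffusion constants, binding rates) are not
  calibrated: uniform masses and the desk-scale friction protocol make
  them internally consistent but not physical.
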