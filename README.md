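# onebpa

Residue-scale simulation and analysis of the direct binding between
arginine-rich dipeptide repeat proteins and nuclear transport components.

## What this is for

C9orf72-expansion poly(proline–arginine) (polyPR) disrupts nucleocytoplasmic
transport, and one candidate mechanism is direct, electrostatically driven
binding of polyPR to the soluble transport machinery (importin-α adaptors,
Ran, RanGAP, RanGEF, NTF2, and the exporters of importin-α). `onebpa`
implements the one-bead-per-amino-acid (1BPA) coarse-grained model used to
quantify that binding, for anyone who wants to run or extend such analyses
without a cluster-scale MD stack:

* **Model builder** — one bead per residue at the Cα position from PDB/FASTA
  input; folded cores held by an elastic network (stiff harmonic bonds
  between structured beads closer than 1.4 nm, K = 8000 kJ/mol/nm²);
  unresolved or low-confidence (< 70 pLDDT) regions treated as disordered
  chains; polyPR chains of any repeat number (PRn: 2n beads, charge +n e).
* **Force field** — piecewise 8–6 hydrophobic potential
  φ<sub>hp</sub> (ε<sub>hp</sub> = 13, ε<sub>rep</sub> = 10 kJ/mol,
  σ = 0.6 nm, mixing ε<sub>ij</sub> = ε<sub>hp</sub>(ε<sub>i</sub>ε<sub>j</sub>)<sup>0.27</sup>);
  screened Coulomb electrostatics with a distance-dependent dielectric
  ε<sub>r</sub>(r) = S<sub>s</sub>[1 − (r²/z²)e<sup>r/z</sup>/(e<sup>r/z</sup>−1)²]
  (S<sub>s</sub> = 80, z = 0.25 nm; κ = 1.0 / 1.5 nm⁻¹ at 100 / 200 mM salt);
  8–6 cation–π potentials between polyPR R (or K) and component F/Y/W with
  minimum −ε<sub>cp</sub> at r<sub>m</sub> = 0.45 nm; excluded volume
  (ε<sub>ij</sub> = 10 kJ/mol) for everything else. Analytic forces.
* **Simulator** — BAOAB Langevin dynamics (300 K, Δt = 0.02 ps,
  γ = 0.02 ps⁻¹ defaults) in cubic periodic boxes, bitwise reproducible per
  seed; velocity Verlet at γ = 0 for NVE checks.
* **Contact analysis** — time-averaged contact number C<sub>t</sub> at a
  1 nm cutoff, normalized by N<sub>TC</sub>·N<sub>PR</sub>; per-residue
  contact probabilities; contact sites at probability > 0.10;
  N<sub>shared</sub> against binding-site annotations; SEM from 3-block
  averaging.
* **Charge-parameter correlation** — linear fits of normalized
  C<sub>t</sub> against NCPR − f·M/R<sub>g</sub> and 1-D optimization of the
  dipole weight f by fit quality (R²).
* **Synthetic data** — toy folded components with exact net charge and
  controlled dipole moment, annotation fixtures, and correlation datasets
  with known ground truth, so the whole pipeline runs and is tested without
  any downloads.

See `vignettes/onebpa-methods.Rmd` for the model, its assumptions, numerical
choices, and limitations.

## Worked example

A charged, high-dipole toy component ("RanGAP-like": 100 residues, net
charge −20 e, charges spatially segregated) binding PR20 at 100 mM salt:

```r
library(onebpa)
params <- default_force_field(salt = 100)

toy <- gen_toy_component(100, net_charge = -20, frac_aromatic = 0.1,
                         segregate = TRUE, seed = 808, params = params,
                         name = "RanGAP-like")
toy$descriptors
#> descriptors (single conformation): NCPR -0.2000 e, M 21.364 e nm,
#>   Rg 0.871 nm, length 100

pr20 <- build_polypr(20, params)
cfg <- sim_config(salt = 100, n_steps = 1e5, save_interval = 250, seed = 1)
pl <- place_complex(pr20, toy$model, cfg, seed = 1, distance = 3.5)
sys <- assemble_system(list(toy$model, pr20), positions = pl$positions,
                       box = pl$box, params = params)
traj <- run_langevin(sys, cfg)   # ~1.5 min on one CPU
traj
#> cg_trajectory: 140 beads, 401 frames, 2000.0 ps, box 31.99 nm

cc <- count_contacts(traj, which(sys$is_polypr), which(!sys$is_polypr))
cc
#> contacts: Ct = 365.828 +/- 5.235 (normalized 9.146e-02) over 320 frames
```

Read: averaged over the production window (last 80% of the run), ~366
polyPR/component residue pairs sit within 1 nm per frame; dividing by
N<sub>TC</sub>·N<sub>PR</sub> = 100·40 gives the normalized C<sub>t</sub>
0.091 (± the 3-block SEM). The same protocol on a neutral, low-dipole
"Ran-like" toy gives C<sub>t</sub> = 0 — the directional contrast that the
acceptance suite asserts.

Contact sites and overlap with an annotated interface:

```r
probs <- contact_probability(traj, which(!sys$is_polypr), which(sys$is_polypr))
sites <- call_contact_sites(probs)          # probability > 0.10
length(sites)
#> [1] 82
ann <- gen_annotation(toy$model, "cterm_quartile", partner = "RanGTP")
n_shared(sites, ann)
#> [1] 24
```

Optimizing the dipole weight f on a synthetic correlation dataset generated
with f_true = 0.0036 (9 components × 2 polyPR lengths × 2 salts):

```r
d <- gen_correlation_dataset(n_components = 9, f_true = 0.0036,
                             noise_sd = 0.01, seed = 7)
optimize_f(d)
#> charge-parameter fit: f = 0.0035695 (aggregate mean R^2 = 0.997)
#>      group length salt     slope  intercept r_squared low_r2 n
#> 1 PR20.100   PR20  100 -1.472357 0.02462945 0.9988805  FALSE 9
#> 2 PR50.100   PR50  100 -1.943084 0.02512696 0.9995041  FALSE 9
#> 3 PR20.200   PR20  200 -1.049063 0.01378305 0.9963394  FALSE 9
#> 4 PR50.200   PR50  200 -1.304297 0.01701207 0.9931507  FALSE 9
```

The recovered f (0.00357) sits within 1% of the generating value; fits whose
R² falls below the threshold would be flagged `low_r2`, never hidden.

## Command line

A thin CLI wraps the main entry points:

```sh
Rscript inst/cli/onebpa.R make-fixtures --dir fixtures --seed 1
Rscript inst/cli/onebpa.R simulate --model fixtures/rangap_like.json \
    --repeats 20 --steps 100000 --salt 100 --seed 1 --out traj
Rscript inst/cli/onebpa.R analyze --traj traj --model fixtures/rangap_like.json \
    --annotation fixtures/rangap_like_sites.tsv --out summary.json
Rscript inst/cli/onebpa.R fit --data fixtures/correlation_dataset.tsv --out fit.json
```

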