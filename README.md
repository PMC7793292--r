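# protasym

Quantifying protomer asymmetry in two-protomer protein assemblies from
conformational ensembles.

Dimeric holoenzymes such as the PKA regulatory-subunit:catalytic-subunit
tetramer are nominally C2-symmetric, yet their two halves (protomers) can
behave very differently: in the RIIβ holoenzyme one cyclic-nucleotide-binding
(CNB-B) domain is far more flexible than its twin, and this asymmetry is
functionally linked to cAMP activation. `protasym` packages the ensemble and
solution-scattering analyses used to detect and quantify that kind of
asymmetry, driven either by multi-model PDB ensembles (snapshots standing in
for MD trajectories) or by its own seeded synthetic-ensemble generator.

## What it computes

* **Superposition & RMSF** — Kabsch least-squares fitting and per-residue
  root-mean-square fluctuation profiles, aligned per protomer on a stable
  core so internal motion is isolated:
  RMSF_i = sqrt(⟨|x_i − ⟨x_i⟩|²⟩).
* **Inter-domain polar vectors** — per-frame (d, θ, φ) of an anchor-to-anchor
  vector (e.g. PBC of CNB-A → PBC of CNB-B) in a body-fixed frame, plus a
  mean-normalized asymmetry index between protomers:
  ΔX = 100 · (1/N) Σ_f |X₁f/X̄₁ − X₂f/X̄₂| for X ∈ {θ, φ, d}.
* **Hinge angles** — principal-axis decomposition of the long B/C/N helix
  into segments and the angles at its two hinge points.
* **Pocket metrics** — landmark pair distances (Ala360 Cβ–Leu351 Cγ style
  open/closed coordinates), normalized distance populations, and
  Shrake–Rupley solvent-accessible surface area with a configurable
  (e.g. cAMP-sized, 2.8 Å) probe.
* **SAXS invariants** — Debye model profiles, P(r) and Dmax, Rg by Guinier
  and by P(r), Porod volume with the MW ≈ Vp/1.7 rule, Kratky transform and
  compactness flag, and profile-to-data χ².
* **Hill activation fitting** — EC50 and Hill coefficient with analytic
  standard errors from dose–response curves, plus construct comparison
  (EC50 ratios, reduced-cooperativity flags).
* **Synthetic data** — a coarse two-protomer generator with per-protomer
  hinge-fluctuation sigmas and pocket open-state fractions, uniform bead
  spheres for closed-form scattering oracles, and noisy Hill curves; all
  bit-reproducible under a seed.

## Worked example

```r
library(protasym)

gen <- make_two_protomer_ensemble(
  protomer_template(),
  ensemble_params(n_frames = 500, hinge_sigma_p1 = 2, hinge_sigma_p2 = 20,
                  core_jitter_sigma = 0.1, seed = 42))
traj <- gen$trajectory

core <- function(ch) atom_selection(chain = ch, resid_range = c(201, 265))
pA <- compute_rmsf(traj, core("A"), atom_selection(chain = "A"))
pB <- compute_rmsf(traj, core("B"), atom_selection(chain = "B"))

sA <- interdomain_vector_series(traj,
        atom_selection(chain = "A", resids = 230, names = "CA"),
        atom_selection(chain = "A", resids = 359, names = "CA"), core("A"))
sB <- interdomain_vector_series(traj,
        atom_selection(chain = "B", resids = 230, names = "CA"),
        atom_selection(chain = "B", resids = 359, names = "CA"), core("B"))
asymmetry_index(sA, sB)
```

Output (as printed by the session that produced it):

```
mobile-domain RMSF: protomer A 4.91 A, protomer B 50.44 A (ratio 10.3)
asymmetry index: dtheta 70.6%, dphi 1467.3%, dd 1.28%
open-state (6.9 +/- 0.6 A) population mass: 0.29
sphere R=10: Rg(Guinier) 7.89 A, Rg(P(r)) 7.75 A, Vp 4326 A^3
Hill fit: EC50 288 +/- 16 nM, n 0.92 +/- 0.04
```

Reading this: the protomer whose hinge fluctuates with a 20° SD shows a
10-fold larger mobile-domain RMSF than its 2° twin; the inter-domain vector
asymmetry index is far above the symmetric null in θ and φ; the pocket
open-state mass recovers the generator's 0.3 open fraction; the bead-sphere
scattering invariants sit on the closed forms (√(3/5)·10 = 7.746 Å,
(4/3)π·10³ = 4189 Å³); and the Hill fit recovers the generating
EC50 = 285 nM, n = 0.949 within its standard errors.

A command-line interface with the same operations ships in
`inst/cli/protasym.R` (subcommands `run`, `rmsf`, `vectors`, `asymmetry`,
`hinges`, `pocket`, `saxs`, `hill-fit`), and `run_pipeline()` executes a
declarative JSON config end to end.

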