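---
title: "Methods: quantifying protomer asymmetry in conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying protomer asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A C2-symmetric holoenzyme built from two identical protomers need not behave
symmetrically: in PKA RIIβ holoenzymes, one protomer's second
cyclic-nucleotide-binding domain (CNB-B) can be dramatically more flexible
than the other's, and the oncogenic DnaJB1-PKAc fusion perturbs this balance
together with cAMP activation behaviour. Detecting such asymmetry requires
ensemble statistics, not single structures. `protasym` implements the
analysis layer: given a coordinate ensemble (multi-model PDB; snapshots of
an MD trajectory), it quantifies per-protomer flexibility, inter-domain
displacement geometry, binding-pocket accessibility, solution-scattering
invariants, and activation thermodynamics.

Because the raw trajectories, scattering curves and activation data behind
the motivating study are not public, the package carries a synthetic
generator that reproduces the *statistical structure* those analyses assume,
with known ground truth. Every analysis is validated against closed forms,
brute-force oracles, or the generator's latent variables.

## Ensemble model and RMSF

Frames are rigid-body superposed with the Kabsch algorithm (SVD with
determinant correction, so reflections are never returned; configurations of
rank < 2 are rejected). RMSF uses a two-round mean-structure iteration:
align all frames to frame 1 on the alignment selection, average, then
re-align the original frames to that average and re-average. Two rounds are
converged for rigid-plus-hinge ensembles and keep the cost deterministic;
further rounds change fixture profiles by well under the sampling noise.

The alignment selection is a per-protomer stable core (default residues
201–265 of the synthetic template). Aligning per protomer is a deliberate
choice: a global alignment mixes inter-protomer motion into both profiles,
whereas core alignment isolates each protomer's internal motion — which is
the quantity contrasted when one CNB-B is called "flexible". Residue-level
RMSF is the unweighted mean over that residue's selected atoms (CA in
one-atom-per-residue models); no mass weighting, no B-factor conversion.

## Inter-domain polar vectors and the asymmetry index

The vector from an anchor in the CNB-A phosphate-binding cassette (PBC) to
an anchor in the CNB-B PBC is tracked per frame in spherical polar form
(d, θ, φ). Conventions that the output records explicitly:

* **Anchor atom**: residues are the natural specification; the default atom
  is CA because side-chain atoms add rotamer noise irrelevant to domain
  displacement. Configurable.
* **Body frame**: θ and φ require a frame. Each frame is superposed onto
  frame 1 of the ensemble using a configurable core selection; axes are
  inherited from the reference coordinates. d is frame-invariant and the
  tests assert this; θ and φ are frame-dependent and therefore only
  comparable between series computed in the same frame.
* **φ branch cuts**: azimuth series are unwrapped (±360° jumps removed)
  before any averaging, otherwise the mean is corrupted by the branch cut.

The asymmetry index between matched-frame series is, per component
X ∈ {θ, φ, d}:

ΔX = 100 · (1/N) Σ_f | X₁f/X̄₁ − X₂f/X̄₂ |

Mean-normalization makes Δ dimensionless and cancels common scale
(proportional series give exactly 0). The per-frame **absolute value** is a
design decision: a signed sum with each series normalized by its own mean is
identically ≈ 0 by construction, which cannot be the intended "average per
frame difference". The absolute-value form is declared here and in the
result object rather than silently assumed. Note the index is positive even
for two *independent* draws from identical distributions; the meaningful
comparison is Δ(asymmetric) against Δ(symmetric null), which the acceptance
suite performs across 10 seeds.

## Hinge angles

The long B/C/N helix is decomposed into user-supplied segment ranges (the
exact residue boundaries are structure-specific and are required
configuration, not defaults). Each segment's axis is the first principal
axis of its atom coordinates — more robust to local curvature than an
end-to-end vector — oriented N→C, and hinge angles are arccos of
consecutive-axis dot products. On ideal α-helical fixtures (1.5 Å rise,
100°/residue) with whole numbers of turns, a constructed 30° kink is
recovered to well within 2°; segments covering partial turns bias the
principal axis by a degree or two, which is why the test fixtures use
18-residue (5-turn) segments.

## Pocket metrics

The pocket-opening coordinate is a plain per-frame distance between two
landmark atoms (the Ala360 Cβ–Leu351 Cγ pair in the motivating system:
6.9 Å in the open holoenzyme form, 4.9 Å in the closed cAMP-bound form).
Populations are normalized histograms, default bin width 0.1 Å to match the
0.1 Å reporting precision of such landmark distances; the density integrates
to 1 and mixing series is linear in frame weight.

Accessibility is Shrake–Rupley SASA: `n_sphere_points` (default 960) points
on each pocket atom's expanded sphere (r_atom + probe), a point accessible
iff outside every other atom's expanded sphere — all atoms occlude, not only
pocket atoms. Points come from a deterministic golden-spiral lattice, not
random sampling, so results are reproducible without seeds; the price is
that rigid-motion invariance holds only to the lattice resolution (~0.1% at
960 points; convergence 960→3840 changes fixture areas by < 0.5%). Radii are
an element-keyed van der Waals table (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20, P 1.80 Å) with an override argument; unknown elements are an error,
never a silent default. The probe radius standing in for "the radius of
cAMP" is nowhere stated numerically in the motivating work; the package
default is 2.8 Å, the radius of a sphere with approximately cAMP's molecular
volume, always recorded in the result object.

## SAXS invariants

Model intensities use the Debye sum through a weighted pair-distance
histogram (O(n²) distances once, then O(n_q · n_bins)); the i = j and q → 0
limits are 1, so I(0) = (Σf)² exactly. Uniform f = 1 is the default since
the validated quantities are geometric. P(r) is the distinct-pair histogram
normalized to unit area, with Dmax the largest pair distance. The P(r)-route
radius of gyration uses Rg² = ∫r²P dr / (2∫P dr) with a (1 − Σf²/(Σf)²)
correction for the self-pair term that a distinct-pair histogram omits; the
correction is O(1/n), invisible for bead models, but required for the
two-point closed form Rg = d/2 to hold exactly.

The Guinier fit is a weighted linear fit of ln I on q² over the largest
low-q window satisfying qmax·Rg ≤ 1.3 (standard practice; configurable),
found by iterating fit→trim from a small seed window, with cycle detection.
The Porod invariant integrates q²I by trapezoid and extends beyond qmax with
the fitted K/q⁴ asymptote (truncation otherwise biases Vp low); a
coefficient-of-variation check on q⁴I over the high-q tail sets a
`plateau_ok` flag — bead models of smooth bodies oscillate and legitimately
fail it, so it flags rather than errors. Molecular weight uses the empirical
rule MW(kDa) = Vp/1.7/1000, reported as integer kDa alongside the exact
value. χ² between model and data fits a single scale factor in closed form
and divides by N − 1.

## Hill activation fitting

The Hill model is evaluated as a logistic in n(ln c − ln EC50), which is
algebraically identical to c^n/(EC50^n + c^n) but cannot overflow. Fitting
is least squares on (log10 EC50, n, y0, ymax): the log parameterization
enforces positivity and conditions the problem. y0 and ymax are fitted by
default (residual baselines are typical even in normalized assays) with
optional fixing. Standard errors are the usual residual-variance-scaled
inverse curvature (cov ≈ 2s²H⁻¹ at the optimum), delta-method-transformed
to the EC50 scale; non-convergence sets a flag instead of raising.

## The synthetic generator: what it does and does not emulate

The two-protomer generator places two copies of a coarse one-atom-per-residue
template C2-symmetrically about z. Per frame and protomer: the mobile domain
(CNB-B analogue, residues 266–360) rotates rigidly about the pivot residue
(265) by an angle ~ N(0, σ_hinge); core atoms receive isotropic N(0, σ_core)
jitter; the pocket landmark pair is reset to a separation drawn from the
latent open/closed state. Stated-world defaults and their reasons:

* **Pocket landmarks 6.9 / 4.9 Å with 0.3 Å spread** — the literature
  open/closed values for the Ala360–Leu351 coordinate; 0.3 Å makes the
  bimodality cleanly resolvable at 0.1 Å binning, as in published
  population plots.
* **Hinge σ defaults 2° vs 20°** — no quantitative amplitudes are published
  for the flexible protomer; these are free parameters chosen once to give
  an unambiguous stiff/flexible contrast (an order of magnitude) while
  keeping the mobile domain attached. Recovery tests compare against the
  generator's own latent draws, not against published amplitudes.
* **Open fraction 0.3** — a visibly minor open population, qualitatively
  matching a closed-prone wild-type pocket.
* **σ_core = 0.1 Å** — small thermal jitter so superposition is non-trivial
  but core RMSF stays far below mobile-domain RMSF.

All draws flow from one seeded stream per call; the pipeline derives
per-stage seeds from the root seed so inserting a stage does not perturb
others. What the generator does **not** emulate: real protein geometry and
chemistry, force-field physics, correlated inter-protomer dynamics,
solvation, or accelerated-MD reweighting. A green test therefore establishes
that the *measurement machinery* is correct on data with the assumed
statistical structure — not that any particular biological system has a
given asymmetry.

Similarly, the two reference-structure fixtures shipped under
`inst/extdata/` are labelled synthetic: they place the landmark pair at the
published 6.9/4.9 Å separations so the distance machinery can be exercised
at reporting precision offline, but they are not the deposited crystal/EM
coordinates, and measurements on them do not re-derive the structural fact.

## Numerical conventions and degenerate inputs

* Coordinates are Å throughout; no unit conversion anywhere.
* Author residue numbering is authoritative; insertion codes are part of
  the residue key; bare-resid selections match any insertion code.
* Alternate locations: highest occupancy wins, first-seen on ties —
  a deterministic single-conformer convention.
* A vector along the body +z axis has undefined azimuth; φ is reported 0.
* Selections resolving to zero (or, where one is required, ≠ 1) atoms are
  errors naming the criteria; empty structures, single frames, collinear
  point sets, and zero-mean normalizations all raise typed errors rather
  than returning NaN.
* PDB writing is fixed-column; round trips preserve (chain, resid, name)
  exactly and coordinates to 3 decimals.

## Known limitations

* θ/φ are body-frame-dependent; only d is frame-free. Cross-study
  comparisons of Δθ/Δφ require an agreed frame convention.
* P(r) comes from model coordinates; regularized indirect transforms of
  experimental data (GNOM-style) are out of scope.
* SASA treats atoms as hard spheres with a single probe; no reentrant
  surface, no volumetric pocket detection.
* The Hill fitter is per-curve; no global parameter sharing across
  constructs.
* The Porod plateau flag is conservative on discrete bead models (their
  q⁴I oscillates); inspect `plateau_ok` together with the geometry.
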