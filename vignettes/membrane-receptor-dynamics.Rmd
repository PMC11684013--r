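---
title: "Quantifying membrane-dependent receptor dynamics with memsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-dependent receptor dynamics with memsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsig)
```

## The scientific problem

NK-cell inhibition through the NKG2A/CD94 receptor depends on a chain of
physical events that all happen in or near a lipid bilayer: HLA-E binds the
extracellular domain (ECD), the transmembrane helices (TMD) transmit the
engagement, and the intracellular ITIM tyrosines (Tyr8, Tyr40 of NKG2A) must
stay solvent-accessible to be phosphorylated. Changing the membrane — headgroup
charge, acyl-chain length, saturation, cholesterol content — changes each of
those steps. `memsig` implements the trajectory-analysis layer needed to
quantify such effects from all-atom MD output: correlated-motion statistics,
essential dynamics, residue-anchored geometry, bilayer structure, solvent
exposure and interaction persistence.

The package deliberately separates *analysis* from *simulation*: it consumes a
topology (PDB) plus coordinates (multi-model PDB or DCD) and an anchor map
naming the residues that define each observable. Running MD, building systems
and assigning protonation states are out of scope.

## The statistics implemented

**Dynamic cross-correlation.** For Cα atoms $i, j$ with displacement vectors
$\Delta r_i$ from their time-mean positions (after an RMS fit to the
iteratively averaged structure, which removes global rotation and
translation),

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
{\sqrt{\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle}} \in [-1, 1].$$

$\Delta r$ is the full 3-vector and the numerator is the vector dot product —
the standard DCCM convention. Atoms with zero variance would make the quotient
undefined; their rows/columns are set to `NA` with a warning rather than
silently dropped.

**Domain-pair simplification.** For domains $A, B$ the correlation score is
the signed sum $\mathrm{CS}(A,B) = \sum_{i \in A}\sum_{j \in B} C_{ij}$ over
ordered residue pairs, and the correlation density divides by $|A|\,|B|$.
Two conventions had to be fixed here because they are genuinely open:
diagonal blocks include the $i = j$ self terms (so the density of a pair of
singleton domains is the underlying $C_{ij}$, and summing CS over the whole
domain-pair matrix reproduces the grand sum of $C$), and the summation is
*signed*, not of magnitudes — anticorrelation cancels correlation, which is
what makes the density a useful directionality summary.

**Essential dynamics.** Mass-weighted covariance of the fitted Cα ensemble
(fit reference: the starting configuration), eigendecomposed; variance
fractions, cumulative variance and per-frame projections on the leading
components are reported. Coordinates with exactly zero variance (frozen
atoms) are excluded with a warning — they would contribute spurious null
directions.

**Clustering.** Average-linkage agglomeration on the matrix of pairwise
post-fit backbone RMSDs, cut where the smallest inter-cluster linkage
exceeds an epsilon of 7 Å (the protocol value); medoids represent clusters,
with ties broken toward the earliest frame. The linkage rule is configurable
because "hierarchical agglomerative" alone does not pin it down; average
linkage is the common default for RMSD metrics.

**Residue-anchored geometry.** All angle observables reduce to unit vectors
between mass-weighted anchor centres of mass, compared against the unit-cell
z axis or against each other. The TM tilt ψ (Val73 → Val92 axis vs. vertical)
is folded to [0°, 90°] so that it is direction-independent; the helix
crossing angle φ is left unfolded on [0°, 180°] so parallel and antiparallel
packing stay distinguishable. The receptor-head bending angles α_V
(Cys58–Ser110) and α_H (His184–Thr126) are histogrammed in 3° boxes and as a
joint 2D occupancy grid; TM angle distributions use 1° boxes. Histograms are
left-closed, right-open, anchored at 0°, and report percent of snapshots
(they sum to exactly 100). Helix "top/bottom" anchors default to the
first/last four Cα of the annotated TM span — the anchor map owns this
choice since the enumeration is not standardized.

**Bilayer structure.** The electron density profile bins atomic electron
counts (atomic numbers; partial charges ignored, the common
trajectory-analysis convention) along z about the electron-weighted bilayer
centre, averages over frames, divides by bin volume and normalizes to unit
maximum (the normalization constant is a documented choice; unit-area would
differ only by a scale). Peaks are located after a 3-bin moving average, one
per leaflet; a profile whose inter-peak trough is not clearly below the
peaks (less than 60 % of the lower peak) has no defined bilayer thickness
and reports `NA` — this catches uniform or single-peaked degenerate input.
Area per lipid is exact arithmetic, lateral box area over lipids per
leaflet. Deuterium order parameters
$S_{CD} = \langle (3\cos^2\theta - 1)/2 \rangle$ use the C–H angle to the
fixed z normal; the sign is reported as computed (ordered bilayer chains are
negative, near −0.2), with no magnitude folding. The membrane normal is
fixed to z throughout — no local-normal estimation — so strong curvature
shows up as peak broadening rather than being quantified; curvature analysis
is a non-goal.

**Solvent and interactions.** The water RDF normalizes shell counts by the
instantaneous solvent density each frame (NPT-safe) under minimum-image
distances; `r_max` beyond half the smallest box length is refused.
Contact persistence is the percent of frames in which the minimum
heavy-atom distance of a residue pair falls below 4 Å (the protocol
threshold); hydrogens are excluded by default, matching the usual
heavy-atom convention. Hydrogen bonds use a geometric criterion of
donor–acceptor ≤ 3.5 Å and donor–H···acceptor ≥ 120°; these two numbers are
the package's choice (the protocol fixes only the 4 Å persistence
threshold) and are exposed as arguments. Without a resolvable hydrogen the
angle gate is dropped, with a warning.

**Secondary structure.** A deliberately simplified three-state
Kabsch–Sander assignment: backbone H-bonds score
$E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, bonded below −0.5; two consecutive i → i+4 turns make the
spanned residues helix, H-bonds with sequence separation > 4 mark strand,
everything else is coil. Amide hydrogens are reconstructed from the
previous C=O direction when absent. The full 8-state alphabet (3₁₀/π
helices, turns, bridges) is out of scope: the assignment exists to track
helix-content trends, not to replace a reference DSSP implementation.

## Periodicity and alignment policy

Cells are orthorhombic. Minimum-image wrapping applies to membrane, solvent
and inter-molecular distance observables, never to intra-receptor geometry
(a receptor kept whole must not be re-wrapped through a face). The default
alignment selection is the receptor Cα set; windowing drops an
equilibration span specified in ns (the protocol value is 500 ns of 2 μs),
then strides, then aligns to `"start"`, `"average"`, or a supplied frame.
Window offsets are expressed in ns rather than frame counts because the
saving interval of a run is not, in general, known to the analysis layer.

## What the synthetic generators emulate

Each generator produces the minimal ensemble for which one observable has an
analytic oracle:

* `gen_correlated_trajectory()` — per-atom 3-vector displacements built from
  a shared Cholesky/eigen square root of the target matrix, so the expected
  displacement-vector correlation *equals* the target exactly.
* `gen_helix_pair()` — straight helix axes in the xz-plane at exact tilt and
  crossing angles; per-frame jitter rotates about ŷ, so the per-frame tilt is
  ψ + δ and the crossing |φ + δ₂ − δ₁|: means stay exactly at the
  prescription away from the folds.
* `gen_membrane_slab()` — coarse pseudo-lipids: a headgroup bead with a
  pooled headgroup electron count (atomic number 50, phosphocholine-like) at
  z ≈ ±d/2 (s.d. 2 Å), a 3.75 Å glycerol/carbonyl gap, then an acyl chain at
  1.25 Å per carbon with two hydrogens each. C–H directions are drawn along
  z with probability p = (2S+1)/3 and uniformly in-plane otherwise, making
  the S_CD expectation exactly the prescription over its whole reachable
  range [−0.5, 1]. The gap matters: without it chain electrons merge into
  the headgroup peak and shift the density maximum off the headgroup plane,
  breaking the generator's own ground truth.
* `gen_solvent()` — ideal-gas water oxygens (uniform RDF oracle) or an exact
  shell at radius r₀ (peak-position oracle).
* `gen_contact_schedule()` — a two-atom distance series below/above the 4 Å
  threshold in exactly `round(occupancy · n_frames)` frames.
* `gen_ideal_chain()` — N/CA/C/O backbones at fixed (φ, ψ) with standard
  bond geometry; (−57°, −47°) yields i → i+4 H-bond energies ≈ −2.2
  kcal/mol (well past the −0.5 cutoff), (−140°, 135°) yields none.

What these fixtures do **not** emulate: force-field energetics, realistic
water geometry, lipid conformational disorder, curvature, or any coupling
between observables. Passing the recovery suite therefore demonstrates the
*estimators* are correct and unbiased at the stated tolerances, not that
real membranes behave like the fixtures.

## Numerical choices

* Superposition is Kabsch via SVD with a determinant guard against
  reflections; weighted fits use normalized weights. Fitting is idempotent
  to < 1e-9 Å.
* The averaged structure iterates fit-and-mean until the mean moves
  < 1e-6 Å (cap 50 iterations).
* PSD square roots for correlation targets come from an eigendecomposition
  with negative eigenvalues clipped at 0, so exactly singular targets
  (e.g. a perfectly anticorrelated pair) are legal.
* Electron-density bins default to 1 Å; RDF bins to 0.1 Å. The density
  peak search smooths with a 3-bin moving average; both widths are
  arguments.
* Leaflet assignment sends a headgroup exactly on the midplane to the upper
  leaflet (documented ≥ convention).
* Medoid ties break toward the earliest frame index; `which.min` makes this
  deterministic.
* Every generator consumes one seeded RNG stream per call and restores the
  caller's RNG state, so fixtures are bit-reproducible and non-interfering.

## Problem sizes used in the validation suite

The recovery suite and the acceptance script run at desk scale, chosen so
sampling tolerances are meaningful but runtimes stay in seconds: 10⁴ frames
for correlation and PCA recovery (tolerances 0.05 and 0.01), 5 × 10³ frames
for jittered angle means (0.3°), 49-lipid leaflets over 20 frames for
thickness (±1 bin), 64-lipid leaflets over 30 frames for S_CD (±0.01), a
~460-molecule solvent box over 25 frames for the RDF (3σ per bin, 1 % on the
coordination integral), and 10³-frame contact schedules (exact).

## Known limitations

* Orthorhombic cells only; triclinic trajectories must be wrapped upstream.
* The membrane normal is global z; tilted or undulating bilayers bias
  S_CD and the density profile exactly as they do in any fixed-normal
  analysis.
* The three-state secondary-structure alphabet under-calls helix termini
  relative to full DSSP (by construction a run needs two consecutive
  turns).
* `simplify_correlation()` requires domains to tile the correlation
  matrix's residues; partial domain maps are an error, not a silent subset.
* The DCD writer emits the little-endian CHARMM dialect only; big-endian
  files are readable through the bio3d-backed reader but not written.

## A worked end-to-end run

```{r run, eval = FALSE}
hp <- gen_helix_pair(tilt = 45, crossing = 35, noise_sd = 5,
                     n_frames = 200, seed = 1)
rep <- run_analysis(list(
  trajectory_object = hp$traj, anchor_map = hp$map,
  output_dir = "out", window = list(offset_ns = 20, align = "average"),
  stages = list(rmsd = TRUE, rmsf = TRUE, correlation = TRUE, pca = TRUE,
                cluster = list(epsilon = 7), geometry = TRUE)))
print(rep)
```

The same battery over real input replaces `trajectory_object` with
`structure:`/`trajectory:` paths and the anchor map with the receptor
numbering (`default_anchor_map()` encodes the NKG2A/CD94/HLA-E anchors).
`run_synthetic_suite(seed)` regenerates every fixture and prints the
prescribed-vs-recovered table the tests assert on.
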