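# memsig

Trajectory analysis of membrane-dependent receptor dynamics, built around the
NKG2A/CD94/HLA-E inhibitory immune complex. NK-cell inhibition through this
receptor is a membrane-embedded process end to end: HLA-E engages the
extracellular domain, the transmembrane helices relay the signal, and the
intracellular ITIM tyrosines (Tyr8/Tyr40 of NKG2A) must remain water-exposed
to be phosphorylated. `memsig` is for computational structural biologists who
have all-atom MD trajectories of such systems in different bilayers (POPC,
POPA, DLPC, DPPC, POPC/cholesterol, ...) and need the full quantitative
analysis battery, reproducibly and with every estimator validated against
synthetic ground truth.

## What it computes

| Layer | Observables |
|---|---|
| global dynamics | RMSD, RMSF, B-factors (8π²/3 · RMSF²), conformation clustering (average-linkage backbone RMSD, ε = 7 Å) |
| correlated motion | dynamic cross-correlation matrix `C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨Δr_i²⟩⟨Δr_j²⟩)`; domain-pair correlation scores CS(A,B) = Σ C_ij and densities CS/(\|A\|·\|B\|) |
| essential dynamics | mass-weighted Cα PCA: eigenvalues, variance fractions, PC1/PC2 projections |
| TM geometry | tilt ψ (helix axis vs. unit-cell vertical, folded ≤ 90°), crossing angle φ (unfolded, [0°, 180°]), percent-frequency histograms at 1° |
| receptor head | bending angles α_V (Cys58–Ser110) and α_H (His184–Thr126) vs. vertical, 3° histograms and joint 2D occupancy |
| bilayer | normalized electron density and peak-to-peak thickness, area per lipid, leaflet assignment, deuterium order parameters S_CD |
| interactions | water RDF g(r) around probe atoms, contact counts, contact/H-bond persistence (% frames within 4 Å), simplified 3-state Kabsch–Sander secondary structure |

Input is a PDB topology plus a multi-model PDB or DCD trajectory, and an
anchor map (YAML or `default_anchor_map()`) naming chains, domain spans and
key residues. Every analysis has a synthetic generator with an analytic
oracle, so the whole battery can be exercised end to end without any MD data.

## Worked example

Generate a rigid TM helix pair at 45° tilt and 35° crossing with 5° angular
jitter, then measure both angles back:

```r
library(memsig)
hp <- gen_helix_pair(tilt = 45, crossing = 35, noise_sd = 5,
                     n_frames = 300, seed = 1)
print(hp$traj)
#> Trajectory: 52 atoms, 300 frames, 2 chain(s) [A,B]
#>   cell: 100.0 x 100.0 x 150.0 A
#>   time: 0.000 .. 299.000 ns

a <- lapply(c("helix_a_bottom", "helix_a_top", "helix_b_bottom", "helix_b_top"),
            resolve_anchor, traj = hp$traj, map = hp$map)
psi <- tilt_angle_series(hp$traj, a[[1]], a[[2]])
phi <- crossing_angle_series(hp$traj, a[[1]], a[[2]], a[[3]], a[[4]])
sprintf("tilt psi: %.2f +/- %.2f deg", mean(psi), sd(psi))
#> [1] "tilt psi: 45.17 +/- 4.82 deg"
sprintf("crossing phi: %.2f +/- %.2f deg", mean(phi), sd(phi))
#> [1] "crossing phi: 34.78 +/- 7.02 deg"
```

The tilt series recovers the prescribed 45° within sampling error (s.e. of the
mean is 5°/√300 ≈ 0.29°), and the crossing-angle spread is √2 times the
single-helix jitter, as expected for the difference of two independent 5°
jitters. `angle_histogram(psi, bin = 1)` bins the series into the 1°
percent-frequency distribution used for TM-angle reporting.

The full validation table — every generator prescription vs. what the
matching estimator recovers — comes from one call:

```r
run_synthetic_suite(seed = 1)
#>                               observable prescribed recovered tolerance pass
#> 1                   C12 (prescribed 0.6)        0.6   0.59505     5e-02 TRUE
#> 5                 tilt psi, 5 deg jitter       45.0  45.19767     3e-01 TRUE
#> 6                    thickness, d = 30 A       30.0  30.00000     1e+00 TRUE
#> 7                 S_CD (prescribed -0.2)       -0.2  -0.20086     1e-02 TRUE
#> 9           area per lipid (120x120/225)       64.0  64.00000     1e-09 TRUE
#> 12     PC1 variance fraction (4:1 modes)        0.8   0.80094     1e-02 TRUE
#> 14 interior helix fraction (ideal alpha)        1.0   1.00000     0e+00 TRUE
#> ... (15 rows)
```

Real trajectories run through the same config-driven pipeline:

```r
rep <- run_analysis(list(
  structure = "complex.pdb", trajectory = "run.dcd",
  anchor_map = default_anchor_map(nkg2a = "A", cd94 = "B", hlae = "C"),
  window = list(offset_ns = 500, align = "average"),
  output_dir = "out",
  stages = list(rmsd = TRUE, rmsf = TRUE, correlation = TRUE, pca = TRUE,
                cluster = list(epsilon = 7), geometry = TRUE,
                membrane = TRUE, interaction = TRUE)))
```

which writes plot-ready CSVs (`rmsd.csv`, `cross_correlation.csv`,
`tilt_hist.csv`, `electron_density.csv`, `persistence.csv`, ...) plus a JSON
run report listing every output, warning and failure.

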