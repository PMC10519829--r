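# mdmembr

Ensemble analysis for membrane-protein simulation and crystallographic
data, built around a monotopic phosphoglycosyl transferase (monoPGT)
embedded in a Gram-negative inner-membrane model together with its
membrane-resident substrate, undecaprenol phosphate (UndP).

The package is aimed at structural bioinformaticians who have converted
MD trajectories (multi-model PDB or XYZ-with-box) and crystallographic
artifacts (multi-chain PDB, CCP4/MRC difference maps) and want the
trajectory-side statistics of such a study as tested, reusable functions:

- **Membrane organization** — the nematic order parameter of acyl-chain
  directors, P₂ = ½(3⟨cos²θ⟩ − 1), where θ is the angle between a chain's
  principal axis and the bilayer normal (1 = parallel, −0.5 = in-plane);
  the hexatic bond-orientational order |Ψ₆ₖ| = |⅙ Σₗ e^{i6θ_{kl}}| over the
  six nearest neighbours of each chain in a leaflet (1 = perfect hexagonal
  packing); Voronoi area-per-lipid from a periodic planar tessellation of
  one terminal carbon per chain; mass-density profiles along the bilayer
  normal, recentred on the phosphate midplane.
- **Ligand and protein conformation** — radius of gyration (reported in
  nm), Kabsch superposition, RMSD series, iteratively superposed RMSF with
  the pseudo-B conversion B = 8π²⟨u²⟩/3, membrane insertion depth below
  the phosphate plane, reentrant-helix hinge angles from principal axes of
  Cα windows, and loop-openness Cα–Cα distances.
- **Binding** — residue–residue contact maps at a heavy-atom distance
  cutoff (default 5 Å, minimum image) and contact probabilities over a
  trajectory.
- **Essential dynamics** — PCA of aligned backbone ensembles
  (diagonalizing the 3M × 3M coordinate covariance) and cross-ensemble
  mode comparison through eigenvector inner products O_{ij} = |vᵢ·wⱼ|.
- **Difference-density analysis** — σ-level computation, 3.0 σ peak
  detection, 3.5 Å sphere integration and per-site totals on CCP4/MRC
  maps.
- **Synthetic data** — seeded generators that emulate each input class
  with planted ground truth (a 67:23:10 POPE:POPG:CL bilayer with
  0.5–1 mol% UndP and controllable tilt/packing disorder, two-state
  mobile-loop protein ensembles, Gaussian-blob density maps, scheduled
  binding trajectories), so the whole pipeline is testable offline.

## Worked example

Generate the default synthetic bilayer (200 phospholipids, 100 per
leaflet, two UndP molecules) and compute its order parameters:

```r
library(mdmembr)
mem <- gen_membrane(seed = 20260928 %% 100000, n_frames = 5)
compute_p2(mem$trajectory)$summary
#>  species      mean sd  sd_molecule
#>       CL 0.6693947  0 3.132305e-16
#>     POPE 0.6693947  0 2.371207e-16
#>     POPG 0.6693947  0 2.700653e-16

fr <- mem$trajectory$frames[[1]]
la <- assign_leaflets(fr, mem$topology)
cp <- chain_points(fr, mem$topology, la, "upper")
mean(compute_psi6(cp, fr$box)$modulus)
#> [1] 0.3944

voronoi_areas(fr, mem$topology, la, "upper")$summary
#>  species mean_area
#>       CL 114.48327
#>     POPE  59.02691
#>     POPG  56.94109
```

The planted tilt of 28° fixes P₂ at its closed form 0.669 in every frame
(the generator places director atoms exactly on a line); the default
lattice jitter gives hexatic order at the liquid-disordered scale
(≈ 0.4), and the Voronoi areas land near 58 Å² for the two-chain
phospholipids and twice that for four-chain cardiolipin, with the summed
cells exactly tiling the box.

The analysis workflow in `analysis/01_simulate.R` …
`analysis/07_density_peaks.R` runs each stage as a narrative script —
simulation inputs, membrane order, UndP conformers, protein validation
(RMSD/RMSF, 14 Å planted insertion depth, 118° planted hinge recovered at
117.2°), contact maps, PCA overlap (O₁₁ = 0.983 between the 200-frame
"simulation" and the 8-chain "crystal" ensemble sharing one planted loop
mode), and density-peak integration (site totals within 1% of the
manifests' analytic integrals) — writing tables under `results/`.

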