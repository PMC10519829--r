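---
title: "Methods: membrane order, conformational ensembles and density analysis in mdmembr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane order, conformational ensembles and density analysis in mdmembr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmembr)
```

mdmembr implements the trajectory- and crystal-side analyses used to
characterize a monotopic phosphoglycosyl transferase (monoPGT) in a model
bacterial inner membrane with its undecaprenol-phosphate (UndP) substrate.
This vignette is the package's account of the underlying models, the
parameters that matter, the synthetic-data design, and the numerical
choices a maintainer would otherwise have to reverse-engineer.

## Coordinate conventions

Coordinates are Ångström throughout; only the radius of gyration is
converted to nm, at the reporting layer, because ligand flexibility in
this field is conventionally quoted in nm. Boxes are orthorhombic;
triclinic cells raise an explicit unsupported-format error. Atom indices
are 1-based (the R and bio3d convention), while residue numbers are
always those written in the input file, so selections like
`resid 61-81` (the mobile loop) read identically in file and report.

## Membrane order

**Directors and P₂.** Each acyl chain contributes an independent director
(POPE/POPG two chains each, cardiolipin four) because the Voronoi
protocol counts chains separately and the order statistics should match.
The director is the principal axis of the listed chain carbons (largest
eigenvector of the coordinate second-moment matrix), sign-fixed from the
first listed atom to the last: a subset definition like "C1 through C16"
names all atoms, and a two-point vector is noisier. The two-point
alternative is `method = "endpoints"`. Per frame and species, cos²θ
against the bilayer normal is pooled over chains, P₂ = ½(3⟨cos²θ⟩ − 1) is
evaluated per frame, and the summary is the mean ± sd *over frames* —
that is the spread a table of trajectory statistics reports — with the
molecule-spread sd also emitted (`sd_molecule`) since the convention is
ambiguous in the literature.

**Hexatic order.** |Ψ₆ₖ| = |⅙ Σₗ exp(6iθ_{kl})| over the six nearest
neighbours of chain k under the minimum image, with θ measured against
the laboratory x-axis; the modulus is provably independent of that
reference and of rigid rotations, which the tests exercise. Neighbour
ties are broken by smallest site index so degenerate lattices (e.g.
square-lattice diagonals) are deterministic. Ψ₆ and Voronoi areas are
leaflet-local 2D statistics: cross-leaflet neighbours are excluded by
construction, and at least 7 sites are required.

**Voronoi areas.** The periodic tessellation is realized by replicating
the points into the eight neighbouring images, tessellating the 3×3
tiling with `deldir`, and keeping the central-image cells; cell areas are
recomputed from tile vertices with the shoelace formula, so the cells
partition the box to ~10⁻⁹ relative accuracy. Duplicate points under the
periodic metric are an error rather than silently perturbed — the caller
should deduplicate knowingly.

**Density profiles.** Per frame the z origin moves to the phosphate
midplane (mean phosphate z, not the box centre — robust to asymmetric
solvation), coordinates are wrapped into one period, group masses are
histogrammed and divided by the bin volume, then averaged over frames.
Binning conserves group mass exactly; the default output is absolute mass
density with per-group max-normalization behind `normalize = "max"`.

## Conformational metrics

**Superposition.** Kabsch via SVD of the weighted covariance with the
determinant correction, so the rotation is always proper. RMSF uses
iterative superposition onto the evolving mean (converged to < 10⁻⁶ Å
mean shift, ≤ 100 iterations); the fit set defaults to the analysed
atoms but should be the rigid scaffold when a mobile loop would dominate
the fit (`fit_selection`). Pseudo-B uses the isotropic harmonic identity
B = 8π²⟨u²⟩/3 — a standard crystallographic relation reported alongside
raw RMSF rather than endorsed as a calibration.

**Insertion depth.** The reference plane is the per-frame mean phosphate
z of the protein's leaflet; depth is the clamped distance into the
membrane, so atoms outside contribute zero and the statistic is invariant
under global z-translation.

**Hinge angle.** Window axes are principal axes of the Cα windows,
sign-fixed N→C; the hinge is the *interior* angle at the kink,
arccos(−u·v), so a straight helix reads 180° and a reentrant helix
kinked at a Ser-Pro motif reads its kink angle (≈ 118° in the system this
package models). The raw inter-axis convention is `convention = "axis"`.
Default windows are residues 7–22 and 25–36: the reentrant helix spans
residues 1–36, the kink sits between 23 and 24, and terminal residues
1–6 are excluded as frayed. On ideal helices the principal-axis method
carries ± 2–3° of helix-phase wobble, which is the documented tolerance;
exact published hinge values depend on the (unstated) axis-fitting method
and windows, so both are config-exposed rather than hidden.

## Contact maps

A residue pair is in contact when any heavy-atom pair is strictly below
the cutoff under the minimum image. Heavy atoms only, by default: the
5 Å cutoff scale matches the heavy-atom contact convention, and
all-atom trajectories would otherwise count hydrogens; `include_h`
restores them. Strict inequality at the cutoff is a determinism
statement, not a physical claim. Probabilities are frame fractions, so
probability × n_frames is integral, enlarging the cutoff never decreases
any entry, and swapping groups transposes the map — all tested as
properties.

## Ensemble PCA

Ensembles are matched conformations (simulation frames, or crystal
chains matched by residue id with incomplete-backbone residues dropped
pairwise), iteratively superposed onto their mean and mean-centred. PCA
diagonalizes the 3M×3M coordinate covariance through the SVD of the K×3M
stack. Covariance uses 1/K (population) normalization — visible for an
8-chain crystal ensemble, switchable via `bessel` — and eigenvector
signs are fixed by making the largest-magnitude component positive so
overlap matrices reproduce run-to-run. Backbone means N, Cα, C, O by
default, with Cα-only available for low-resolution crystal ensembles
where backbone O placement is unreliable; modes are unweighted (no mass
weighting — the choice is flagged since conventions differ). The two
ensembles are aligned independently and compared on the shared atom
correspondence; the inner product is alignment-insensitive only for
matched orderings, which is a documented caveat rather than a hidden
assumption.

## Density peaks

σ is the population standard deviation about the map *mean* (difference
maps are near zero-mean, so the about-zero convention nearly coincides;
`about_zero` switches). Peak detection thresholds the mean-subtracted
value at level·σ and requires a strict 26-neighbour local maximum, so
adding a constant to the map changes nothing. Sphere integration uses
the voxel-centre-in-sphere rule with no partial-voxel weighting: it is
grid-deterministic, and the voxelization error is bounded by the surface
shell (≈ 3% for a uniform field at spacing ≤ r/7, far less for compact
peaks). Site totals sum per-peak sphere integrals *without*
deduplication — the procedure this reproduces adds the integrals — and a
union-of-spheres mode exists but is off by default. The site region is a
sphere (default 8 Å) around a user-supplied point because "where the
nucleotide is expected to bind" is inherently a user input. CCP4/MRC
mode-2 maps are read/written directly (no installed R package handles
the format), honouring the column/row/section axis-order header.

## Synthetic data: what is emulated, what is not

The generators produce simplified bead/united-atom geometries with
correct topology labels — the analyses consume geometry plus names only.
They plant the quantity each analysis estimates, and every generator
returns a manifest of the planted truth; recovery tests read only the
manifest.

`gen_membrane` defaults are the study conditions: 67:23:10 POPE:POPG:CL,
200 phospholipids (100 per leaflet), 1 mol% UndP (two molecules) within
the physiologically motivated 0.5–1 mol% window, anchored by their
phosphate at the interface of one leaflet. Where only the *measured*
order is stated, free geometric parameters were fixed once to reproduce
those scales by construction and not revisited: tilt θ₀ = 28° (closed
form P₂ = 0.669, the liquid-disordered value), lattice spacing 5.8 Å
(≈ 29 Å² per chain, i.e. ≈ 58 Å² per two-chain lipid), lateral jitter
0.2 of the spacing (mean |Ψ₆| ≈ 0.4, the liquid-disordered packing
scale). Chains are exactly straight and tilted at exactly θ₀ with random
azimuths, so P₂ is recovered to 10⁻¹² — by design: the generator plants
the delta-distributed tilt the closed-form check needs. What this does
*not* emulate: chain internal disorder (gauche defects), headgroup
chemistry, water/ions, undulations, or any energetics; passing tests
show the estimators are correct on planted geometry, not that a real
bilayer would produce these values.

`gen_undp_conformers` uses an 11-bead isoprene-unit chain with 4.4 Å
spacing; the extended rod's Rg = b√((n²−1)/12) = 1.39 nm and the closed
ring's Rg = b/(2 sin(π/n)) = 0.78 nm bracket the published ≈ 0.85 nm
average of the real, mostly coiled carrier.

`gen_protein_two_state` plants one dominant motion: a rigid translation
of the mobile loop (residues 61–81) towards a reference residue, with
the net-translation/rotation content projected out (six rigid-body
generators, QR-orthogonalized) because ensemble superposition provably
absorbs the rigid component — without the projection the crystal-side
PC1 overlap drops to ≈ 0.88 for purely geometric reasons. Amplitude is
per-loop-atom displacement (default 1.5 Å) with isotropic per-coordinate
noise at 1/10 of it; the "simulation" trajectory draws open/closed
states 50/50 and the "crystal octamer" uses two closed, four open and
two intermediate chains, mirroring the conformer census of the
eight-chain asymmetric unit this emulates.

`gen_density_map` sums isotropic Gaussians (analytic integral
A(2π)^{3/2}w³ per blob, recorded in the manifest) plus optional noise;
`gen_binding_trajectory` realizes per-residue contact fractions as a
deterministic first-k-frames schedule so recovered probabilities are
exact, not merely unbiased.

Sub-seeds are derived per molecule and frame from the call seed, so
adding molecules or extending a trajectory never reshuffles existing
coordinates — the property that makes incremental fixtures stable.

## Problem sizes and determinism

The shipped analyses and tests run at desk scale: 5-frame membranes of
200 lipids, 200-frame protein ensembles of 140 residues, 64³ maps at
0.5 Å, 100-frame binding schedules, and 20 seeded replicates for the
overlap recovery experiment. These sizes were chosen so each stage's
statistic is already at its asymptote (the recovery experiments are
machine-precision or percent-level at these sizes) while the whole suite
runs in well under a minute per stage. Published trajectory statistics
from μs-scale all-atom MD (P₂ ≈ 0.67–0.72, |Ψ₆| ≈ 0.40, areas ≈ 58 Å²,
hinge ≈ 117°) are *context* for the generator defaults, not quantities
a desk-scale emulation can independently reproduce.

## Known limitations

- Orthorhombic boxes only; no triclinic minimum image.
- The selection grammar covers species/resid/name/chain with and/or —
  no parentheses, no negation.
- Voronoi cells are computed per leaflet in 2D; strongly undulating
  membranes would need a curved-surface treatment.
- The crystal-ensemble worked example uses the synthetic ideal-helix
  construct when deposited coordinates are not locally available; the
  same call reproduces the published hinge on a local copy of the
  deposited structure.
- Contact analysis is O(residues² × atoms²) per frame in plain R;
  adequate for the residue counts here, not for proteome-scale maps.
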