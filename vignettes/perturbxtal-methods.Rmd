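---
title: "Methods: comparative crystallography with perturbxtal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative crystallography with perturbxtal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbxtal)
```

perturbxtal quantifies how a protein crystal structure responds to a
physical perturbation — elevated temperature or hydrostatic pressure —
by comparing two or more isomorphous structures of the same protein
against a named reference. This vignette documents the model behind each
analysis stage, the default parameters, and why those defaults were
chosen. Every stage is exercised end-to-end on a deterministic synthetic
crystal whose ground truth is known exactly, so the numbers shown here
are reproducible on any machine.

## The synthetic test crystal

All examples use the package's built-in generator: a 14-residue
ideal-geometry α-helical peptide (φ = −57°, ψ = −47°) with side-chain
rotamers drawn deterministically from the built-in mode table
(advancing to the next mode when a side chain would clash), placed in a
30 × 34 × 40 Å P2₁2₁2₁ cell with 20 ordered waters kept at least 2.4 Å
from the protein and 3.0 Å from each other, including all
crystal-symmetry images.

```{r toy}
toy <- build_toy_crystal()
toy
```

Controlled perturbations — rotamer flips, rigid loop shifts, water
displacements, B-factor inflation — are applied with `perturb()`, which
records the ground truth it planted:

```{r perturb}
pr <- perturb(toy, list(
  list(kind = "rotamer-flip", resno = 2, target_chi1 = 180),
  list(kind = "water-move", water = 5, distance = 2.6),
  list(kind = "loop-shift", from = 12, to = 13, distance = 1.0)),
  seed = 14)
pr$truth
```

## Volumes

`cell_volume()` evaluates the exact triclinic formula
$V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
2\cos\alpha\cos\beta\cos\gamma}$ and rejects geometrically impossible
angle combinations. `percent_change()` reports changes relative to the
reference, rounded to one decimal by default because that is the
precision at which cell dimensions are conventionally reported.

`protein_volume()` measures the solvent-excluded molecular volume on a
grid: a voxel is *blocked* when it lies within (van der Waals radius +
probe radius) of any atom; the solvent region is the blocked-free space
reachable from the box boundary (flood fill); the reachable region is
then dilated by the probe radius, and the molecular volume is everything
not covered. Defaults: grid 0.3 Å and probe 1.4 Å (the water-probe
convention). The blocked radius is shrunk by a quarter voxel to correct
the systematic surface overestimate of voxel counting; with this
calibration a single carbon atom's volume is within 0.5% of the
closed-form sphere and grid refinement from 0.4 to 0.2 Å changes the
toy-protein volume by under 1%. The van der Waals radii are a fixed
documented set (C 1.70, N 1.55, O 1.52, S 1.80, H 1.10 Å). Waters are
excluded by default (`include_waters = FALSE`).

```{r volumes}
cell_volume(toy$cell)
protein_volume(toy, grid = 0.3)
```

## Ordered-solvent comparison

`unique_waters()` classifies each water of a query structure as shared
or unique relative to one or more reference structures using
`min_symmetry_distance()`: the minimum Euclidean distance to any
crystal-symmetry image (all space-group operators × lattice translations
within ±1 cell) of any reference water. A water is unique when that
distance exceeds the threshold to *every* reference. The default
threshold is 2.0 Å; the translation shell of 1 is exhaustive because
2 Å is far smaller than any cell edge. Because isomorphous cells still
differ by a few percent, coordinates are compared in a common frame: by
default each structure's waters are converted to fractional coordinates
in its own cell and re-orthogonalized in the reference cell
(`frame = "fractional"`); a superposition-based mode is available
(`frame = "superposed"`).

```{r waters}
unique_waters(pr$structure, toy, threshold = 2.0)
```

## Backbone displacement

`superpose()` implements the Kabsch least-squares rigid superposition
(proper rotation enforced). `ca_distance_profile()` reports per-residue
Cα distances after superposing the mobile structure onto the reference;
residues expected to move can be excluded from the fit (but are still
profiled) via `fit_exclude`, which prevents a genuinely displaced loop
from dragging the global fit. The descriptive cut used in report
summaries is 0.3 Å. `ca_rmsf()` gives per-residue fluctuations about
the mean over a structure set, and `altloc_ca_separation()` measures
Cα separations between alternate conformers within one model.

```{r displacement}
prof <- ca_distance_profile(pr$structure, toy,
                            fit_exclude = paste0("A|", 12:13, "|"))
subset(as.data.frame(prof), ca_dist_A > 0.3)
```

## Ringer curves and correlation flagging

`ringer_curve()` swings a residue's γ atom about the Cα–Cβ axis so that
χ1 takes each angle on a grid (default step 10°, small enough to resolve
the ~120°-spaced rotamer wells at 36 samples per residue) and records
the map density at each position, σ-scaled by default so that curves
from different maps are comparable. Interpolation is trilinear by
default — adequate for maps sampled at a quarter of the resolution —
with separable Catmull-Rom tricubic available. `flag_changed_residues()`
compares per-residue curves between two conditions by Pearson
correlation and flags residues with CC below 0.5, a conservative
midpoint: planted rotamer flips in synthetic maps drive the CC negative
(≈ −0.3) while unchanged residues stay near +1 even with 5% map noise.
Residue ranges whose density is known to change for other reasons can
be excluded.

```{r ringer}
m0 <- simulate_map(toy, grid = 0.25, noise_sigma = 0.05, seed = 1)
m1 <- simulate_map(pr$structure, grid = 0.25, noise_sigma = 0.05, seed = 2)
flag_changed_residues(ringer_curves(m0, toy),
                      ringer_curves(m1, pr$structure),
                      threshold = 0.5, exclude = "12-13")
```

The simulated maps place a normalized 3D Gaussian of variance
$B/(8\pi^2) + (\text{grid}/2)^2$ and weight occupancy × Z at every atom
and every symmetry image, so they obey the space-group symmetry by
construction; optional white noise is stated in σ units of the noiseless
map. The grid term keeps the narrowest atoms resolvable at the sampling
rate, and the generator refuses grids coarser than half the smallest
Gaussian width.

## Rotamers

`dihedral()` returns IUPAC-signed torsions. `name_rotamer()` assigns
the nearest mode in a built-in compact table of modal χ values per
residue type (penultimate/MolProbity-style p/t/m nomenclature), with
two-fold-symmetric terminal torsions (Asp, Glu, Phe, Tyr) folded before
matching, and returns OUTLIER when any χ deviates more than 40° from its
nearest mode. `rotamer_diff()` counts residues whose rotamer changed
between two structures; with alternate conformers the default
"any-match" policy counts a residue as unchanged if *any* conformer
name matches across structures (a "primary" highest-occupancy policy is
available), and excluded residue ranges are removed from both numerator
and denominator.

```{r rotamers}
rotamer_diff(pr$structure, toy, exclude = "12-13")
```

## Torsion-angle embedding

`extract_torsions()` collects φ/ψ (masked at chain breaks, detected by
a C–N distance over 2 Å) and χ1–χ4 per residue.
`embed_torsions()` encodes each torsion shared by all structures as a
(sin, cos) pair — the standard circular embedding, so a 359°→1° change
is small — centers the features, and decomposes by SVD. Component signs
are fixed deterministically (largest-magnitude loading positive), the
explained-variance fractions are non-increasing, and at most n − 1
components are nonzero for n structures.

```{r embed}
flipped <- lapply(1:3, function(s)
  perturb(toy, list(list(kind = "rotamer-flip", resno = 2,
                         target_chi1 = 180)), seed = s)$structure)
emb <- embed_torsions(lapply(c(list(toy, toy, toy), flipped),
                             extract_torsions))
emb$scores
```

## The pipeline

`run_pipeline()` executes every stage against a named reference and
aggregates the results; each summary number is taken directly from the
stage output it summarizes, never recomputed. Thresholds live in a
single configuration block (water 2.0 Å, CC 0.5, displacement 0.3 Å,
optional exclusion ranges). `write_report()` fixes floating-point
formatting to six significant digits so identical runs produce
byte-identical CSV and JSON outputs. A command-line wrapper for all
stages ships in `system.file("cli", "perturbxtal.R",
package = "perturbxtal")`.

```{r pipeline}
pr$structure$label <- "perturbed"
report <- run_pipeline(list(ref = toy, perturbed = pr$structure),
                       compute_protein_volume = FALSE)
report$summary
```

## Problem sizes

The package targets single protein domains (hundreds of residues, a few
hundred waters) and maps up to a few tens of millions of grid points.
The grid protein volume is the slowest stage (seconds to a minute at
0.3 Å for a domain-sized protein); every other stage runs in well under
a second on the synthetic crystal and in seconds on domain-sized
structures.
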