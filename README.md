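# xpcilung

Propagation-based X-ray phase-contrast lung micro-CT, end to end and
verifiable: phantom → wave-optics image formation → filtered back
projection → segmentation → 3D alveolar morphometry.

## Why

Lungs are air-filled soft tissue. Absorption radiography barely sees them,
but the refractive index `n = 1 − δ − iβ` has a real part whose effect on
the beam — the phase shift — is roughly a thousand times stronger than the
absorption for soft tissue at hard X-ray energies. Let the beam propagate
a metre or so past the sample and Fresnel diffraction converts phase
gradients at every air/tissue interface into intensity fringes: in-line
phase-contrast imaging. With CT over 180°, individual alveoli of a newborn
mouse (100–150 µm) become visible and measurable.

The original experiments cannot be rerun from a desk — there is a mouse, a
synchrotron, and no deposited raw data. This package therefore implements
the full computational chain and validates every stage against a digital
lung phantom with analytic ground truth:

* **Phantom** — body cylinder, bifurcating airway tree, alveolar spheres
  of known diameter, bone ribs; rasterized to δ/β voxel grids from a
  documented material table (`δ ∝ 1/E²`, `β ∝ 1/E⁴`).
* **Forward model** — transmission `q = exp(−μ/2 + iφ)` with
  `μ = (4π/λ)∫β dl`, `φ = −(2π/λ)∫δ dl`; exact angular-spectrum Fresnel
  propagation (plus the linearized weak-object propagator
  `F{I} = δ(u,v) − M + 2πλz(u²+v²)Φ` as a cross-check); area-weighted
  detector binning; Poisson noise. Defaults mirror the experiment:
  18 keV, z = 1.2 m, 13 µm pixels, 1296 projections over 180°.
* **Reconstruction** — flat-field normalization, −log sinograms,
  parallel-beam FBP (Ram-Lak or Hann), preserving the edge-enhanced
  fringes.
* **Segmentation** — rib threshold, automatic histogram-valley threshold
  with Otsu fallback, sub-threshold zeroing + gray-scale rescale, and
  seeded 3D region growing (26/6-connectivity) for the bronchial tree.
* **Morphometry** — per-alveolus volume, equivalent diameter
  `(6V/π)^{1/3}`, 3D max/min Feret diameters and their ratio, and surface
  area from watertight marching-tetrahedra iso-surface meshes; CSV output;
  STL/PLY/OBJ export and plane clipping for rendering.

## Worked example

A compact phantom (512 µm cube, 5 alveoli of 80–110 µm) through the whole
chain, about 50 s on one core:

```r
library(xpcilung)

spec <- phantom_spec(
  extent_um = 512, pitch_um = 4,
  tree = list(depth = 2, root_radius_um = 50, radius_ratio = 0.7,
              root_length_um = 130),
  alveoli = list(count = 5, diameter_range_um = c(80, 110)),
  ribs = list(count = 2, tube_radius_um = 24, ring_radius_frac = 0.33),
  seed = 11
)
geom <- beam_geometry(detector_pitch_um = 8, n_angles = 120)
run  <- run_pipeline(spec, geom, seed = 5)
summary(run)
```

```
planted alveoli: 5 (true mean diameter 87.5 um)
recovered components: 5, mean equivalent diameter 83.3 um
valley threshold 3.044e-05, elapsed 48.3 s
```

Here the five planted spheres come back as five distinct components with
equivalent diameters about 4 µm (half a detector pixel) below the planted
truth — the expected slight erosion of thresholding at the air/tissue
valley.

`run$stats` holds one record per recovered chamber (id, volume,
equivalent/max/min diameter, ratio, surface area, centroid — the CSV
columns), and `match_alveoli(run)` pairs them with the planted ground
truth. At the full default scale (256³ voxels at 4 µm, 21 alveoli on
100–150 µm, 240 projections; ~10 min) the pipeline recovers 21/21 planted
alveoli with mean equivalent diameter 112.8 µm and mean absolute diameter
error 6.4 µm — inside the planted 100–150 µm range, within two detector
pixels per object.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/xpci-lung run-all --config cfg.yaml --seed 1 --out out/
Rscript inst/cli/xpci-lung measure --labels out/labels_alveoli.tif --out stats.csv
```

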