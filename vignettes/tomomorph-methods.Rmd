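---
title: "Quantifying the probe-tissue interface in micro-CT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the probe-tissue interface in micro-CT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Implanted neural probes trigger a foreign-body response — glial scarring, a
cavity sheath along the shaft, vascular reorganisation, and occasionally
calcium-phosphate deposits — that degrades recording quality over weeks.
Synchrotron phase-contrast micro-CT can image unstained, resin-embedded brain
tissue *with the probe in place* at roughly micrometre voxel size, so the
interface can be quantified in 3D without sectioning. The price is a
metal-induced directional artifact: X-rays traversing the platinum tracks
edge-on lose signal, producing a low-SNR streak band ("missing wedge") to the
sides of the shaft in which cells and vessels cannot be segmented reliably.

`tomomorph` packages that analysis chain: volume I/O and preprocessing,
threshold segmentation of the tissue classes, artifact-exclusion masking,
and the distance-transform morphometry that produces vessel-diameter
distributions, nearest-vessel distance statistics, calcification volumes and
calcification-to-probe distances. Because the tomograms such studies rest on
are tens of gigabytes and typically available only on request, the package
also ships a seeded synthetic phantom generator with voxel-level ground
truth; every stage is validated against it.

## Pipeline

A run is fully described by one `pipeline_config()`:

```{r}
library(tomomorph)

cfg <- pipeline_config(phantom = phantom_spec(seed = 1))
rep <- run_pipeline(cfg)
glance(rep)
autoplot(rep, which = "vessel_distance")
```

Stages execute in order:

1. **volio** — phantom generation or TIFF-stack reading
   (`read_stack()`/`write_stack()`, multi-page or slice-directory, voxel
   size in a JSON sidecar), optional `bin_volume()` block binning and
   `convert_to_8bit()` windowed bit-depth reduction, `reorient()` rotations
   and cropping.
2. **segment** — `segment_volume()` applies the grayscale windows in
   priority order (metal, calcification, cavity, vessel, cell; the rest is
   tissue), cleans each mask by connected-component size, and derives the
   exclusion mask and analysis domain.
3. **morphometry** — volumes and fractions, `local_thickness()` over the
   vessel mask, `distance_to_set()` for nearest-vessel and
   calcification-to-probe distances, histograms and medians, assembled into
   a `morphometry_report`.

## The measurements

**Distance transforms.** `edt_to_background()` and `distance_to_set()`
compute exact Euclidean distances between voxel centers, weighting each axis
by its physical pitch (anisotropy-aware), via the separable
lower-envelope transform. Two conventions matter and are fixed here:
distances are center-to-center, and for the EDT of a structure everything
*outside* the volume counts as background (one padding layer). Without the
padding rule, a structure touching the volume face would look infinitely
thick. `distance_to_set()` applies no padding — only real target voxels
attract — and refuses an empty target, since a median of undefined distances
is meaningless.

**Local thickness.** The vessel "diameter" at a voxel is defined by maximal
inscribed spheres (Hildebrand–Rüegsegger): twice the largest EDT radius of
any foreground ball that covers the voxel, with *open*-ball containment
(strict `<`). The open ball resolves boundary ties so that an *n*-voxel slab
reports (n+1)·pitch everywhere, consistently. Together with center-to-center
distances this biases reported diameters upward by about one voxel: a tube
of true diameter d rasterized at 1 µm reports its mode in [d, d+2] µm. The
bias is documented rather than corrected, because the reference definition
(`local_thickness_bruteforce()`, a literal exhaustive evaluation) uses the
identical convention and the test suite requires *exact* equality between
the accelerated and the brute-force implementation on randomized volumes.
The acceleration (skipping spheres provably contained in a neighbour's
sphere, with a conservative epsilon so only certainly-redundant spheres are
dropped) therefore changes nothing but runtime.

Before sphere fitting, the vessel mask is passed through `fill_holes()`:
enclosed background components (6-connected, not touching the volume
boundary) are filled. Interior voxels lost to intensity noise are not
"surrounding space", but without filling each one would puncture every
inscribed sphere around it and collapse the thickness toward the voxel
scale. The reported masks, volumes and fractions stay unfilled; filling is
a property of the thickness measurement only.

**Volumes and fractions.** `structure_volume()` is voxel count times voxel
volume. Vessel and cell fractions are reported over the *analysis domain*
(volume minus probe, cavity and exclusion mask); probe metal and
calcification use the full volume, since their contrast is unaffected by the
artifact. Histograms are half-open bins `[k·w, (k+1)·w)` from zero, default
width 1 µm; medians of even counts average the two central order statistics.

**Percent changes.** `percent_change()` keeps full precision;
`round_percent()` rounds to the nearest integer, ties away from zero. On the
canonical worked example, medians 10.7 → 17.2 µm give +60.75%, printed 61%.
Note that rounded inputs can disagree with percentages computed from
unrounded values (2.3% vs 2.0% gives −13.0% on the printed numbers); the
package therefore always reports the full-precision change alongside the
rounded one.

## Preprocessing conventions

- **Binning** uses non-overlapping block *means* (a factor-2 binning of a
  438 nm grid yields the 876 nm grid; of 574.24 nm, the 1148.48 nm grid).
  Means rather than decimation because binned tomograms show no visible
  contrast loss, which subsampling would not guarantee. Trailing partial
  blocks are discarded, not padded.
- **Quantization** is round-half-up everywhere (`floor(x + 0.5)`), which
  makes the documented examples exact (window midpoint 127.5 → 128).
- **8-bit conversion** maps a `(lo, hi)` window linearly to 0–255; the
  default window is the 0.1st–99.9th percentile range of the volume.
- **Thresholds are inclusive** (`lo <= v <= hi`), so masks are monotone in
  the window and worked examples are exact.

## Segmentation design

The studies this workflow descends from segmented cells and vessels
*manually* after contrast enhancement. The package substitutes explicit,
recorded parameters: per-class grayscale windows plus connected-component
cleanup (`min_component_voxels`, default 10 at 26-connectivity). The default
windows match the default phantom intensity model — metal at the saturation
value, calcification 170–239, tissue around 120, cells 77–105, vessels
44–76, cavity 24–43. On real tomograms the windows are the analyst's choice,
exactly as the manual thresholds were; the config file makes that choice
reproducible.

The default windows are deliberately *disjoint*. Overlapping windows
interact badly with connected-component logic under noise: with a cavity
window reaching into the vessel intensity range, the ~30% of vessel voxels
whose noisy values fall inside it form percolating clusters along the
vessel network, and wherever that network touches the shaft sheath the
whole cluster is claimed by the probe-adjacent cavity component. Disjoint
windows confine each class's noise outliers to sub-percolation densities,
where component-size cleanup removes them.

Component cleanup is a noise-robustness device. With zero noise it is
disabled in the validation tests (`min_component_voxels = 1`), because
overlap between structures (a vessel crossing a cell) legitimately leaves
sub-threshold fragments of the losing class that cleanup would delete.

The cavity is identified by its window *plus* adjacency: only components
touching the probe within a one-voxel dilation count, so unrelated dark
blobs are not mistaken for the shaft sheath.

**Exclusion geometry.** The artifact-corrupted region around the probe is
excluded from vessel/cell quantification. Whether the exclusion should
surround the whole shaft or only its two artifact-facing sides is not
decidable from the underlying description ("distance of less than 46 µm to
the sides of the probe shaft"), so both are implemented: `radial` (default;
all voxels within 46 µm of any probe voxel) and `directional` (the radial
set intersected with the two half-spaces beyond the probe's bounding slab
along the artifact axis). The default distance is 46 µm.

## The phantom: what it emulates, and what it does not

`phantom_spec()` defaults encode the study conditions at a desk-tractable
scale:

- **Volume**: 48 × 420 × 420 voxels at 1 µm isotropic. The real processed
  tomograms are 600–1700 µm per side at 0.876/1.148 µm voxels; the phantom
  keeps the full probe width but a thin z-slab, so the default pipeline runs
  in seconds-to-minutes on one CPU. 1 µm was chosen as a round value between
  the two study grids.
- **Vessels**: dark tortuous tubes, diameters lognormal around 5 µm clipped
  to 3–20 µm, random chords with jittered control points; tubes are added
  until a target volume fraction is reached — 2.3% by default (the control
  cortex value; rodent cortex is 2–2.6% across studies).
- **Cells**: darker-than-neuropil spheres, 10^5 /mm³, radii 2.5–5 µm.
  Whether somata appear brighter or darker than neuropil in these tomograms
  is not stated anywhere; darker was chosen so the class is separable from
  tissue by thresholding, and the polarity is enforced (and checked) by
  `render_intensities()`.
- **Probe**: a 380 µm × 12 µm shaft spanning the volume in z, carrying 12
  saturated metal tracks (only the metal is visible in real tomograms — the
  polyimide substrate is not), surrounded by an elliptical low-intensity
  cavity sheath.
- **Calcifications**: bright blobs placed 20–150 µm from the shaft plane.
  They are generated only when a probe is present, since they are an
  implantation-site phenomenon.
- **Intensities**: 8-bit class means cavity 40 < vessel 60 < cell 90 <
  tissue 120 < calcification 220 < metal 255 (saturated), Gaussian noise
  SD 8. These are generator defaults chosen for well-separated thresholds,
  not measured values.
- **Artifact**: inside the band of axis lines through probe voxels
  (half-width 46 µm), noise SD is multiplied by 1.5 and alternating ±
  streaks of amplitude (inflation−1)·SD are added, constant along the
  artifact axis (default y — the direction in which a beam traverses the
  most metal). Scaling the streaks by the noise SD means zero-noise phantoms
  have no artifact, which is what makes exact-recovery tests possible.

All randomness comes from one seeded generator consumed in a fixed order
(cells, vessels, calcifications, rendering noise, artifact noise), so equal
specs give voxel-identical volumes.

The phantom deliberately does **not** model: vascular branching or network
topology, cortical layering, partial-volume boundary voxels (class means are
exact up to noise), the physics of phase retrieval and reconstruction, ring
artifacts, or tissue shrinkage. Passing tests therefore demonstrate that the
*measurement chain* is correct — exact distance transforms, exact
sphere-fitting, correct bookkeeping — not that the default thresholds would
segment any particular real tomogram; on real data the windows must be
chosen by inspection, as they were in the original manual workflow.

## Validation strategy and problem sizes

- The accelerated thickness equals the brute-force definition *exactly* on
  50 randomized 24³ mixed blob/tube masks; both transforms match exhaustive
  nearest-neighbour search to 10⁻⁹ µm on 20 randomized 16³ masks (isotropic,
  anisotropic and sub-micrometre spacings).
- Analytic phantoms pin the conventions: a 5-voxel slab reads 6 µm
  everywhere away from the lateral edges; planes spaced 20 µm give a median
  nearest-distance of exactly 5 µm; rasterized cylinders are within 10% of
  πr²L; tubes of 4/8/12 µm report modal thickness within [d, d+2].
- On the study-scale zero-noise phantom every class is recovered with
  Dice = 1 and the vessel fraction matches ground truth exactly; at noise
  SD 8 the vessel Dice is ≥ 0.9 and the fraction within 0.5 percentage
  points of truth, both evaluated over the analysis domain — mirroring the
  original practice of excluding the artifact-corrupted band, where manual
  and automatic segmentation alike break down (the full-volume Dice on the
  same phantom is ~0.63, almost entirely due to the band and sheath).
- Conservation properties: histogram counts sum to the domain size;
  class-partition fractions sum to 1; thickness ≥ 2·EDT pointwise.

These sizes keep the whole suite around two minutes on one CPU while still
exercising the full default geometry (8.5 million voxels) end to end.

## Degenerate inputs and numerical corner cases

- Empty probe mask → empty exclusion mask (with a warning if a probe was
  declared present); empty analysis domain → error.
- Empty distance target → error (median undefined); empty histogram domain
  → all-zero histogram.
- Constant volume under contrast enhancement → returned unchanged with a
  warning. Zero reference in `percent_change()` → error.
- Tube rasterization marks a voxel iff its center is within the radius
  (inclusive; ties toward foreground); sub-pitch tubes keep a one-voxel
  chain so thin tracks never vanish; a centerline entirely outside the
  volume yields an empty mask with a warning, not a failure.

## Known limitations

- Reported diameters carry the ~+1 voxel convention bias described above.
- The exclusion-mask geometry on real data depends on probe type and data
  quality; 46 µm is a study-specific default, not a constant of nature.
- Calcification statistics are only defined when a probe (metal) mask is
  nonempty; probe-free runs flag them as `NA`.
- No tissue-shrinkage correction is applied; absolute volumes refer to the
  processed (fixed, dehydrated, embedded) tissue state.
- Statistical inference across animals is out of scope: each report
  describes one volume (n = 1), and `compare_reports()` only tabulates
  deltas and percent changes between two runs.
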