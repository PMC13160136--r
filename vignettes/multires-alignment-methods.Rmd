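---
title: "Methods: multi-resolution volume-EM alignment, segmentation export, and acquisition planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-resolution volume-EM alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrvem)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which parameters matter, what the
synthetic phantom does and does not emulate, and where the design was
genuinely open.

## The problem

A serial block-face scanning electron microscope images the freshly cut
face of a resin-embedded tissue block, removes a ~50 nm section, and
repeats. Large fields of view are acquired as grids of overlapping tiles
(15% of tile shape by default). A multi-resolution strategy scans the whole
region of interest at cellular resolution (~40 nm/px) and selected
compartments at synaptic resolution (~10 nm/px). The raw output is
therefore a set of directory trees of 8-bit TIFF tiles whose filenames
encode grid position and section number, plus per-section metadata giving
the pixel size.

`mrvem` turns these trees into (1) one coherent cellular-resolution stack,
(2) synaptic-resolution stacks registered into that stack's frame, (3) a
chunked segmentation graph ready for collaborative proofreading, (4) a
filtered synaptic connectivity table, and (5) an estimate of the
acquisition time the multi-resolution strategy saved.

## Registration model

**Metric.** All matching uses normalized cross-correlation (NCC), computed
with FFTs and windowed sums. NCC is invariant to the gain and offset drift
that accumulates over weeks-long scans. A match is kept only if the peak
correlation reaches `min_peak` (default 0.3), the secondary/primary peak
ratio stays below `max_peak_ratio` (default 0.9, with an exclusion zone
scaled to a quarter of the patch so broad peaks are not their own
"secondary"), the peak does not sit on the edge of the searchable window,
and neither patch is dominated by black fill (warped images are zero-filled
outside their source).

**Sub-pixel refinement.** The conventional parabola fit through the
correlation peak is biased by the asymmetry of the local autocorrelation —
on our textured phantoms the bias reaches a quarter pixel even for
identical images. We instead refine by iterative Lucas–Kanade steps on the
intensity-normalized patches: solve the linearized SSD for the 2-vector
offset, resample, repeat (3 iterations, patch subsampled to ~33 samples per
axis). This is exact at zero displacement and reduces per-node noise to a
few hundredths of a pixel. The parabola fit remains as a fallback for peaks
at window borders.

**Flow fields.** `estimate_flow()` places patch centers on a regular grid
(stride default `patch_size/4`), inset so every search window fits inside
the image; `multiscale_flow()` runs coarse-to-fine over downsampling
factors (default 4 then 1), pre-warping the moving image with the
accumulated field before each refinement. `filter_flow()` median-filters
the field over 3×3 node neighborhoods and *invalidates* nodes deviating
more than 2 px from the neighborhood consensus — isolated wrong matches
are failures, not measurements.

**Elastic mesh.** Flow constraints are regularized by a 4-connected spring
mesh (spacing defaults to the flow stride) minimizing

\[ E = \sum_{\text{springs}} \tfrac12 k\,(\lVert p_i - p_j\rVert - L_0)^2
     + \sum_{\text{nodes}} \tfrac12 w_n\,\lVert d_n - t_n\rVert^2 , \]

by damped gradient descent with momentum and a fixed step below the
stability bound \(2/(4k + \max w)\); iterations that would raise the energy
are rejected (step halved), so energy is non-increasing and the result
deterministic. The default stiffness `k = w` passes smooth fields almost
unchanged while attenuating single-node outliers to ~1/5. Boundary nodes
obey the same springs as interior ones — detector distortion is strongest at
the field-of-view edges, and pinning the boundary would forbid correcting
exactly the region that needs it most. The energy functional itself is this
package's definition; we treat the functional used by other elastic
aligners as unspecified and validate ours against closed-form minima.

## Pipeline structure

**XY stitching.** Tile pairs are coarsely registered by NCC in their
nominal overlap bands (template anchored at the leading edge of the second
tile and trimmed by the search pad, so a ±pad offset is observable in both
axes even for narrow overlaps; the supported floor is a declared overlap of
10 px). Pairwise offsets are reconciled into per-tile translations by
weighted least squares with the first tile anchored; invalid pairs fall
back to nominal placement with a warning. Residual deformation is handled
by one mesh per tile, with flow constraints in the overlap bands split
antisymmetrically between the two tiles of each pair, and the composite is
rendered with linear feather blending (ramp width 8 px).

**Root slice and Z alignment.** When several stitched images exist for one
section, keypoint matching (Harris corners + NCC descriptors, consensus
affine fit) decides overlap; overlapping groups are fused, disjoint ones
kept apart. The root slice is the first section that is a single contiguous
image, and alignment proceeds outward from it in both directions, each
section aligned to its last processed neighbor.

The per-step coarse model is a translation, with the keypoint affine as a
fallback when translation matching fails (e.g. under rotation). This is a
deliberate deviation from using a full affine every step: a per-neighbor
affine estimated from noisy matches carries ~1% spurious scale that
compounds into large drift over a long stack, while true non-rigid residue
is the mesh's job anyway. The elastic refinement then runs dual-scale flow
(a large patch for accurate interior estimates plus a smaller patch whose
node hull reaches closer to the borders; small-patch constraints only fill
mesh nodes the large-patch hull misses) followed by two refinement passes
that re-measure residual flow on the rendered result and compose the
correction into the mesh — this cancels most of the patch-averaging
attenuation of a single pass. Sections marked as skip are warped with their
neighbor's transform but never serve as reference; missing sections become
black slices, and the search range grows by a factor \(1 + k/2\) when
bridging \(k\) missing sections.

**Cross-resolution registration.** Each synaptic-resolution slice is
downsampled to the cellular pitch, located in the nearest non-black
reference section (ties toward the lower index) by whole-template NCC, and
elastically refined at the reference scale. The mapping uses the
pixel-center convention: high-resolution pixel \(v\) sits at
\((v-0.5)/r + 0.5\) of its downsampled window. No intra-stack Z alignment
is performed — the reference stack already provides the frame.

**Resumability.** Every step appends status records to a JSON-lines
journal; re-runs skip units whose latest record is `done` and whose cached
outputs exist, and `journal_wipe()` invalidates arbitrary step/unit ranges.
Because every stage is deterministic, an interrupted-and-resumed run is
bit-identical to an uninterrupted one, and `rerender_stack()` reproduces
the aligned stack exactly from the saved affines and meshes.

## Segmentation graph

The watershed treats the affinity volume as an edge-weighted voxel graph.
Seeds are connected components over edges with affinity ≥
`frag_threshold_hi` (default 0.9); the flood processes edges in decreasing
affinity down to `frag_threshold_lo` (default 0.2), growing labels along
bottleneck-optimal paths, with ties broken by lexicographic (z, y, x)
order — the implementation is a sorted union-find, validated against a
literal repeated-scan flood in the tests.

Agglomeration merges clusters in order of decreasing linkage affinity
("mean" of boundary affinities by default, "max" available) and stamps
each contact edge with `1 − (linkage affinity when its endpoints first
share a cluster)` as its merge score. This linkage-time definition is a
choice: the merge score of a never-directly-merged edge is not otherwise
pinned down. Final segmentations keep edges with score ≤ t and relabel by
connected components (labels = minimum member id).

For proofreading export, supervoxels are split chunk-wise (default 64³),
per-chunk fragments get 64-bit ids packing layer (8 bits), x/y/z chunk
coordinates (10 bits each) and an in-chunk segment id (26 bits) — widths
are this package's defaults, as only the fields are standardized. R's
doubles cannot hold 64-bit integers exactly, so ids are decimal strings
computed with exact 16-bit-limb arithmetic. Edges are classified in-chunk /
between-chunk / cross-chunk; cross-chunk edges (rejoining fragments of one
supervoxel) carry fixed affinity 1 so split supervoxels always reconnect
when boundary splitting is off; `initial_agglomeration()` can discard both
between- and cross-chunk edges to fragment the initial proofreading state
at regular intervals, which trades merge work for protection against large
false-merge artifacts. Thresholding is on the merge-score scale (discard
score > t) throughout.

## Connectivity

Predicted pre/post voxel pairs are annotated with the label under each
side; rows touching background or out-of-bounds are dropped and counted.
Confidence filtering and autapse removal commute, so their order is
irrelevant; autapses are treated as prediction artifacts. The weak-edge
rule keeps connections with at least `min_synapses = 4` synapses, i.e.
discards three or fewer — the stricter of the two published phrasings of
this rule; the parameter is exposed for the other convention. The
confidence threshold has no canonical published value and defaults to 0.

## Acquisition estimator

For tile maps of \(g_x \times g_y\) tiles of \(n_x \times n_y\) px over
\(n_z\) sections at dwell time \(t\): \(N = g_x g_y n_z n_x n_y\) pixels
and \(t_{\text{total}} = \sum_i N_i t_i\). The tissue extent of a tile map
is \(x = p\,(g_x n_x - n_x o (g_x - 1))\) — the first tile contributes its
full width, each further tile a \((1-o)\) step — and the hypothetical
all-synaptic scenario images that footprint on every section:
\(N_{\text{highres}} = \sum_i n_{z,i} A_i / P_{\text{highres}}\). The
slice factor is required for dimensional consistency with the published
per-dataset totals; without it the hypothetical scenario costs less than a
single section. This count deliberately ignores overlap between the (more
numerous) hypothetical tiles and therefore underestimates the savings.
Sizes assume 1 byte per pixel and decimal terabytes. Displayed gain
factors round half away from zero to one decimal; full precision is
retained in the report object.

## The synthetic phantom: what it emulates, and what it does not

The generator is the package's definition of its study conditions:

* **Neurites** are tubes along z (disks of the configured radius per
  section) whose axes wiggle with a mean-reverting (AR(1), persistence
  0.8, step 0.4 px) lateral offset. Mean reversion matters: with a free
  random walk the tissue itself drifts, the sequential aligner faithfully
  follows it, and "recover the acquisition warp" stops being a
  well-defined target. Real central-complex fibers run roughly straight
  over one 50 nm section, so sub-pixel wiggle without net wander is the
  realistic regime. Default density (e.g. 40 tubes of radius 7 in a 160 px
  field) keeps several structures inside every matching patch.
* **Texture** has an organelle-scale component (8 px cells, persistence
  0.9 per section) and a vesicle-scale component (2 px cells, persistence
  0.5): large structures span many sections, fine texture decorrelates
  quickly. Membranes are drawn dark (grey 40) at every 6-connected label
  interface; interiors ~150, extracellular space ~200, ±25 texture, plus
  optional sensor noise.
* **The acquisition warp** composes a per-section rigid translation, a
  smooth elastic field (≤ 5 sinusoidal components whose joint wave-vector
  magnitude is bounded by 1/min(field size) — drawing the two axis
  frequencies independently can produce a combined wavelength shorter than
  a matching patch, which no patchwise flow can recover — with amplitudes
  drifting slowly along z), and an independent per-tile translation
  jitter. Acquired tiles sample the phantom through this backward map.
* **Affinities** are exactly 1 within a label and 0 across, with optional
  membrane "holes" (a boundary patch flipped to affinity 1 per touching
  pair, emulating burst membranes that cause false merges) and clipped
  additive noise. **Synapses** are voxel pairs inside labels with a
  configurable autapse rate and uniform confidence scores.

Not emulated: electron-optics physics, charging artifacts beyond a
brightness gradient option, real tissue texture statistics, section
thickness variation, or anisotropic point-spread. Passing the recovery
tests therefore demonstrates the geometry of the pipeline — stitching, the
transform chain, the bookkeeping — under EM-like contrast, not robustness
to every artifact of a real microscope.

## Numerical choices and degenerate inputs

* Coordinates are 1-based (R's convention) and voxel-centered; every
  transform is a backward map (output position → source position).
  Out-of-source samples are black (0).
* Relaxation stops when the largest node update falls below `tol`
  (10⁻³ px) or at `max_iters` (400).
* Tie-breaks are explicit everywhere: correlation-peak ties prefer the
  smallest displacement, then lexicographic order; watershed edge ties use
  the anchor voxel's (z, y, x) order; cluster-merge ties the smaller pair
  ids; reference-slice ties the lower index.
* Constant patches, textureless regions, unparseable filenames,
  inconsistent tile shapes, empty inventories, sub-minimum overlaps and
  bit-budget overflows all raise explicit errors or flagged-invalid
  results rather than propagating silently.
* Problem sizes in the tests and the acceptance script (20 × 160 × 160
  phantoms, ≤ 16³ segmentation toys, 100-case oracle sweeps) were chosen so
  the full suite exercises every stage end-to-end at interactive run
  times while keeping all tolerances at the values stated above.

## Known limitations

* Sequential neighbor alignment accumulates a slow random walk of
  content-driven matching noise along z; the recovery RMS grows roughly
  with the square root of the distance to the root slice. Global joint
  optimization over all sections would remove this but is out of scope.
* The stitcher models per-tile placement as translation + elastic
  residual; a grossly rotated tile would need the keypoint path.
* Fusion merges members pairwise into the first member's frame; very long
  fusion chains could accumulate resampling blur.
* The chunked-graph export emits a single layer of the id hierarchy; the
  multi-level octree of a hosting proofreading platform is out of scope.
* On-disk outputs use TIFF slices and JSON transform bundles rather than a
  chunk-parallel array store; the journal is a flat JSON-lines file.
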