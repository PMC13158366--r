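---
title: "Quantifying mitochondrial network morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The problem

Mitochondria continuously fragment (fission) and merge (fusion). In
fluorescence micrographs of a mitochondrial stain, the balance between
the two shows up as the mix of three morphological classes: *punctates*
(dots, the product of fragmentation), *rods* (unbranched tubules) and
*networks* (branched structures whose skeleton contains at least one
junction). Shifts toward punctates indicate fission and cellular stress;
longer, more branched networks indicate fusion. `mitomorph` turns a raw
single-channel micrograph into a per-cell or per-field table of 18
morphology parameters built on these classes, plus group-comparison
statistics, so that such shifts can be quantified rather than eyeballed.

## The pipeline

1. **CLAHE illumination correction** (`claheCorrect`). Stained images
   carry strong local brightness variation; contrast-limited adaptive
   histogram equalization evens it out. Defaults: 10 x 10 px contextual
   regions, clip limit 0.02, 256 bins. A small kernel equalizes the
   brightness of individual mitochondria. Two details matter and are
   worth stating precisely:
   - *Tile semantics.* "Kernel 10 x 10" is read as a 10 x 10-**pixel**
     contextual region (tiles of that size, histograms computed on
     mirrored padding, per-tile mappings bilinearly interpolated between
     tile centers). CLAHE implementations disagree on whether the kernel
     counts pixels or tiles, so `tileGrid = TRUE` switches to the
     tile-grid reading.
   - *Clip normalization.* The per-bin ceiling is
     `max(1, clip * tilePixels / nBins)`, the normalization of
     Zuiderveld's original routine (and OpenCV's). The alternative
     convention `clip * tilePixels` (scikit-image's) is available as
     `clipMode = "tileFraction"`, but it allows a local contrast slope of
     `clip * nBins` (5.1x at the defaults), which stretches background-only
     tiles across the whole intensity range; a global threshold then
     splits the background on any sparsely stained field. The reference
     normalization caps the slope near 2.6x and keeps background and
     signal separable. This choice is the single most consequential
     numerical decision in the package.
2. **Otsu thresholding** (`otsuThreshold`). A 2-class threshold
   maximizing between-class variance over the full-resolution histogram;
   foreground is strictly above the threshold, ties break toward the
   smaller threshold. After CLAHE a single global threshold is well
   posed and is the default; a per-window adaptive variant (thresholds
   interpolated between window centers) is available via
   `mode = "adaptive"`. Because the Otsu objective ignores a very light
   foreground class, the pipeline re-estimates the threshold recursively
   on the upper class while the foreground fraction exceeds
   `threshold.max_foreground` (default 0.15 — mitochondrial strokes never
   cover that share of a field, while out-of-focus cell bodies can; the
   recursion then climbs past them). Two mask cleanups follow: a radius-1 binary
   closing (heals 1-2 px shot-noise cuts in thin tubules; it cannot
   merge objects more than 2 px apart) and removal of components below
   `threshold.min_object` = 5 px (shot-noise specks; the smallest real
   object, a diffraction-limited punctate, thresholds to a footprint an
   order of magnitude larger).
3. **Zhang-Suen thinning** (`zhangSuenThin`). The classic
   two-subiteration boundary-peeling scheme, with deletions applied
   simultaneously within a subpass, iterated to a fixpoint. Three
   documented pathologies of the verbatim rules are corrected
   afterwards, each preserving topology:
   - staggered 2-px-wide diagonal staircases are reduced by one north
     and one south pass of the standard staircase-removal templates;
   - the rare fully set 2 x 2 block left where branches cross is
     resolved by deleting 8-simple pixels (or, for crossings where no
     corner is simple, deleting one corner and re-attaching the severed
     arm through a shared 4-neighbor);
   - an input component the rules erase completely (they delete an
     isolated 2 x 2 square outright) is restored as its medoid pixel, so
     the 8-connected component count of the mask is always preserved.
4. **Skeleton graph** (`buildGraph`). 8-connected components; per-pixel
   degree; mutually adjacent degree->=3 pixels merged into junction
   clusters; branches traced between nodes (endpoints and clusters) with
   geodesic lengths (1 per axial step, sqrt(2) per diagonal step).
   Two graph-level cleanups precede classification: terminal branches of
   at most `spurLength` = 3 px at clusters with three or more incident
   ends are dropped (thinning spurs of the thick stroke boundary), and
   clusters left with fewer than three incident branch ends are
   dissolved, merging their branches with the intra-cluster geodesic
   added — a digitized straight line crosses pixel rows in short
   degree-3 "corners" that are not junctions in any topological sense.
   Classification: `network` if a junction cluster survives (node-free
   closed loops also count as networks, with the cycle as their single
   branch — a recorded convention); otherwise `rod` when larger than
   `punctateMax` skeleton pixels and `punctate` when not. The default
   boundary is 5 px: with a PSF sigma of ~1.5 px, the smallest
   resolvable dot thresholds to a blob whose skeleton can reach 5 px, so
   a smaller boundary would split physically identical dots between the
   two classes by digitization luck. The boundary is a convention, not a
   measurement, and is exposed as `graph.punctate_max`.
5. **Metrics** (`computeMetrics`). The 18 parameters (skeleton area,
   class counts, class percentages, class length totals, mean rod
   length, network branch counts and lengths, all-branch statistics,
   combined network-and-rod mean length) follow the definitional
   formulas listed on the help page. Percentages are count-based shares
   by default (a length-weighted variant via
   `metrics.percent_basis = "length"`); any mean with an empty
   denominator is `NA`, never 0, and is written as an empty CSV cell.
6. **Normalization** (`normalizeMetrics`). Extensive parameters (area,
   counts, length totals) divide by cell surface area (segmented
   fibroblast-like cells, area in px^2 or um^2 when the pixel size is
   known) or by the nucleus count of the analyzed area (clustered
   stem-cell colonies, where single cells cannot be outlined);
   percentages and means are intensive and unchanged.
7. **Statistics** (`compareGroups`). Per-group mean and SD (n-1
   denominator); two groups get an unpaired two-sided t-test (pooled
   variance by default — classic ANOVA plus Tukey assumes
   homoscedasticity, and the two are used side by side; Welch via
   `welch = TRUE`); three or more get one-way ANOVA with Tukey HSD
   adjusted p-values from the studentized-range distribution.
   Significance is the strict inequality p < alpha (default 0.05). No
   multiple-testing control is applied across the 18 parameters; each
   comparison is reported on its own.

## Segmentation

Spatially separated ("differentiated") cells are outlined from the
stain channel alone: grayscale opening (suppressing features smaller
than the disk) and Gaussian smoothing, a global Otsu threshold, hole
filling, and a distance-transform watershed to declump touching cells;
objects outside the equivalent-diameter window (default 40–400 px,
suited to spread cells at 40x — a configuration choice, not a
measurement) are discarded. A minimum object-to-surround contrast of 8
intensity units guards against "finding" cells in a blank noisy field.
The field skeleton is computed once and split by the cell labels;
skeleton pixels on background attach to the nearest cell within
`segment.max_gap` = 5 px, else they are dropped (the straddle rule; the
per-cell pixel counts plus drops always equal the field skeleton
exactly). Nuclei in the optional Hoechst channel are counted by
smoothing, Otsu, hole filling, watershed splitting of touching nuclei
and a minimum-area filter.

## The synthetic-image generator

No real micrographs ship with the package, so verification rests on
`generateScene`: seeded fields with exact ground truth. Punctates are
compact 3 x 3 blobs; rods are gently curved 2-px-wide strokes (quadratic
Bezier, bend up to 8% of length); networks are star trees with 3–5
straight branches around a junction. Strokes are blurred with a Gaussian
PSF (sigma 1.5 px, within the diffraction-limited regime of a 40x/0.65
objective), peak-normalized per object class so dots and tubules carry
the same dye brightness, modulated by a planar illumination field
`1 + 0.5g` (which gives CLAHE something real to correct), offset by a
camera background of 20 counts, Poisson shot noise, and 8-bit
quantization — a peak signal-to-noise ratio around 12. Objects place by
rejection sampling honoring a boundary-to-boundary separation of 15 px
(at least 6 PSF sigmas, so objects stay distinct after blur); in crowded
fields the separation relaxes gradually but never below that floor. The
default field is 288 x 288 px, the size at which the densest supported
inventories (20 punctates + 20 rods up to 60 px + 5 networks) still
place reliably.

`generateMulticellField` lays cell disks of elevated background on a
jittered grid with a guaranteed boundary gap and fills each with its own
objects, optionally rendering one blurred nuclear disk per cell.

`fccpTransform` models the uncoupler (FCCP) stress response — rapid
fragmentation of the network — as a derived scene: a chosen fraction of
rods splits into punctate pairs (triples from 30 px) pinned along the
former tubule, and each network sheds the matching fraction of its
branches (always keeping three, so it remains a network), the detached
branches reappearing as free rods of identical length. Branch
detachment conserves drawn length exactly; rod-to-punctate splitting
discards the tubule length by construction, since a punctate is a dot —
fragmentation genuinely destroys resolvable length, and no rendering of
"2–3 dots" can carry 40 px of tubule. Only the *direction* of the
response (more punctates, shorter mean branch length) is asserted
anywhere; no magnitude claim is made.

What the generator does *not* emulate: out-of-focus light and 3-D
structure projected into the focal plane, vesicular autofluorescence,
photobleaching within an acquisition, true tubule curvature
distributions, and the dense perinuclear mitochondrial mats of real
fibroblasts where even a human cannot separate objects. Passing the
recovery suite therefore shows the measurement chain is faithful on
resolvable, separated structures — not that real micrographs yield
error-free censuses.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: Otsu
against a per-threshold brute-force scan (1,000 random bimodal
histograms, exact agreement required); thinning against its four
contracts (subset, 1-px width, component-count preservation,
idempotence) on 200 random blob masks; the full pipeline against
generator ground truth (100 seeded scenes of 5–20 punctates, 5–20 rods,
1–5 networks; at least 95 exact class censuses; the seed-averaged
mean-rod-length error within 15% of geometric truth with at least 95
of 100 scenes individually inside the band — the measured mean error
is 4–5%, and the rare excursions to ~18% come from two objects merging
end to end); segmented-vs-aggregate conservation on
multi-cell fields (straddle drops at most 1% of skeleton pixels); the
fragmentation direction on 100 scene pairs (at least 99 must shift both
ways, and 12-field arms must test significant at alpha 0.05); and the
group statistics against closed-form F, t and studentized-range
computations (1e-8). These sizes keep the whole suite within a few
minutes on one core while leaving the acceptance margins wide;
`scripts/acceptance.R` re-runs the same checks from scratch at the same
sizes under a caller-chosen seed.

## Numerical and degenerate-input decisions

- Coordinates are `(row, col)`, 0-based in the documentation, with pixel
  centers on integer coordinates; all modules share the convention.
- Intensities are never rescaled at read time; 8- and 16-bit TIFF and
  PNG round-trip bit-exactly. Multi-channel exports resolve to the
  brightest plane by default (the stain channel in red-stain RGB
  exports), or to an explicit plane index.
- A constant image has no 2-class split: `otsuThreshold` raises a
  degenerate-input error; the segmentation and nucleus counters treat
  blank fields as "no objects" (K = 0, count 0) with a warning rather
  than an error.
- Ties in the Otsu objective break toward the smallest threshold;
  component and branch enumeration follows row-major scan order, so
  every result is deterministic. Spur removal resolves ambiguous
  configurations in scan order too, which is why exact
  90-degree-rotation invariance is only guaranteed for the pure graph
  (`spurLength = 0`).
- `buildGraph` refuses skeletons containing a fully set 2 x 2 block
  (integrity error naming the offending pixel) rather than silently
  measuring a malformed input.
- Zero-denominator means are `NA` end to end: in the S4 object, in the
  CSV (empty cell), and dropped per group by `compareGroups`.
- All-zero-variance groups with unequal means are reported as p = 0
  with a `degenerate` flag rather than NaN.

## Known limitations

- Classification is per 2-D component: overlapping structures merge
  into one object, as in any single-plane analysis.
- The punctate/rod boundary and the spur length are conventions tied to
  the imaging scale; at a different magnification both should be revised
  together with the PSF width.
- Tukey HSD assumes homoscedastic groups; the Welch option covers the
  two-group case only.
- The CellProfiler-style cell detector is a minimal, documented
  equivalent (threshold + distance-transform watershed); it does not
  reproduce that module's full option surface.
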