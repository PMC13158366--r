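# mitomorph

Quantification of mitochondrial network morphology from single-channel
fluorescence micrographs.

Mitochondria shift continuously between fragmented and fused states, and
the balance is a sensitive readout of cellular health: fission produces
*punctates* (dots) and short *rods*, fusion builds branched *networks*.
`mitomorph` turns a raw micrograph of a mitochondrial stain (e.g.
Mitotracker Red, TIFF or PNG, 8- or 16-bit) into an 18-parameter
morphology table per cell or per field, and compares parameter tables
across experimental groups. It is aimed at labs that want a scriptable,
fully documented alternative to interactive image-analysis toolchains
for mitochondrial phenotyping — for example when comparing patient-derived
versus control cell lines, or untreated versus uncoupler-stressed cells.

## Method

The measurement chain is:

1. **CLAHE** illumination correction (10×10 px contextual regions, clip
   limit 0.02, 256 bins) to even out staining brightness;
2. **Otsu thresholding** (global 2-class threshold maximizing
   between-class variance; adaptive windowed variant available) to a
   binary mask, followed by a 1-px closing and speck removal;
3. **Zhang–Suen thinning** to a one-pixel-wide skeleton, with
   topology-preserving cleanup of the scheme's documented artifacts;
4. a **skeleton graph**: endpoints, junction clusters, and branches
   with geodesic lengths (1 per axial step, √2 per diagonal step); each
   8-connected component is classified as punctate (no junction, ≤ 5
   px), rod (no junction, larger) or network (≥ 1 junction);
5. the **18 morphology parameters** (skeleton area; punctate/rod/network
   counts, percentages and length totals; mean rod length; network
   branch counts and mean lengths; all-branch statistics), normalized by
   cell surface area (segmented mode) or nucleus count (aggregate
   colony mode);
6. **group statistics**: mean ± SD, unpaired t-test (two groups) or
   one-way ANOVA with Tukey HSD (three or more), significant at
   p < 0.05.

Spatially separated cells are segmented from the stain channel alone
(smoothing, Otsu, distance-transform watershed declumping); clustered
colonies are analyzed as whole fields. A seeded synthetic-micrograph
generator with exact ground truth (`generateScene`,
`generateMulticellField`, `fccpTransform`) makes every stage verifiable
without any external data; the methods vignette
(`vignettes/mitomorph-methods.Rmd`) documents the model, the defaults
and the design decisions.

## Worked example

Generate a synthetic field with a known object inventory, run the full
pipeline, and compare the result with the ground truth:

```r
library(mitomorph)

gen <- generateScene(sceneSpec(nPunctates = 8, nRods = 10,
                               nNetworks = 2, rngSeed = 42))
res <- analyzeImage(gen$image)
res$graph
#> SkeletonGraph: 20 components (8 punctate, 10 rod, 2 network), 511 px
truthCounts(gen$truth)
#> punctate      rod  network
#>        8       10        2
metricValues(res$metrics)[c("mean_rod_length", "network_pct",
                            "mean_length_all_branches")]
#>          mean_rod_length              network_pct mean_length_all_branches
#>                 38.26518                 10.00000                 22.80546
```

The pipeline recovered the exact class census (8 punctates, 10 rods, 2
networks). `mean_rod_length` (38.3 px) is the average geodesic skeleton
length of the ten unbranched tubules; `network_pct` says networks make
up 10% of the 20 objects; `mean_length_all_branches` averages length
over every branch-like unit (punctates, rods, and individual network
branches). Writing a batch of such records with `writeMetricsTable()`
produces one CSV row per analysis unit, with undefined means (e.g. mean
network length in a field without networks) as empty cells, never 0.

On real data the entry points are `readRawImage()` +
`analyzeImage()`/`analyzeImageSegmented()` for single fields, and
`analyzeBatch(dir, mode = "aggregate" | "segmented")` for directories
(a `*_nuclei.tif` companion image triggers nucleus-count
normalization). A thin command-line wrapper with `skeletonize`,
`analyze`, `synth` and `compare` subcommands is installed under
`inst/scripts/mitomorph`.

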