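---
title: "Quantifying 3D smFISH transcript colocalization: methods and design"
author: "smFISHcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D smFISH transcript colocalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smFISHcoloc)
library(SummarizedExperiment)
```

# The measurement problem

Single-molecule fluorescence in situ hybridization (smFISH, e.g. the
RNAscope assay) labels individual mRNA molecules as diffraction-limited
puncta. In tissue sections imaged as confocal z-series, the question this
package answers is *per-cell*: how many transcripts of each probed gene
sit inside each nucleus, which cells are positive for a gene, and do two
genotype groups differ in per-cell transcript load? A typical use is
counting a target transcript (say *Wt1*) specifically within the cell
population marked by a reporter transcript (*Cre*).

The pipeline has five stages, each a separate, testable function:

1. **Nucleus segmentation** (`segmentNuclei`): Gaussian smoothing of the
   DAPI channel, adaptive (local-mean) thresholding, 26-connected
   labelling with a minimum-volume filter, and watershed splitting of
   oversized objects on the negated distance transform.
2. **Spot detection** (`detectSpots`): an intensity threshold per probe
   channel, 26-connected clustering of supra-threshold voxels, watershed
   splitting of merged clusters on the negated intensity, and a minimum
   fragment size.
3. **3D assignment** (`assignSpots`): each punctum is assigned to the
   nucleus whose label covers the voxel containing the punctum's
   intensity-weighted centroid; puncta whose centres fall outside every
   nucleus are excluded from further analysis.
4. **Positivity calling** (`callPositive`): a cell is positive for a gene
   iff more than `k` transcripts are assigned to its nucleus, with
   `k = 2` by default -- counts 0-2 are negative, 3 and above positive.
5. **Group comparison** (`compareGroups`): unpaired pooled-variance
   (Student) two-sample t test on per-cell counts (and on per-stack mean
   counts), two-sided, significance at p < 0.05. Welch's form is
   available behind `varEqual = FALSE`, but the pooled test is the
   default and is what `runPipeline` reports.

All geometry is computed in physical micrometres, never in raw voxel
indices: confocal stacks are anisotropic (the z step is several times the
xy pixel size), and a centroid or distance computed in voxel units would
be systematically wrong along z. The single coordinate convention used
everywhere is that voxel index $i$ (0-based) along an axis with voxel
size $v$ has its centre at $(i + 0.5)\,v$.

Blinding is part of the design: `runPipeline` maps image identities to
opaque codes (`blindImages`) before any quantification, processes images
in code order, and only joins group labels back after per-cell profiles
are complete. The inverse map is written to a separate key file that the
analysis itself never reads.

# The synthetic-data generator

No imaging raw data accompanies the assay this pipeline models, so the
package ships a generator (`synthParams`, `simulateStack`,
`simulateExperiment`) that produces 3D multi-channel stacks with
exhaustive ground truth: every nucleus ellipsoid, every true spot centre,
every intended per-cell count. Every downstream stage is validated
against that truth.

What it emulates, and the defaults (all overridable):

* **Field geometry.** 32 z-planes of 0.5 um through a 16 um section
  (the physical section thickness fixes the z extent), 320 x 320 xy
  pixels of 0.1 um -- a 63x-confocal-like 16 x 32 x 32 um field. The
  acquisition this mimics does not publish pixel sizes; these are
  declared, typical values, not inferred ones.
* **Nuclei.** 50 axis-aligned ellipsoids with semi-axes drawn uniformly
  from 2.2-2.5 um (5 um-scale near-spherical nuclei, volumes 45-65
  um^3), placed by rejection sampling fully inside the grid. A
  `touchingFraction` (default 20%) is placed with surface-to-surface gaps
  of 0.02-0.25 um to force merged objects that only the splitting stage
  can separate; all other pairs keep at least 1 um of clearance.
* **Transcripts.** Per nucleus and channel, a count drawn uniformly from
  `spotsPerCell` (default 3-8) is placed uniformly inside the ellipsoid;
  free (extranuclear) transcripts arrive as a Poisson field (5 per 1000
  um^3 per channel). Two margins keep the ground truth unambiguous under
  voxelised segmentation: owned spots sit at least 0.4 um inside their
  nucleus surface, free spots at least 1.5 um outside every nucleus. A
  transcript centred on the nuclear boundary is genuinely ambiguous at
  0.1-0.5 um voxel resolution, and an evaluation against truth should
  not hinge on coin flips at the surface. Spots of one channel keep at
  least 1.25 um mutual distance (>= 3 PSF sigma on every axis), the
  optically-resolvable regime.
* **Optics and camera.** Nuclei render as binary masks blurred by an
  anisotropic Gaussian PSF (sigma 0.4/0.15/0.15 um in z/y/x); puncta as
  Gaussian blobs of the same PSF with peak amplitude 3000 over a
  constant background of 500; additive Gaussian read noise with sd 100
  (peak-SNR 30 -- branched-DNA-amplified RNAscope puncta are bright, and
  the detector tests separately cover the >= 5 SNR floor); intensities
  clipped to the unsigned 16-bit range and rounded. Poisson shot noise
  is available behind `shotNoise = TRUE` but off by default: additive
  noise is sufficient to exercise thresholding, which is what the noise
  is for.
* **Reproducibility.** One root seed per stack; each stage (placement,
  spots, rendering, per-channel noise) draws its own child seed derived
  deterministically from it, so a stage can be regenerated independently
  and identical parameters always produce bit-identical stacks.

What it deliberately does **not** emulate: PSF aberrations and depth
dependence, channel bleed-through, photobleaching, tissue
autofluorescence, intensity variation between puncta, or segmentation-
hostile nuclear shapes. Passing the recovery tests therefore shows the
algorithms are *correct implementations* that work under realistic
geometry, density and noise; it does not certify performance on real
tissue, where threshold and volume parameters will need tuning per
dataset -- which is why every parameter is exposed in configuration and
serialised to the run log.

# Parameters that matter, with units and defaults

## Segmentation (`segmentationConfig`)

* `smoothSigma` (um, default 0.5 isotropic): pre-threshold Gaussian
  blur. At sd-100 read noise this suppresses the noise on the smoothed
  DAPI field to ~3 intensity units, so the threshold margin below
  operates on an essentially noise-free field.
* `adaptWindow` (um, default 6): side of the cubic local-mean window.
  Chosen at roughly 1-2 nucleus diameters: much larger windows average
  over many cells and background, which flattens the local mean towards
  the global background and dilates (and merges) segmented nuclei in
  sparse regions; a window near the object scale tracks local context.
* `adaptOffset` (default 0.15 of the dynamic range): the strictness
  margin. A voxel is foreground iff its smoothed intensity exceeds the
  local mean **plus** this offset. The offset is the knob with the
  monotone guarantee (raising it never grows the foreground), and it
  must clear two hurdles: the residual noise on the smoothed field
  (trivially, at 3 units) and the blurred skirt of bright objects
  (substantively). At 15% of range the threshold crosses a blurred
  nucleus edge about 1 sigma of total blur outside the true surface, a
  dilation the volume gate below is sized to absorb.
* `minVolume` / `maxVolume` (um^3, defaults 15 / 75): the volume gate.
  `minVolume` discards debris; it sits well below the smallest expected
  nucleus (45 um^3 before erosion). `maxVolume` flags split candidates
  and must sit *between* the largest single-nucleus volume (65 um^3
  plus threshold dilation) and the smallest fused doublet (~2 x 45).
  Oversized-but-compact objects are safe: a single qualifying distance
  maximum means watershed returns them intact, so a slightly low
  `maxVolume` costs only compute, while a high one silently leaves
  doublets merged.
* `seedMinSep` (um, default 3.5) and `seedMinHeight` (um, default 1.5):
  watershed seed control for splitting. Candidate seeds are local maxima
  of the anisotropy-corrected Euclidean distance transform. Seeds closer
  together than `seedMinSep` -- about 0.8x the minimum centre-to-centre
  distance of touching nuclei (two minimal radii) -- are merged, keeping
  the strongest; seeds with distance value below `seedMinHeight` are
  surface bumps, not nucleus centres, and are dropped. Both filters
  exist because adaptive thresholding of blurred boundaries produces
  lumpy object surfaces whose spurious distance maxima would otherwise
  oversplit: a seed separation equal to just one nucleus radius
  demonstrably fragments merged clusters of the default geometry.

## Spot detection (`spotConfig`)

* `threshold` (default: 0.995 quantile of the channel): the detection
  cutoff. The quantile default is a reproducible stand-in for the
  manual, per-experiment intensity cutoff a microscopist would set; an
  absolute per-channel value can (and for calibrated data should) be
  supplied instead, and the resolved absolute value is recorded in the
  spot table metadata and run log. Both per-image (the default) and
  global-across-experiment thresholds are legitimate; the package
  computes per-image and leaves global calibration to the caller.
* `minSpotVoxels` (default 2): rejects single-voxel fragments, the
  weakest defensible size filter; the size of each accepted spot is
  measured and reported rather than filtered further.
* `watershedMinDepth` (intensity units, default 400): two intensity
  maxima within one supra-threshold cluster remain separate spots only
  if the saddle between them dips at least this far below the lower
  peak. At 4x the default read-noise sd, noise ripples on a single
  punctum cannot split it, while two genuinely separate puncta at the
  minimum generator spacing produce saddles several times deeper.

## Quantification

* `k` (default 2): the positivity threshold -- positive means *more
  than* k transcripts. Monotone in the count and antitone in k.
* The group test is the pooled-variance Student t (`var.equal = TRUE`),
  reported with t, df, two-sided p and the mean difference; per-cell
  and per-stack-mean summaries are both emitted (and, when a
  reporter/target pair is configured, target counts within
  reporter-positive cells), since pooling cells across images and
  averaging per image answer slightly different questions and the
  original analysis level is not recoverable.

## Enrichment statistics

The over-representation module is formula-level and database-free: gene
sets arrive as plain symbol vectors, and any homolog mapping is the
caller's two-column table.

* `hypergeomUpper(a, a+c, a+b, N)` computes the upper tail
  $P(X \ge a)$ by summing hypergeometric point probabilities in log
  space (log-gamma binomials + log-sum-exp), stable for backgrounds of
  tens of thousands of genes.
* `fisherExact2x2` reports the same upper tail as its one-sided p -- on
  a 2x2 table the Fisher test *is* the hypergeometric test, an identity
  the test suite verifies exhaustively for all tables with N <= 12 --
  plus the standard two-sided p (sum of all same-margin tables whose
  point probability does not exceed the observed one, with a 1e-7
  relative tolerance for floating-point ties, matching the reference
  implementation) and the sample (cross-product) odds ratio
  $ad/bc$. The conditional-MLE odds ratio would also be defensible; the
  cross-product form is what plain "OR" reporting usually means, and
  the choice is documented here and in the output.
* `bhAdjust` is the Benjamini-Hochberg step-up rule,
  $\mathrm{adj}_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$ capped at 1,
  returned in input order. One property worth stating because it is
  often assumed: the step-up map is *not* idempotent. Re-adjusting
  already-adjusted values can move them further up (e.g.
  (0.4, 0.9) -> (0.8, 0.9) -> (0.9, 0.9)), because the adjusted vector
  is more compressed than the original; re-adjustment is monotone
  upward and capped at 1, and that is the property the tests assert.
* `enrichGeneLists` intersects the gene set with the expressed
  background before building the table, so genes never tested for
  expression cannot inflate an enrichment, and refuses DE lists that
  are not subsets of the background.

# Numerical and degenerate-case decisions

* **Filtering.** Gaussian kernels are truncated at 3 sigma and
  renormalised; boundaries are mirror-reflected, which preserves the
  mean. Smoothing is separable with per-axis sigma in voxel units
  (sigma_um / voxel_um), so physical isotropy holds on anisotropic
  grids. The local mean uses an integral image with the window clipped
  at the volume boundary (the mean is over the in-bounds part). A
  perfectly constant volume returns an all-background mask directly:
  at zero dynamic range the comparison against the local mean would be
  decided by accumulated floating-point rounding, i.e. by noise of the
  arithmetic rather than of the data.
* **Connectivity and determinism.** 26-connectivity everywhere in 3D
  (standard for blob-like objects). Component labels are assigned in
  raster-scan order of each component's first voxel; watershed floods
  ascending with FIFO tie-breaking on equal heights; plateau maxima are
  collapsed to their first voxel in scan order; equal-value seed
  candidates are ordered by scan position. Every tie in the pipeline is
  broken by a fixed rule, so identical inputs give identical outputs.
* **Distance transform.** Exact squared Euclidean distance by the
  per-axis lower-envelope algorithm, with physical (anisotropic) axis
  weights; distances are to the nearest background voxel within the
  grid.
* **Spot properties.** Centroids are intensity-weighted (sub-voxel
  accuracy matters for 3D assignment); size is the voxel count of the
  watershed fragment; peak is its maximum intensity.
* **Assignment.** Containment is decided by the label of the centroid's
  voxel. Labels are disjoint by construction, so no tie-breaking is
  needed, and "centre outside every nucleus" maps exactly to label 0.
* **Statistics.** The t test delegates to the standard implementation
  (pooled variance), with explicit errors for groups smaller than two
  or zero pooled variance; the hypergeometric/Fisher/BH statistics are
  computed from their formulas as described above, with the standard
  library implementations serving as independent cross-checks in the
  test suite only.

# Validation fixtures and what they show

The test suite validates every stage against independent brute-force
oracles (direct convolution, sliding-window means, flood fill,
exhaustive hypergeometric enumeration, the hand-written pooled-t
formula), and the pipeline end-to-end against generator ground truth:

* **Recovery fixture** (the default study geometry): two genotypes x 5
  stacks x 50 nuclei, two probe channels, with a planted difference of
  3 Wt1 transcripts per cell (control 2-7, perturbed 5-10). Across this
  fixture the pipeline recovers the nucleus count within 2%, median
  centroid error well under 1 um, per-cell counts exactly for isolated
  nuclei, and positivity calls above 95% concordance.
* **Power/type-I fixture**: the same two-genotype design scaled to 10
  nuclei per stack in a 16 x 16 x 16 um field with the Wt1 channel
  only, 50 seeded replicates of the full pipeline under the
  alternative and 50 under the null. These sizes are the package's
  validation choice: 50 cells per group give the planted 3-transcript
  shift an effect size around d = 1.7, so the power requirement is
  comfortably testable, while a hundred full-resolution replicates of
  the complete render-segment-detect-assign-test pipeline stay cheap
  enough to run routinely on one CPU. The t test rejects in >= 90% of
  alternative replicates and in <= 10% of null replicates (binomial
  slack at 50 replicates around the nominal 5%).

`scripts/acceptance.R` recomputes all of these quantities from scratch
at a caller-supplied seed and writes them as JSON.

# Known limitations

* Ellipsoidal, non-overlapping nuclei and isotropic Gaussian PSFs are
  idealisations; the segmentation defaults encode the generator's
  nucleus-size prior and must be re-derived (volume gate, seed
  separation) for tissues with different nuclear sizes.
* The intensity threshold default (0.995 quantile) assumes spots occupy
  well under 0.5% of the channel volume; extremely dense expression
  violates this and needs an absolute threshold.
* Spot counts are punctum counts: no calibration from integrated
  intensity to molecule numbers inside merged clusters is attempted
  beyond watershed splitting.
* Per-animal nesting (cells within stacks within animals) is not
  modelled; the package reports both per-cell and per-stack summaries
  and leaves mixed-effects modelling to the caller.

# A worked end-to-end example

```{r example, eval = FALSE}
library(smFISHcoloc)

p <- synthParams(nNuclei = 10L, gridShape = c(32L, 160L, 160L), seed = 42L)
sim <- simulateStack(p)

ns <- segmentNuclei(sim$stack)
spots <- rbind(assignSpots(detectSpots(sim$stack, "Cre"), ns),
               assignSpots(detectSpots(sim$stack, "Wt1"), ns))
profiles <- callPositive(cellCounts(spots, ns, c("Cre", "Wt1")), k = 2)

evaluateRecovery(sim$truth, ns, profiles)
```
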