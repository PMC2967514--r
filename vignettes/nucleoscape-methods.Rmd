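---
title: "Methods: 3D nuclear architecture quantification and permutation gene-set statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D nuclear architecture quantification and permutation gene-set statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nucleoscape` implements, as a tested pipeline, the two computational arms
of a cell-scattering study on hepatic progenitor cells: (i) quantification
of nuclear architecture from confocal z-stacks — chromocenter and
heterochromatin-focus counts, volumes and intensities per nucleus, and 3D
radial positioning of gene loci — and (ii) gene-set regulation statistics
on a 3-condition expression matrix. Because the original raw image stacks
are not available, both arms ship with synthetic-data generators whose
outputs carry exact ground truth; every statistical claim made by the
package is validated against that truth in the test suite.

# The imaging model

## Geometry

Nuclei are axis-aligned ellipsoids. Adherent cultured cells have flattened
nuclei, so the default semiaxes are (5, 5, 2.387) μm, giving a nuclear
volume of ~250 μm³ — the mean reported for this cell system. Per-nucleus
volumes vary by a coefficient of variation of 0.10 (isotropic rescaling of
the semiaxes), a typical cell-to-cell spread.

Chromocenters are solid spheres with lognormal volumes (right-skewed and
positive, matching the strong skew of measured chromocenter volumes); the
default mean is 8 μm³ with sd = 30% of the mean, and condition set points
of 8 / 6 / 4 μm³ reproduce the untreated / receptor-blocked /
growth-factor-stimulated conditions. FISH locus spots are small spheres
(radius 0.4 μm, the apparent size of a hybridized BAC probe signal) whose
centers follow a configurable *radial law*: the spot's distance from the
nuclear center divided by the center-to-boundary distance along the same
ray is drawn from the law, and the direction uniformly from the sphere.
This construction makes the true radial fraction known exactly for every
spot and invariant under isotropic rescaling of the nucleus, which the
tests exploit.

Object placement is sequential rejection sampling, largest object first,
requiring a surface-to-surface gap of at least 0.6 μm (wide enough that
the default PSF cannot bridge two neighbours above threshold). When no
admissible position is found within `max_attempts`, the best-separated
candidate seen is used and the object is flagged `overlapping` in the
ground-truth table — overlap is permitted but always reported, because
merged objects are a real failure mode the quantifier must face, and the
count laws must stay exact.

The default chromocenter count is Poisson with mean 3 per nucleus. This is
deliberately below the 10–20 chromocenters of a typical mouse nucleus: at
a mean volume of 8 μm³, ten chromocenters would occupy a third of the
nuclear volume and necessarily merge, and neither this pipeline nor the
commercial object counters it replaces split merged aggregates. Keeping
the density low makes per-object volume recovery identifiable; the cost is
that the generator does not emulate the clustered, crowded arrangement of
real chromocenters (see *Limitations*).

## Acquisition

Voxels default to 0.2 × 0.2 × 0.25 μm (the 250 nm axial separation of the
emulated acquisitions; the lateral pixel size of the original microscope is
not documented, so 200 nm is a typical confocal choice, not a claim).
Channels are rendered as background + amplitude × indicator, convolved
with a separable Gaussian PSF (σ = 0.15 μm lateral, 0.3 μm axial — typical
confocal scale), and degraded with Poisson shot noise. The defaults
(background 5, amplitude 100 expected photons) give an object SNR of ~9.5.
A configuration whose expected object diameter falls below 2 voxels on any
axis is refused with a resolution error rather than rendered.

Stacks are written one 16-bit multi-page TIFF per nucleus per channel with
a JSON voxel-size sidecar, plus `truth.json` and the full configuration as
`dataset.yaml`; a fixed seed reproduces a dataset bit for bit.

# Quantification

Nuclear segmentation is global Otsu thresholding of the DAPI channel,
3D hole filling, and 26-connected component labeling (26-connectivity
merges diagonal touches, as blob-oriented 3D object pickers do);
components below 30 μm³ are discarded. Object detection runs per nucleus,
inside the nucleus mask, and objects are clipped to the mask. Volumes are
voxel count × voxel volume; centers of mass are intensity-weighted means
of voxel centers (voxel *(i, j, k)* has its center at
*((i−0.5)dx, (j−0.5)dy, (k−0.5)dz)*).

## Thresholding: a calibrated choice

Four threshold methods are available, because no single automatic
threshold serves all channels:

* **`otsu`** (the `detect_objects()` default): per-nucleus Otsu on the
  within-mask intensities. On PSF-blurred spheres Otsu lands below the
  half-amplitude level (the blurred edge voxels pull the foreground class
  mean down), which dilates volumes by ~8–10% at these object sizes.
* **`amplitude`** (the `quantify_dataset()` default for dense object
  channels): an Otsu prepass locates the foreground; the plateau amplitude
  is estimated as the upper-half median of foreground voxels; the final
  threshold is background + 0.45 × (plateau − background). The fraction
  0.45 was calibrated on noiseless rendered spheres at the default PSF by
  computing the bias-versus-threshold curve against ground truth: 0.5
  (the FWHM convention) erodes volumes of σ-sized spheres by ~5%, Otsu's
  effective ~0.37 dilates them, and 0.45 is volume-unbiased across the
  4–8 μm³ range (recovery within ~1% at the three condition set points).
* **`halfmax`** (default for the `locus` channel): background median +
  half of the background-to-peak range. FISH spots occupy well under 0.1%
  of the nuclear volume, far too little foreground for Otsu's bimodality
  assumption — Otsu then splits the background noise and returns one
  nucleus-sized "object". `halfmax` only assumes a bright, sparse signal.
* **`fixed`**: a user-supplied value, for reproducibility experiments.

Automatic methods additionally apply a detection limit (Rose criterion,
default 5): if the mean foreground–background separation is below 5
background standard deviations, the channel is declared object-free. This
is what keeps a nucleus with zero true objects from yielding a spurious
giant component when Otsu is forced to split pure noise. Components
smaller than `min_size` = 8 voxels are discarded as shot-noise singletons.

# Architecture statistics

**Radial fraction.** A ray is cast from the nucleus center of mass through
the signal's center of mass and marched outward in steps of ¼ of the
smallest voxel edge; the boundary is taken at the midpoint of the last
inside / first outside step, and the fraction ‖signal−center‖ /
‖boundary−center‖ is clamped to [0, 1]. A signal whose center of mass
falls outside the mask (blur can push a peripheral spot's center across
the jagged voxel boundary) is rejected and counted, not clamped — clamping
would silently inflate the outermost shell exactly where the scientific
question lives. A signal coincident with the center returns 0 (the
direction is undefined but the distance is not).

**Shells.** Fractions are binned into five 20% shells, left-closed, with
1.0 assigned to shell 5. Counts always sum to the number of records and
the cumulative distribution is returned as plot-ready points.

**Tests.** Condition distributions are compared with the two-sample
Kolmogorov–Smirnov test (exact D over the pooled points, asymptotic
p-value at effective size n·m/(n+m), via `stats::ks.test`). Counts per
nucleus are compared with a pooled-rate z-test ("proportions test"): rates
are total objects over total nuclei per group, the variance is pooled, the
p-value two-sided. The per-nucleus-rate reading of the test is one of two
defensible interpretations (the alternative — a Poisson GLM on per-nucleus
counts — would weight nuclei rather than totals); the pooled form is the
classical prop-test applied to aggregate counts. Mean volumes and mean
fluorescence intensities are compared with Welch's t (safer than the
pooled form when condition variances differ, identical in the
equal-variance limit). The sample-size target of 50–70 nuclei per
condition for radial experiments is the scale at which the KS comparison
holds its nominal size (the suite verifies 5% ± 2% type-I error at n = 60
per sample).

# Expression statistics

The generator models normalized log2 intensities directly (the upstream
array normalization is out of scope, so the generator produces its
downstream product): per-gene baselines ~ N(7, 1.5), i.i.d. Gaussian noise
(sd 0.25 log2 units) per cell, a 3-class × 3-replicate design, and planted
sets shifted by ±δ in one class. Randomly drawn planted sets are disjoint
by construction; explicitly specified sets may overlap but conflicting
planted effects raise an error. Chromosome labels default to 20
equally-weighted chromosomes (a mouse-like karyotype with uniform gene
density; a density profile can be supplied).

**Per-gene DE test.** A pooled-variance Student t per gene with
uncorrected p < 0.05, matching the study's significance convention. The
pooled rather than Welch form is a deliberate choice: with three
replicates per class, the Welch–Satterthwaite approximation is markedly
conservative (empirical size ~3.5% at nominal 5%), while the pooled test
is exactly calibrated under the generator's homoscedastic noise — and
calibration of the DE rate is what the downstream chromosome-ratio and
enrichment analyses rely on. Genes with zero variance in both classes get
p = 1 and a flag. This test is a stand-in for the original moderated
array fit; absolute DE counts from the original study are not expected to
be reproduced.

**Permutation heat values.** The set score is the *unweighted mean* over
set genes of the class-versus-rest mean difference — the mean (not the
sum) keeps scores comparable across set sizes, which a shared heat-plot
color scale requires. The permutation unit is the class-versus-rest
membership indicator, resampled uniformly; permuting genes instead would
destroy inter-gene correlation, which this statistic implicitly preserves.
Ties count in both tails ("stronger or equal"). The encoding direction
(n_down/N near 0 versus 1 − n_up/N near 1) follows the sign of the
observed score. With 9 samples and 3 per class there are only C(9,3) = 84
distinct splits, so enumeration replaces sampling whenever the number of
splits is at most N; the suite checks that sampled values (N = 10000)
match the exhaustive ones within Monte-Carlo error and that null heat
values are uniform. Whether the original analysis permuted with or
without replacement is undocumented; uniform resampling of the indicator
(with replacement across permutations) is used, and the exhaustive mode
makes the distinction immaterial at this design size.

**GO enrichment.** Upper-tail hypergeometric p per category
(P(X ≥ k); by definition this is 1 when the observed overlap is 0),
Holm-adjusted across all tested categories; genes without annotation are
excluded from both the universe and the DE list, with the exclusion count
reported. The suite verifies the p-values against brute-force enumeration
of all draws for universes up to 12 genes.

**Chromosome ratios.** DE genes per chromosome divided by genes per
chromosome; unmapped DE genes are listed, never silently dropped. Under
the generator's uniform gene placement and uniformly planted DE, the
ratios are flat (coefficient of variation < 0.2 across chromosomes),
which is the generator-level counterpart of the "de-regulation is evenly
distributed" observation.

# Pipeline and formats

`run_pipeline()` executes declared stages in order from one configuration
(R list or YAML): `simulate_images`, `quantify`, `radial`, `compare`,
`simulate_expression`, `enrich`. Every stage draws from a seed derived
deterministically from the root seed, the stage name and its position, so
reruns are bit-identical and adding a stage does not perturb another
stage's draws. A manifest (JSON) records per-stage parameters, seeds and
outputs; a failing stage names itself and leaves the partial manifest and
outputs in place. Formats: multi-page TIFF (images), GMT (gene sets),
TSV/CSV (tables, '.' decimal, UTF-8), JSON (truth, stats, manifests),
YAML (configuration). There is no shell executable: the exported functions
and `run_pipeline()` are the interface.

# Problem sizes

The test suite and the acceptance script run at the study's own scale
where that is what is being claimed, and smaller where only correctness of
arithmetic is at stake: volume recovery uses 100 nuclei per condition
(~300 chromocenters, comfortably past the ≥ 100 needed for a stable mean);
radial positioning uses 60 nuclei × 2 spots; KS calibration uses 1000
replicates of n = 60; permutation checks use the full 9-sample design with
N = 10000 against all 84 exact splits; DE calibration uses 10,000 genes.

# Limitations

* The generator renders ideal ellipsoids and spheres: no nuclear-envelope
  irregularity, no nucleoli, no chromocenter clustering or peripheral
  attachment, no spectral bleed-through, spherical aberration,
  photobleaching or chromatic shift. Passing tests demonstrate that the
  *measurement chain* is unbiased and calibrated under the stated imaging
  model, not that it would be on arbitrary real data.
* Chromocenter density is kept low so objects stay separable; merged
  objects are reported, not split (no watershed), exactly as in the
  commercial pipeline this replaces.
* Absolute volume agreement on real data is threshold-calibration
  dependent; the `amplitude` calibration is specific to Gaussian-like PSFs
  of roughly the default scale.
* The per-gene DE stand-in is not an empirical-Bayes moderated fit, and
  the GO layer tests over-representation only (no conditional or
  topology-aware testing). The gene-set statistic is the mean-difference
  permutation form, not a weighted-KS enrichment score.
* Mouse-to-human homology mapping, array normalization and any download of
  public repositories are out of scope; maps arrive as plain input tables.
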