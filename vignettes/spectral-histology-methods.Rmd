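---
title: "Methods: label-free infrared spectral histology with irsh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free infrared spectral histology with irsh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irsh)
```

## The problem

Infrared spectral histology (IRSH) characterises tissue sections without any
staining: a mid-infrared microscope records, at every pixel, an absorbance
spectrum whose bands report the local biochemical composition (protein amide
bands, lipid ester bands, carbohydrates). Segmenting these hyperspectral
cubes recovers histological structures — in mouse skin: epidermis, dermis,
hypodermis, muscle, subcutaneous fat and hair bulbs — and the per-structure
pixel abundances can be compared between animal groups, for example wild-type
(WT) skin versus skin from lumican-knockout (KO) animals, whose dermis is
markedly thickened by disorganised type I collagen.

Two practical obstacles dominate. First, sections are usually
formalin-fixed and paraffin-embedded (FFPE), and paraffin has strong alkane
bands (CH2 scissoring doublet at 1462/1472 cm^-1, CH3 bend at 1378 cm^-1,
CH stretches at 2920/2850 cm^-1) that contaminate every pixel. Second,
pixel spectra are scaled by the local section thickness and ride on a slowly
varying baseline. `irsh` addresses all three nuisances jointly by extended
multiplicative signal correction (EMSC) — "digital dewaxing" — and then runs
a *common* K-means over the pixels of all images so cluster identities are
directly comparable across samples and groups.

## The EMSC dewaxing model

Each pixel spectrum $s(\nu)$ is decomposed by ordinary least squares as

$$ s(\nu) \;=\; c\, m(\nu) \;+\; \sum_i b_i\, p_i(\nu)
   \;+\; \sum_{j=0}^{q} d_j\, x(\nu)^j \;+\; e(\nu), $$

where $m$ is a tissue target spectrum (by default the mean spectrum over all
tissue pixels of the cohort, `chooseTarget()`), the $p_i$ are paraffin
interference components (the mean spectrum of a pure-paraffin calibration
image followed by the leading principal-component loadings of its
mean-centred pixels, `buildParaffinBasis()`), $x$ is the wavenumber axis
rescaled affinely to $[-1, 1]$ (numerical conditioning of the polynomial
terms), and $e$ is the residual. The corrected spectrum is

$$ s_{\text{corr}} = \bigl(s - \textstyle\sum_i b_i p_i - \sum_j d_j x^j\bigr) / c
   \;=\; m + e / c . $$

The scale $c$ absorbs section-thickness variation, the $b_i$ absorb the
paraffin contribution, the $d_j$ absorb the baseline, and the *tissue
variability is retained in the residual term* $e/c$, rescaled to unit
thickness. The least-squares problem is solved by QR factorisation; a
rank-deficient design is a hard error naming the offending columns, never a
silent pseudo-inverse.

Key parameters, with defaults and rationale:

| parameter | default | meaning / why |
|---|---|---|
| `nComponents` | 8 | paraffin principal components; captures crystallinity/thickness variability of the wax, in line with published EMSC-dewaxing practice |
| `polyOrder` | 2 | polynomial baseline order (configurable 0–4); a quadratic tracks scattering-type drift without eating band structure |
| `cMin` | 0.2 | pixels whose fitted scale is below this are blank (pure paraffin, holes) and are masked rather than corrected |
| processed range | 1800–800 cm^-1 | the fingerprint window used for all downstream processing; crop is inclusive at both ends |

Two exact properties anchor the implementation and its tests. (i) For any
noiseless spectrum lying in the span of the design with $c > 0$, the
correction is exact: fitting and inverting recovers the generating
coefficients to machine precision. (ii) Scaling a spectrum by $\alpha > 0$
scales $(c, b, d)$ by $\alpha$ and leaves the corrected spectrum unchanged.

A consequence worth stating explicitly: with a *shared* target $m$, a pixel
of class $\ell$ with clean signature $E_\ell \neq m$ is corrected to a fixed
spectrum $m + (E_\ell - \Pi E_\ell)/(1 + \gamma_\ell)$, where $\Pi$ is the
projection onto the design span — not to $E_\ell$ itself. This mapping is
one-to-one on distinct class signatures and independent of thickness,
paraffin load and baseline, which is exactly what clustering needs; but
recovery of the *literal* endmember is only exact when the pixel's signature
lies in the design span. The validation suite therefore checks literal
endmember recovery by dewaxing each tissue stratum against its own endmember
target (placing those pixels in the span), and checks segmentation,
abundance and fold-change recovery under the shared mean target, as the
pipeline actually runs.

## Common K-means segmentation

Unmasked corrected pixels from all images are pooled (`poolPixels()`) and a
single K-means model is fitted (`kmeansFit()`): Lloyd iterations under
squared Euclidean distance, k-means++ initialisation, `nInit = 20` seeded
restarts with the lowest inertia retained, convergence when the largest
centroid displacement falls below `1e-6` (at most 300 iterations). Empty
clusters are re-seeded to the point farthest from its current centroid.
Assignment ties break towards the lowest cluster id. Every restart draws its
stream from a seed derived from the model seed, so the whole stage is
bit-reproducible. No additional normalisation is applied before clustering:
the EMSC division by $c$ has already removed thickness scaling.

On instances small enough to enumerate every partition (n <= 10, k <= 3) the
restarted fit attains the exhaustive optimum; this is asserted in the test
suite rather than assumed. Class counts follow the segmentation practice for
skin sections: k = 5 and k = 10 are both exercised, plus k = 6 (the number
of distinct phantom tissue classes) for ground-truth recovery.

Cluster abundance per image is
$\mathrm{percent}(j) = 100\,\#\{\text{pixels} = j\}/\#\{\text{tissue pixels}\}$,
and the WT/KO contrast per cluster is summarised by mean ± SEM, the KO/WT
fold change, and a classic pooled-variance two-sided Student t-test
(`studentsT()`, df = n1 + n2 − 2, p from the t distribution). Significance
is declared at p < 0.01, with no multiplicity adjustment — deliberately
mirroring the analysis convention of small-cohort IRSH studies (a Welch
variant is available behind a flag). Cluster-to-structure identity, done by
eye against stained sections in real studies, is done here against the
phantom ground truth by an exact Hungarian assignment maximising the
confusion-matrix diagonal (`matchClustersToTruth()`).

## Correlation mapping

`correlateImage()` computes the Pearson correlation of every unmasked pixel
with a reference spectrum (shipped: a *synthetic* type I collagen reference
built from the dermis band model plus paraffin, since no measured rat-tail
spectrum can be distributed). Following the original workflow the default
correlates the *raw* (atmospheric-corrected) image against an FFPE-like
reference over the full acquired axis; a dewaxed mode correlates corrected
spectra against the clean collagen model instead. Negative correlations are
kept in `rRaw` but clipped to 0 in the display map, matching the 0 (dark) to
1 (white) rendering convention; constant pixels have no defined correlation
and are masked. Pearson was chosen over a normalised dot product: both are
consistent with reported dermis coefficients, and Pearson's mean-centring
makes the map invariant to residual offsets.

## The skin phantom generator

Because no imaging data are deposited for this kind of study, every stage is
validated on seeded synthetic phantoms (`generatePhantom()`) that emulate
the acquisition: 6.25 um pixels, 4000–750 cm^-1 at 2 cm^-1 point spacing
(the instrument's 4 cm^-1 spectral resolution does not pin down its point
spacing; 2 cm^-1 is this package's choice and is configurable). A phantom is
a horizontal stack of epidermis, dermis, hypodermis, muscle and subcutaneous
fat, with elliptical hair bulbs placed randomly (non-overlapping) inside the
dermis. For the KO group the dermis fraction is multiplied by
`dermisThicknessRatio` (default 2, the anatomical contrast between groups)
and the other layers are rescaled so image size stays comparable.

Pixel spectra follow the generative model
$t\,E_\ell + a\,P + B + \varepsilon$: class endmember $E_\ell$ scaled by a
truncated-normal thickness $t$ (mean 1, sd 0.1), paraffin endmember $P$
scaled by a truncated-normal amplitude $a$ (mean 0.3, sd 0.1), a random
polynomial baseline $B$ (order 2, coefficient sd 0.02 AU) and i.i.d.
Gaussian noise (sd 0.005 AU). Endmembers are Gaussian/Lorentzian band
models from generic protein/lipid assignments; only the collagen amide III
triplet (1330/1280/1204 cm^-1) and the layer anatomy are anchored to
published skin spectra, so all amplitudes remain configurable. The noise and
paraffin levels are calibration-free choices representing a well-behaved
transmission measurement with moderate residual wax. Ground truth (labels,
thickness, paraffin) is stored alongside the cube, and in the noiseless,
baseline-free case recombining the truth fields reproduces the cube exactly.

What the phantoms deliberately do *not* emulate: resonant-Mie scattering,
detector noise structure, atmospheric water-vapour lines, partial-volume
mixing at layer boundaries, and anatomically realistic dermal texture.
Passing tests therefore demonstrate the correctness of the algorithms under
the stated generative model, not instrument-grade robustness on real FFPE
sections.

One observed (and physically plausible) behaviour: adipose tissue absorbs
weakly in the fingerprint region, so subcutaneous-fat pixels fit with small
scales $c$ and sit closest to the blank-pixel threshold; at the default
`cMin = 0.2` a minority of fat pixels can be masked. Abundance fold changes
of the dermis cluster are essentially unaffected because the masking is
balanced between groups.

## Problem sizes and determinism

The shipped validation uses 64 x 64 phantoms (4096 pixels, 501 processed
channels), cohorts of 3 WT + 3 KO, and 10–50 K-means restarts depending on
the check — sizes chosen so the full suite runs comfortably on a laptop
while keeping every stochastic bound comfortably away from its threshold.
All randomness flows from explicit seeds through `deriveSeed()` (fixed
per-field and per-phantom substreams), so cohort generation, clustering and
the full `runPipeline()` are bit-reproducible: two runs with the same config
produce byte-identical CSV tables.

## Worked example

```{r example, eval = FALSE}
cfg <- validateConfig(config = list(
  phantom = list(rows = 48, cols = 48),
  clustering = list(k_list = c(5, 10)),
  output_dir = "irsh_run"))
report <- runPipeline(cfg)
report$comparisons[["10"]]       # per-cluster WT/KO contrast at k = 10
report$dermisClusters[["10"]]    # which cluster is the dermis
```

The run directory contains the simulated containers (`simulate/`), dewaxed
cubes with per-pixel EMSC maps (`dewax/`), false-colour label maps and
abundance tables per k, comparison CSVs, correlation maps, and `report.md`
with the tables and md5 hashes of every CSV.

## Known limitations

- The EMSC target is a plain mean spectrum; no iterative target refinement.
- k is user-chosen (5/10 by convention here); no automatic model selection.
- The pooled t-test on n = 3 per group is reported because it is the field's
  convention for such designs, not because it is statistically powerful.
- Correlation maps are qualitative; no spectral unmixing is attempted.
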