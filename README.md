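# irsh — infrared spectral histology of FFPE tissue sections

`irsh` is an R package for label-free histology from mid-infrared
hyperspectral images of formalin-fixed, paraffin-embedded (FFPE) tissue
sections. It is aimed at spectroscopists and biologists who want to turn a
rows x cols x wavenumbers absorbance cube into histological structure maps
and group-level statistics without any staining — for example, quantifying
dermis remodelling in lumican-knockout (KO) versus wild-type (WT) mouse skin.

The pipeline has four computational stages:

1. **Digital dewaxing (EMSC).** Every pixel spectrum `s` is decomposed by
   least squares as

   `s = c·m + Σ bᵢ·pᵢ + Σ dⱼ·xʲ + e`

   where `m` is a tissue target spectrum, the `pᵢ` are paraffin interference
   components (mean + principal components of a pure-paraffin calibration
   image), and the `xʲ` are polynomial baseline terms. The corrected
   spectrum `(s − Σbᵢpᵢ − Σdⱼxʲ)/c = m + e/c` is free of paraffin, baseline
   and section-thickness scaling; blank pixels (`|c|` below a threshold) are
   masked. Processing is restricted to the 1800–800 cm⁻¹ fingerprint window.
2. **Common K-means.** Pixels pooled from all images are clustered once
   (Lloyd + k-means++, seeded restarts, lowest inertia wins), so cluster
   identities and false colours are comparable across samples and groups;
   k = 5 and k = 10 are the conventional class counts for skin.
3. **Abundance statistics.** Per-image cluster percentages, per-cluster
   WT/KO mean ± SEM, KO/WT fold change and a pooled-variance Student t-test
   (significance at p < 0.01).
4. **Correlation mapping.** Pixel-by-pixel Pearson correlation against a
   reference spectrum (a synthetic type I collagen reference ships with the
   package), rendered on a 0 (dark) to 1 (white) scale.

Because no public dataset exists for this kind of study, the package also
contains a first-class synthetic generator: layered skin phantoms
(epidermis, dermis with hair bulbs, hypodermis, muscle, subcutaneous fat)
with known ground truth — per-pixel tissue class, thickness and paraffin
load — including the ~2x dermis-thickness contrast between groups. Every
stage is validated against this ground truth.

## Worked example

```r
library(irsh)

cfg <- validateConfig(config = list(
  phantom    = list(rows = 40, cols = 40, n_hair_bulbs = 2),
  clustering = list(k_list = 6, n_init = 5),
  output_dir = "irsh_run"))
report <- runPipeline(cfg, verbose = FALSE)

report$dermisClusters[["6"]]
#> [1] 3
subset(report$comparisons[["6"]], cluster_id == 3,
       c(mean_wt, mean_ko, fold_change, p_value, significant))
#>    mean_wt  mean_ko fold_change      p_value significant
#> 4 29.57261 52.47176    1.774336 2.213847e-08        TRUE
```

Reading: the common K-means at k = 6 identified cluster 3 as the dermis
(matched against the phantom ground truth); its abundance rises from ~29.6%
of tissue pixels in WT images to ~52.5% in KO images — a 1.77-fold increase
(the configured dermis-thickness ratio is 2.0; hair-bulb carving and integer
row rounding account for the gap), significant at p < 0.01. The run
directory holds the HDF5 cubes, EMSC fit maps, false-colour label PNGs,
abundance/comparison CSVs, correlation maps and a Markdown report.

A thin command-line front end over the same functions is included:

```sh
Rscript inst/cli/irsh.R run --config config.yaml
Rscript inst/cli/irsh.R dewax --image X.h5 --paraffin P.h5 --out Xd.h5
```

See `vignettes/spectral-histology-methods.Rmd` for the model, parameter
choices, and what the phantoms do and do not emulate.

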