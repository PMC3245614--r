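# radialFISH

Quantitative analysis of **radial chromosome territory positioning** in
interphase nuclei from fluorescence in situ hybridization (FISH) microscopy.

Interphase chromosomes occupy preferred radial positions — gene-poor and
small chromosomes tend toward the nuclear periphery, gene-rich ones toward
the interior — and these positions shift when cells exit the cell cycle or
express mutant nuclear lamins. The standard way to measure a territory's
radial position from 2D FISH images is the **erosion-shell analysis**: the
DAPI-stained nucleus is outlined and divided into five concentric shells of
*equal area* (shell 1 at the periphery, shell 5 the interior); the
chromosome-paint signal in each shell is expressed as a percentage of its
in-nucleus total and normalized by the corresponding DAPI percentage,

```
normalized_k = probe%_k / DAPI%_k ,   k = 1..5
```

so that a value of 1 means the paint is distributed like bulk DNA. Cohorts
of nuclei are summarized as mean ± SEM per shell and conditions are compared
shell-by-shell with unpaired, unequal-variance two-tailed (Welch) t-tests at
P < 0.05. The companion 3D analysis measures, in confocal z-stacks with
anisotropic voxel spacing (0.2 µm axial), the distance from each segmented
territory's geometric center to the nearest nuclear periphery, raw and
normalized by nucleus size ((major+minor)/2 or major axis), and plots
frequency-distribution curves per condition.

The package implements the full pipeline — nucleus segmentation (Otsu,
largest component, hole filling), distance-transform equal-area shell
construction, per-shell signal measurement with optional background
correction, cohort statistics, 3D territory segmentation and
periphery-distance measurement — together with a **synthetic image
generator** that renders 2D fields and 3D stacks of nuclei with territories
placed under controllable radial laws (Beta distributions on the normalized
elliptical radius), so every stage can be validated against ground truth
without microscopy data.

## Worked example

Simulate two matched cohorts of 50 nuclei whose territories follow a
peripheral and an interior radial law, run the erosion-shell analysis and
compare them:

```r
library(radialFISH)

cfgP <- sceneConfig(radialLaw = "peripheral", nNuclei = 50, seed = 1)
cfgI <- sceneConfig(radialLaw = "interior",   nNuclei = 50, seed = 2)
cohorts <- makePopulationPair(cfgP, cfgI)

resP <- aggregateProfiles(shellProfiles(cohorts$a, backgroundSubtract = TRUE),
                          "peripheral")
resI <- aggregateProfiles(shellProfiles(cohorts$b, backgroundSubtract = TRUE),
                          "interior")
resP
#> PopulationResult 'peripheral': 50 nuclei, 5 shells (1 = periphery)
#>      shell1 shell2 shell3 shell4 shell5
#> mean  1.472  1.829  1.134  0.459  0.123
#> sem   0.157  0.101  0.132  0.105  0.061

classifyPosition(resP)   # "peripheral",   center of mass 2.19
classifyPosition(resI)   # "interior",     center of mass 4.90

compareShells(resP, resI)
#>   shell           t       df            p significant degenerate
#> 1     1   9.3452877 49.08696 1.783143e-12        TRUE      FALSE
#> 2     2  17.9813171 49.64275 2.200567e-23        TRUE      FALSE
#> 3     3   8.0978277 53.19174 7.617545e-11        TRUE      FALSE
#> 4     4   0.4807796 97.97629 6.317450e-01       FALSE      FALSE
#> 5     5 -34.4188125 75.47990 6.828478e-48        TRUE      FALSE
```

The peripheral cohort is enriched in shells 1–2 and depleted in shell 5; the
interior cohort shows the mirror image, and the Welch tests flag the outer
and inner shells as significantly different — the signature of a
periphery ↔ interior repositioning. `plotShellHistogram()` draws the
conventional histogram with SEM bars and significance markers;
`territoryDistances()` and `frequencyCurve()` provide the 3D analysis.

File-based workflows (TIFF in, CSV/PNG/YAML out) are driven by
`runPipeline()` with a YAML config — see `inst/extdata/example_scene.yaml`
and the thin CLI wrapper `inst/scripts/radialfish.R`.

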