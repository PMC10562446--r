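# seqifr

Simulation, assembly and quality control for **sequential
immunofluorescence (seqIF)** imaging runs.

seqIF multiplexes protein markers on a single tissue section by
iterating stain → image → elute cycles: each cycle stains two markers
(TRITC and Cy5 channels) plus a DAPI counterstain, images the sample as
a tile grid, and chemically strips the antibodies before the next cycle.
The raw product of an *n*-cycle run is thousands of 16-bit tiles that
must be flat-field corrected, stitched, registered across cycles on the
DAPI channel, background-subtracted and stacked into one aligned
OME-TIFF — and the method itself must be characterized: how completely
does elution remove signal, how stable are epitopes over 20 cycles, how
repeatable and spatially uniform is the staining?

`seqifr` implements that computational pipeline and its
characterization statistics for R, together with a synthetic acquisition
generator (cell phantom, autofluorescence, vignetting, rigid inter-cycle
drift, Poisson–Gaussian camera noise, incomplete elution) that ledgers
every generating parameter, so each stage is testable against ground
truth without any instrument data.

## The statistics at its core

* **Signal-to-background ratio (SBR)** — Otsu-threshold segmentation of
  background-subtracted layers (pixel mode), or positive/negative cell
  classification on per-cell means (cell mode);
  `SBR = mean(signal) / mean(background)`.
* **Elution efficiency** (percent), from secondary-only negative
  controls imaged before staining and after elution:

  ```
  (1 − [(Elu − Neg)_POS − (Elu − Neg)_NEG] / (Stain − Neg)_POS) × 100
  ```

  The NEG-area term cancels global background changes, making the
  estimator exactly invariant to constant offsets.
* **Epitope stability** — SBR at elution-cycle checkpoints as a percent
  of the initial staining.
* **Repeatability CV** — `100 · sd / mean` across repeated runs.
* **Signal uniformity** — exposure-normalized positive means over a grid
  of ROIs, variation per axis as a CV in percent.

Assembly uses phase correlation plus Nelder–Mead refinement restricted
to Euclidean transforms (recovering drifts to ~0.03 px / ~0.02° on
synthetic DAPI mosaics), linear-feathered stitching, bilinear
resampling, and min-1-normalized flat-field references.

## Worked example

```r
library(seqifr)

cfg <- run_config(markers = c("CD20", "CD3", "panCK", "CD68"), seed = 11)
validate_config(cfg)
#> character(0)
out <- run_pipeline(cfg, out_dir = "seqif_demo")
out$qc$sbr
#>   marker cycle channel       sbr  true_sbr
#> 1   CD20     1   TRITC 10.001731 10.000000
#> 2    CD3     1     Cy5 10.013407 10.000000
#> 3  panCK     2   TRITC  8.065656 10.044446
#> 4   CD68     2     Cy5  8.086051  9.927181
out$qc$elution
#>   marker efficiency_pct true_efficiency_pct
#> 1   CD20       95.06486                  95
#> 2    CD3       94.94937                  95
```

The pipeline simulated a 2-cycle, 3×4-tile acquisition with 5% elution
residual, built flat-field references from calibration tiles, assembled
the aligned 5-layer stack (`seqif_demo/stack.ome.tiff`) and measured QC.
Cycle-1 markers recover their ledgered SBR of 10 almost exactly;
cycle-2 markers read low because their thin membrane/cytoplasm
structures are smeared by the drift-correcting resampling — a real
interpolation effect discussed in the vignette. The elution estimator
recovers the generating 95% efficiency within ±0.1 point.

A thin CLI wrapper ships in `inst/cli/seqif`
(`seqif run --config run.yaml --out dir --seed 1`).

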