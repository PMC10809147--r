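# microdart

Spatio-temporal analysis of Ca²⁺ microdomains in ratiometric live-cell
fluorescence microscopy.

## The problem

Localized, short-lived elevations of free cytosolic Ca²⁺ — *microdomains* —
are among the earliest signatures of immune-cell activation: they appear
within seconds of a stimulatory bead touching a T cell or NK cell.
Quantifying them across a population of cells is hard for two reasons.
First, the raw recordings need heavy postprocessing (channel registration,
background subtraction, bleaching correction, deconvolution, ratio
computation). Second, cells differ in shape and deform over time, so "near
the contact site" or "at the cell center" means something different in
every frame of every cell.

`microdart` addresses both. It implements a complete batch pipeline:

1. **Postprocessing** — intensity-based affine channel registration (phase
   correlation + normalized cross-correlation refinement), percentile/ROI
   background subtraction, per-pixel ratio `R = ch1/ch2` with clipping, and
   three bleaching corrections (frame-wise additive, frame-wise
   multiplicative, and an additive correction based on the biexponential
   fit `f(t) = a + b₁·e^(−t/τ₁) + b₂·e^(−t/τ₂)`).
2. **Deconvolution** — per-frame Richardson–Lucy restoration
   `uₖ₊₁ = uₖ · (P* ⊛ d / (P ⊛ uₖ))` with reflective boundaries and a
   user-supplied or Gaussian PSF.
3. **Detection and tracking** — classical instance segmentation (Otsu +
   watershed; any external segmenter can be plugged in as a function),
   optimal per-frame-pair Hungarian linking gated at a maximum
   displacement, and extraction of a translation-compensated per-cell ROI.
4. **Shape normalization** — each cell outline `(r_o, θ)` is mapped onto a
   circle of radius `c · r_av`, where `r_av = Σ r_o,i / N` is the mean
   outline radius, by pure radial scaling (angles preserved,
   nearest-neighbor inverse resampling).
5. **Microdomain detection** — connected sets of cell pixels whose
   *relative* intensity (pixel / frame's mean cell intensity) exceeds a
   threshold, with size and connectivity filters; invariant to global
   intensity scaling by construction.
6. **Dartboard projection** — every cell is rotated so its bead-contact
   direction coincides, shifted so contact time is t = 0, and its domains
   are binned on an equal-area polar grid (bullseye + annuli with radii
   `r_k = R·√(b² + k(1−b²)/n)`), normalized to *events per unit area per
   second per cell*.

A synthetic-video generator (`synthetic_spec()` / `generate_dataset()`)
produces ratiometric recordings with complete ground truth — cell masks,
event locations and times, bleaching curves, known channel misalignment —
so every stage of the pipeline is testable without any external data.

## Worked example

Simulate a two-cell bead-stimulation recording and run the full pipeline:

```r
library(microdart)
dir <- tempfile()
spec <- synthetic_spec(n_cells = 2, image_size = c(52, 100), n_frames = 20,
                       frame_interval_s = 0.5, cell_radius_px = 13,
                       radius_jitter_px = 1, contact_frame = 3,
                       contact_clock = c(12, 6), rate_near = 2,
                       rate_far = 0.2, noise_sigma = 3, seed = 17)
gt <- generate_dataset(spec, dir = dir)

res <- run_pipeline(list(
  input_ch1 = file.path(dir, "ch1.tif"),
  input_ch2 = file.path(dir, "ch2.tif"),
  contacts  = file.path(dir, "contacts.csv"),
  out_dir   = file.path(dir, "out"),
  frame_interval_s = 0.5, register_mode = "none",
  min_area_px = 60, window_post_s = 6,
  time_bins = list(c(0, 3), c(3, 6))))

res$group
#> <group_summary> 2 cell(s), activated fraction 1.000, 15 timepoint(s)
head(res$group$timepoints)
#>   t_rel_s mean sem n sem_defined
#> 1    -1.0  0.0 0.0 2        TRUE
#> 2    -0.5  0.0 0.0 2        TRUE
#> 3     0.0  0.5 0.5 2        TRUE
#> 4     0.5  1.0 0.0 2        TRUE
#> 5     1.0  1.5 0.5 2        TRUE
#> 6     1.5  2.0 0.0 2        TRUE

tab <- dartboard_table(res$accumulator)
head(tab[order(-tab$density), ], 5)
#>  time_bin_start time_bin_end ring segment count       area   density n_cells
#>               3            6    3       1     8 0.05026548 26.525824       2
#>               0            3    3       1     5 0.05026548 16.578640       2
#>               0            3    4       1     3 0.05026548  9.947184       2
#>               0            3    3      12     2 0.05026548  6.631456       2
#>               0            3    4       4     2 0.05026548  6.631456       2
```

Both simulated cells were stimulated (near-contact event rate 10× the
background rate), and the readout shows exactly that: every cell is
"activated" (≥ 1 domain from contact on), domain counts rise right after
t = 0, and the hottest dartboard cells are in **segment 1** — the segment
centered on the (aligned) bead-contact direction — in the outer rings,
where the events were placed. `out/` additionally contains per-cell ROI
TIFFs, per-cell domain CSVs, group and dartboard CSVs, a rendered
`dartboard.pdf`, the resolved configuration (provenance) and a log.

A thin command-line driver with `simulate | run | ...` subcommands is at
`inst/scripts/microdart.R`:

```sh
Rscript inst/scripts/microdart.R simulate --out data --seed 5
Rscript inst/scripts/microdart.R run --config cfg.yaml --out out
```

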