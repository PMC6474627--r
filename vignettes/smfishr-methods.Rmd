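---
title: "Counting single molecules: the models and choices behind smfishr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting single molecules: the models and choices behind smfishr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

smfishr quantifies single-molecule fluorescence in-situ hybridization
(smFISH) experiments of the kind used to follow innate-immune gene
induction — IL1β and TNF-α in LPS-stimulated monocytes — at the
single-cell level. Each mature mRNA, tiled by ~20–50 singly labeled
oligo probes, appears as one near-diffraction-limited spot; nascent
transcription shows up as a bright nuclear *burst site* where on the
order of a hundred intron-containing transcripts co-localize at the
active locus; antibody staining adds a per-cell protein signal. The
package segments cells from three channels, digitally counts spots,
calls burst sites, assembles a per-cell record, and computes the
downstream statistics: count-distribution fits with AIC model
comparison, time-course summaries with scan-level error bars, and
pairwise single-cell correlations. A ground-truth scene simulator
makes every stage testable without raw microscopy data.

This vignette explains the models, the tunable parameters and the
design decisions, in that order of importance.

## Segmentation: three channels, one watershed

Cells are segmented by fusing three independent sources of evidence
(`segment()`):

1. **Nuclei from DAPI** (`detect_nuclei()`): Sobel gradient magnitude,
   Otsu threshold on the gradient, morphological closing to seal the
   edge rings, hole filling, small-object removal, then a
   distance-transform watershed to split touching nuclei. Nuclei both
   seed the cell watershed and define the nuclear/cytoplasmic
   partition of every spot.
2. **Cell rims from bright-field** (`phase_congruency_edges()`):
   phase congruency measures the agreement of local Fourier phase
   across scales, so it marks edges by their *structure* rather than
   their contrast — scaling the image by any positive constant leaves
   the map unchanged, which matters because bright-field intensity is
   arbitrary. We use the log-Gabor formulation (4 scales from a 3 px
   minimum wavelength at multiplier 2.1, 6 orientations, spread
   σ/f = 0.55) with Rayleigh-statistics noise compensation at
   k = 2 SD. The map is binarized at its 0.90 quantile.
3. **Expression regions from the smFISH channel**
   (`fish_foreground()`): the LoG spot response above the
   automatically selected threshold (the same code path as spot
   detection), dilated by 3 px, guaranteeing that strongly expressing
   regions end up inside a cell boundary.

The three binaries are added and any pixel with sum ≥ 1 is foreground
— a pixelwise union (`combine_binaries()`). Cleanup
(`morphological_cleanup()`) applies a closing of radius 2 px, a 3 px
median (for a binary mask this is exactly a majority vote, computed
by a box filter), hole filling, and removal of components below
`min_cell_area`. Finally `watershed_cells()` grows each nucleus to
the foreground boundary by seeded region growing on distance from
the nucleus, so two nuclei sharing a blob split along their
equidistance line (ties land on either side within one pixel);
foreground components containing no nucleus are dropped, and a
nucleus stranded outside the foreground becomes its own cell with a
warning. Cells touching the image border are flagged and excluded
from per-cell tables by default — partial cells bias counts low.

Every segmentation asserts its structural invariants: labels
consecutive, exactly one nucleus per cell, nucleus inside its cell,
cells disjoint.

## Spot detection: LoG, the threshold plateau, and sub-pixel fits

`log_filter()` convolves with the negated scale-normalized
Laplacian-of-Gaussian at `sigma_f` (default 1.5 px, the PSF width of
a high-NA objective at camera sampling), turning spots of radius
≈ `sigma_f`·√2 into positive local maxima. A constant image maps to
exactly zero (zero-sum kernel).

**Threshold selection** (`threshold_scan()`) renders the classic
manual procedure — plot spots-versus-threshold, pick the knee —
as an explicit rule. Candidate maxima are counted above each
threshold of a grid of 100 points spanning the 50th–100th
percentiles of the positive response with *geometric* spacing:
real-spot responses sit decades above the noise floor, and geometric
spacing resolves both regimes regardless of image size (percentile
spacing puts nearly all points in the noise regime, which dominates
pixel counts). The curve's smoothed |ΔN/ΔT| (5-point moving
average), normalized to its maximum, must stay at or below
`plateau_frac` = 0.02 for `plateau_width` = 5 consecutive grid
intervals; the threshold at the *end* of that first sustained-flat
run is selected, so the residual noise tail inside the run is
cleared. If no plateau exists the grid midpoint is returned with a
warning — and `fish_foreground()` treats that fallback as "no spot
population stands out", returning an empty mask.

**Fitting** (`fit_gaussian2d()`): each candidate (8-connected local
maximum; equal-valued plateaus reduced to their lexicographically
smallest pixel) is fit by Levenberg–Marquardt least squares of the
isotropic model

$$ I(r, c) = b + A \exp\!\left(-\frac{(r - x_0)^2 + (c - y_0)^2}{2\sigma^2}\right) $$

on a 9×9 window, initialized from moments (background = window-border
median, amplitude = peak − background, width = `sigma_f`). The
integrated intensity is $2\pi A \sigma^2$. Overlapping spots are fit
independently per candidate; there is no multi-emitter
deconvolution, which sets the ~3 px resolution limit discussed under
the simulator. An isotropic single-σ model is used throughout
(burst-site width comparisons are reported as one σ per object).

**QC gates** (`qc_gate()`): width within [0.5, 2]·`sigma_f`,
amplitude above 3× the local residual noise SD, residual RMS at most
half the amplitude, non-converged fits rejected. Every rejection
carries a reason. Counts per cell are then by the spot's center
pixel — spots are sub-pixel points, so overlap-area assignment would
be spurious precision.

## Burst sites and copy numbers

Burst calling (`detect_bursts()`) reruns the same pipeline on the
intron channel with a coarser LoG (`burst_sigma_factor` = 3×
`sigma_f`), a proportionally relaxed lower width gate, and an
acceptance floor: a site must integrate at least `burst_rmin` = 5
single-copy equivalents. The single-copy reference
(`single_copy_reference()`) is the median integrated intensity of
isolated QC-passed single molecules — by default lone single introns
from the same channel (the simulator guarantees some; real lone
introns are rare), with the gene's mRNA channel as configurable
fallback. The median is robust to the occasional unresolved doublet.
Copies per site are then the dimensionless ratio
integrated/reference (`estimate_copies()`); because both numerator
and denominator are fitted integrals from the same image, the
estimate is invariant to global intensity scaling. Using the fitted
Gaussian integral rather than a raw pixel sum makes it
background-robust.

Cells carrying more than two sites (a diploid locus has at most two
alleles) are flagged anomalous — segmentation error or mitosis — and
retained; statistics can exclude them via
`exclude_anomalous_cells`.

## Statistics

*Distribution fits* (`fit_count_distribution()`): Poisson (λ̂ = mean),
log-normal (μ̂, σ̂ from the mean and 1/n-SD of log counts) and gamma
(Newton iteration on log k − ψ(k) = log x̄ − mean(log x), moment
initialization) with AIC = 2k − 2logL. Zero counts are excluded for
the positive-support families with the zero fraction reported;
`compare_count_fits()` restricts *all* families to the same positive
sample so AICs are comparable. Bursting expression is overdispersed
(index of dispersion ≫ 1), which is exactly what the
Poisson-versus-heavy-tail AIC ordering quantifies.

*Time courses* (`timecourse_summary()`): the grand mean is
cell-weighted; the error bar is the SD across scan means — scan-to-
scan reproducibility, deliberately decoupled from the much broader
single-cell spread. A single-scan time point has no error value.

*Correlations* (`correlate()`): Pearson on raw per-cell values per
(condition, time) group, as scatter plots of counts are read;
Spearman optional; zero-variance input yields NA with a reason. The
size confound is controlled by `area_correlation()` (area versus
count). For *recovering a planted copula parameter* the package
provides `copula_correlation()`, the normal-scores correlation:
Pearson on heavy-tailed marginals is attenuated toward zero — for
log-normal marginals with log-SD s the population Pearson is
(e^{ρs²} − 1)/(e^{s²} − 1), e.g. 0.713 at ρ = 0.8, s = 1 — whereas
the normal-scores estimate is invariant to the monotone marginal
transform and consistent for ρ itself. Conversely, when the
simulator must *plant* a target Pearson r, the copula parameter is
back-transformed as ρ = log(1 + r(e − 1)) for s = 1.

*Published tables* (`ingest_supplementary_table()`): per-cell raw
data workbooks (xlsx, or a directory of per-sheet CSVs) are mapped
into the cell-table schema through an explicit, declared sheet map —
sheet layouts vary too much to guess, so unmapped layouts raise an
error listing what was found.

## The simulator: what it emulates, and what it does not

`sim_params()` / `render_scene()` generate scenes whose defaults
*are* the study conditions: 20 cells per field; heavy-tailed
log-normal per-cell counts (meanlog = log 100, sdlog = 1 — median
100 copies/cell, dispersion index ≫ 5); between-gene dependence from
a Gaussian copula (default ρ = 0.36, the unstimulated baseline);
0–2 nuclear burst sites per cell with P = (0.3, 0.5, 0.2), i.e. 0.9
sites/cell, each of ~100 transcripts (log-normal, sdlog 0.3)
rendered as co-located PSFs jittered within 1 px, biased toward the
nuclear rim as observed for these loci; a few isolated lone introns
per cell (the single-copy reference); protein as a per-cell uniform
fill affine in the mRNA count with 20% multiplicative noise; counts
scaled by (area/mean area)^0.5 so the size confound has signal;
per-molecule amplitude 200 iu (CV 10%) on background 100 iu with
Poisson shot noise and 6 iu read noise — peak SNR ≈ 11.

**Geometry.** The field is camera-native 2048×2048 with cell radii
120–150 px and nuclear radii 55–70 px. This follows from the optics
the PSF width implies: σ_psf = 1.5 px corresponds to ~0.065 µm/px
(100×/1.49 NA objective on a 6.5 µm-pixel sCMOS camera), at which a
16–20 µm PMA-differentiated monocyte spans 120–150 px in radius. The
sampling also sets an identifiability budget: two molecules closer
than ~2σ√2 ≈ 3 px merge into one LoG maximum, and with independent
per-candidate fits (no multi-emitter model) one of the pair is
necessarily lost. At ~100 molecules per cell the default geometry
keeps the expected merge fraction at a few percent; proportionally
smaller cells at the same σ_psf would make single-molecule counting
fail for *any* detector, which is why the geometry is anchored to
the physical sampling rather than chosen for rendering speed. Tests
use the same sampling with smaller fields and fewer cells so the
suite runs in minutes; the acceptance script uses one full default
field (~2000 molecules over the two genes), eleven 1024² burst
scenes (~250 sites), and table-level kinetics at 1000 cells × 3
scans per time point — the study's own scan size.

**Not emulated:** optical aberrations, z-dependent PSF shape,
photobleaching, uneven illumination, autofluorescence texture,
cell-shape irregularity (cells are discs), segmentation-error modes
beyond touching cells, and mechanistic (telegraph-model)
transcription dynamics — counts are drawn from their stationary
heavy-tailed marginals. Passing tests therefore demonstrate that the
algorithms are correct and calibrated on images matching their
assumptions, not that the pipeline is robust to every real-world
artifact; on real data the QC-rejection reasons and the threshold
scan curve (`autoplot()` it) are the first diagnostics to inspect.

## Numerical and degenerate-input choices

- Pixel convention: 1-based (row, col), pixel centers at integer
  coordinates; sub-pixel positions continuous in the same frame.
  `x0` runs along rows, `y0` along columns, uniformly everywhere.
- Z-stacks are reduced by maximum-intensity projection before
  analysis (deterministic, testable); per-plane analysis can be
  composed from the same primitives if needed.
- Scenes are written as camera-native 16-bit integer TIFF pages;
  integer-valued scenes round-trip bit-identically.
- All randomness flows from a single seed (`Config$seed`, the
  `--seed` flags); identical seeds give bit-identical scenes.
- Watershed/plateau ties: equal-valued candidate plateaus take the
  lexicographically smallest pixel; equidistant watershed pixels
  resolve within one pixel of the equidistance line.
- Constant images: zero LoG response, zero phase congruency, zero
  nuclei — degenerate, never an error. All-zero samples for
  log-normal/gamma fits *are* an error (no positive support).
- The gamma shape Newton iteration is guarded against non-positive
  steps (halving) and runs at most 50 iterations from the moment
  start; the fitted mean k̂θ̂ equals the sample mean by construction.
- Fit non-convergence is flagged, excluded downstream, and counted,
  never silently dropped.

## Known limitations

Isotropic single-σ PSF only; no 3-D localization; no multi-emitter
splitting (crowding bias at > ~0.005 molecules/px²); burst copies
inherit the single-copy reference's bias if the reference channel is
mis-chosen; protein is relative per channel (no absolute
calibration, no secreted fraction); Pearson correlations on counts
are attenuated relative to latent dependence (use
`copula_correlation()` when the copula scale is wanted); the CSV
cell-table schema is wide (per-gene columns), which suits tens of
channels, not thousands.
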