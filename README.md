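# smfishr

Digital quantification of single-molecule FISH experiments in R: from
multi-channel microscope fields to per-cell transcript counts,
transcriptional burst sites and protein signal, and on to the
single-cell statistics that characterize inflammatory gene induction.

## The problem

In smFISH, each mRNA molecule is tiled by ~20–50 singly labeled oligo
probes and appears as one diffraction-limited spot; nascent
transcription appears as a bright nuclear focus ("intron bursting
site") holding on the order of 100 transcripts; antibody staining
adds protein content. Imaging IL1β and TNF-α in LPS-stimulated
monocytic cells this way yields, per cell: mRNA counts split into
nuclear and cytoplasmic pools, burst-site counts, and protein
intensity — the raw material for time courses, count-distribution
fits and single-cell correlations that distinguish coordinated from
independently activated genes. smfishr is for labs doing that kind
of experiment (and for methodologists who want a testbed with ground
truth): it implements the full analysis chain with a simulator that
plants every statistical structure the pipeline assumes.

## What it computes

- **Segmentation** (`segment`): nuclei from DAPI (edge detection +
  distance-transform watershed), cell rims from bright-field via
  contrast-invariant *phase congruency* (log-Gabor), high-expression
  regions from the smFISH channel; the three binaries are unioned,
  cleaned morphologically, and partitioned by a nucleus-seeded
  watershed. Every cell contains exactly one nucleus.
- **Spot counting** (`count_spots`): scale-normalized LoG filtering
  at σ_f; automatic threshold from the spots-vs-threshold curve (the
  smoothed |ΔN/ΔT| must stay ≤ 2% of its maximum for 5 consecutive
  grid points); sub-pixel 2-D Gaussian fits
  I = b + A·exp(−((r−x₀)² + (c−y₀)²)/2σ²) by Levenberg–Marquardt;
  QC gates on width, SNR and residuals; per-cell assignment with
  nuclear/cytoplasmic split.
- **Burst sites** (`detect_bursts`): the same pipeline at 3σ_f with
  an intensity floor; transcript copies per site estimated as
  integrated intensity 2πAσ² over the single-copy reference (median
  of isolated single molecules).
- **Statistics**: Poisson/log-normal/gamma MLEs with AIC
  (`fit_count_distribution`, `compare_count_fits`); time-course
  means with scan-level SD error bars (`timecourse_summary`);
  Pearson correlations per time point (`correlate`,
  `area_correlation`), plus the normal-scores copula estimator
  (`copula_correlation`); ingest of published per-cell workbooks
  (`ingest_supplementary_table`).
- **Simulator** (`sim_params`, `render_scene`,
  `simulate_timecourse`): camera-native scenes with known cells,
  spots, burst sites and protein latents; log-normal counts with
  Gaussian-copula gene–gene dependence; full determinism under a
  seed.

## Worked example

Simulate a small field, segment it, count one gene, and fit the count
distribution:

```r
library(smfishr)

p <- sim_params(width = 1024, height = 1024, n_cells = 8,
                cell_radius = c(100, 130), nucleus_radius = c(45, 60))
sim <- render_scene(p, seed = 7)
sim
#> <smfish_sim> sim: 8 cells, 1308 planted spots, 13 burst sites

seg <- segment(sim$scene)
seg
#> <smfish_segmentation> sim: 8 cell(s), 0 on border

spots <- count_spots(sim$scene, "fish:IL1B", seg)
spots
#> <smfish_spots> fish:IL1B: 690 candidates, 677 passed QC, 0 unassigned
spots$scan
#> <smfish_threshold_scan> 100 thresholds, selected 14.48, n_spots at selection 690

tab <- build_cell_table(seg, spots_by_channel = list(IL1B = spots),
                        condition = "LPS", time_minutes = 60)
tab[, c("cell_id", "area_px", "count_IL1B", "nuclear_IL1B", "cyto_IL1B")]
#> # A tibble: 8 × 5
#>   cell_id area_px count_IL1B nuclear_IL1B cyto_IL1B
#>     <int>   <int>      <int>        <int>     <int>
#> 1       1   36233        163           13       150
#> 2       2   38453         75            3        72
#> 3       3   39468        173           21       152
#> 4       4   32833         52            5        47
#> 5       5   52878         59            2        57
#> 6       6   33647         49            3        46
#> 7       7   47993         73            2        71
#> 8       8   52432         33            1        32

compare_count_fits(tab$count_IL1B)[, c("family", "logLik", "AIC", "delta_aic")]
#> # A tibble: 3 × 4
#>   family    logLik   AIC delta_aic
#>   <chr>      <dbl> <dbl>     <dbl>
#> 1 lognormal  -40.7  85.4     0
#> 2 gamma      -41.1  86.2     0.825
#> 3 poisson   -131.  264.    178.
```

Reading the output: the threshold scan settled at 14.5 response units
where the spot count has stopped changing; 677 of 690 candidate fits
passed QC and every one landed in a cell; counts are heavy-tailed
across cells (33–173 copies) and mostly cytoplasmic, and the AIC
ordering — log-normal ≈ gamma ≪ Poisson, Δ AIC ≈ 178 — is the
signature of transcriptional bursting rather than constitutive
(Poisson) expression.

Planted gene–gene dependence is recovered on the copula scale:

```r
cnt <- sample_counts(sim_params(rho = 0.8), n_cells = 500, seed = 1)
copula_correlation(cnt$IL1B, cnt$TNFA)
#> [1] 0.785
```

`autoplot()` methods exist for threshold scans, distribution fits and
segmentations; `plot_timecourse()`, `plot_correlation_timecourse()`
and `plot_cell_scatter()` cover the downstream results. A thin
command-line front end with `simulate` / `segment` / `spots` /
`bursts` / `quantify` / `stats` subcommands ships in
`inst/cli/smfishr`.

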