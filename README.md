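# chromodyn

Quantitative analysis of live-cell confocal imaging of chromatin and
chromatin remodelers, built around the readouts used to study SWI/SNF
(BRM) dynamics on *Drosophila* salivary-gland polytene chromosomes:

* **FRAP kinetics** — background correction, double normalization against
  the whole-nucleus channel, full-scale rescaling, and least-squares
  fitting of the double-exponential recovery
  `F(t) = a(1 − e^(−k₁t)) + b(1 − e^(−k₂t))`, reporting the mobile
  fraction `a + b` and the half-time t½ solving `F(t½) = (a+b)/2`.
* **FLIP-FRAP** — half-nucleus bleach analysis under a two-compartment
  exchange model, with a fluorescence-conservation check (bleached-half
  gain vs unbleached-half loss) and the exchange half-equilibration time.
* **Chromatin condensation** — binning histone-GFP voxel intensities into
  background/white/gray/black classes (thresholds 0–82 / 83–148 /
  149–224 / >224 after percentile auto-brightness), chromosome volume
  fractions across nuclei, and per-class density ratios against the
  genomic composition: `density_c = genomic fraction / volume fraction`.
* **Fiber-model compaction** — extended 11 nm nucleosomal fiber length
  `L = bp × 0.34 nm / 6.8`, linear fold-compaction
  `L / observed length`, and a cylinder-volume variant comparing DNA
  densities in bp/µm³.
* **Clustering / colocalization** — the circular-neighborhood variance
  filter (population variance, radius 2) whose nuclear mean quantifies
  punctate clustering, Welch/pooled two-sample t tests from raw samples
  or published `(mean, sd, n)` summaries, and thresholded Manders
  coefficients M1/M2.
* **Synthetic data** — seeded generators for recovery curves (including
  slow histone-turnover and biphasic polymerase regimes), two-compartment
  FLIP pairs, and banded-nucleus phantoms (ellipsoidal nucleus,
  band-stacked chromosome, nucleolar void, Gaussian PSF, Poisson + read
  noise) with exact ground truth, so every analysis stage is testable
  without microscope data.

The methods vignette (`vignettes/chromodyn-methods.Rmd`) documents the
models, conventions and numerical choices in detail.

## Worked example

```r
library(chromodyn)

# a fast-remodeler-like FRAP curve on a 70 ms protocol, ~2% curve noise
acq <- acquisition_spec(n_pre = 20, n_post = 200, interval = 0.070,
                        bleach_depth = 0.8, noise_sd = 0.02, seed = 1L)
cur <- simulate_frap_curve(kinetic_params_for_t_half(0.7), acq)
fit <- fit_double_exponential(full_scale_normalize(background_correct(cur)))
fit
#> <frap_fit double> a=0.7817 k1=1.298/s  b=0.2683 k2=0.08364/s
#>   mobile fraction 1.000, t1/2 0.807 s, sse 0.116

# condensation from printed genomic and volume fractions
cond <- relative_condensation(genomic_composition(0.05, 0.25, 0.70),
                              c(white = 0.52, gray = 0.43, black = 0.05))
cond
#> <condensation_result> gray/white 6.05-fold, black/gray 24.08-fold, black/white 145.6-fold

# fragment compaction against the extended 11 nm fiber
fold_compaction_linear(extended_fiber_length(360000),
                       fragment_measurement(0.72))$fold
#> [1] 25
```

The fitted half-time recovers the 0.7 s ground truth within curve noise
(0.81 s at this seed; the median over 200 seeds is within a few percent
of truth, as the test suite verifies); the density ratios
say gray chromatin is ~6-fold more condensed than open interband
chromatin and black chromatin another ~24-fold (~146-fold total); and a
360 kb fragment whose extended fiber would span 18 µm but which measures
0.72 µm in vivo is 25-fold compacted.

## Analysis workflow

The numbered scripts under `analysis/` run the full study-style workflow
on the synthetic fixture bundle and write tables under `results/`:

```sh
Rscript analysis/01_fixtures.R        # fixture bundle + ground-truth sidecars
Rscript analysis/02_frap_kinetics.R   # curve fits, half-time ratios, FLIP-FRAP
Rscript analysis/03_condensation.R    # volume fractions, density ratios, compaction
Rscript analysis/04_cluster_coloc.R   # variance statistic, t test, Manders
```

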