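# parastorm

Frame-parallel analysis of single-molecule localization microscopy
(SMLM/dSTORM) data in R.

## The problem

SMLM builds a super-resolved image by localizing sparse, stochastically
blinking fluorophores frame by frame and accumulating millions of fitted
positions.  The localization stage dominates the processing time — iterative
Gaussian fitting of a large field of view can take hours on a workstation —
but it is embarrassingly parallel, because each camera frame is analysed
independently.  `parastorm` implements that parallel architecture end to
end, for people who want to process dSTORM movies (or prototype SMLM
analysis strategies) without a cluster-bound toolchain:

1. **Localization** — per frame: difference-of-Gaussians spot detection,
   then sub-pixel fitting with one of three engines:
   - `nwls`: iterative nonlinear weighted least squares on an integrated
     (error-function) 2D Gaussian PSF, weights `1/max(y, 1)`;
   - `mle`: Poisson maximum likelihood for the same PSF model, minimizing
     `sum(mu_i - y_i log mu_i)` by damped Fisher scoring;
   - `phasor`: non-iterative position from the phase of the first Fourier
     coefficients of the spot ROI (fast preview-quality localization).
2. **Parallel scheduling** — frames are divided *interleaved* across W
   workers (worker w takes frames w, w+W, w+2W, ...).  Because emitter
   activity decays over the acquisition, interleaving gives every worker a
   comparable workload where contiguous blocks would not.
3. **Merge** — per-worker tables are stably re-sorted into the original
   frame order; the merged raw table is byte-identical to a single-worker
   run.
4. **Postprocessing and rendering** — automated filters (intensity >= 1
   photon, z uncertainty <= 500 nm, 10th–75th intercentile width window),
   fiducial-free drift correction by redundant cross-correlation,
   consecutive-frame merging of repeated localizations, and histogram /
   average-shifted-histogram / Gaussian renderings plus z colour-coded 2D
   projections for astigmatic 3D data.

Lateral precision is tracked with the Thompson formula

    dx^2 = (sigma^2 + a^2/12) / N  +  8 pi sigma^4 b^2 / (a^2 N^2)

(`sigma` PSF width, `a` pixel size, `N` photons, `b` background SD), and
astigmatic 3D uses Huang-style defocus curves
`sigma(z) = sigma0 sqrt(1 + ((z - c)/d)^2)` per axis, inverted on a 1 nm
grid with parabolic refinement.

A synthetic dSTORM simulator (blinking/bleaching emitters on filament-like
structures, integrated-Gaussian PSF, Poisson + read noise, lateral drift,
optional astigmatic defocus) provides ground truth so every stage is
testable at desk scale.

## Worked example

```r
library(parastorm)

## simulate a 200-frame dSTORM movie: 40 emitters on filaments,
## ~1000 photons/event, 10 background photons/px, 100 nm pixels
cfg   <- simulationConfig(n_frames = 200L, n_emitters = 40L, p_on = 0.05,
                          structure = "filaments", seed = 42L)
truth <- generateGroundTruth(cfg)
paths <- renderMovie(truth, cfg, "demo.ome.tif")

## run the pipeline: 4 interleaved workers, Poisson-MLE fitting
res <- runPipeline(paths$movie, n_nodes = 1, jobs_per_node = 4,
                   engine = "mle", post = "minphot,sigma")
res$report
#> RunReport: 4 worker(s), 551 localizations
#>   per-worker counts: 127, 126, 136, 162
#>   merged table: .../localizations_raw.csv
res$post
#> LocalizationTable (2D): 358 localizations, frames 1..200
#>   provenance: 7 step(s); last: sigma [69.8266, 134.223] nm: kept 358 of 551

## compare against ground truth
m <- matchLocalizations(res$raw, truth, radius_nm = 50,
                        min_separation_nm = 500)
mean(m$matched)                      # fraction of true events recovered
#> [1] 0.9948052
sqrt(mean(m$dist_nm[m$matched]^2))   # lateral RMSE, nm
#> [1] 10.10901
thompsonUncertainty(130, 100, 1000, 10)  # precision bound at these settings
#> [1] 9.461234
```

The run directory contains `localizations_raw.csv` and the postprocessed
`localizations_post_minphot-sigma.csv` (ThunderSTORM-compatible CSVs), an
average-shifted-histogram preview (`preview_2D.png`/`.tif`), and a
timestamped `run.log`.  Passing a calibration file
(`runPipeline(movie, calibration = "cal.yaml", ...)`) switches to
elliptical fitting and z lookup; outputs are then tagged `3D` and include
a depth colour-coded projection.

A shell entry point with the same semantics is installed at
`inst/scripts/parastorm`:

```sh
Rscript inst/scripts/parastorm run demo.ome.tif --engine mle --jobs-per-node 4
Rscript inst/scripts/parastorm run movie3d.ome.tif cal.yaml      # 3D
Rscript inst/scripts/parastorm run 'well_*.ome.tif' -b --nodes 4 # batch
```

## Package layout

- `R/` — S4 classes (`MovieHandle`, `LocalizationTable`,
  `AstigCalibration`, `WorkerPlan`, ...) and the module implementations:
  `io-movie`/`io-table`, `simulate`, `detect`, `localize`, `calibrate`,
  `parallel`, `postprocess`, `render`, `pipeline`, `cli`.
- `vignettes/parastorm-methods.Rmd` — models, assumptions, parameter
  choices and limitations.
- `tests/testthat/` — unit, property and acceptance-grade tests (all
  fixtures simulated in code).
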