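# ifstate

Instantaneous-frequency microstate analysis of multichannel EEG.

Conventional EEG microstates segment brain activity by the spatial
distribution of signal *power*. `ifstate` instead segments by the spatial
distribution of *instantaneous frequency* (IF): within the theta/alpha band
(4–13 Hz), the electrodes whose oscillation momentarily runs faster than
the scalp average are **phase-leading**, and the quasi-stable pattern of
*which region leads* defines a leading-phase microstate. The package is
aimed at researchers analysing resting-state EEG dynamics — in particular
group comparisons such as healthy controls (HC) versus Alzheimer's disease
(AD), where rhythm slowing and altered state transitions are the phenomena
of interest.

## Method

For each electrode *i*, the band-passed signal is Hilbert-transformed and
the IF is the derivative of the unwrapped analytic phase,
median-filtered (0.1 s window) to suppress phase slips. The spatial
deviation field

&nbsp;&nbsp;&nbsp;&nbsp;dIF&#8342;(t) = IF&#8342;(t) − mean&#8342; IF(t)

is positive where a region leads and negative where it lags. Its
cross-electrode standard deviation, smoothed with a 0.025-s median, is the
**GF-IF** (global field instantaneous frequency): high when one region
strongly leads, low when the scalp is spatially uniform. The dIF
topographies at GF-IF **maxima**, pooled over all subjects of both groups,
are clustered by Euclidean k-means (k = 4); state transitions are placed
at GF-IF **minima**. Per recording the package reports:

- **emergence frequency** — GF-IF maxima per second, overall and per state;
- **occurrence-duration rate** — fraction of evaluated time each state occupies;
- **transition matrix** — P(state → state) across consecutive peaks
  (self-transitions included).

A validation suite characterises GF-IF dynamics (Welch PSD on a
0.001–1 Hz grid, multiscale sample entropy with m = 2, r = 0.2 over 20
scales, and 10 IAAFT surrogates with 100 iterations), and group statistics
use Student's t-tests with Benjamini–Hochberg FDR control at q < 0.05 over
the declared family sizes (PSD 1000, MSE 20, emergence 5, occurrence 4,
transitions k²), plus Pearson correlations of metrics with MMSE scores in
the AD group.

A seeded synthetic-cohort generator (`generate_cohort`) produces 16-channel
narrowband recordings with a hidden switching process that makes one scalp
region phase-lead at a time, providing ground truth for every stage.

## Worked example

```r
library(ifstate)

ch  <- generate_cohort(n_hc = 4, n_ad = 4, seed = 7,
                       hc_params = synth_params(duration_s = 30))
cfg <- pipeline_config(); cfg$dynamics <- FALSE; cfg$restarts <- 20
res <- analyze_cohort(ch$recordings, cfg)

print(res$model)
#> <if_state_model> k = 4, seed = 17, inertia = 1299.23
#>   states: right, left, occipital, frontal

print(res$metrics[[1]])
#> <if_microstate_metrics> 130 segments, 6.579 /s overall
#>      state emergence occurrence
#>      right    3.1377     0.4499
#>       left    0.8097     0.1414
#>  occipital    1.4170     0.1943
#>    frontal    1.2146     0.2143

print(res$tests$occurrence)
#>                   name          t           p significant
#> 1   occurrence_frontal  1.1977501 0.276179364       FALSE
#> 2 occurrence_occipital -4.9939895 0.002467067        TRUE
#> 3      occurrence_left  0.6917280 0.514969107       FALSE
#> 4     occurrence_right  0.8378647 0.434207199       FALSE

tapply(res$subject_table$mean_if, res$subject_table$group, mean)
#>       AD       HC
#> 8.233493 9.028054
```

The fitted model recovers all four canonical leading-phase states. The
per-recording metrics show how often each state emerges and how much time
it occupies. The occurrence-rate test table flags the planted occipital
deficit of the AD-like group (negative t = lower in AD) as FDR-significant,
and the group-mean IF reflects the planted ~0.8 Hz slowing of the AD-like
rhythm.

For file-based workflows, write a cohort to disk and run everything from
its manifest:

```r
man <- write_cohort(ch, "cohort_dir")
run_full_analysis(man, out_dir = "results_dir")
```

or use the thin CLI in `inst/cli/ifstate`
(`ifstate synth | run-all | dynamics`).

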