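# semfocus

Fine focusing and astigmatism correction in a general-purpose scanning
electron microscope (SEM) are done while watching a fast, very noisy video
stream. At picoampere probe currents the structure needed to judge focus can
sit far below the noise floor of a single frame, and naive sharpness metrics
collapse. `semfocus` is an R toolkit for operators and instrument-software
developers that turns such a stream into a stable focusing signal, built
around three ideas:

1. **Two-frame covariance SNR.** For registered frames `t1 = s + n1`,
   `t2 = s + n2` sharing the specimen signal `s` with independent noise,

   ```
   SNR = S_sigma / N_sigma
       = sqrt( Cov(t1,t2) / ( sqrt(Var(t1) Var(t2)) - Cov(t1,t2) ) )
   ```

   The estimate is invariant to contrast/brightness (affine) changes, so it
   makes an honest focus-evaluation signal.

2. **SNR-priority acquisition.** The steadiness of repeated covariance
   measurements on an M-pixel frame follows the stability index

   ```
   I(M, SNR) = M SNR^4 / (2 SNR^2 + 1)
   ```

   which is quartic in SNR but only linear in M: at low SNR it pays to
   sacrifice pixels for SNR. Repeated 2x2 block averaging of an oversampled
   frame doubles the SNR per step while quartering M (~4x index gain per
   step); the package sweeps the levels and selects the index maximum.

3. **Active acquisition.** Causal smoothing (4-point moving average) and
   4-frame integration steady the focus graph; a prominence-tested peak
   detector reports the just-focus point or an honest "no usable peak"; and
   when the current field's signal is insufficient, candidate fields around
   the observation region (beam shifts) are ranked by the stability index
   to find a stronger one — even under defocus.

A seeded **virtual SEM** (specimen texture, defocus and astigmatic blur,
current/dwell-dependent noise, beam shift, magnification) provides ground
truth for every claim the package makes about itself.

## Worked example

```r
library(semfocus)

# a virtual specimen observed at high magnification with a 26 pA TV scan
spec <- generate_specimen(512, 512, feature_scale = 1, seed = 7)
acq  <- acquisition_params(width = 160, height = 120, sampling = "nearest",
                           psf_scale = 6, seed = 1)
opt  <- optics_state(magnification = 8, current = 26)

set.seed(1)
t1 <- render_frame(spec, opt, acq)
t2 <- render_frame(spec, opt, acq)
estimate_snr(t1, t2)
#> Two-frame covariance SNR estimate
#>   pixels (M): 19200   status: ok
#>   cov: 1.15463   var1: 12.2169   var2: 12.3197
#>   signal sd: 1.07454   noise sd: 3.3337   SNR: 0.3223
```

A single TV-scan pair sits at SNR 0.32: the specimen signal (sd 1.07) is
buried under noise three times stronger. Sweeping 2x2 reductions:

```r
sw <- reduction_sweep(t1, t2, r_max = 5)
tidy(sw)
#> # A tibble: 6 x 7
#>   level width height     m   snr index_value chosen
#>   <int> <int>  <int> <int> <dbl>       <dbl> <lgl>
#> 1     0   160    120 19200 0.322       172.  FALSE
#> 2     1    80     60  4800 0.625       411.  FALSE
#> 3     2    40     30  1200 1.23        684.  FALSE
#> 4     3    20     15   300 2.44        822.  TRUE
#> 5     4    10      7    70 2.42        188.  FALSE
#> 6     5     5      3    15 2.05         28.2 FALSE
```

Each level roughly doubles the SNR while the oversampled signal survives
(0.32 → 0.63 → 1.2 → 2.4); the stability index peaks at level 3 and falls
once averaging starts destroying signal, so level 3 is selected. Now a focus
sweep at 3 pA — generator SNR ≈ 0.1, where the unprocessed graph is useless:

```r
opt3 <- optics_state(magnification = 8, current = 3)
st <- sem_stream(spec, ramp_trajectory(opt3, "defocus", -3, 3, 48), acq)
g <- evaluate_sweep(st$frames, st$meta$defocus, reduction = sw$chosen,
                    window = 4, integration = 4)
glance(g)
#> # A tibble: 1 x 7
#>   n_samples metric level window integration peak_tick peak_control
#>       <int> <chr>  <int>  <int>       <int>     <int>        <dbl>
#> 1        41 snr        3      4           4        30        0.702
```

The full chain finds the just-focus peak at defocus 0.70 (true focus 0;
the causal smoothing lag accounts for ≈ 0.6 of the offset) out of a stream
whose raw per-frame SNR is 0.1. `autoplot(g)` draws the operator's graph;
`evaluate_sweep(..., reduction = 0, window = 1)` on the same stream returns
no usable peak.

## Command line

`inst/cli/semfocus` wraps the same functionality:

```sh
semfocus simulate     --input scenario.yaml --stack out.tif --meta out.csv
semfocus estimate-snr --t1 a.tif --t2 b.tif --out snr.csv
semfocus reduce       --stack out.tif --r-max 5 --out sweep.csv
semfocus focus-sweep  --input scenario.yaml --reduction auto --out graph.csv
semfocus search-fov   --input scenario.yaml --radius 160 --out fields.csv
```

Scenario YAML files describe seed, specimen, acquisition, optics and
trajectory; see `?read_scenario`.

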