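# depthbreath

Contactless respiratory monitoring from the depth channel of an RGB-D
camera, in R.

Breathing moves the body surface: during inhalation the chest and abdominal
walls travel a few millimetres toward an observer facing the subject. An
RGB-D camera (e.g. an Intel RealSense-class device) delivers a per-pixel
depth map in millimetres alongside the color image, so respiration appears
as a small periodic modulation of depth over the trunk. `depthbreath`
implements the full analysis chain for such recordings:

1. **Background masking** — pixels beyond 1.5 m, and null-depth pixels, are
   masked; the unmasked silhouette is refined by morphological closing.
2. **Face detection** on the masked color stream (pluggable detector
   interface), retried over frames up to a budget.
3. **Automatic ROI placement** from the face box at `(x, y)`, size `w×h`,
   frame height `H`:

   ```
   thorax  = [x, x+w) × [H − 2h,   H − 3h/2)
   abdomen = [x, x+w) × [H − 5h/6, H − h/3)
   ```

   Both regions have area `w·h/2` and scale with the subject's apparent
   size.
4. **Signal acquisition** — per frame, the mean depth of each ROI (one
   arithmetic mean per region: constant work per sample, so many regions
   can be tracked synchronously and in real time).
5. **Conditioning** — normalization, causal moving average (window
   `ws = 8` samples), and a zero-phase Butterworth band-pass of
   0.08–0.5 Hz (4.8–30 breaths/min) that preserves peak timing.
6. **Breath metrics** — prominence-based inhalation-peak detection, the
   breath-by-breath tachogram `br = 60/Δt` breaths/min, and sliding
   `n`-cycle window averages.
7. **Agreement statistics** against a reference signal — breath pairing,
   Bland–Altman bias and limits of agreement `bias ± 1.96·sd`, and
   `RMSE = sqrt(mean((BR_est − BR_ref)²))`.

Because no public RGB-D breathing corpus exists, the package ships a
deterministic synthetic scene generator (`synthesize_sequence()`) that
renders annotated 640×480 depth+color sequences — subject at 1 m,
background at 2.5 m, per-pixel depth noise σ = 2.5 mm, null-depth dropout,
frame-timing jitter, configurable breathing waveforms with exact
ground-truth breath times — so the entire pipeline is testable end to end.
A 16-bit depth-PNG directory container provides lossless storage and
interchange.

Intended users: researchers prototyping camera-based vital-sign estimation,
and anyone needing a reproducible reference implementation of the
mean-depth ROI method with honest synthetic benchmarks.

## Worked example

Simulate one minute of natural breathing at 16 breaths/min (±3%
breath-to-breath jitter) observed at both thorax and abdomen, run the
pipeline, and compare the thoracic estimate against the generator's exact
breath times:

```r
library(depthbreath)

cfg  <- scene_config(duration_s = 60, seed = 42)
prof <- breathing_profile(rate_bpm = 16, amplitude_mm = 4,
                          interval_jitter_frac = 0.03)
seq  <- synthesize_sequence(cfg, list(thorax = prof, abdomen = prof),
                            materialize = FALSE)
seq
#> <frame_sequence> 900 frames, 640x480 px, 59.9319 s, nominal 15 fps (lazy)

res <- run_pipeline(seq)
res$mean_br
#>   thorax  abdomen
#> 15.88325 16.04033

head(res$tachogram$thorax, 3)
#>   breath_index    time_s   br_bpm
#> 1            1  4.850388 16.19741
#> 2            2  8.683061 15.65487
#> 3            3 12.540189 15.55562

report <- compare_tachograms(res$tachogram$thorax,
                             gt_tachogram(seq$annotations, "thorax"))
report
#> <agreement_report> n=15  bias=-0.023  LoA [-0.200, 0.154] (x1.96)  RMSE=0.090 breaths/min
```

Reading: the whole-recording mean rates land within ~0.15 breaths/min of
the 16 breaths/min drive; breath by breath, the camera estimate differs
from the true event timing by a bias of −0.02 breaths/min with 95% limits
of agreement of ±0.2 breaths/min on this noise-free-of-artifacts synthetic
scene. `run_pipeline(..., out_dir = ...)` additionally writes every
intermediate series, both tachograms per ROI, and a run log.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/depthbreath.R simulate --rate-bpm 16 --duration-s 60 --seed 1 --out rec/
Rscript inst/cli/depthbreath.R extract  --input rec/ --out out/
Rscript inst/cli/depthbreath.R analyze  --input out/thorax_filtered.csv --out out/an/
Rscript inst/cli/depthbreath.R compare  --vs out/thorax_tachogram.csv --gt out/abdomen_tachogram.csv
```

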