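# ahrswim

Swim-training analysis from a trunk-worn AHRS (attitude and heading
reference system). Given a 13-column CSV log — time (ms), accelerometer
(g), gyroscope (deg/s), magnetometer (gauss), and the fused pitch, roll
and heading angles (deg) at a nominal 100 Hz — the package segments the
session into laps, labels each lap's stroke style, counts strokes, and
reports the indicator set coaches work with: lap time, stroke rate, trunk
elevation, body balance and body rotation. A seeded synthetic-session
generator with aligned ground truth makes every stage testable end to
end.

## How it works

* **Laps.** Swimming keeps trunk pitch inside ±20°; turns push it toward
  ±90° and stops hold it near −90°. Each excursion of |pitch| past 70°
  is an event — a stop when the triggering extremum separation (or
  dwell) is ≥ 3 s, else a turn — with boundaries refined by a sliding
  0.5 s window re-entering the ±20° band. Backstroke bucket/cross-over
  turns that leave no pitch excursion are recovered by flagging lap
  times more than 3 scaled MADs (MAD = median(|xᵢ − median(x)|),
  scaled by 1.4826) from the median and locating the ~180° heading
  reversal inside the flagged lap.
* **Style.** Backstroke is swum supine, so the 0.5 Hz low-passed z
  accelerometer sits near −1 g (rule threshold −0.5 g). The other three
  styles are separated on per-lap channel energies
  E = round(Σ|x(n) − x̄| / N) of the low-passed, m/s²-scaled
  accelerometer axes, by an SVM (polynomial kernel, box constraint 1e5,
  degree 1) or a 3-10-3 neural network trained by gradient descent with
  momentum (α = 0.5, η = 0.3).
* **Strokes.** Front crawl/backstroke: every roll peak (maxima and
  minima) is an arm stroke; peaks must lie outside the band
  mean ± k·sd of the 3 Hz low-passed roll (k = 2 and 2.36) and reach
  20° of rotation. Butterfly/breaststroke: stroke cycles are the
  segments between surviving filtered pitch minima (k = 1.34 and 0.74),
  resampled to 200 samples; each cycle's central 50% is compared by
  dynamic time warping against the mean-wave template and discarded
  beyond a rejection threshold.
* **Accuracy bookkeeping.** Against ground truth, detections match true
  stroke times one-to-one within 0.3 s and accuracy is
  (TP + TN) / (TP + FP + TN + FN), with correctly rejected candidates
  credited as TN.

The methods vignette (`vignettes/methods.Rmd`) explains each stage, its
parameters and defaults, the generator's scope, and the numerical
choices.

## Worked example

Train a style model on generated laps, simulate a six-lap session
(including a pitch-silent bucket turn and a stop), and analyze it:

```r
library(ahrswim)
set.seed(1)
corp_styles <- rep(c("butterfly", "breaststroke", "front_crawl"), each = 20)
feats <- t(vapply(corp_styles, function(st) {
  l <- generate_lap(lap_spec(st), 100, noise_sd_deg = 1.5, noise_sd_g = 0.03)
  extract_features(l$signals[, c("acc_x", "acc_y", "acc_z")], 100)
}, numeric(3)))
model <- train_style_model(feats, corp_styles, kind = "svm")

spec <- session_spec(
  lapply(c("front_crawl", "backstroke", "backstroke", "breaststroke",
           "butterfly", "front_crawl"), lap_spec),
  events = c("tumble", "bucket", "open", "stop", "tumble"), seed = 7)
gs <- generate_session(spec)
report <- analyze_session(gs$session, model)
print(report)
#> <session_report> 6 laps, 5 events
#>  index        style lap_time stroke_count stroke_rate
#>      1  front_crawl    25.70           20    46.69261
#>      2   backstroke    26.00           18    41.53846
#>      3   backstroke    25.90           18    41.69884
#>      4 breaststroke    21.38           10    28.06361
#>      5    butterfly    22.58           14    37.20106
#>      6  front_crawl    25.69           20    46.71078
```

Every lap is delimited, styled and counted as generated (the spec asked
for 20/18/18/10/14/20 strokes). The event log shows the recovered bucket
turn — its apex pitch is only 9°, far below the 70° trigger, so it was
found through the lap-time outlier plus heading reversal:

```r
print(report$events, row.names = FALSE, digits = 4)
#>  kind apex_t start_t  end_t apex_pitch
#>  turn  26.03   25.70  26.30      84.14
#>  turn  52.86   52.30  53.32       9.17
#>  turn  79.49   79.22  80.05     -90.00
#>  stop 102.20  101.43 105.72     -90.00
#>  turn 128.59  128.30 128.90      84.47
```

Indicators follow each style's dominant motion component, e.g. butterfly
trunk elevation (per-cycle pitch range, here a 35°-amplitude undulation
→ ≈ 68° after filtering) and front-crawl body rotation per side
(45° rotation bursts → ≈ ±38° filtered peaks; equal sides mean a
symmetric stroke):

```r
subset(report$style_summary,
       indicator %in% c("body_rotation", "trunk_elevation") &
         style %in% c("front_crawl", "butterfly"))
#>        style       indicator    role     mean     sd n_laps
#>    butterfly trunk_elevation overall  68.3477 0.0000      1
#>    butterfly   body_rotation overall   0.0121 0.0000      1
#>  front_crawl   body_rotation     max  37.6274 0.1269      2
#>  front_crawl   body_rotation     min -37.5982 0.0808      2
```

`write_report(report, "report.json", "report.csv")` serializes the lap
table, event log and per-style aggregates.

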