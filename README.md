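# boneprox

Bone-proximity detection from through-needle viscoelastic probing.

Epidural needle placement is a blind procedure: the clinician steers a
needle between vertebrae toward a 2–7 mm target space, and striking
vertebral bone is a frequent complication. One assistive approach replaces
the needle's stylet with a stiff blunt probe that is briefly actuated
~2 mm beyond the tip as the needle advances in 0.5 mm steps. Each actuation
records a paired force/displacement response of the tissue ahead of the tip
(a *probe event*: 100 samples over 0.25 s at 400 Hz on both channels), and
the viscoelastic character of those responses changes as the soft-tissue
layer over bone thins. `boneprox` is an R implementation and test bench for
the full analysis stack behind that idea, aimed at researchers in
needle-guidance and biomedical signal processing:

* a mechanistic **simulator** of probe events and needle insertions
  (Kelvin–Voigt tissue element with distance-dependent stiffness, ramp-and-
  hold solenoid actuation with a hard stop, Gaussian sensor noise and
  instrument-resolution quantization),
* **feature extraction**: population moments and FFT magnitudes over four
  canonical subsequence windows, composed into four named feature sets,
* **sequence processing**: replicate sampling (one of three probe events
  per depth) and multiprobe compilation (a sliding window of `N`
  consecutive feature vectors),
* three **detectors** — linear SVM, random forest (binary labels:
  within 5 mm of bone or not), and a gradient-boosted regressor of distance
  thresholded at 5 mm — under train/test-split and leave-one-group-out
  regimes, grouped by insertion,
* an **evaluation layer**: sequential first-positive detection depth,
  signed detection error (negative = early, positive = late), average
  error / MAE / RMSE, error histograms, learning curves, a
  perpendicular-vs-parallel directionality protocol, and a closed-form
  random-guess baseline.

The detection rule is sequential: the needle depth of the first probe event
classified as within the 5 mm forewarning margin becomes the detection
depth for the whole insertion, and its signed error is measured against the
threshold depth `bone_strike_depth − 5`.

## Worked example

```r
library(boneprox)

cfg <- simulation_config(seed = 11)       # default mechanics: onset 3.5 mm
ds  <- generate_dataset(cfg, 20)          # 12 train / 4 test / 4 validation
ds
#> <insertion_dataset> 20 insertions (train=12, test=4, validation=4) at 400 Hz

ex <- run_experiment(ds, "subsequence_force_ffts", multiprobe = 3,
                     classifier = "linear_svm", regime = "split", seed = 5)
ex$summary
#> average error 2.09 mm, MAE 2.09 mm, RMSE 2.09 mm (n = 40)

head(ex$results[, c("insertion_id", "sequence", "detection_depth",
                    "threshold_depth", "signed_error")], 4)
#>   insertion_id sequence detection_depth threshold_depth signed_error
#> 1        ins13        1            47.5        45.66116     1.838842
#> 2        ins13        2            48.0        45.66116     2.338842
#> 3        ins13        3            47.5        45.66116     1.838842
#> 4        ins13        4            47.5        45.66116     1.838842

attr(error_histogram(ex$results$signed_error), "mode")
#> [1] 2

random_guess_baseline(40, 0.5, 5)
#> average error -15.00 mm, MAE 15.68 mm, RMSE 19.02 mm (n = 81)
```

Read: on simulated insertions whose stiffness signal only diverges within
~3.5 mm of bone, the SVM detector fires consistently ~2 mm *after* the
needle has passed the 5 mm threshold (equal average error, MAE and RMSE =
high bias, low variance, with the error histogram clustered at +2 mm) —
the detector is reliable but cannot see further than the physics lets it.
Random guessing on a 40 mm insertion would be an order of magnitude worse
(MAE 15.68 mm), which is the floor any useful detector must beat.

A sharp-onset regime, where the stiffness jump coincides exactly with the
5 mm class boundary, is available for parameter-recovery checks:

```r
mech <- mechanical_params(onset_distance = 5, onset_form = "step")
```

and `mechanical_params(delta_k = 0)` gives a distance-blind null generator
for false-positive calibration.

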