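# circlepose

Single-view 3D pose estimation of circular targets with known radius, and
its application to iris-based gaze estimation.

A planar circle of known radius R, seen by one calibrated pinhole camera,
images as an ellipse. `circlepose` recovers the circle's 3D centre and unit
normal from that single view — a staple of monocular metrology (fiducial
localization, calibration targets) and the geometric core of
model-based eye tracking, where the iris is the circle and its normal is
the eyeball's optical axis.

Two estimators are implemented:

* **Closed-form conic back-projection** (`solve_closed_form()`): the image
  conic `a u² + b v² + c uv + d u + e v + f = 0` is lifted to the
  back-projection cone `Q` (`A = a f0², …, F = f`), `Q` is eigendecomposed
  to `λ1 ≥ λ2 > 0 > λ3`, the tilted unit-offset section radius

      r = (1/|λ2|) · sqrt( |λ1||λ3|(|λ2|+|λ3|) / (|λ1|+|λ3|) )

  fixes the scale `S = R/r`, and the two admissible section planes are
  rotated back to the camera frame. One ellipse is always consistent with
  exactly two poses; both are returned.

* **Space-circle least-squares fit** (`solve_circle()`): each edge point
  becomes a viewing ray `i_k`; a candidate pose `(P, n)` intersects the
  rays with the target plane at `t_k = (n·P)/(n·i_k)`, and
  Levenberg–Marquardt minimizes the stacked radius residuals
  `‖p_k − P‖ − R` and coplanarity residuals (triple products of
  consecutive centre-to-edge vectors) over the six pose parameters,
  warm-started from the closed form.

Around the solvers: a constrained direct ellipse fitter, a Monte Carlo
noise bench (`run_sweep()`) comparing both methods under SNR-controlled
Gaussian edge noise, and a gaze layer (`calibrate_user()`,
`point_of_regard()`, `evaluate_gaze()`) that calibrates a user's iris
radius and kappa angle from known fixation targets and intersects the
visual axis with the screen.

## Worked example

The reference scene: a 16 mm camera viewing a circle of radius
6.5726701 mm at centre `(−30.7587037, −99.5438179, 310.8944607)` mm,
16 noise-free edge points.

```r
library(circlepose)
scene <- make_reference_scene()
fit <- solve_circle(scene$points, scene$circle$radius, camera = scene$camera)
fit$solutions[[1]]$circle
#> <circle3d> center (-30.7587, -99.5438, 310.8945) mm,
#>            normal (-0.18061, 0.10860, -0.97754), R = 6.5727 mm
error_metrics(fit$solutions[[1]]$circle, scene$circle)
#>  center_error_mm normal_error_deg
#>     2.388787e-13     0.000000e+00
```

The fitted centre matches the generating pose to machine precision; the
second returned solution is the other branch of the two-fold ambiguity.
Under noise (`add_noise(scene$points, noise_config(60))`) both solvers
degrade gracefully; `run_sweep()` quantifies this over a 100→40 dB SNR
grid with 20 replicates per level and reports mean centre error (mm) and
normal error (degrees) per method.

A synthetic gaze round trip:

```r
calib <- make_gaze_session(calibration_targets())   # 5 fixations
model <- calibrate_user(calib)
model
#> <eye_model> iris radius 5.8000 mm, kappa 5.0000 deg (h 5.0000, v 0.0000)
attr(evaluate_gaze(make_gaze_session(test_targets()), model), "rmse")
#>         x_mm         y_mm        x_deg        y_deg
#> 1.982856e-09 1.572716e-09 2.454932e-10 1.956322e-10
```

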