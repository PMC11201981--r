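# thermoscreen

Inverse thermal modeling for breast cancer screening from infrared surface
temperatures, exercised end to end on synthetic breast phantoms.

Malignant breast tumors are metabolically hyperactive and well perfused, so
they behave as interior heat sources whose faint imprint reaches the skin.
`thermoscreen` implements the computational core of a screening approach
built on that physics:

* **Forward model** — steady-state Pennes bioheat equation
  ∇·(k∇T) + ω_b ρ_b c_b (T_a − T) + q_m + q_t = 0 on a voxelized
  hemispherical breast phantom (fat / gland / tumor / chest wall),
  discretized with a conservative cell-centered finite-volume scheme:
  harmonic-mean face conductivities, convective + linearized radiative skin
  boundary, isothermal chest wall, compiled conjugate-gradient solver.
* **Tumor source** — the empirical size-dependent relation
  q_t(D) = C₁ / (C₂ ln(100 D) + C₃) (C₁ = 3.27×10⁶ W m⁻³, C₂ = 468.5,
  C₃ = 50; q_t(1 cm) = 65,400 W m⁻³), applied uniformly over tumor voxels
  and re-evaluated whenever the candidate diameter changes.
* **Observation model** — skin-surface node temperatures, an 8-view
  infrared rendering at 45° azimuth steps around the pendant breast, and
  additive Gaussian camera noise at the camera's 0.02 °C thermal
  sensitivity.
* **Inverse fit** — Levenberg–Marquardt estimation of θ = (x_c, y_c, z_c, D)
  from observed surface temperatures via repeated forward solves
  (δ = −(JᵀJ + λ diag JᵀJ)⁻¹ Jᵀr), starting from a 1.8 cm tumor at the
  breast centroid, followed by a presence/absence decision: a fit that
  parks the source outside the breast, at the chest wall, below the voxel
  scale, or below the camera-noise floor is classified *absent*.
* **Validation** — a packaged 25-tumor clinical cohort table (reference
  statistics), and a reproducible synthetic batch pipeline reporting size
  and location errors, sensitivity, and specificity.

The methods vignette (`vignettes/inverse-thermal-screening.Rmd`) documents
the model, its assumptions, every default, and the validation design.

## Worked example

Simulate a breast with a 15 mm tumor, observe it with camera noise, and
invert:

```r
library(thermoscreen)

phantom <- build_hemisphere_phantom(breast_radius = 0.07, voxel_size = 0.0025)
geom    <- discretize_phantom(phantom)
truth   <- tumor_params(center = c(0.012, -0.018, 0.028), diameter = 0.015)

observed <- forward_model(truth, phantom, geom = geom)
observed <- add_camera_noise(observed, noise_model(sigma = 0.02, seed = 42))

fit <- lma_fit(observed, phantom, geom = geom)
classify_detection(fit, phantom, noise_sigma = 0.02)
#> <inverse_result> tumor PRESENT after 7 iterations (ftol)
#>   theta_hat: center (12.0, -17.7, 27.1) mm, D 15.8 mm
#>   residual RMS 0.0201 degC (tumor-free model 0.0274 degC)
#>   decision: in-breast
```

The fitted center is 0.9 mm from the truth and the diameter is within
0.8 mm; the residual RMS has dropped to the camera-noise level, which is
what a correctly recovered source looks like. The full batch pipeline:

```r
report <- run_batch(default_run_config(seed = 1))
report
#> <validation_report> 10 tumor-bearing + 10 tumor-free cases
#>   sensitivity 100%, specificity 100%
#>   size error: max 3.3 mm, mean 0.6 mm
#>   location error: max 1.9 mm, mean 0.5 mm
```

Every tumor (diameters 8–25 mm, depths 10–40 mm) is found, no tumor-free
phantom triggers a false positive, and the recovered sizes and centers stay
within millimeters of the truth despite 0.02 °C noise.

The cohort fixture:

```r
summarize_cohort(load_cohort_table())
#> <cohort_summary> 25 tumor rows (statistics are per tumor, not per patient)
#>   age: median 67, range 42-72
#>   density: PF=2 SF=17 HD=5 ED=1
#>   ...
```

A thin command-line front end (`inst/cli/thermoscreen.R`) exposes
`simulate`, `invert`, `run-case`, `run-batch`, and `cohort-stats`
subcommands over the same functions, with YAML configs and seeded outputs.

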