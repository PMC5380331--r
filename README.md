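# hscadhesion

Quantitative adhesion analytics for human hematopoietic stem and progenitor
cells (HSC) on ligand-functionalized supported lipid membranes.

## The problem

How strongly do stem cells bind their bone-marrow niche, and through which
molecular axis? Supported membranes presenting a chemokine (SDF1α, binding
the receptor CXCR4) or a homophilic adhesion molecule (N-cadherin) at a
controlled mean lateral spacing `<d>` turn that question into dose–response
measurements. This package implements the full quantitative tool chain such
experiments need, for experimentalists and image analysts working with
supported-membrane niche models:

1. **Ligand spacing model.** Anchor lipids at molar fraction `x` in a matrix
   of area `A_lipid ≈ 65 Å²` per lipid give a mean ligand spacing
   `d = sqrt(A_lipid / x)` (`mean_ligand_spacing()` /
   `spacing_to_fraction()`).
2. **Hill unbinding transition.** The fraction of adherent cells χ (or the
   tight-adhesion area `A_adh`) vs spacing follows the decreasing empirical
   Hill curve

   χ(d) = χ_min + (χ_max − χ_min) / (1 + (d/d\*)^n),

   with critical distance `d*` and cooperativity coefficient `n`
   (`hill_evaluate()`, `hill_fit()`).
3. **RICM height reconstruction.** Reflection interference contrast
   microscopy encodes the membrane–substrate separation `h` in the fringe
   intensity; a scalar two-beam model with a finite illumination numerical
   aperture (INA),

   I(h)/I_bg = 1 + V₀ · sinc(φ(1−c)/2) · cos(φ(1+c)/2 + π),
   φ = 4π n₃ h / λ,  c = cos(asin(INA/n₃)),

   is inverted on its first monotone branch to give per-pixel heights; the
   *area of tight adhesion* counts pixels with low, stable separation
   (`forward_intensity()`, `reconstruct_height()`, `tight_adhesion_area()`).
4. **Pressure-wave detachment.** A picosecond-laser pressure wave detaches
   adherent cells; the calibration `P ∝ E_pulse^0.47` links pulse energy to
   pressure, and the critical pressure `P*` detaching 50% of cells is
   estimated by a binomial logistic dose–response fit with bootstrap CI
   (`fit_calibration()`, `estimate_critical_pressure()`).
5. **Contour-fluctuation spectroscopy.** Cell contours from phase-contrast
   time-lapse are resampled into amplitude maps `r(θ, t)` in the
   center-of-mass frame; their spatio-temporal autocorrelation `Γ(Δθ, Δt)`
   and angular Fourier mode powers `P_m = ⟨|c_m|²⟩` quantify how cells
   dissipate energy through shape deformation, and a three-way classifier
   labels the motion rotational / oscillatory / translational
   (`amplitude_map()`, `autocorrelation_map()`, `mode_power_spectrum()`,
   `classify_motion()`).

Seeded synthetic generators (`make_*()`, `render_phase_contrast()`,
`make_ricm_scene()`) emulate every raw input with known ground truth, so the
whole pipeline is testable without microscopy data.

## Worked example

```r
library(hscadhesion)

# Anchor molar fraction needed for an 11 nm mean ligand spacing
spacing_to_fraction(11)
#> [1] 0.005371901

# Simulate a 50-cells-per-spacing adhesion assay and refit the Hill curve
tab <- make_adhesion_counts(d_values = c(6, 11, 18, 27, 34, 50),
                            chi_min = 0, chi_max = 100, d_star = 27,
                            n_coop = 3, n_cells = 50, seed = 42)
hill_fit(tab)
#> <hill_fit> (fraction) chi_min = 0.00, chi_max = 95.44,
#>            d* = 29.40 nm (SE 3.13), n = 3.22 (SE 0.78)

# Critical detachment pressure from a simulated pressure-escalation assay
P <- exp(seq(log(2), log(20), length.out = 7))
det <- make_detachment_data(P, p_star = 7, slope = 8, n_cells = 50, seed = 42)
estimate_critical_pressure(det, seed = 1)
#> <detachment_curve> P* = 6.91 MPa [6.51, 7.36] (logistic fit, 7 pressures)

# Shape-fluctuation spectroscopy of a synthetic oscillatory cell
cs <- make_contour_series(motion_params("oscillatory", seed = 42))
am <- amplitude_map(cs)
mode_power_spectrum(am)
#> <mode_spectrum> m = 0..10, dominant m = 2, total P(m=2..10) = 0.2509 um^2
classify_motion(am)
#> <motion_class> oscillatory (m2 frac 1.00, periodicity 0.89, drift 0.004)
```

Reading the numbers: the refitted critical distance (29.4 ± 3.1 nm) and
cooperativity (3.2 ± 0.8) recover the generating truth (27 nm, 3) within
error from only 50 cells per spacing; the estimated `P*` brackets the true
7 MPa median; the dominant deformation mode `m = 2` with an alternating-axis
periodicity score of 0.89 is the signature of oscillatory pseudopod
extension.

## End-to-end pipeline

```r
cfg <- pipeline_config(seed = 7, outdir = "out",
                       optics = optical_model(pixel_size = 0.1),
                       scene = scene_params(pixel_size = 0.1,
                                            photon_budget = 1e4))
run_pipeline("simulate", cfg)  # contours, RICM stack, count tables (text files)
run_pipeline("ricm", cfg)      # height map + tight-adhesion area
run_pipeline("modes", cfg)     # amplitude maps, spectra, motion labels
run_pipeline("hill", cfg)      # Hill fit of the simulated counts
run_pipeline("detach", cfg)    # calibration + P*
run_pipeline("report", cfg)    # per-class summary CSV
```

A command-line wrapper with `--config/--seed/--input/--outdir/--log-level`
flags lives at `inst/cli/hscadhesion-cli.R`. All artifacts are plain text
(PGM image stacks, CSV tables, JSON fits) and every JSON output embeds
provenance (config hash, seed, package version).

## Documentation

The methods vignette (`vignettes/hscadhesion-methods.Rmd`) describes the
models, their assumptions, the synthetic-data generators, numerical choices
and known limitations.
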