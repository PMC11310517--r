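# micellr

Quantitative analysis of small charged micelles — lipopeptide and
surfactant aggregates a few nanometres across — treated as model charged
colloids. The package turns three routine bench measurements into physical
numbers:

* **Absolute-intensity SAXS curves** are fitted with a polydisperse
  core-shell sphere form factor times the Hayter–Penfold rescaled-MSA
  (RMSA) structure factor for screened-Coulomb repulsion,
  `I(q) = P(q) S(q) + BG`. From the fit come the core and shell radii,
  the hard-sphere radius R_HS, effective volume fraction φ, effective
  charge z_eff and ionic strength I.
* **Electrostatics** are derived from the structure-factor parameters: the
  Debye length κ⁻¹ = √(ε_r ε₀ k_B T / 2e²I), the surface (zeta) potential
  ψ₀ = z_eff e / [π ε_r ε₀ σ (2 + κσ)] (with its unscreened κ→0 variant —
  both are reported), and inter-micellar Yukawa potential-energy curves
  U(r) = π ε₀ ε_r σ² ψ₀² exp(−κ(r−σ))/r with contact values in k_BT.
* **Micelle molar mass and association number** come from the absolute
  forward intensity, M_mic = I(0) N_A / (c [r₀ v_p (ρ_l − ρ₀)]²), and
  independently from the head-group area, p = 4πR_i²/A.
* **Surface-tension and conductivity dilution series** give the critical
  micelle concentration from two-segment breakpoint fits, plus the surface
  excess Γ = −(dγ/dlog₁₀c)/(RT) and area per molecule A = 1/(Γ N_A).

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`, `glance()`, `augment()` and `autoplot()` methods. A numerical
Ornstein–Zernike reference solver and ground-truth synthetic-data
generators for every stage make the whole chain testable end to end. The
methods vignette (`vignettes/micelle-saxs-analysis.Rmd`) documents the
models, conventions and numerical choices.

## Worked example

Simulate a realistic 0.5 wt% charged-micelle measurement, fit it, and
derive the physical quantities:

```r
library(micellr)

tr    <- default_micelle_truth()          # 0.5 wt% lipopeptide-like micelle
curve <- simulate_saxs(tr$form, tr$yukawa, seed = 42, concentration = 0.5)
fit   <- fit_saxs(curve)
fit
#> <SAXS core-shell x S(q)[hp] fit: synthetic>
#>   200 points, reduced chi-square 0.984, converged
#>    r_core=14.23, r_outer=26.43, sigma_r=4.452, mu=-1.553, eta=0.1184,
#>    bg=0.0003538, r_hs=74.21, phi=0.05141, z_eff=14.96, ionic_strength=0.005205
```

The fit recovers the generating geometry (true R_i = 14.08 Å,
R_o = 26.59 Å) within a percent and the charge state within a few percent.
Electrostatics from the fitted structure factor:

```r
yk <- fit$yukawa
debye_length(yk$ionic_strength)                                   # 42.2 A
surface_potential(yk$z_eff, 2*yk$r_hs, screened = FALSE)          # 36.2 mV
surface_potential(yk$z_eff, 2*yk$r_hs,
                  debye_kappa(yk$ionic_strength), screened = TRUE) # 13.1 mV
contact_potential(yk)                                             # 10.7 kBT
```

The unscreened surface potential (≈36 mV) is the number comparable to
measured zeta potentials; the contact repulsion of ~11 k_BT is typical for
highly charged micelles. Mass and association number from the forward
intensity (0.5 wt% = 0.005 g cm⁻³; palmitoyl-tail electron densities):

```r
i0 <- form_factor_intensity(0, fit$form)   # 0.0896 cm^-1
micelle_mass(i0, c_mic = 0.005, v_p = 1.15, rho_l = 0.299,
             rho_0 = 0.333, m_mol = 675.4)
#> # A tibble: 1 x 2
#>    m_mic     p
#>    <dbl> <dbl>
#> 1 88942.  132.
```

CMC and area per molecule from a simulated tensiometry series, and the
geometric association-number cross-check:

```r
ten <- analyze_series(simulate_tension(seed = 7), m_mol = 675.4)
ten
#> <CMC analysis (tension series, 20 points)>
#>   CMC: 0.03948 wt% (0.000585 M)
#>   gamma0: 48.455 mN/m | Gamma: 4.9e-06 mol/m^2 | A: 33.9 A^2
association_from_area(fit$estimate[["r_core"]], ten$area)   # 75.2
```

`run_pipeline()` chains all of this over a set of curve files and series
and writes CSV/JSON reports; `inst/cli/micellr-cli.R` wraps the same
functions for shell use.

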