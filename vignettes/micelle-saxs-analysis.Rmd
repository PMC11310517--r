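---
title: "Models and methods: micelle structure and interactions from SAXS, tension and conductivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: micelle structure and interactions from SAXS, tension and conductivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellr)
```

micellr analyses small, charged, spherical micelles — lipopeptide or
surfactant aggregates tens of Angstrom across — as model charged colloids.
This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices behind the implementation, and
what the simulation-based tests do and do not demonstrate.

## The scattering model

Absolute-intensity small-angle X-ray scattering from an isotropic solution
of centrosymmetric particles is modelled in the monodisperse approximation

$$I(q) = P(q)\,S(q) + \mathrm{BG},$$

where $P(q)$ is the single-particle (form-factor) intensity, $S(q)$ the
inter-particle structure factor, and BG a flat background. The
factorisation is exact only for identical particles; we retain it even with
a polydisperse form factor, deliberately, because micelle structure changes
with concentration and a decoupling correction would add parameters the
data cannot constrain. This is a known approximation, not an oversight.

### Core-shell sphere form factor

A micelle is modelled as a dense alkyl core (radius $R_i$) inside a
hydrated head-group shell (outer radius $R_o$), each with a uniform excess
scattering contrast. The amplitude is

$$F(q) = V_o\,\Delta\rho_{sh}\,\Phi(qR_o) + V_i\,(\Delta\rho_c -
\Delta\rho_{sh})\,\Phi(qR_i), \qquad
\Phi(x) = \frac{3(\sin x - x\cos x)}{x^3},$$

with $V = 4\pi R^3/3$. Internally the shell contrast is fixed at 1 and the
core contrast at $\mu$ (typically negative for an alkyl core in water,
since the core is electron-poorer than water while the hydrated peptide
shell is electron-richer). $\Phi$ is evaluated by series expansion below
$x = 10^{-2}$, so $q = 0$ is a legal grid point — needed to extrapolate the
forward intensity $I(0)$ used for molar-mass determination.

**Polydispersity.** Only the outer radius is polydisperse: a Gaussian with
standard deviation $\sigma_R$, truncated to
$[\max(R_i + 0.1, R_o - 4\sigma_R),\, R_o + 4\sigma_R]$ and renormalised,
with $R_i$ held fixed. One size distribution on $R_o$ matches the
parameter count of the standard analysis of such data; widths that would
put more than 1% of the distribution below the core radius are rejected as
unphysical. The average of $|F|^2$ is computed by fixed-order
Gauss–Legendre quadrature (64 points by default, order configurable). The
quadrature is effectively exact here: doubling the order changes the result
at the $10^{-14}$ level, and a $5\times 10^4$-point trapezoid oracle agrees
to better than $10^{-6}$ relative.

**Intensity scale.** The reported scale $\eta$ multiplies
$\langle |F(q)|^2 \rangle / V_o^2$, so it lumps (contrast $\times$
volume)$^2$ and number density into a single cm$^{-1}$-bearing parameter.
Published parameter tables for such fits rarely state their scale
convention; ours is documented and round-trip consistent (simulate with
$\eta$, fit, recover $\eta$), and the synthetic defaults choose $\eta$ so
the absolute forward intensity sits at the measured order of magnitude
(a few times $10^{-2}$ cm$^{-1}$ at 0.5 wt%), far above typical
backgrounds ($\sim 10^{-4}$ cm$^{-1}$).

### Structure factor: charged spheres in the rescaled MSA

Charged micelles repel through a screened-Coulomb (one-Yukawa) potential
acting outside a hard core of diameter $\sigma = 2R_{HS}$:

$$\beta U(r) = \gamma_0\,\frac{\sigma}{r}\,e^{-\kappa(r-\sigma)},
\qquad \gamma_0 = \frac{\pi\varepsilon_0\varepsilon_r\sigma\psi_0^2}{k_BT},$$

with $\psi_0$ the surface potential and $\kappa$ the Debye–Hückel inverse
screening length. The structure factor is the analytic mean-spherical
approximation (MSA) solution for this fluid with the Hansen–Hayter
rescaling: whenever the raw MSA produces a negative pair-correlation value
at contact (unphysical; it happens at low volume fraction and strong
charge), the hard-core diameter is enlarged until $g(\sigma^+) = 0$, and
the structure factor of the rescaled fluid is evaluated on the original
$q$ grid. This is the standard RMSA treatment of charged colloids.

**How the analytic solution is computed.** We solve the one-Yukawa MSA via
the Baxter–Wiener–Hopf factorisation of the Ornstein–Zernike equation
(the factorisation route; it yields the same solution as the original
rescaled-MSA algebra for charged spheres). The factor function is

$$q(t) = \tfrac{a}{2}t^2 + bt + c_0 + C\,e^{-kt} \;(0<t<1), \qquad
q(t) = D\,e^{-kt} \;(t>1),$$

in reduced units ($\sigma = 1$, $k = \kappa\sigma$). Substituting this
ansatz into the factorised equations and matching terms produces six
algebraic residual equations in $(a, b, c_0, C, D, H)$, where $H$ is the
Yukawa moment of the outside pair correlation that closes the system. The
equations were derived symbolically and frozen into the package; at zero
coupling they are solved exactly by the Percus–Yevick hard-sphere
coefficients, which anchors the branch. The small system is solved by
damped Newton iteration with continuation in $\gamma_0$ from the
hard-sphere limit — continuation is what selects the physical root, since
the polynomial system has spurious branches at strong coupling. The
structure factor follows in closed form,
$S(Q) = |\hat Q(Q)|^{-2}$ with $\hat Q(Q) = 1 - 12\eta\int_0^\infty
q(t)e^{iQt}\,dt$ elementary, which also guarantees $S > 0$ everywhere. For
$Q < 0.05$ the transform is evaluated by a moment series to avoid
catastrophic cancellation; scaled variables ($De^{-k}$, $He^{k}$) keep the
algebra stable at strong screening. The contact value has the closed form
$g(1^+) = a + b - k(Ce^{-k} - De^{-k})$, and the rescaling factor is found
by bisection on $s \in (s_{\min}, 1]$ with a $|g| < 10^{-6}$ stopping rule.

**Validation strategy.** Two independent routes check the analytic
solution. At zero charge it must coincide with the Wertheim closed form of
the Percus–Yevick hard-sphere structure factor (it does, to $10^{-9}$).
At finite charge it is compared with a brute-force numerical
Ornstein–Zernike solver (`oz_msa_reference_reduced()`): Picard iteration of
the MSA closure on a $2^{12}$-point radial grid extending 40 diameters,
with spherical Fourier transforms done by fast sine transform. Three
details matter for the oracle's quality: the hard-core boundary is placed
halfway between grid points (second-order accuracy across the
discontinuity; a factor ~50 in accuracy), the fixed-point iteration is
stabilised by Anderson (DIIS) mixing with history depth 3, and the Yukawa
coupling is ramped in steps of at most one $k_BT$ at contact with warm
starts. The ramping is essential: plain Picard iteration at strong coupling
converges onto spurious fixed points of the discretised equations (with
unphysical structure-factor peaks), which continuation avoids. Analytic and
numerical solutions agree to a few times $10^{-4}$ across a
$3\times3\times3$ grid of volume fraction, screening and coupling spanning
$\phi \le 0.16$, $k \le 10$, $\gamma_0 \le 50$.

The volume-fraction domain is capped at 0.64 (random close packing);
micellar fits live far below this.

## Electrostatic quantities

The Debye length is
$\kappa^{-1} = \sqrt{\varepsilon_r\varepsilon_0k_BT/(2e^2I)}$ with the
ionic strength converted to a number density; the default solvent
permittivity is the empirical pure-water value (80.1 at 293 K),
overridable. The surface potential from the effective charge comes in two
conventions, both first-class:

* screened: $\psi_0 = z_{\mathrm{eff}}e\,/\,[\pi\varepsilon_r\varepsilon_0
  \sigma(2 + \kappa\sigma)]$;
* unscreened ($\kappa \to 0$): $\psi_0 = z_{\mathrm{eff}}e\,/\,
  (2\pi\varepsilon_r\varepsilon_0\sigma)$.

For a typical dilute micelle fit ($z_{\mathrm{eff}} \approx 15$,
$\sigma \approx 145$ Å, $\kappa^{-1} \approx 43$ Å) the two differ by
almost a factor of three (37 mV versus 13.7 mV), and the unscreened value
is the one that matches independently measured zeta potentials. Reports
therefore print both rather than silently choosing. The inter-micellar
pair potential uses the dimensionally consistent one-Yukawa form with
$\sigma^2/r$ (contact value $\pi\varepsilon_0\varepsilon_r\sigma\psi_0^2$);
a superficially similar form with a single power of $\sigma$ circulates in
the applied literature but does not carry energy units. Contact potentials
for micellar parameters land in the tens of $k_BT$, consistent with
measured values for charged colloids once the high micellar charge is
accounted for.

`effective_charge_from_potential()` is the exact algebraic inverse of
`surface_potential()`, and the tests enforce the round trip at $10^{-10}$.

## Molar mass and association number

Absolute forward scattering gives a model-independent micelle molar mass,

$$M_{mic} = \frac{I(0)\,N_A}{c_{mic}\,[r_0 v_p(\rho_l - \rho_0)]^2},$$

with $r_0$ the classical electron radius, $v_p$ the partial specific
volume, and $\rho_l$, $\rho_0$ the solute and water electron densities
(e Å$^{-3}$, converted internally to e cm$^{-3}$). $I(0)$ is taken from
the fitted form factor evaluated at $q = 0$, never from a Guinier
extrapolation — the structure factor contaminates the measured low-$q$
region, while the fitted $P(0)$ is immune. The micelle concentration
defaults to the total surfactant concentration; subtracting the CMC is an
option. Near contrast match ($|\rho_l - \rho_0| < 10^{-4}$) the inversion
is refused.

Electron densities can be built from the Tanford alkyl-chain volume
$v = 27.4 + 26.9\,n$ Å$^3$ ($n$ = chain carbons excluding the terminal
methyl; $n = 15$ for palmitoyl gives 430.9 Å$^3$ and, with 129 tail
electrons, 0.299 e Å$^{-3}$).

A second, geometric route divides the core surface area by the area per
head group from tensiometry: $p = 4\pi R_i^2/A$. The two routes agreeing
within ~15% is the expected level of consistency given the approximations
in each. Finally, the position $q_{max}$ of the secondary form-factor
maximum gives a Bragg-like head-group separation $d = 2\pi/q_{max}$, which
is compared with (not judged against) the model's mid-shell diameter
$R_i + R_o$. The extended C16 chain length 17.6 Å is stored as a
documented constant for core-radius comparisons; no formula for it is
implemented.

## CMC, surface excess and area per molecule

Surface-tension series are fitted on a $\log_{10}$ concentration abscissa,
conductivity series on a linear one, both with a continuous two-segment
piecewise-linear least-squares model: candidate breakpoints are scanned
over interior grid positions (at least three points per side) and refined
by golden-section search. If the two-segment model improves the
residual sum of squares over a single line by less than 5% (configurable),
the series is flagged "no breakpoint" — this also catches exactly linear or
constant data, whose SSE ratio would otherwise be 0/0.

The surface excess uses the adsorption-isotherm slope convention exactly as
conventionally printed: $\Gamma = -(\partial\gamma/\partial\log_{10}c)/(nRT)$
with the slope per decade and prefactor $n = 1$. Both the $\ln 10$
conversion and the ionic prefactor $n = 2$ are available as explicit
switches, because the literature is genuinely inconsistent about both; the
default reproduces the numbers this analysis chain is meant to reproduce.
The area per molecule is $A = 1/(\Gamma N_A)$. A $-12.4$ mN m$^{-1}$ per
decade slope at 293 K gives $\Gamma = 5.09\times10^{-6}$ mol m$^{-2}$ and
$A = 32.7$ Å$^2$ — the self-consistency anchor used in the tests.
Weight-percent concentrations are converted to molar assuming a dilute
solution density of 1 g cm$^{-3}$.

## The synthetic-data generators

Every pipeline stage has a ground-truth generator, and all simulation tests
run against them.

* `simulate_saxs()` adds Gaussian noise with a photon-counting-like
  standard deviation $s(q) = a\sqrt{I(q) + b}/\mathrm{exposure}$ (default
  $a$: 1% of the root forward intensity). A `"relative"` noise model
  ($s = a\,I$) is available; "1% noise" in the recovery tests means 1%
  relative. Generators are pure functions of (truth, seed).
* The default truth is a dilute (0.5 wt%) charged micelle: $R_i = 14.08$,
  $R_o = 26.59 \pm 4.42$, $\mu = -1.614$, $R_{HS} = 72.37$ Å,
  $\phi = 0.048$, $z_{\mathrm{eff}} = 14.7$, $I = 4.9$ mM at 293 K —
  realistic parameter scales for lipopeptide micelles.
* `simulate_concentration_series()` applies monotone trends around the base
  truth: $R_o$ grows by 2 Å per decade of concentration, $\eta$, BG and
  $\phi$ grow proportionally to concentration, $R_{HS}$ shrinks as
  $c^{-1/4}$, $z_{\mathrm{eff}}$ stays constant. $\phi$ is capped at 0.35:
  naive proportional extrapolation would exceed both the model's validity
  domain and anything real micellar systems show (their effective volume
  fractions grow sublinearly). The structure factor is applied only at and
  above 0.5 wt%, mirroring how dilution series of this kind are modelled.
* Tension and conductivity generators produce exact piecewise-linear truth
  plus Gaussian noise; default grids are 20 log-spaced (tension) and 18
  linear (conductivity) points — typical dilution-series sizes, dense
  enough that the breakpoint is localisable at the stated noise levels.

What the generators do **not** emulate: instrument smearing, detector
geometry, buffer-subtraction artefacts, concentration-dependent micelle
shape change beyond the smooth trends above, or inter-micellar attraction.
Passing recovery tests therefore demonstrate the estimators are correct and
well-conditioned for ideal data of realistic scale and noise — not that
every real curve will fit.

## Fitting and identifiability

Single-curve fits are bounded weighted least squares
(Levenberg–Marquardt) with weights from the measured uncertainties, or
$\sqrt{I}$ as a photon-counting proxy when absent. Default bounds span the
micellar regime with margin ($R_i \in (5, 30)$, $R_o \in (7, 60)$,
$\phi < 0.4$, $z_{\mathrm{eff}} < 300$, $I \in (10^{-4}, 0.5)$ M);
parameters pinned at a bound are flagged, not failed. Fits are
deterministic given curve, initial values and the logged multi-start seed.
Optional multi-start jitters the structure-factor parameters log-uniformly
within a factor of $10^{0.4}$; series fits use six starts for the
concentrated curves because the structure-factor likelihood surface has
genuine local minima when the initial guess is far off.

Series fitting is staged: dilute curves (below 0.5 wt%) are fitted form
factor only; the medians of their form parameters — with the intensity
scale and background scaled proportionally to concentration — seed the
concentrated fits; all parameters remain free per curve (no global tying).

**Identifiability.** At 1% noise the core-shell geometry is sharply
determined (worst-seed errors below 3% for $R_i$, $R_o$). The
structure-factor trio $(R_{HS}, \phi, z_{\mathrm{eff}})$ is different: at
weak structure ($\phi \approx 0.05$) it is nearly degenerate — the fitted
deviance at the wrong $\phi$ is *lower* than at the truth, so this is an
information limit of a single curve, not an optimiser failure. Recovery of
the packing and charge parameters is therefore quantified where the
structure factor carries signal (a 2 wt%-like condition) and summarised as
bias and root-mean-square error over 20 seeds ($\phi$ RMSE ~5%,
$z_{\mathrm{eff}}$ RMSE ~3% there). Practitioners who know the salt
content and micellar charge should fix `ionic_strength` and `z_eff`, which
makes every remaining parameter tightly identifiable.

The model-comparison helper fits the same curve with the charged RMSA and
with the uncharged Percus–Yevick hard-sphere structure factor from the same
start. On charged data the hard-sphere model loses, and — the classic
diagnostic — drags its volume fraction toward crystallisation/jamming
values to mimic charge repulsion; fitted $\phi > 0.55$ raises an explicit
"unphysical" flag.

## Numerical sizes used by the test suite

Simulation tests use 200-point $q$ grids on $[0.005, 0.35]$ Å$^{-1}$,
20-seed repetitions for recovery statistics, 100 replicates for noise
variance checks, $5\times10^4$-point trapezoid and $2^{12}$-point OZ-grid
oracles; these sizes make every oracle at least an order of magnitude more
accurate than the tolerance it guards.

## Known limitations

* The monodisperse approximation $I = PS$ with a polydisperse $P$ (no
  decoupling correction), as discussed above.
* One-Yukawa repulsion only: no van der Waals attraction, charge
  regulation, or two-Yukawa potentials.
* The wt% to molar conversion assumes density 1 g cm$^{-3}$.
* The screened/unscreened surface-potential discrepancy is surfaced, not
  resolved; which convention matches zeta potentials is an empirical
  question, and both are reported.
* Ionic strength is a fit parameter, not computed from counterion
  stoichiometry; whether counterions released on micellisation contribute
  is left to the user's modelling judgement.
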