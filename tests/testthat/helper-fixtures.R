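# shared ground truths for simulation-based tests

# dilute (0.5 wt%) charged-micelle condition: the package default
p1_truth_vec <- function() {
  c(r_core = 14.08, r_outer = 26.59, sigma_r = 4.42, mu = -1.614,
    eta = 0.118, bg = 3.695e-4,
    r_hs = 72.37, phi = 0.0483, z_eff = 14.73, ionic_strength = 0.0049)
}

# concentrated (2 wt%-like) condition with a strong structure factor
conc_truth <- function() {
  list(form = core_shell_params(14.60, 28.41, 3.99, -1.460, 0.472, 1.266e-3),
       yukawa = yukawa_params(46.07, 0.0700, 34.80, 0.0198),
       vec = c(r_core = 14.60, r_outer = 28.41, sigma_r = 3.99, mu = -1.460,
               eta = 0.472, bg = 1.266e-3,
               r_hs = 46.07, phi = 0.0700, z_eff = 34.80,
               ionic_strength = 0.0198),
       concentration = 2)
}

# one noisy curve at 1% relative noise under a given seed
relative_noise_curve <- function(truth, seed, concentration) {
  simulate_saxs(truth$form, truth$yukawa, noise_model = "relative",
                noise_a = 0.01, seed = seed, concentration = concentration)
}
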