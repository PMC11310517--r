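#' Locate the secondary maximum of a fitted form factor
#'
#' Finds the position of the secondary (post-minimum) maximum of the
#' form-factor intensity on a fine grid, the feature whose Bragg-like
#' spacing `2 pi / q_max` tracks the nearest head-group separation.
#'
#' @param form A [core_shell_params()] block.
#' @param q_window Search window in inverse Angstrom.
#' @param n Grid resolution.
#' @return `q_max` in inverse Angstrom (`NA` if no interior maximum).
#' @export
secondary_maximum <- function(form, q_window = c(0.05, 0.35), n = 2000) {
  q <- seq(q_window[1], q_window[2], length.out = n)
  p <- form_factor_intensity(q, form)
  i_min <- which.min(p[seq_len(n %/% 2)])  # first deep minimum
  after <- seq(i_min, n)
  i_max <- after[which.max(p[after])]
  if (i_max %in% c(i_min, n)) return(NA_real_)
  q[i_max]
}

.derived_row <- function(fit, m_mol, v_p, rho_l, rho_0, c_cmc = NA_real_,
                         subtract_cmc = FALSE) {
  conc <- attr(fit$curve, "concentration")
  id <- attr(fit$curve, "sample_id")
  yk <- fit$yukawa
  form <- fit$form
  i0 <- form_factor_intensity(0, form)
  c_eff <- conc
  if (subtract_cmc && !is.na(c_cmc)) c_eff <- max(conc - c_cmc, 0)
  mm <- if (!is.na(c_eff) && c_eff > 0)
    micelle_mass(i0, c_eff / 100, v_p, rho_l, rho_0, m_mol)
  else tibble::tibble(m_mic = NA_real_, p = NA_real_)
  q_max <- secondary_maximum(form)
  hg <- headgroup_separation(if (is.na(q_max)) 0.172 else q_max,
                             form$r_core, form$r_outer)
  row <- tibble::tibble(
    sample_id = id, concentration_wtpct = conc,
    i0_cm1 = i0, m_mic_gmol = mm$m_mic, p_forward = mm$p,
    q_secondary_max_invA = q_max,
    d_bragg_A = hg$d_bragg, d_model_A = hg$d_model
  )
  if (!is.null(yk)) {
    sigma <- 2 * yk$r_hs
    kinv <- debye_length(yk$ionic_strength, yk$temperature, yk$eps_r)
    psi_scr <- surface_potential(yk$z_eff, sigma, 1 / kinv, yk$eps_r, TRUE)
    psi_unscr <- surface_potential(yk$z_eff, sigma, 0, yk$eps_r, FALSE)
    row <- dplyr::bind_cols(row, tibble::tibble(
      kappa_inv_A = kinv, psi0_screened_mV = psi_scr,
      psi0_unscreened_mV = psi_unscr, z_eff = yk$z_eff,
      u0_kT = contact_potential(yk, screened = FALSE),
      s0 = as.numeric(sq_hayter_penfold(1e-5, yk))
    ))
  } else {
    row <- dplyr::bind_cols(row, tibble::tibble(
      kappa_inv_A = NA_real_, psi0_screened_mV = NA_real_,
      psi0_unscreened_mV = NA_real_, z_eff = NA_real_,
      u0_kT = NA_real_, s0 = NA_real_
    ))
  }
  row
}

.params_row <- function(fit) {
  est <- fit$estimate
  all_names <- c("r_core", "r_outer", "sigma_r", "mu", "eta", "bg",
                 "r_hs", "phi", "z_eff", "ionic_strength")
  vals <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
  vals[names(est)] <- est
  tibble::tibble(
    sample_id = attr(fit$curve, "sample_id"),
    concentration_wtpct = attr(fit$curve, "concentration"),
    r_core_A = vals[["r_core"]], r_outer_A = vals[["r_outer"]],
    sigma_r_A = vals[["sigma_r"]], mu = vals[["mu"]],
    eta_cm1 = vals[["eta"]], bg_cm1 = vals[["bg"]],
    r_hs_A = vals[["r_hs"]], phi = vals[["phi"]],
    z_eff = vals[["z_eff"]], ionic_strength_M = vals[["ionic_strength"]],
    redchi2 = fit$redchi2, converged = fit$converged
  )
}

#' Run the full micelle-analysis pipeline
#'
#' Orchestrates the end-to-end chain on a set of SAXS curve files and
#' optional tensiometry series: staged series fitting, electrostatic
#' derivations (Debye length, both surface-potential conventions, contact
#' potential, forward-scattering suppression), micelle molar mass and
#' association number, head-group-separation comparison, and CMC analyses.
#' Per-sample failures are isolated and reported; outputs are written as
#' CSV tables with units in the column names, two-column potential-curve
#' files, and a JSON summary plus a reproducibility log.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   `curves` (character vector of SAXS file paths; required),
#'   `tension_file`, `conductivity_file` (optional paths),
#'   `m_mol` (monomer molar mass, g per mol; default 675.4),
#'   `v_p` (cm^3 per g; default 1.15), `rho_l`, `rho_0` (e per cubic
#'   Angstrom; defaults 0.299, 0.333), `sq_threshold` (wt percent, default
#'   0.5), `q_range` (default `c(0.005, 0.35)`), `subtract_cmc` (default
#'   FALSE), `seed` (default 1), `out_dir` (default `"micellr-report"`).
#' @return Invisibly, a list with the series fit, the parameter and
#'   derived-quantity tables, CMC analyses and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$curves) || !length(config$curves))
    stop("config must list at least one SAXS curve file in `curves`",
         call. = FALSE)
  cfg <- utils::modifyList(list(
    m_mol = 675.4, v_p = 1.15, rho_l = 0.299, rho_0 = 0.333,
    sq_threshold = 0.5, q_range = c(0.005, 0.35), subtract_cmc = FALSE,
    seed = 1, out_dir = "micellr-report", tension_file = NULL,
    conductivity_file = NULL), config)
  missing <- cfg$curves[!file.exists(cfg$curves)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  curves <- lapply(cfg$curves, read_saxs_curve)
  ord <- order(vapply(curves, function(cv) attr(cv, "concentration"), numeric(1)))
  curves <- curves[ord]

  series <- fit_saxs_series(curves, sq_threshold = cfg$sq_threshold,
                            q_range = cfg$q_range)

  cmc <- list()
  if (!is.null(cfg$tension_file))
    cmc$tension <- analyze_series(read_isotherm(cfg$tension_file),
                                  m_mol = cfg$m_mol)
  if (!is.null(cfg$conductivity_file))
    cmc$conductivity <- analyze_series(read_isotherm(cfg$conductivity_file),
                                       m_mol = cfg$m_mol)
  c_cmc <- if (!is.null(cmc$tension)) cmc$tension$c_cmc_wt else NA_real_

  ok <- !vapply(series$fit, is.null, logical(1))
  params_tbl <- dplyr::bind_rows(lapply(series$fit[ok], .params_row))
  derived_tbl <- dplyr::bind_rows(lapply(series$fit[ok], .derived_row,
                                         m_mol = cfg$m_mol, v_p = cfg$v_p,
                                         rho_l = cfg$rho_l, rho_0 = cfg$rho_0,
                                         c_cmc = c_cmc,
                                         subtract_cmc = cfg$subtract_cmc))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    params = file.path(cfg$out_dir, "fit_parameters.csv"),
    derived = file.path(cfg$out_dir, "derived_quantities.csv"),
    summary = file.path(cfg$out_dir, "summary.json"),
    log = file.path(cfg$out_dir, "run.log")
  )
  utils::write.csv(params_tbl, paths$params, row.names = FALSE)
  utils::write.csv(derived_tbl, paths$derived, row.names = FALSE)

  pot_paths <- character()
  for (f in series$fit[ok]) {
    yk <- f$yukawa
    if (is.null(yk)) next
    sigma <- 2 * yk$r_hs
    kinv <- debye_length(yk$ionic_strength, yk$temperature, yk$eps_r)
    psi <- surface_potential(yk$z_eff, sigma, 0, yk$eps_r, screened = FALSE)
    pc <- pair_potential(seq(sigma, 4 * sigma, length.out = 200), sigma, psi,
                         1 / kinv, yk$eps_r, yk$temperature)
    pp <- file.path(cfg$out_dir,
                    paste0("potential_", attr(f$curve, "sample_id"), ".txt"))
    write_potential_curve(pc, pp)
    pot_paths <- c(pot_paths, pp)
  }

  cmc_tbl <- dplyr::bind_rows(lapply(cmc, tidy))
  if (nrow(cmc_tbl)) {
    paths$cmc <- file.path(cfg$out_dir, "cmc_analysis.csv")
    utils::write.csv(cmc_tbl, paths$cmc, row.names = FALSE)
  }

  summary <- list(
    n_curves = length(curves),
    n_fitted = sum(ok),
    failures = series$error[!ok],
    concentrations_wtpct = series$concentration,
    cmc = if (nrow(cmc_tbl)) cmc_tbl else NULL
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  cfg_for_hash <- cfg[order(names(cfg))]
  b <- .fit_bounds()
  writeLines(c(
    sprintf("config_hash: %s", rlang::hash(cfg_for_hash)),
    sprintf("seed: %d", cfg$seed),
    sprintf("q_range: %g %g", cfg$q_range[1], cfg$q_range[2]),
    sprintf("sq_threshold_wtpct: %g", cfg$sq_threshold),
    sprintf("bounds_lower: %s", paste(names(b$lower), b$lower, sep = "=", collapse = " ")),
    sprintf("bounds_upper: %s", paste(names(b$upper), b$upper, sep = "=", collapse = " ")),
    sprintf("curves: %s", paste(cfg$curves, collapse = ", ")),
    sprintf("converged: %s", paste(series$converged, collapse = ", "))
  ), paths$log)

  if (!sum(ok)) stop("all curve fits failed", call. = FALSE)
  invisible(list(series = series, params = params_tbl, derived = derived_tbl,
                 cmc = cmc, paths = c(paths, list(potentials = pot_paths))))
}
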