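#' Tumor volume and sphere-equivalent diameter
#'
#' Maps cancer-cell count to tumor volume (`cells * vol_cell / packing`) and
#' sphere-equivalent diameter (`(6 V / pi)^(1/3)`); the inverse map is exact.
#'
#' @param cancer_cells cell count(s), >= 0; vectorized.
#' @param p a [model_params()] list.
#' @return A tibble with columns `cancer_cells`, `volume_cm3`, `diameter_cm`.
#' @export
tumor_geometry <- function(cancer_cells, p = model_params()) {
  .check_nonneg(cancer_cells = cancer_cells)
  vol <- cancer_cells * p$vol_cell / p$packing
  tibble::tibble(
    cancer_cells = cancer_cells,
    volume_cm3 = vol,
    diameter_cm = (6 * vol / pi)^(1 / 3)
  )
}

#' @rdname tumor_geometry
#' @param diameter_cm sphere-equivalent diameter(s), cm.
#' @return For [cells_from_diameter()], the cell count(s).
#' @export
cells_from_diameter <- function(diameter_cm, p = model_params()) {
  .check_nonneg(diameter_cm = diameter_cm)
  (pi / 6) * diameter_cm^3 * p$packing / p$vol_cell
}

# C-side parameter vector (order must match src/qsp_rhs.c)
.parms_vec <- function(p, d_target = p$d_init) {
  h_clone <- p$n_clones^p$n_clone_exp /
    (p$n_clones^p$n_clone_exp + p$k_clone_half^p$n_clone_exp)
  c(p$k_growth, p$c_max, p$k_kill_tcr, p$k_kill_tce, h_clone,
    p$k_treg_suppress, p$k_clear, p$k_release, p$k_uptake, p$k_deg,
    p$s_apc, p$k_d_apc, p$k_mat, p$k_antigen_half, p$k_mig, p$k_d_apc_ln,
    p$k_apc_half, p$k_act, p$n_clones, p$s_naive, p$d_naive, p$k_pro,
    p$n_div, p$q_in, p$q_out, p$k_death_teff, p$q_per, p$q_per_back,
    p$d_teff_c, p$k_act_treg, p$s_treg, p$k_pro_treg, p$n_div_treg,
    p$q_in_treg, p$q_out_treg, p$k_death_treg, p$d_treg_c, p$eps_cells,
    p$vol_cell, p$packing, d_target, p$k_apo, p$f_tce, p$beta_tce, p$c_ref)
}

.state_names <- c("cancer_cells", "dying_cells", "antigen_pool",
                  "apc_immature", "apc_mature_tumor", "apc_mature_ln",
                  "t_naive_central", "t_act_ln", "teff_central",
                  "teff_peripheral", "teff_tumor", "treg_ln", "treg_central",
                  "treg_tumor")

# Drug-free Hill factors for a patient (constants of the pre-treatment phase)
.hill_baseline <- function(p) {
  list(
    h_syn = checkpoint_hill_curve(
      0, p$pd1_total, p$pdl1_cancer, p$r_pdl2, p$chi, p$kd_pd1_pdl1,
      p$kd_pd1_pdl2, p$kd_drug, p$contact_area_scale, p$k_half_syn, p$n_syn,
      p$delta
    ),
    h_ln = checkpoint_hill_curve(
      0, p$pd1_total, p$pdl1_apc, p$r_pdl2, p$chi, p$kd_pd1_pdl1,
      p$kd_pd1_pdl2, p$kd_drug, p$contact_area_scale, p$k_half_ln, p$n_ln,
      p$delta
    ),
    h_tce = 0
  )
}

# Time-gridded Hill forcings for a treated patient. The checkpoint/TCE Hill
# factors depend on time only through the local drug concentration, so each
# is tabulated on a log-spaced concentration grid once and mapped through the
# closed-form PK series.
.hill_forcings <- function(p, regimens, horizon, n_time = 1601, n_conc = 80) {
  tgrid <- seq(0, horizon, length.out = n_time)
  conc_at <- rep(0, n_time)   # atezolizumab, plasma
  conc_ci <- rep(0, n_time)   # cibisatamab, plasma
  pk_at <- pk_atezolizumab()
  pk_ci <- pk_cibisatamab()
  for (reg in regimens) {
    if (reg$drug_id == "atezolizumab") {
      sch <- build_dose_schedule(reg, horizon, pk_at$mw)
      if (nrow(sch)) conc_at <- conc_at + plasma_concentration_fun(sch, pk_at)(tgrid)
    } else {
      sch <- build_dose_schedule(reg, horizon, pk_ci$mw)
      if (nrow(sch)) conc_ci <- conc_ci + plasma_concentration_fun(sch, pk_ci)(tgrid)
    }
  }
  map_through <- function(conc, curve_fun) {
    cmax <- max(conc)
    if (cmax <= 0) return(rep(curve_fun(0), length(conc)))
    grid <- c(0, 10^seq(log10(cmax) - 12, log10(cmax), length.out = n_conc))
    h <- curve_fun(grid)
    stats::approx(grid, h, xout = conc, rule = 2)$y
  }

  h_syn <- map_through(conc_at * pk_at$gamma_tumor, function(cc) {
    checkpoint_hill_curve(cc, p$pd1_total, p$pdl1_cancer, p$r_pdl2, p$chi,
                          p$kd_pd1_pdl1, p$kd_pd1_pdl2, p$kd_drug,
                          p$contact_area_scale, p$k_half_syn, p$n_syn, p$delta)
  })
  h_ln <- map_through(conc_at * pk_at$gamma_ln, function(cc) {
    checkpoint_hill_curve(cc, p$pd1_total, p$pdl1_apc, p$r_pdl2, p$chi,
                          p$kd_pd1_pdl1, p$kd_pd1_pdl2, p$kd_drug,
                          p$contact_area_scale, p$k_half_ln, p$n_ln, p$delta)
  })
  h_tce <- map_through(conc_ci * pk_ci$gamma_tumor, function(cc) {
    tce_hill_curve(cc, p$cea_total, p$cd3_total, p$lam, p$kd_cea, p$kd_cd3,
                   p$contact_area_scale, p$k_half_tce, p$n_tce)
  })

  list(
    tgrid = tgrid,
    forcings = list(cbind(tgrid, h_syn), cbind(tgrid, h_ln),
                    cbind(tgrid, h_tce)),
    conc_atezolizumab = conc_at,
    conc_cibisatamab = conc_ci
  )
}

.y0_seed <- function(p) {
  stats::setNames(
    c(p$seed_cells, 0, 0, p$s_apc / p$k_d_apc, 0, 0, p$s_naive / p$d_naive,
      0, 0, 0, 0, 0, 0, 0),
    .state_names
  )
}

#' Grow a virtual patient's tumor to its pre-treatment size
#'
#' Integrates the drug-free system from a small seed tumor (`seed_cells`,
#' default 1e4) until the sphere-equivalent diameter reaches `d_init`, or
#' until `t_cap` days have elapsed. Patients whose tumor never reaches
#' `d_init` — because growth is too slow within the horizon or because
#' baseline immunity controls the tumor — are flagged `no_tumor` and later
#' excluded from trials as non-patients.
#'
#' @param p a [model_params()] list.
#' @param rtol,atol solver tolerances.
#' @return A list with `state` (named vector at the stopping time), `time`
#'   (days on the pre-treatment clock), `no_tumor` (flag), and `observables`
#'   (tibble of screened quantities: diameter, blood T density, tumor
#'   activated-T density, Teff:Treg ratio).
#' @export
initialize_pretreatment <- function(p, rtol = 1e-6, atol = 1e-3) {
  base <- .hill_baseline(p)
  tf <- rbind(c(0, 0), c(p$t_cap, p$t_cap))
  forc <- list(cbind(tf[, 1], rep(base$h_syn, 2)),
               cbind(tf[, 1], rep(base$h_ln, 2)),
               cbind(tf[, 1], rep(base$h_tce, 2)))
  y0 <- .y0_seed(p)
  times <- seq(0, p$t_cap, by = 10)
  sol <- deSolve::lsodar(
    y = y0, times = times, func = "derivs_qsp", parms = .parms_vec(p),
    dllname = "tcevct", initfunc = "init_qsp", initforc = "forc_qsp",
    forcings = forc, fcontrol = list(method = "linear", rule = 2),
    rootfunc = "root_qsp", nroot = 1L,
    rtol = rtol, atol = atol, nout = 1L, outnames = "diameter_cm"
  )
  if (any(!is.finite(sol[nrow(sol), -1]))) {
    rlang::abort("pre-treatment integration produced non-finite state",
                 class = "tcevct_integration_error")
  }
  last <- sol[nrow(sol), ]
  state <- pmax(last[.state_names], 0)
  t_end <- unname(last["time"])
  diam <- unname(last["diameter_cm"])
  no_tumor <- t_end >= p$t_cap - 1e-9 && diam < p$d_init

  vol <- max(state[["cancer_cells"]], 0) * p$vol_cell / p$packing
  obs <- tibble::tibble(
    tumor_diameter_cm = diam,
    blood_t_density = (state[["t_naive_central"]] + state[["teff_central"]] +
                         state[["treg_central"]]) / p$blood_volume_ul,
    tumor_activated_t_density = if (vol > 0) state[["teff_tumor"]] / vol else 0,
    teff_treg_ratio = state[["teff_tumor"]] / (state[["treg_tumor"]] + 1e-9)
  )
  list(state = state, time = t_end, no_tumor = no_tumor, observables = obs)
}

#' Simulate a treated virtual patient
#'
#' Integrates the tumor-immune system from a patient's pre-treatment state
#' under one or more dosing regimens, with the checkpoint and TCE Hill
#' factors driven by closed-form plasma pharmacokinetics scaled to the tumor
#' and lymph-node interstitium. Day 0 is the first treatment day.
#'
#' @param p a [model_params()] list.
#' @param regimens list of [regimen()] objects (possibly empty for an
#'   untreated control).
#' @param pre result of [initialize_pretreatment()]; computed on the fly if
#'   `NULL`.
#' @param horizon days to simulate (default 400, the response-evaluation day).
#' @param grid_step output grid step (days).
#' @param rtol,atol solver tolerances.
#' @return A tibble of class `tcevct_trajectory`: `time_days`, all model
#'   states, `diameter_cm`, `teff_density_tumor` (cells/cm^3),
#'   `teff_treg_ratio`, `conc_atezolizumab` and `conc_cibisatamab` (plasma,
#'   molar).
#' @export
simulate_patient <- function(p, regimens, pre = NULL, horizon = 400,
                             grid_step = 2, rtol = 1e-6, atol = 1e-3) {
  if (is.null(pre)) pre <- initialize_pretreatment(p)
  if (isTRUE(pre$no_tumor)) {
    rlang::abort("patient flagged `no_tumor`; not eligible for simulation",
                 class = "tcevct_validation_error")
  }
  fr <- .hill_forcings(p, regimens, horizon)
  times <- seq(0, horizon, by = grid_step)
  sol <- deSolve::lsoda(
    y = pre$state, times = times, func = "derivs_qsp",
    parms = .parms_vec(p), dllname = "tcevct", initfunc = "init_qsp",
    initforc = "forc_qsp", forcings = fr$forcings,
    fcontrol = list(method = "linear", rule = 2),
    rtol = rtol, atol = atol, hmax = 1, nout = 1L, outnames = "diameter_cm"
  )
  if (nrow(sol) < length(times) || any(!is.finite(sol[nrow(sol), -1]))) {
    rlang::abort(
      sprintf("integration failed at t = %.2f days", sol[nrow(sol), "time"]),
      class = "tcevct_integration_error"
    )
  }
  states <- pmax(sol[, .state_names, drop = FALSE], 0)
  vol <- states[, "cancer_cells"] * p$vol_cell / p$packing
  out <- tibble::as_tibble(as.data.frame(states))
  out <- dplyr::mutate(
    out,
    time_days = sol[, "time"],
    diameter_cm = (6 * vol / pi)^(1 / 3),
    teff_density_tumor = ifelse(vol > 0, states[, "teff_tumor"] / vol, 0),
    treg_density_tumor = ifelse(vol > 0, states[, "treg_tumor"] / vol, 0),
    teff_treg_ratio = states[, "teff_tumor"] / (states[, "treg_tumor"] + 1e-9),
    conc_atezolizumab = stats::approx(fr$tgrid, fr$conc_atezolizumab,
                                      xout = sol[, "time"], rule = 2)$y,
    conc_cibisatamab = stats::approx(fr$tgrid, fr$conc_cibisatamab,
                                     xout = sol[, "time"], rule = 2)$y,
    .before = 1
  )
  class(out) <- c("tcevct_trajectory", class(out))
  out
}
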