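#' Default whole-patient model parameters
#'
#' Returns the packaged default parameterization of the tumor-immune model:
#' tumor growth and geometry, antigen handling and APC maturation, T-cell
#' activation/proliferation/trafficking, Treg dynamics, receptor surface
#' densities, binding constants and Hill transducer constants. Any field can
#' be overridden by name. Patient-variable axes (the ones sampled by the
#' virtual-cohort generator) all live here as plain fields, so a sampled
#' patient is just this list with some fields replaced.
#'
#' Rates are per day, diameters cm, receptor densities sites/cell, solution
#' affinities molar, surface affinities sites/cell.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `tcevct_params`.
#' @export
model_params <- function(...) {
  p <- list(
    # tumor growth & geometry
    k_growth = 0.012,        # logistic growth rate (1/day)
    c_max = 1e12,            # carrying capacity (cells; ~16 cm sphere)
    c_ref = 2e12,            # reference cell count for perfusion surface scaling
    d_init = 3,              # pre-treatment target diameter (cm)
    vol_cell = 1e-9,         # cell volume (cm^3)
    packing = 0.5,           # cell packing fraction of tumor volume
    # killing
    k_kill_tcr = 6.2,        # native TCR-route killing capacity (1/day)
    k_kill_tce = 0.27,       # TCE-synapse killing capacity (1/day)
    f_tce = 0.05,            # effector:target saturation scale of TCE killing
    beta_tce = 0.02,         # checkpoint sensitivity of the TCE killing route
    k_treg_suppress = 1,     # strength of Treg suppression of killing
    # immunogenicity / activation
    n_clones = 30,           # TMB: activatable T cell clones
    k_clone_half = 85,       # half-max clone count for TCR recognition
    n_clone_exp = 6,         # Hill exponent of clonal recognition
    k_act = 1.9e-5,          # activation rate per clone (1/day)
    k_pro = 1,               # egress/turnover of activated T cells (1/day)
    n_div = 0.3,             # effective proliferation generations at full priming
    # dying cells / antigen / APC
    k_apo = 0.001,           # spontaneous tumor-cell turnover feeding antigen (1/day)
    k_clear = 0.5,
    k_release = 1e-10,
    k_uptake = 1e-9,
    k_deg = 2,
    s_apc = 1e6,
    k_d_apc = 0.1,
    k_mat = 1.5,
    k_antigen_half = 0.3,
    k_mig = 0.5,
    k_d_apc_ln = 0.2,
    k_apc_half = 1e5,
    # naive pool
    s_naive = 5e7,
    d_naive = 0.01,
    # effector trafficking & death
    q_in = 1,
    q_out = 0.02,
    k_death_teff = 0.1,
    q_per = 0.3,
    q_per_back = 0.1,
    d_teff_c = 0.1,
    # Treg mirror
    k_act_treg = 0.1,
    s_treg = 8.6e5,
    k_pro_treg = 1,
    n_div_treg = 3,
    q_in_treg = 1,
    q_out_treg = 0.02,
    k_death_treg = 0.1,
    d_treg_c = 0.1,
    # receptors & binding
    pd1_total = 1e4,
    pdl1_cancer = 1e4,
    pdl1_apc = 3e4,
    cea_total = 1e5,
    cd3_total = 1e5,
    r_pdl2 = 0.035,
    chi = 10,
    lam = 10,
    delta = 1,
    kd_pd1_pdl1 = 500,
    kd_pd1_pdl2 = 1e6,
    kd_drug = 4e-10,
    kd_cea = 2e-8,
    kd_cd3 = 2e-7,
    contact_area_scale = 1e9,
    # Hill transducers
    k_half_syn = 1400, n_syn = 2,
    k_half_ln = 2000, n_ln = 2,
    k_half_tce = 6e4, n_tce = 2,
    # numerics & misc
    eps_cells = 1,
    seed_cells = 1e4,
    t_cap = 6000,
    blood_volume_ul = 5e6
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      rlang::abort(paste0("unknown model parameter(s): ",
                          paste(bad, collapse = ", ")),
                   class = "tcevct_validation_error")
    }
    p[names(dots)] <- dots
  }
  structure(p, class = c("tcevct_params", "list"))
}

#' Default virtual-patient parameter space
#'
#' One row per sampled axis: `name` (a [model_params()] field), `baseline`,
#' `low`, `high`, sampling `scale` (`"linear"` or `"log10"`) and `unit`.
#' Receptor densities, affinities, trafficking/source rates and TMB are
#' sampled on a log10 scale; growth rate, initial diameter and the
#' dimensionless efficiencies on a linear scale. The TMB axis spans 1-220
#' clones so that 0.8 of the normalized log range sits near 75 clones and the
#' top of the range exceeds 200.
#'
#' @param delta_axis if `TRUE`, add the PD-L2 Hill weight `delta` as a
#'   sampled axis on \[0, 1\] (the PD-L2-weighting variant); otherwise
#'   `delta` stays at its fixed default of 1.
#' @return A tibble describing the parameter space.
#' @export
default_parameter_space <- function(delta_axis = FALSE) {
  sp <- tibble::tribble(
    ~name,          ~baseline, ~low,     ~high,    ~scale,   ~unit,
    "k_growth",     0.0099,    0.007,    0.014,    "log10",  "1/day",
    "c_max",        3e11,      2.2e10,   2e12,     "log10",  "cells",
    "d_init",       3,         1,        5,        "linear", "cm",
    "n_clones",     30,        1,        220,      "log10",  "clones",
    "pdl1_cancer",  3e4,       1e4,      10^5.5,   "log10",  "sites/cell",
    "pdl1_apc",     3e4,       1e3,      10^5.5,   "log10",  "sites/cell",
    "pd1_total",    1e4,       1e3,      1e5,      "log10",  "sites/cell",
    "chi",          10,        1,        100,      "linear", "dimensionless",
    "cea_total",    1e5,       1e3,      1e6,      "log10",  "sites/cell",
    "lam",          10,        1,        100,      "linear", "dimensionless",
    "cd3_total",    1e5,       10^4.5,   10^5.5,   "log10",  "sites/cell",
    "kd_cd3",       2e-7,      1e-8,     1e-6,     "log10",  "M",
    "r_pdl2",       0.035,     0,        0.07,     "linear", "ratio",
    "q_in",         1.5,       1,        2.2,      "log10",  "1/day",
    "s_naive",      3.9e7,     1.6e7,    9.5e7,    "log10",  "cells/day",
    "s_treg",       8.6e5,     4.8e5,    1.55e6,   "log10",  "cells"
  )
  if (delta_axis) {
    sp <- dplyr::bind_rows(sp, tibble::tibble(
      name = "delta", baseline = 1, low = 0, high = 1,
      scale = "linear", unit = "dimensionless"
    ))
  }
  validate_parameter_space(sp)
  sp
}

#' Validate a parameter-space description
#'
#' @param space a tibble with columns `name`, `baseline`, `low`, `high`,
#'   `scale`, `unit`.
#' @return The space, invisibly, after validation.
#' @export
validate_parameter_space <- function(space) {
  need <- c("name", "baseline", "low", "high", "scale", "unit")
  miss <- setdiff(need, names(space))
  if (length(miss)) {
    rlang::abort(paste0("parameter space is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "tcevct_validation_error")
  }
  if (anyDuplicated(space$name)) {
    rlang::abort("parameter-space axis names must be unique.",
                 class = "tcevct_validation_error")
  }
  bad_scale <- setdiff(unique(space$scale), c("linear", "log10"))
  if (length(bad_scale)) {
    rlang::abort(paste0("unknown scale(s): ", paste(bad_scale, collapse = ", ")),
                 class = "tcevct_validation_error")
  }
  problems <- character()
  for (i in seq_len(nrow(space))) {
    r <- space[i, ]
    if (!(r$low < r$high)) {
      problems <- c(problems, sprintf("axis `%s`: low must be < high", r$name))
    }
    if (r$baseline < r$low || r$baseline > r$high) {
      problems <- c(problems, sprintf("axis `%s`: baseline outside [low, high]", r$name))
    }
    if (r$scale == "log10" && r$low <= 0) {
      problems <- c(problems, sprintf("axis `%s`: log10 axis must be strictly positive", r$name))
    }
  }
  if (length(problems)) {
    rlang::abort(paste(problems, collapse = "; "), class = "tcevct_validation_error")
  }
  invisible(space)
}

#' Default physiological screening bounds
#'
#' Clinical-plausibility windows applied to the pre-treatment state of each
#' virtual patient: tumor diameter (cm), total T-cell density in blood
#' (cells/uL), activated T-cell density in tumor (cells/cm^3) and the tumor
#' Teff:Treg ratio. These are calibration placeholders standing in for
#' clinically measured reference ranges.
#'
#' @return A tibble with columns `name`, `low`, `high`.
#' @export
default_screen_bounds <- function() {
  tibble::tribble(
    ~name,                      ~low,  ~high,
    "tumor_diameter_cm",        1,     15,
    "blood_t_density",          500,   3000,
    "tumor_activated_t_density", 1e2,  1e7,
    "teff_treg_ratio",          0.1,   50
  )
}
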