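#' Pharmacokinetic parameter sets
#'
#' Two-compartment linear disposition parameters for an intravenously dosed
#' antibody, plus biodistribution coefficients mapping plasma concentration to
#' tumor and tumor-draining-lymph-node interstitial concentrations
#' (interstitial = gamma x plasma, no delay).
#'
#' Packaged defaults: atezolizumab values are literature-typical for an IgG1
#' checkpoint antibody (clearance 0.20 L/day, central volume 3.28 L,
#' peripheral volume 3.63 L, distribution clearance 0.546 L/day, 145 kDa);
#' cibisatamab values are typical for a 2+1 IgG-based T-cell engager
#' (clearance 0.56 L/day, 100 kDa). Both are configuration defaults intended
#' to be replaced by study-fitted values where available.
#'
#' @param cl systemic clearance (L/day).
#' @param v_c central (plasma) volume (L).
#' @param v_p peripheral volume (L).
#' @param q inter-compartment distribution clearance (L/day).
#' @param mw molar mass (g/mol).
#' @param gamma_tumor,gamma_ln biodistribution coefficients in (0, 1].
#' @return A list of class `tcevct_pk` with the validated fields.
#' @export
pk_params <- function(cl, v_c, v_p, q, mw, gamma_tumor = 0.1, gamma_ln = 0.3) {
  vals <- list(cl = cl, v_c = v_c, v_p = v_p, q = q, mw = mw,
               gamma_tumor = gamma_tumor, gamma_ln = gamma_ln)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L ||
        !is.finite(vals[[nm]]) || vals[[nm]] <= 0) {
      rlang::abort(sprintf("PK parameter `%s` must be a positive number.", nm),
                   class = "tcevct_validation_error")
    }
  }
  if (gamma_tumor > 1 || gamma_ln > 1) {
    rlang::abort("biodistribution coefficients must lie in (0, 1].",
                 class = "tcevct_validation_error")
  }
  structure(vals, class = "tcevct_pk")
}

#' @rdname pk_params
#' @export
pk_atezolizumab <- function() {
  pk_params(cl = 0.20, v_c = 3.28, v_p = 3.63, q = 0.546, mw = 145000,
            gamma_tumor = 0.1, gamma_ln = 0.3)
}

#' @rdname pk_params
#' @export
pk_cibisatamab <- function() {
  pk_params(cl = 0.56, v_c = 3.1, v_p = 2.7, q = 0.35, mw = 100000,
            gamma_tumor = 0.1, gamma_ln = 0.3)
}

#' Dosing regimen
#'
#' @param drug_id `"atezolizumab"` or `"cibisatamab"`.
#' @param dose_mg dose per administration (mg, >= 0).
#' @param interval_days days between doses (> 0).
#' @param first_dose_day day of first dose (>= 0).
#' @param n_doses number of doses, or `Inf` to dose until the horizon.
#' @return A list of class `tcevct_regimen`.
#' @examples
#' regimen("atezolizumab", 1200, 21)   # 1200 mg Q3W
#' regimen("cibisatamab", 60, 7)       # 60 mg QW
#' @export
regimen <- function(drug_id, dose_mg, interval_days, first_dose_day = 0,
                    n_doses = Inf) {
  drug_id <- match.arg(drug_id, c("atezolizumab", "cibisatamab"))
  if (dose_mg < 0) rlang::abort("`dose_mg` must be >= 0.", class = "tcevct_validation_error")
  if (interval_days <= 0) rlang::abort("`interval_days` must be > 0.", class = "tcevct_validation_error")
  if (first_dose_day < 0) rlang::abort("`first_dose_day` must be >= 0.", class = "tcevct_validation_error")
  structure(
    list(drug_id = drug_id, dose_mg = dose_mg, interval_days = interval_days,
         first_dose_day = first_dose_day, n_doses = n_doses),
    class = "tcevct_regimen"
  )
}

#' Expand a regimen into bolus dose events
#'
#' Doses fall on `first_dose_day + k * interval_days` for `k = 0, 1, ...`,
#' within the half-open window `[first_dose_day, horizon_days)`: a dose
#' landing exactly on the horizon is excluded.
#'
#' @param reg a [regimen()].
#' @param horizon_days simulation horizon (> 0).
#' @param mw molar mass used to convert mg to moles (g/mol, > 0).
#' @return A tibble with columns `time_days` (strictly increasing) and
#'   `moles` (= `dose_mg / 1000 / mw`); zero rows for a zero dose.
#' @export
build_dose_schedule <- function(reg, horizon_days, mw) {
  stopifnot(inherits(reg, "tcevct_regimen"))
  if (!is.finite(mw) || mw <= 0) {
    rlang::abort("`mw` must be a positive molar mass.", class = "tcevct_validation_error")
  }
  if (horizon_days <= 0) {
    rlang::abort("`horizon_days` must be > 0.", class = "tcevct_validation_error")
  }
  if (reg$dose_mg == 0 || reg$n_doses < 1) {
    return(tibble::tibble(time_days = numeric(), moles = numeric()))
  }
  times <- seq(reg$first_dose_day, horizon_days - 1e-9, by = reg$interval_days)
  if (is.finite(reg$n_doses)) times <- utils::head(times, reg$n_doses)
  tibble::tibble(time_days = times, moles = reg$dose_mg / 1000 / mw)
}

# Macro-constants of the 2-compartment model: hybrid rate constants and the
# bi-exponential coefficients for the central concentration after a unit bolus.
.pk_macro <- function(pk) {
  k10 <- pk$cl / pk$v_c
  k12 <- pk$q / pk$v_c
  k21 <- pk$q / pk$v_p
  s <- k10 + k12 + k21
  root <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  # C_c(t) per mole dosed: A*exp(-alpha t) + B*exp(-beta t)
  a_coef <- (alpha - k21) / (pk$v_c * (alpha - beta))
  b_coef <- (k21 - beta) / (pk$v_c * (alpha - beta))
  list(alpha = alpha, beta = beta, a_coef = a_coef, b_coef = b_coef,
       k10 = k10, k12 = k12, k21 = k21)
}

#' Closed-form plasma concentration under repeated bolus dosing
#'
#' Superposes the bi-exponential single-dose solution of the linear
#' two-compartment model (bolus into the central compartment) over a dose
#' schedule. The series jumps upward by `dose / v_c` at each dose time and is
#' continuous elsewhere.
#'
#' @param t_grid sorted, non-negative times (days).
#' @param schedule dose-event tibble from [build_dose_schedule()].
#' @param pk a [pk_params()] object.
#' @return A tibble with columns `time_days`, `conc_central`,
#'   `conc_peripheral` (molar; peripheral reported as amount/`v_p`).
#' @export
plasma_concentration <- function(t_grid, schedule, pk) {
  stopifnot(inherits(pk, "tcevct_pk"))
  if (is.unsorted(t_grid) || any(t_grid < 0)) {
    rlang::abort("`t_grid` must be sorted and non-negative.",
                 class = "tcevct_validation_error")
  }
  m <- .pk_macro(pk)
  cc <- numeric(length(t_grid))
  cp <- numeric(length(t_grid))
  if (nrow(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      dt <- t_grid - schedule$time_days[i]
      on <- dt >= 0
      d <- schedule$moles[i]
      cc[on] <- cc[on] + d * (m$a_coef * exp(-m$alpha * dt[on]) +
                                m$b_coef * exp(-m$beta * dt[on]))
      # peripheral amount per mole: k12*v_c/(alpha-beta) * (exp(-beta t)-exp(-alpha t)) / v_p
      cp[on] <- cp[on] + d * m$k12 / (pk$v_p * (m$alpha - m$beta) / pk$v_c) /
        pk$v_c * (exp(-m$beta * dt[on]) - exp(-m$alpha * dt[on]))
    }
  }
  tibble::tibble(time_days = t_grid, conc_central = cc, conc_peripheral = cp)
}

#' Fast scalar evaluator for central concentration
#'
#' Same closed form as [plasma_concentration()], returned as a function of
#' time for use as an ODE forcing.
#'
#' @inheritParams plasma_concentration
#' @return `function(t)` giving central molar concentration, vectorized.
#' @export
plasma_concentration_fun <- function(schedule, pk) {
  m <- .pk_macro(pk)
  t_dose <- schedule$time_days
  d <- schedule$moles
  function(t) {
    out <- numeric(length(t))
    for (i in seq_along(t_dose)) {
      dt <- t - t_dose[i]
      on <- dt >= 0
      out[on] <- out[on] + d[i] * (m$a_coef * exp(-m$alpha * dt[on]) +
                                     m$b_coef * exp(-m$beta * dt[on]))
    }
    out
  }
}

#' ODE cross-check integration of the two-compartment model
#'
#' Direct numerical integration of the same linear system used by the closed
#' form, with bolus dose events and a cumulative-elimination state for mass
#' audits. Used to validate the superposition solution.
#'
#' @inheritParams plasma_concentration
#' @return A tibble with `time_days`, `conc_central`, `conc_peripheral`,
#'   `eliminated_moles`.
#' @export
plasma_concentration_ode <- function(t_grid, schedule, pk) {
  stopifnot(inherits(pk, "tcevct_pk"))
  rhs <- function(t, y, p) {
    list(c(
      -(p$cl / p$v_c) * y[1] - (p$q / p$v_c) * y[1] + (p$q / p$v_p) * y[2],
      (p$q / p$v_c) * y[1] - (p$q / p$v_p) * y[2],
      (p$cl / p$v_c) * y[1]
    ))
  }
  events <- NULL
  if (nrow(schedule)) {
    events <- list(data = data.frame(
      var = "amt_central", time = schedule$time_days, value = schedule$moles,
      method = "add"
    ))
  }
  times <- sort(unique(c(t_grid, schedule$time_days)))
  sol <- deSolve::ode(
    y = c(amt_central = 0, amt_peripheral = 0, eliminated = 0),
    times = times, func = rhs, parms = pk,
    events = events, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  sol <- sol[match(t_grid, sol[, "time"]), , drop = FALSE]
  tibble::tibble(
    time_days = t_grid,
    conc_central = sol[, 2] / pk$v_c,
    conc_peripheral = sol[, 3] / pk$v_p,
    eliminated_moles = sol[, 4]
  )
}
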