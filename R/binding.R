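#' Quasi-steady-state equilibrium of the PD-1/PD-L1/PD-L2 checkpoint synapse
#'
#' Solves the simultaneous surface-binding equilibrium between PD-1 on an
#' effector T cell, PD-L1 and PD-L2 on the opposing cell (cancer cell or
#' antigen-presenting cell), and a bivalent anti-PD-L1 antibody present in the
#' local interstitium. The reaction scheme is
#' \itemize{
#'   \item PD-1 + PD-L1 <-> C1, surface dissociation constant `kd_pd1_pdl1`
#'     (sites/cell),
#'   \item PD-1 + PD-L2 <-> C2, surface dissociation constant `kd_pd1_pdl2`,
#'   \item drug + PD-L1 <-> D1 (monovalent arm capture, solution-phase
#'     `kd_drug`, molar; the drug is not depleted),
#'   \item D1 + PD-L1 <-> D2 (cross-arm capture of a second PD-L1), with
#'     effective surface dissociation `contact_area_scale * kd_drug / chi`.
#' }
#' `chi` is the cross-arm binding efficiency: an avidity multiplier on the
#' second-arm capture step. `chi = 0` reduces the drug to a monovalent
#' binder. PD-L2 abundance is tied to PD-L1 through the per-patient ratio
#' `r_pdl2` (PD-L2 total = `r_pdl2 *` PD-L1 total), bounded in \[0, 0.07\]:
#' PD-L2 is expressed at most at a small fraction of PD-L1 and never alone.
#'
#' Binding is treated as fast relative to cellular dynamics, so complexes are
#' algebraic (quasi-steady-state) quantities, not ODE states. The equilibrium
#' reduces to a single scalar root-find on free PD-L1 in \[0, total\]; free
#' PD-1 and free PD-L2 then follow in closed form from a stable quadratic.
#'
#' @param pd1_total PD-1 sites per T cell (>= 0).
#' @param pdl1_total PD-L1 sites per target cell (>= 0).
#' @param r_pdl2 PD-L2:PD-L1 expression ratio, in \[0, 0.07\].
#' @param drug_conc local molar concentration of anti-PD-L1 antibody (>= 0).
#' @param chi cross-arm binding efficiency (dimensionless, >= 0).
#' @param kd_pd1_pdl1,kd_pd1_pdl2 surface dissociation constants (sites/cell).
#' @param kd_drug solution dissociation constant of the drug (molar).
#' @param contact_area_scale conversion factor from molar to sites/cell for
#'   surface reactions (sites/cell per molar).
#' @return A one-row tibble with columns `c_pd1_pdl1`, `c_pd1_pdl2`,
#'   `c_drug_pdl1_mono`, `c_drug_pdl1_cross`, `free_pd1`, `free_pdl1`,
#'   `free_pdl2` (all sites/cell).
#' @examples
#' solve_checkpoint_equilibrium(
#'   pd1_total = 3000, pdl1_total = 10000, r_pdl2 = 0, drug_conc = 0,
#'   chi = 10, kd_pd1_pdl1 = 1000, kd_pd1_pdl2 = 300, kd_drug = 4e-10,
#'   contact_area_scale = 1e9
#' )
#' @export
solve_checkpoint_equilibrium <- function(pd1_total, pdl1_total, r_pdl2,
                                         drug_conc, chi,
                                         kd_pd1_pdl1, kd_pd1_pdl2, kd_drug,
                                         contact_area_scale) {
  stopifnot(length(pd1_total) == 1L, length(pdl1_total) == 1L)
  .check_nonneg(
    pd1_total = pd1_total, pdl1_total = pdl1_total, drug_conc = drug_conc,
    chi = chi, kd_pd1_pdl1 = kd_pd1_pdl1, kd_pd1_pdl2 = kd_pd1_pdl2,
    kd_drug = kd_drug, contact_area_scale = contact_area_scale
  )
  if (r_pdl2 < 0 || r_pdl2 > 0.07) {
    rlang::abort("`r_pdl2` must lie in [0, 0.07].", class = "tcevct_validation_error")
  }

  p_tot <- pd1_total
  l1_tot <- pdl1_total
  l2_tot <- r_pdl2 * pdl1_total

  out <- tibble::as_tibble(.checkpoint_solve_vec(
    drug_conc, pd1_total, pdl1_total, r_pdl2, chi,
    kd_pd1_pdl1, kd_pd1_pdl2, kd_drug, contact_area_scale
  ))

  res_p <- abs(out$free_pd1 + out$c_pd1_pdl1 + out$c_pd1_pdl2 - p_tot) / max(p_tot, 1)
  res_l1 <- abs(out$free_pdl1 + out$c_pd1_pdl1 + out$c_drug_pdl1_mono +
                  2 * out$c_drug_pdl1_cross - l1_tot) / max(l1_tot, 1)
  res_l2 <- abs(out$free_pdl2 + out$c_pd1_pdl2 - l2_tot) / max(l2_tot, 1)
  if (max(res_p, res_l1, res_l2) > 1e-8) {
    rlang::abort(
      sprintf(
        "checkpoint equilibrium did not converge (residuals: PD-1 %.3g, PD-L1 %.3g, PD-L2 %.3g)",
        res_p, res_l1, res_l2
      ),
      class = "tcevct_solver_error"
    )
  }
  out
}

#' Checkpoint Hill inhibition factor
#'
#' Maps bound inhibitory-complex densities to the fractional PD-1 signal
#' `H in [0, 1]` used to attenuate T-cell killing (tumor synapse) or
#' proliferative capacity (priming in the tumor-draining lymph node). The
#' signal strength is `S = c_pd1_pdl1 + delta * c_pd1_pdl2`, where `delta`
#' weights the PD-1/PD-L2 complex: `delta = 0` removes PD-L2 signalling,
#' `delta = 1` counts it at parity with PD-L1. Downstream terms multiply by
#' `1 - H`.
#'
#' @param c_pd1_pdl1,c_pd1_pdl2 bound complex densities (sites/cell).
#' @param k_half half-maximal signal density (sites/cell).
#' @param n_hill Hill exponent (>= 1).
#' @param delta PD-L2 weight in \[0, 1\].
#' @return Hill factor(s) in \[0, 1\]; vectorized over complex densities.
#' @export
hill_checkpoint <- function(c_pd1_pdl1, c_pd1_pdl2, k_half, n_hill = 2, delta = 1) {
  .check_nonneg(c_pd1_pdl1 = c_pd1_pdl1, c_pd1_pdl2 = c_pd1_pdl2, k_half = k_half)
  if (n_hill < 1) rlang::abort("`n_hill` must be >= 1.", class = "tcevct_validation_error")
  if (any(delta < 0 | delta > 1)) {
    rlang::abort("`delta` must lie in [0, 1].", class = "tcevct_validation_error")
  }
  s <- c_pd1_pdl1 + delta * c_pd1_pdl2
  s^n_hill / (s^n_hill + k_half^n_hill)
}

#' Quasi-steady-state equilibrium of the CEA x CD3 T-cell-engager synapse
#'
#' Solves the trimer (CEA-TCE-CD3) equilibrium that forms the cytolytic
#' synapse between a cancer cell and a T cell:
#' \itemize{
#'   \item TCE + CEA <-> CEA dimer (`kd_cea`, molar),
#'   \item TCE + CD3 <-> CD3 dimer (`kd_cd3`, molar),
#'   \item CEA dimer + CD3 <-> trimer, effective surface dissociation
#'     `contact_area_scale * kd_cd3 / lam`,
#'   \item CD3 dimer + CEA <-> trimer, effective surface dissociation
#'     `contact_area_scale * kd_cea / lam` (thermodynamic-cycle consistent).
#' }
#' `lam` is the TCE cross-arm binding efficiency; `lam = 0` abolishes trimer
#' formation so the drug cannot act. Because both arms are consumed by the
#' trimer, the trimer-vs-dose curve is bell-shaped (the "hook" effect): at
#' saturating dose each receptor is occupied by its own antibody molecule and
#' cross-linking is lost.
#'
#' @param cea_total CEA sites per cancer cell (>= 0).
#' @param cd3_total CD3 sites per T cell (>= 0).
#' @param tce_conc local molar TCE concentration (>= 0; not depleted).
#' @param lam cross-arm binding efficiency (dimensionless, >= 0).
#' @param kd_cea,kd_cd3 solution dissociation constants (molar).
#' @param contact_area_scale molar to sites/cell conversion for the surface
#'   cross-linking step.
#' @return A one-row tibble with columns `dimer_cea`, `dimer_cd3`, `trimer`,
#'   `free_cea`, `free_cd3` (sites/cell).
#' @export
solve_tce_equilibrium <- function(cea_total, cd3_total, tce_conc, lam,
                                  kd_cea, kd_cd3, contact_area_scale) {
  stopifnot(length(cea_total) == 1L, length(cd3_total) == 1L, length(tce_conc) == 1L)
  .check_nonneg(
    cea_total = cea_total, cd3_total = cd3_total, tce_conc = tce_conc,
    lam = lam, kd_cea = kd_cea, kd_cd3 = kd_cd3,
    contact_area_scale = contact_area_scale
  )

  out <- tibble::as_tibble(.tce_solve_vec(
    tce_conc, cea_total, cd3_total, lam, kd_cea, kd_cd3, contact_area_scale
  ))

  res_e <- abs(out$free_cea + out$dimer_cea + out$trimer - cea_total) / max(cea_total, 1)
  res_d <- abs(out$free_cd3 + out$dimer_cd3 + out$trimer - cd3_total) / max(cd3_total, 1)
  if (max(res_e, res_d) > 1e-8) {
    rlang::abort(
      sprintf("TCE equilibrium did not converge (residuals: CEA %.3g, CD3 %.3g)",
              res_e, res_d),
      class = "tcevct_solver_error"
    )
  }
  out
}

# Vectorized core of the TCE trimer equilibrium: closed-form stable quadratic
# (free CD3 eliminated against free CEA), valid for vector tce_conc.
.tce_solve_vec <- function(tce_conc, cea_total, cd3_total, lam,
                           kd_cea, kd_cd3, contact_area_scale) {
  a <- tce_conc / kd_cea
  b <- tce_conc / kd_cd3
  cc <- a * lam / (contact_area_scale * kd_cd3)   # trimer = cc * E * D
  if (cea_total == 0 || cd3_total == 0) cc <- rep(0, length(a))
  # E(1+a) + cc*E*D = E_tot ; D(1+b) + cc*E*D = D_tot; eliminate E:
  # cc(1+b) D^2 + [(1+a)(1+b) + cc(E_tot - D_tot)] D - D_tot (1+a) = 0
  qa <- cc * (1 + b)
  qb <- (1 + a) * (1 + b) + cc * (cea_total - cd3_total)
  qc <- -cd3_total * (1 + a)
  disc <- sqrt(qb^2 - 4 * qa * qc)
  d <- ifelse(cc > 0, 2 * (-qc) / (qb + disc), cd3_total / (1 + b))
  e <- cea_total / (1 + a + cc * d)
  list(
    dimer_cea = a * e,
    dimer_cd3 = b * d,
    trimer = cc * e * d,
    free_cea = e,
    free_cd3 = d
  )
}

#' TCE Hill activation factor
#'
#' Maps trimer (synapse) density to the fractional TCE-mediated killing
#' activation `H in [0, 1]`.
#'
#' @param trimer trimer density (sites/cell); vectorized.
#' @param k_half half-maximal trimer density (sites/cell).
#' @param n_hill Hill exponent (>= 1).
#' @return Hill factor(s) in \[0, 1\].
#' @export
hill_tce <- function(trimer, k_half, n_hill = 2) {
  .check_nonneg(trimer = trimer, k_half = k_half)
  if (n_hill < 1) rlang::abort("`n_hill` must be >= 1.", class = "tcevct_validation_error")
  trimer^n_hill / (trimer^n_hill + k_half^n_hill)
}

# Vectorized core of the checkpoint equilibrium: simultaneous bisection on
# free PD-L1 across a vector of drug concentrations (the balance function is
# strictly increasing in free PD-L1). ~70 iterations reach machine precision.
.checkpoint_solve_vec <- function(drug_conc, pd1_total, pdl1_total, r_pdl2,
                                  chi, kd_pd1_pdl1, kd_pd1_pdl2, kd_drug,
                                  contact_area_scale, iters = 70L) {
  p_tot <- pd1_total
  l1_tot <- pdl1_total
  l2_tot <- r_pdl2 * pdl1_total
  k1 <- kd_pd1_pdl1
  k2 <- kd_pd1_pdl2
  a <- drug_conc / kd_drug
  inv_kcross <- if (chi > 0) chi / (contact_area_scale * kd_drug) else 0
  n <- length(drug_conc)
  if (l1_tot == 0) {
    z <- rep(0, n)
    return(list(c_pd1_pdl1 = z, c_pd1_pdl2 = z, c_drug_pdl1_mono = z,
                c_drug_pdl1_cross = z, free_pd1 = rep(p_tot, n),
                free_pdl1 = z, free_pdl2 = z))
  }
  free_p <- function(l1) {
    u <- 1 + l1 / k1
    b <- u * k2 + l2_tot - p_tot
    2 * p_tot * k2 / (b + sqrt(b^2 + 4 * u * p_tot * k2))
  }
  lo <- rep(0, n)
  hi <- rep(l1_tot, n)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    p <- free_p(mid)
    g <- mid + p * mid / k1 + a * mid + 2 * a * mid^2 * inv_kcross - l1_tot
    up <- g < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  l1 <- (lo + hi) / 2
  p <- free_p(l1)
  l2 <- l2_tot / (1 + p / k2)
  list(
    c_pd1_pdl1 = p * l1 / k1,
    c_pd1_pdl2 = p * l2 / k2,
    c_drug_pdl1_mono = a * l1,
    c_drug_pdl1_cross = a * l1^2 * inv_kcross,
    free_pd1 = p,
    free_pdl1 = l1,
    free_pdl2 = l2
  )
}

#' Checkpoint Hill factor as a function of local drug concentration
#'
#' Convenience curve used to build ODE forcings: evaluates the full
#' checkpoint equilibrium and Hill transducer over a vector of anti-PD-L1
#' concentrations for one patient's receptor configuration.
#'
#' @param drug_conc vector of molar concentrations.
#' @inheritParams solve_checkpoint_equilibrium
#' @inheritParams hill_checkpoint
#' @return Numeric vector of Hill factors, same length as `drug_conc`.
#' @export
checkpoint_hill_curve <- function(drug_conc, pd1_total, pdl1_total, r_pdl2, chi,
                                  kd_pd1_pdl1, kd_pd1_pdl2, kd_drug,
                                  contact_area_scale, k_half, n_hill = 2,
                                  delta = 1) {
  cx <- .checkpoint_solve_vec(drug_conc, pd1_total, pdl1_total, r_pdl2, chi,
                              kd_pd1_pdl1, kd_pd1_pdl2, kd_drug,
                              contact_area_scale)
  hill_checkpoint(cx$c_pd1_pdl1, cx$c_pd1_pdl2, k_half, n_hill, delta)
}

#' TCE Hill factor as a function of local drug concentration
#'
#' @param tce_conc vector of molar TCE concentrations.
#' @inheritParams solve_tce_equilibrium
#' @inheritParams hill_tce
#' @return Numeric vector of Hill factors, same length as `tce_conc`.
#' @export
tce_hill_curve <- function(tce_conc, cea_total, cd3_total, lam, kd_cea, kd_cd3,
                           contact_area_scale, k_half, n_hill = 2) {
  sp <- .tce_solve_vec(tce_conc, cea_total, cd3_total, lam, kd_cea, kd_cd3,
                       contact_area_scale)
  hill_tce(sp$trimer, k_half, n_hill)
}

.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      rlang::abort(sprintf("`%s` must be finite and non-negative.", nm),
                   class = "tcevct_validation_error")
    }
  }
  invisible(TRUE)
}
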