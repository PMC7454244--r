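# Shared helpers: independent oracles and cached expensive runs.

# Closed-form two-species binding: C = ((P+L+K) - sqrt((P+L+K)^2 - 4PL)) / 2
two_species_complex <- function(p_tot, l_tot, kd) {
  s <- p_tot + l_tot + kd
  (s - sqrt(s^2 - 4 * p_tot * l_tot)) / 2
}

# Independent damped fixed-point oracle for the TCE trimer equilibrium,
# deliberately avoiding the closed-form quadratic used by the implementation.
tce_fixed_point_oracle <- function(cea_total, cd3_total, tce_conc, lam,
                                   kd_cea, kd_cd3, kappa,
                                   iters = 20000, damp = 0.5) {
  a <- tce_conc / kd_cea
  b <- tce_conc / kd_cd3
  cc <- if (tce_conc > 0 && lam > 0) a * lam / (kappa * kd_cd3) else 0
  e <- cea_total
  d <- cd3_total
  for (i in seq_len(iters)) {
    e_new <- cea_total / (1 + a + cc * d)
    d_new <- cd3_total / (1 + b + cc * e)
    if (max(abs(e_new - e), abs(d_new - d)) < 1e-12 * max(1, cea_total)) {
      e <- e_new; d <- d_new
      break
    }
    e <- damp * e_new + (1 - damp) * e
    d <- damp * d_new + (1 - damp) * d
  }
  list(free_cea = e, free_cd3 = d, trimer = cc * e * d,
       dimer_cea = a * e, dimer_cd3 = b * d)
}

# Brute-force PRCC from inversion of the full rank-correlation matrix:
# partial corr(i, j | rest) = -P[i,j] / sqrt(P[i,i] P[j,j]), P = R^-1.
prcc_matrix_oracle <- function(params, outcome) {
  m <- cbind(apply(as.matrix(params), 2, rank), outcome = rank(outcome))
  r <- stats::cor(m)
  p <- solve(r)
  k <- ncol(m)
  vapply(seq_len(k - 1), function(j) {
    -p[j, k] / sqrt(p[j, j] * p[k, k])
  }, numeric(1))
}

# Brute-force AUC by pairwise concordance counting with half-credit ties.
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}

# A patient whose tumor responds quickly under combination therapy.
responder_params <- function(...) {
  model_params(n_clones = 180, k_growth = 0.008, d_init = 3, ...)
}

ref_arms <- function() default_arms()

# Expensive full-scale runs are computed once per test session.
.cache <- new.env(parent = emptyenv())

cached_cohort <- function() {
  if (is.null(.cache$cohort)) .cache$cohort <- generate_cohort(n = 2000, seed = 1)
  .cache$cohort
}

cached_trial <- function() {
  if (is.null(.cache$trial)) .cache$trial <- run_trial(cached_cohort(), ref_arms())
  .cache$trial
}

cached_delta_trial <- function() {
  if (is.null(.cache$delta)) {
    co <- generate_cohort(default_parameter_space(delta_axis = TRUE),
                          n = 2000, seed = 1)
    arm <- list(arm_spec("atezolizumab_mono",
                         list(regimen("atezolizumab", 1200, 21))))
    .cache$delta <- list(cohort = co, trial = run_trial(co, arm))
  }
  .cache$delta
}
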