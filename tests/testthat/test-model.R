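test_that("tumor geometry maps are exact and invertible", {
  p <- model_params()
  g <- tumor_geometry(0, p)
  expect_identical(g$volume_cm3, 0)
  expect_identical(g$diameter_cm, 0)
  # a pi/6 cm^3 sphere has diameter exactly 1 cm
  cells <- 0.5235987755982988 * p$packing / p$vol_cell
  expect_equal(tumor_geometry(cells, p)$diameter_cm, 1, tolerance = 1e-12)
  set.seed(1)
  n <- 10^runif(100, 3, 12)
  back <- cells_from_diameter(tumor_geometry(n, p)$diameter_cm, p)
  expect_equal(back, n, tolerance = 1e-12)
})

test_that("cancer compartment reduces to logistic growth when killing is off", {
  p <- model_params(k_kill_tcr = 0, k_kill_tce = 0)
  pre <- initialize_pretreatment(p)
  tr <- simulate_patient(p, list(), pre = pre, horizon = 100,
                         rtol = 1e-9, atol = 1e-4)
  c0 <- pre$state[["cancer_cells"]]
  closed <- p$c_max / (1 + (p$c_max / c0 - 1) * exp(-p$k_growth * 100))
  expect_equal(tr$cancer_cells[nrow(tr)], closed, tolerance = 1e-6)
})

test_that("a zero-dose TCE regimen reproduces the atezolizumab-mono trajectory exactly", {
  p <- model_params()
  pre <- initialize_pretreatment(p)
  mono <- simulate_patient(p, list(regimen("atezolizumab", 1200, 21)), pre = pre)
  combo0 <- simulate_patient(p, list(regimen("atezolizumab", 1200, 21),
                                     regimen("cibisatamab", 0, 7)), pre = pre)
  expect_identical(mono$cancer_cells, combo0$cancer_cells)
  expect_identical(mono$teff_tumor, combo0$teff_tumor)
})

test_that("absent APC PD-L1 removes all priming inhibition", {
  p <- model_params(pdl1_apc = 0)
  h <- checkpoint_hill_curve(0, p$pd1_total, 0, p$r_pdl2, p$chi, p$kd_pd1_pdl1,
                             p$kd_pd1_pdl2, p$kd_drug, p$contact_area_scale,
                             p$k_half_ln, p$n_ln, p$delta)
  expect_identical(h, 0)
})

test_that("pre-treatment initialization stops at the target diameter", {
  p <- model_params(d_init = 2.5)
  pre <- initialize_pretreatment(p)
  expect_false(pre$no_tumor)
  expect_gte(pre$observables$tumor_diameter_cm, 2.5 - 1e-6)
  expect_lt(pre$observables$tumor_diameter_cm, 2.6)
})

test_that("patients whose tumors never grow are flagged as non-patients", {
  expect_true(initialize_pretreatment(model_params(k_growth = 0))$no_tumor)
  # an immune-competent draw controls its tumor below the target diameter
  strong <- model_params(n_clones = 220, k_kill_tcr = 40, d_init = 6,
                         k_growth = 0.005, pdl1_cancer = 3e3, pdl1_apc = 1e3)
  expect_true(initialize_pretreatment(strong)$no_tumor)
})

test_that("untreated growth-dominant tumors progress toward carrying capacity", {
  p <- model_params()
  pre <- initialize_pretreatment(p)
  tr <- simulate_patient(p, list(), pre = pre)
  expect_true(all(diff(tr$cancer_cells) > -1))
  expect_gt(tr$diameter_cm[nrow(tr)], 1.2 * tr$diameter_cm[1])
})

test_that("identical patients and regimens give bit-identical trajectories", {
  p <- responder_params()
  pre <- initialize_pretreatment(p)
  regs <- list(regimen("atezolizumab", 1200, 21), regimen("cibisatamab", 60, 7))
  a <- simulate_patient(p, regs, pre = pre)
  b <- simulate_patient(p, regs, pre = pre)
  expect_identical(a, b)
})

test_that("halving solver tolerances moves day-400 diameter by less than 0.1%", {
  for (p in list(model_params(), responder_params())) {
    pre <- initialize_pretreatment(p)
    regs <- list(regimen("atezolizumab", 1200, 21), regimen("cibisatamab", 60, 7))
    d1 <- simulate_patient(p, regs, pre = pre)$diameter_cm
    d2 <- simulate_patient(p, regs, pre = pre, rtol = 5e-7, atol = 5e-4)$diameter_cm
    n <- length(d1)
    expect_lt(abs(d1[n] - d2[n]) / max(d2[n], 0.2), 1e-3)
  }
})

test_that("day-400 burden is non-increasing in cibisatamab dose", {
  p <- model_params(n_clones = 90, k_growth = 0.009, d_init = 5)
  pre <- initialize_pretreatment(p)
  d400 <- vapply(c(0, 15, 60, 240), function(mg) {
    regs <- if (mg > 0) list(regimen("cibisatamab", mg, 7)) else list()
    tr <- simulate_patient(p, regs, pre = pre)
    tr$diameter_cm[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(d400) <= 1e-4))
})

test_that("day-400 burden is non-increasing in TMB, all else fixed", {
  d400 <- vapply(c(10, 40, 80, 140, 220), function(tmb) {
    p <- model_params(n_clones = tmb, k_growth = 0.009, d_init = 5)
    pre <- initialize_pretreatment(p)
    tr <- simulate_patient(p, list(regimen("atezolizumab", 1200, 21)), pre = pre)
    tr$diameter_cm[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(d400) <= 1e-4))
})

test_that("states stay non-negative and combination dominates both monotherapies", {
  space <- default_parameter_space()
  draws <- lhs_sample(space, 1000, seed = 5)
  arms <- list(
    atezo = list(regimen("atezolizumab", 1200, 21)),
    ciba = list(regimen("cibisatamab", 60, 7)),
    combo = list(regimen("atezolizumab", 1200, 21), regimen("cibisatamab", 60, 7))
  )
  bp <- model_params()
  checked <- 0L
  dominance_checked <- 0L
  for (i in seq_len(nrow(draws))) {
    p <- patient_params(draws[i, ], bp)
    pre <- initialize_pretreatment(p)
    if (pre$no_tumor) next
    d_end <- vapply(arms, function(regs) {
      tr <- simulate_patient(p, regs, pre = pre)
      states <- as.matrix(tr[, c("cancer_cells", "dying_cells", "antigen_pool",
                                 "apc_immature", "apc_mature_tumor",
                                 "apc_mature_ln", "t_naive_central", "t_act_ln",
                                 "teff_central", "teff_peripheral", "teff_tumor",
                                 "treg_ln", "treg_central", "treg_tumor")])
      expect_true(all(is.finite(states)))
      expect_true(all(states >= 0))
      tr$diameter_cm[nrow(tr)]
    }, numeric(1))
    checked <- checked + 1L
    if (dominance_checked < 150L) {
      expect_lte(d_end[["combo"]], min(d_end[["atezo"]], d_end[["ciba"]]) + 1e-4)
      dominance_checked <- dominance_checked + 1L
    }
  }
  expect_gte(checked, 500L)
  expect_gte(dominance_checked, 100L)
})

test_that("simulation of a no-tumor patient is refused", {
  p <- model_params(k_growth = 0)
  pre <- initialize_pretreatment(p)
  expect_error(simulate_patient(p, list(), pre = pre),
               class = "tcevct_validation_error")
})
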