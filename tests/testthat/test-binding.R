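test_that("drug-free checkpoint solver matches the two-species quadratic", {
  oracle <- two_species_complex(3000, 10000, 1000)
  cx <- solve_checkpoint_equilibrium(
    pd1_total = 3000, pdl1_total = 10000, r_pdl2 = 0, drug_conc = 0,
    chi = 10, kd_pd1_pdl1 = 1000, kd_pd1_pdl2 = 300, kd_drug = 4e-10,
    contact_area_scale = 1e9
  )
  expect_equal(cx$c_pd1_pdl1, oracle, tolerance = 1e-6)
  # and over a sweep of totals/affinities
  set.seed(42)
  for (i in 1:50) {
    p <- 10^runif(1, 2, 5); l <- 10^runif(1, 2, 5.5); k <- 10^runif(1, 1, 4)
    cx <- solve_checkpoint_equilibrium(p, l, 0, 0, 1, k, 300, 4e-10, 1e9)
    expect_equal(cx$c_pd1_pdl1, two_species_complex(p, l, k), tolerance = 1e-6)
  }
})

test_that("checkpoint mass balances hold over random inputs", {
  set.seed(7)
  for (i in 1:1000) {
    p_tot <- 10^runif(1, 2, 5)
    l_tot <- 10^runif(1, 2, 5.5)
    r <- runif(1, 0, 0.07)
    conc <- 10^runif(1, -12, -5) * rbinom(1, 1, 0.8)
    chi <- runif(1, 0, 100)
    cx <- solve_checkpoint_equilibrium(p_tot, l_tot, r, conc, chi,
                                       10^runif(1, 1, 4), 10^runif(1, 2, 5),
                                       4e-10, 1e9)
    expect_true(all(unlist(cx) >= 0))
    res_p <- abs(cx$free_pd1 + cx$c_pd1_pdl1 + cx$c_pd1_pdl2 - p_tot) / p_tot
    res_l <- abs(cx$free_pdl1 + cx$c_pd1_pdl1 + cx$c_drug_pdl1_mono +
                   2 * cx$c_drug_pdl1_cross - l_tot) / l_tot
    l2 <- r * l_tot
    res_2 <- abs(cx$free_pdl2 + cx$c_pd1_pdl2 - l2) / max(l2, 1)
    expect_lt(max(res_p, res_l, res_2), 1e-8)
  }
})

test_that("saturating drug abolishes PD-1/PD-L1 but never touches PD-L2", {
  big <- 1e6 * 4e-10
  cx <- solve_checkpoint_equilibrium(3000, 10000, 0.05, big, 10, 1000, 300,
                                     4e-10, 1e9)
  expect_lt(cx$c_pd1_pdl1, 1e-2 * two_species_complex(3000, 10000, 1000))
  # with PD-L1 fully blocked, PD-1/PD-L2 relaxes to its own two-species form
  expect_equal(cx$c_pd1_pdl2, two_species_complex(3000, 0.05 * 10000, 300),
               tolerance = 1e-3)
})

test_that("zero PD-L1 zeroes every PD-L1- and PD-L2-containing complex", {
  cx <- solve_checkpoint_equilibrium(3000, 0, 0.05, 1e-8, 10, 1000, 300,
                                     4e-10, 1e9)
  expect_identical(cx$c_pd1_pdl1, 0)
  expect_identical(cx$c_pd1_pdl2, 0)
  expect_identical(cx$c_drug_pdl1_mono, 0)
  expect_identical(cx$free_pd1, 3000)
})

test_that("drug competition and cross-arm avidity are monotone", {
  concs <- 10^seq(-11, -6, length.out = 12)
  c1 <- vapply(concs, function(cc) {
    solve_checkpoint_equilibrium(1e4, 3e4, 0, cc, 10, 500, 300, 4e-10,
                                 1e9)$c_pd1_pdl1
  }, numeric(1))
  expect_true(all(diff(c1) < 0))
  free_l1 <- vapply(c(0, 1, 10, 100), function(x) {
    solve_checkpoint_equilibrium(1e4, 3e4, 0, 1e-9, x, 500, 300, 4e-10,
                                 1e9)$free_pdl1
  }, numeric(1))
  expect_true(all(diff(free_l1) < 0))
})

test_that("checkpoint Hill factor behaves at its anchors", {
  expect_identical(hill_checkpoint(0, 0, 300), 0)
  expect_equal(hill_checkpoint(300, 0, 300, n_hill = 1, delta = 0), 0.5)
  # delta = 0 is identical to a PD-L2-free patient for any complex densities
  h0 <- hill_checkpoint(123, 456, 300, 2, delta = 0)
  expect_identical(h0, hill_checkpoint(123, 0, 300, 2, delta = 1))
  expect_true(all(diff(hill_checkpoint(seq(0, 5000, 100), 0, 300)) >= 0))
})

test_that("TCE equilibrium conserves both receptor pools", {
  set.seed(11)
  for (i in 1:1000) {
    e_tot <- 10^runif(1, 2, 6)
    d_tot <- 10^runif(1, 3, 6)
    conc <- 10^runif(1, -13, -5) * rbinom(1, 1, 0.9)
    lam <- runif(1, 0, 100)
    sp <- solve_tce_equilibrium(e_tot, d_tot, conc, lam, 10^runif(1, -9, -7),
                                10^runif(1, -8, -6), 1e9)
    expect_true(all(unlist(sp) >= 0))
    expect_lt(abs(sp$free_cea + sp$dimer_cea + sp$trimer - e_tot) / e_tot, 1e-8)
    expect_lt(abs(sp$free_cd3 + sp$dimer_cd3 + sp$trimer - d_tot) / d_tot, 1e-8)
    expect_lte(sp$trimer, min(e_tot, d_tot) * (1 + 1e-12))
  }
})

test_that("no drug or no cross-arm efficiency means no synapse", {
  sp0 <- solve_tce_equilibrium(1e5, 1e5, 0, 10, 2e-8, 2e-7, 1e9)
  expect_identical(sp0$trimer, 0)
  expect_identical(sp0$dimer_cea, 0)
  for (conc in 10^seq(-12, -6, 2)) {
    expect_identical(
      solve_tce_equilibrium(1e5, 1e5, conc, 0, 2e-8, 2e-7, 1e9)$trimer, 0
    )
  }
})

test_that("trimer vs dose is hook-shaped and matches a brute-force oracle", {
  doses <- 10^seq(-13, -3, length.out = 81)
  trimer <- vapply(doses, function(cc) {
    solve_tce_equilibrium(1e5, 1e5, cc, 10, 2e-8, 2e-7, 1e11)$trimer
  }, numeric(1))
  # zero at both extremes, unimodal in between
  expect_lt(trimer[1], 1e-3 * max(trimer))
  expect_lt(trimer[length(trimer)], 0.05 * max(trimer))
  peak <- which.max(trimer)
  expect_true(all(diff(trimer[1:peak]) >= -1e-9 * max(trimer)))
  expect_true(all(diff(trimer[peak:length(trimer)]) <= 1e-9 * max(trimer)))
  # peak location and height agree with the independent fixed-point oracle
  oracle <- vapply(doses, function(cc) {
    tce_fixed_point_oracle(1e5, 1e5, cc, 10, 2e-8, 2e-7, 1e11)$trimer
  }, numeric(1))
  expect_equal(which.max(oracle), peak)
  expect_equal(max(trimer), max(oracle), tolerance = 1e-3)
  expect_equal(trimer, oracle, tolerance = 1e-3)
})

test_that("TCE Hill factor is monotone in trimer density", {
  expect_identical(hill_tce(0, 500), 0)
  expect_equal(hill_tce(500, 500), 0.5)
  set.seed(3)
  for (i in 1:1000) {
    k <- 10^runif(1, 1, 5)
    n <- sample(1:4, 1)
    t1 <- 10^runif(1, 0, 6)
    t2 <- t1 * runif(1, 1, 10)
    expect_gte(hill_tce(t2, k, n), hill_tce(t1, k, n) - 1e-12)
  }
})

test_that("binding solvers are deterministic", {
  a <- solve_checkpoint_equilibrium(1e4, 3e4, 0.03, 2e-9, 25, 500, 5e4, 4e-10, 1e9)
  b <- solve_checkpoint_equilibrium(1e4, 3e4, 0.03, 2e-9, 25, 500, 5e4, 4e-10, 1e9)
  expect_identical(a, b)
  x <- solve_tce_equilibrium(1e5, 1e5, 3e-9, 10, 2e-8, 2e-7, 1e9)
  y <- solve_tce_equilibrium(1e5, 1e5, 3e-9, 10, 2e-8, 2e-7, 1e9)
  expect_identical(x, y)
})

test_that("invalid binding inputs are rejected", {
  expect_error(solve_checkpoint_equilibrium(-1, 1e4, 0, 0, 1, 500, 300, 4e-10, 1e9),
               class = "tcevct_validation_error")
  expect_error(solve_checkpoint_equilibrium(1e4, 1e4, 0.2, 0, 1, 500, 300, 4e-10, 1e9),
               class = "tcevct_validation_error")
  expect_error(solve_tce_equilibrium(1e5, 1e5, -1e-9, 1, 2e-8, 2e-7, 1e9),
               class = "tcevct_validation_error")
  expect_error(hill_checkpoint(10, 10, 300, n_hill = 0.5),
               class = "tcevct_validation_error")
})
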