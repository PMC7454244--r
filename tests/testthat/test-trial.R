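test_that("RECIST classification follows the closed-threshold rules", {
  r <- classify_recist(5, 3.4)
  expect_equal(r$pct_change, -32)
  expect_identical(as.character(r$recist), "PR")

  r <- classify_recist(5, 6.1)
  expect_equal(r$pct_change, 22)
  expect_identical(as.character(r$recist), "PD")

  # CR floor wins regardless of percent change
  expect_identical(as.character(classify_recist(5, 0.1)$recist), "CR")
  expect_identical(as.character(classify_recist(0.25, 0.19)$recist), "CR")

  # boundaries are closed: exactly -30 is PR, exactly +20 is PD
  expect_identical(as.character(classify_recist(5, 3.5)$recist), "PR")
  expect_identical(as.character(classify_recist(5, 6.0)$recist), "PD")
  expect_identical(as.character(classify_recist(5, 5.9)$recist), "SD")
  expect_identical(as.character(classify_recist(5, 3.6)$recist), "SD")

  expect_error(classify_recist(0, 1), class = "tcevct_validation_error")
})

test_that("Agresti-Coull interval matches its closed form", {
  # hand evaluation for k = 0, n = 20, z = 1.96
  z <- 1.96
  nt <- 20 + z^2
  pt <- (z^2 / 2) / nt
  half <- z * sqrt(pt * (1 - pt) / nt)
  ci <- orr_with_ci(0, 20)
  expect_identical(ci$orr, 0)
  expect_equal(ci$ci_low, max(0, pt - half))
  expect_equal(ci$ci_high, pt + half)

  expect_equal(orr_with_ci(20, 20)$ci_high, 1)
  expect_equal(round(100 * orr_with_ci(69, 1325)$orr, 1), 5.2)
  expect_error(orr_with_ci(5, 4), class = "tcevct_validation_error")
})

test_that("bootstrap ORR interval matches exact binomial order statistics", {
  expect_equal(bootstrap_orr_ci(rep(TRUE, 50), 31, reps = 500)$ci_low, 1)
  expect_equal(bootstrap_orr_ci(rep(FALSE, 50), 31, reps = 500)$ci_high, 0)

  flags <- rep(c(TRUE, FALSE), c(100, 900))  # ORR 10%, n = 1000
  ci <- bootstrap_orr_ci(flags, 31, reps = 10000, seed = 4)
  exact_lo <- qbinom(0.025, 31, 0.1) / 31
  exact_hi <- qbinom(0.975, 31, 0.1) / 31
  expect_lt(abs(ci$ci_low - exact_lo), 0.01)
  expect_lt(abs(ci$ci_high - exact_hi), 0.01)
  # reproducible by seed
  expect_identical(ci, bootstrap_orr_ci(flags, 31, reps = 10000, seed = 4))
})

test_that("mono-to-combination transitions cover the full class grid", {
  classes <- c("CR", "PR", "SD", "PD")
  grid <- expand.grid(mono = classes, combo = classes, stringsAsFactors = FALSE)
  mono <- tibble::tibble(patient_id = seq_len(16), recist = grid$mono)
  combo <- tibble::tibble(patient_id = seq_len(16), recist = grid$combo)
  ct <- cross_tabulate(mono, combo)
  expect_identical(nrow(ct), 16L)
  # exhaustive expectation from the definition (PR and CR merged)
  m <- ifelse(grid$mono %in% c("CR", "PR"), "PR/CR", grid$mono)
  cb <- ifelse(grid$combo %in% c("CR", "PR"), "PR/CR", grid$combo)
  want <- dplyr::case_when(
    m == "PD" & cb == "PD" ~ "PD-PD",
    m == "PD" & cb == "SD" ~ "PD-SD",
    m == "PD" & cb == "PR/CR" ~ "PD-PR/CR",
    m == "SD" & cb == "SD" ~ "SD-SD",
    m == "SD" & cb == "PR/CR" ~ "SD-PR/CR",
    TRUE ~ "other"
  )
  expect_identical(ct$transition, want)
  # improvements from PR/CR back to PD are counted as "other"
  expect_identical(ct$transition[ct$mono == "PR/CR" & ct$combo == "PD"],
                   rep("other", 2))
  expect_error(cross_tabulate(mono[-1, ], combo),
               class = "tcevct_validation_error")
})

test_that("responder-group labels are mutually exclusive and exhaustive", {
  mk <- function(a, c, cb) {
    resp <- tibble::tibble(
      patient_id = 1L,
      arm_id = c("atezolizumab_mono", "cibisatamab_mono", "combination"),
      recist = factor(c(a, c, cb), levels = c("CR", "PR", "SD", "PD"))
    )
    responder_groups(list(responses = resp))$group
  }
  expect_identical(mk("PR", "PD", "PD"), "ROA")
  expect_identical(mk("PD", "CR", "PD"), "ROC")
  expect_identical(mk("PR", "PR", "PD"), "ROB")  # regardless of combination
  expect_identical(mk("PD", "PD", "PR"), "ROCMB")
  expect_identical(mk("PD", "SD", "SD"), "NR")
  expect_error(responder_groups(list(responses = tibble::tibble(
    patient_id = 1L, arm_id = "combination",
    recist = factor("PD", levels = c("CR", "PR", "SD", "PD"))
  ))), class = "tcevct_validation_error")
})

test_that("an untreated control arm yields no responders in a growth-dominant cohort", {
  co <- generate_cohort(n = 60, seed = 31)
  tr <- run_trial(co, list(arm_spec("control", list())))
  s <- glance(tr)
  expect_identical(s$n_cr_pr, 0L)
  expect_gt(s$n_pd / s$n, 0.9)
})

test_that("trial bookkeeping: classes partition each arm's denominator", {
  tr <- cached_trial()
  s <- glance(tr)
  expect_identical(s$n_cr_pr + s$n_sd + s$n_pd, s$n)
  n_plausible <- sum(cached_cohort()$plausible)
  expect_true(all(s$n + table(factor(tr$failures$arm_id,
                                     levels = s$arm_id)) == n_plausible))
  # same patients simulated in every arm from the identical pre-state
  wide <- table(tr$responses$patient_id)
  expect_true(all(wide == length(unique(tr$responses$arm_id))))
  expect_identical(tidy(tr), tr$responses)
})
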