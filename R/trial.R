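#' Treatment arm specifications
#'
#' The three reference arms of the virtual trial: atezolizumab 1200 mg every
#' three weeks, cibisatamab 60 mg weekly, and their concurrent combination,
#' all evaluated at day 400.
#'
#' @param arm_id one of `"atezolizumab_mono"`, `"cibisatamab_mono"`,
#'   `"combination"`.
#' @param regimens list of [regimen()] objects.
#' @param horizon evaluation horizon (days).
#' @return A list of class `tcevct_arm`.
#' @export
arm_spec <- function(arm_id, regimens, horizon = 400) {
  arm_id <- match.arg(arm_id, c("atezolizumab_mono", "cibisatamab_mono",
                                "combination", "control"))
  structure(list(arm_id = arm_id, regimens = regimens, horizon = horizon),
            class = "tcevct_arm")
}

#' @rdname arm_spec
#' @export
default_arms <- function() {
  list(
    arm_spec("atezolizumab_mono", list(regimen("atezolizumab", 1200, 21))),
    arm_spec("cibisatamab_mono", list(regimen("cibisatamab", 60, 7))),
    arm_spec("combination", list(regimen("atezolizumab", 1200, 21),
                                 regimen("cibisatamab", 60, 7)))
  )
}

#' RECIST 1.1 classification of a diameter change
#'
#' Single-lesion simplification of RECIST 1.1 on sphere-equivalent diameter:
#' percent change is `100 * (d_end - d0) / d0`; complete response (CR) when
#' the final diameter falls below the detection floor `cr_floor`; partial
#' response (PR) at <= -30 percent; progressive disease (PD) at >= +20
#' percent (the absolute 5 mm condition is dropped for a single noiseless
#' synthetic lesion); stable disease (SD) otherwise. Thresholds are closed:
#' exactly -30 is PR and exactly +20 is PD.
#'
#' @param d0 baseline diameter (cm, > 0); vectorized.
#' @param d_end diameter at evaluation (cm, >= 0).
#' @param cr_floor detection floor for CR (cm).
#' @return A tibble with `pct_change` and `recist` (factor CR/PR/SD/PD).
#' @export
classify_recist <- function(d0, d_end, cr_floor = 0.2) {
  if (any(d0 <= 0)) {
    rlang::abort("baseline diameter must be > 0.", class = "tcevct_validation_error")
  }
  pct <- 100 * (d_end - d0) / d0
  cls <- dplyr::case_when(
    d_end < cr_floor ~ "CR",
    pct <= -30 ~ "PR",
    pct >= 20 ~ "PD",
    TRUE ~ "SD"
  )
  tibble::tibble(pct_change = pct,
                 recist = factor(cls, levels = c("CR", "PR", "SD", "PD")))
}

#' Run a multi-arm virtual clinical trial
#'
#' Simulates every plausible patient of a cohort in every arm, starting each
#' arm from the identical pre-treatment state (the same virtual patients are
#' compared across therapies), and classifies the day-`horizon` RECIST
#' response from the percent change of tumor diameter. Patients whose
#' integration fails in an arm are dropped from that arm's denominator only,
#' with the failure recorded.
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param arms list of [arm_spec()]s (default the three reference arms).
#' @param grid_step trajectory output step (days).
#' @param keep_trajectories retain full per-patient trajectories (memory-heavy
#'   at cohort scale; default keeps only baseline/final summaries).
#' @param progress print a note every 250 patient-arm simulations.
#' @return An object of class `tcevct_trial`: list with `responses` (tibble:
#'   `patient_id`, `arm_id`, `d0`, `d_end`, `pct_change`, `recist`),
#'   `summary` (per-arm counts and ORR with Agresti-Coull CI), `failures`,
#'   and `trajectories` (if kept).
#' @export
run_trial <- function(cohort, arms = default_arms(), grid_step = 2,
                      keep_trajectories = FALSE, progress = FALSE) {
  stopifnot(inherits(cohort, "tcevct_cohort"))
  plausible <- dplyr::filter(cohort, .data$plausible)
  if (nrow(plausible) == 0L) {
    rlang::abort("cohort has no plausible patients.", class = "tcevct_validation_error")
  }
  base_params <- attr(cohort, "base_params")
  rows <- list()
  fails <- list()
  trajs <- list()
  n_done <- 0L
  for (arm in arms) {
    for (i in seq_len(nrow(plausible))) {
      pid <- plausible$patient_id[i]
      p <- patient_params(plausible[i, ], base_params)
      pre <- list(state = plausible$pre_state[[i]], no_tumor = FALSE)
      tr <- tryCatch(
        simulate_patient(p, arm$regimens, pre = pre, horizon = arm$horizon,
                         grid_step = grid_step),
        error = function(e) e
      )
      n_done <- n_done + 1L
      if (progress && n_done %% 250 == 0) {
        message("simulated ", n_done, " patient-arms")
      }
      if (inherits(tr, "error")) {
        fails[[length(fails) + 1L]] <- tibble::tibble(
          patient_id = pid, arm_id = arm$arm_id, message = conditionMessage(tr)
        )
        next
      }
      d0 <- tr$diameter_cm[1]
      d_end <- tr$diameter_cm[nrow(tr)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, arm_id = arm$arm_id, d0 = d0, d_end = d_end
      )
      if (keep_trajectories) {
        trajs[[length(trajs) + 1L]] <- dplyr::mutate(
          tr, patient_id = pid, arm_id = arm$arm_id, .before = 1
        )
      }
    }
  }
  responses <- dplyr::bind_rows(rows)
  responses <- dplyr::bind_cols(
    responses, classify_recist(responses$d0, responses$d_end)
  )
  out <- list(
    responses = responses,
    summary = summarize_trial(responses),
    failures = if (length(fails)) dplyr::bind_rows(fails) else
      tibble::tibble(patient_id = integer(), arm_id = character(),
                     message = character()),
    trajectories = if (keep_trajectories) dplyr::bind_rows(trajs) else NULL,
    cohort = cohort
  )
  class(out) <- "tcevct_trial"
  out
}

summarize_trial <- function(responses) {
  responses |>
    dplyr::group_by(.data$arm_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_cr_pr = sum(.data$recist %in% c("CR", "PR")),
      n_sd = sum(.data$recist == "SD"),
      n_pd = sum(.data$recist == "PD"),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(orr_with_ci(.data$n_cr_pr, .data$n)) |>
    dplyr::ungroup()
}

#' Agresti-Coull binomial confidence interval for a response rate
#'
#' Adjusted-Wald interval: with `z` the normal quantile, `n~ = n + z^2`,
#' `p~ = (k + z^2/2) / n~`, the CI is `p~ +/- z sqrt(p~ (1 - p~) / n~)`,
#' clipped to \[0, 1\]. The reported `orr` is the unadjusted `k / n`.
#'
#' @param k responders (0 <= k <= n).
#' @param n patients (>= 1).
#' @param z normal quantile (1.96 for a 95 percent CI).
#' @return A tibble with `orr`, `ci_low`, `ci_high`.
#' @export
orr_with_ci <- function(k, n, z = 1.96) {
  if (n < 1 || k < 0 || k > n) {
    rlang::abort("need 0 <= k <= n and n >= 1.", class = "tcevct_validation_error")
  }
  n_t <- n + z^2
  p_t <- (k + z^2 / 2) / n_t
  half <- z * sqrt(p_t * (1 - p_t) / n_t)
  tibble::tibble(
    orr = k / n,
    ci_low = max(0, p_t - half),
    ci_high = min(1, p_t + half)
  )
}

#' Percentile bootstrap confidence interval for a small-trial ORR
#'
#' Resamples `sample_size` patients with replacement `reps` times from the
#' per-patient responder flags and returns the 2.5th/97.5th percentiles of
#' the resampled response rates — mimicking the enrollment of a small real
#' trial from the plausible virtual population.
#'
#' @param responder logical vector of per-patient responder flags.
#' @param sample_size patients per resample (31 and 25 in the reference
#'   analyses).
#' @param reps bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return A tibble with `orr`, `ci_low`, `ci_high`, `sample_size`, `reps`.
#' @export
bootstrap_orr_ci <- function(responder, sample_size, reps = 10000, seed = 1L) {
  if (!length(responder)) {
    rlang::abort("`responder` must be non-empty.", class = "tcevct_validation_error")
  }
  if (sample_size < 1) {
    rlang::abort("`sample_size` must be >= 1.", class = "tcevct_validation_error")
  }
  set.seed(seed)
  x <- as.numeric(responder)
  orrs <- vapply(seq_len(reps), function(i) {
    mean(x[sample.int(length(x), sample_size, replace = TRUE)])
  }, numeric(1))
  q <- stats::quantile(orrs, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(orr = mean(x), ci_low = q[1], ci_high = q[2],
                 sample_size = sample_size, reps = reps)
}

#' Mono-to-combination response transitions
#'
#' Labels each patient by their RECIST class under a monotherapy versus the
#' combination, merging PR and CR: `PD-PD`, `PD-SD`, `PD-PR/CR`, `SD-SD`,
#' `SD-PR/CR` (the benefit groups of interest, with `PD-PD` and `SD-SD` as
#' reference) and `other` for the remaining class pairs (counted, not
#' analyzed).
#'
#' @param mono,combo response tibbles (columns `patient_id`, `recist`) over
#'   the same patient set.
#' @return A tibble with `patient_id`, `mono`, `combo` (merged classes) and
#'   `transition`.
#' @export
cross_tabulate <- function(mono, combo) {
  if (!setequal(mono$patient_id, combo$patient_id)) {
    rlang::abort("mono and combo arms must cover the same patients.",
                 class = "tcevct_validation_error")
  }
  merge_cls <- function(r) ifelse(r %in% c("CR", "PR"), "PR/CR", as.character(r))
  df <- dplyr::inner_join(
    dplyr::transmute(mono, .data$patient_id, mono = merge_cls(.data$recist)),
    dplyr::transmute(combo, .data$patient_id, combo = merge_cls(.data$recist)),
    by = "patient_id"
  )
  dplyr::mutate(df, transition = dplyr::case_when(
    mono == "PD" & combo == "PD" ~ "PD-PD",
    mono == "PD" & combo == "SD" ~ "PD-SD",
    mono == "PD" & combo == "PR/CR" ~ "PD-PR/CR",
    mono == "SD" & combo == "SD" ~ "SD-SD",
    mono == "SD" & combo == "PR/CR" ~ "SD-PR/CR",
    TRUE ~ "other"
  ))
}

#' Responder-group labels across the three arms
#'
#' Classifies each patient by which therapies they respond to (PR/CR):
#' `ROA` (atezolizumab monotherapy only), `ROC` (cibisatamab monotherapy
#' only), `ROB` (both monotherapies, regardless of combination class),
#' `ROCMB` (combination only) and `NR` (no response to any therapy).
#'
#' @param trial a `tcevct_trial` containing the three reference arms.
#' @return A tibble with `patient_id` and `group`.
#' @export
responder_groups <- function(trial) {
  resp <- trial$responses
  need <- c("atezolizumab_mono", "cibisatamab_mono", "combination")
  if (!all(need %in% resp$arm_id)) {
    rlang::abort("responder_groups() needs all three reference arms.",
                 class = "tcevct_validation_error")
  }
  wide <- resp |>
    dplyr::mutate(resp = .data$recist %in% c("CR", "PR")) |>
    dplyr::select("patient_id", "arm_id", "resp") |>
    tidyr::pivot_wider(names_from = "arm_id", values_from = "resp")
  wide <- dplyr::filter(
    wide, !is.na(.data$atezolizumab_mono) & !is.na(.data$cibisatamab_mono) &
      !is.na(.data$combination)
  )
  dplyr::transmute(wide, .data$patient_id, group = dplyr::case_when(
    atezolizumab_mono & cibisatamab_mono ~ "ROB",
    atezolizumab_mono & !cibisatamab_mono ~ "ROA",
    !atezolizumab_mono & cibisatamab_mono ~ "ROC",
    combination ~ "ROCMB",
    TRUE ~ "NR"
  ))
}

#' @export
tidy.tcevct_trial <- function(x, ...) x$responses

#' @export
glance.tcevct_trial <- function(x, ...) x$summary

#' @export
print.tcevct_trial <- function(x, ...) {
  cat("Virtual clinical trial:", length(unique(x$responses$arm_id)),
      "arm(s),", length(unique(x$responses$patient_id)), "plausible patients\n")
  print(x$summary)
  invisible(x)
}
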