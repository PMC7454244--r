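#' Load and validate a run configuration
#'
#' Reads a YAML run configuration binding the pipeline together: cohort size,
#' seeds, parameter-space overrides, screen bounds, arm specifications and
#' solver/output settings. Unknown keys are rejected by name; every schema
#' violation is reported, not just the first; omitted optional fields fall
#' back to documented defaults which are echoed via message when
#' `echo = TRUE`.
#'
#' @param path path to a YAML configuration file.
#' @param echo message the applied defaults.
#' @return A validated list of class `tcevct_config` with elements
#'   `cohort_size`, `seeds` (`cohort`, `bootstrap`), `space` (tibble),
#'   `bounds` (tibble), `arms` (list of [arm_spec()]), `params`
#'   ([model_params()]), `output_dir`.
#' @export
load_config <- function(path, echo = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: %s", path),
                 class = "tcevct_validation_error")
  }
  raw <- yaml::read_yaml(path)
  known <- c("cohort_size", "seeds", "parameter_space", "screen_bounds",
             "arms", "model_params", "output_dir")
  unknown <- setdiff(names(raw), known)
  problems <- character()
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  defaults_used <- character()

  cohort_size <- raw$cohort_size
  if (is.null(cohort_size)) {
    cohort_size <- 2000
    defaults_used <- c(defaults_used, "cohort_size = 2000")
  } else if (!is.numeric(cohort_size) || cohort_size < 1) {
    problems <- c(problems, "cohort_size must be a number >= 1")
  }

  seeds <- raw$seeds
  if (is.null(seeds)) {
    seeds <- list(cohort = 1L, bootstrap = 1L)
    defaults_used <- c(defaults_used, "seeds = (cohort 1, bootstrap 1)")
  } else {
    if (is.null(seeds$cohort)) {
      seeds$cohort <- 1L
      defaults_used <- c(defaults_used, "seeds$cohort = 1")
    }
    if (is.null(seeds$bootstrap)) {
      seeds$bootstrap <- 1L
      defaults_used <- c(defaults_used, "seeds$bootstrap = 1")
    }
    bad <- !vapply(seeds[c("cohort", "bootstrap")], function(s) {
      is.numeric(s) && s == round(s)
    }, logical(1))
    if (any(bad)) problems <- c(problems, "seeds must be integers")
  }

  space <- default_parameter_space()
  if (!is.null(raw$parameter_space)) {
    ps <- dplyr::bind_rows(lapply(raw$parameter_space, tibble::as_tibble))
    tryCatch(validate_parameter_space(ps),
             error = function(e) {
               problems <<- c(problems, conditionMessage(e))
             })
    space <- ps
  } else {
    defaults_used <- c(defaults_used, "parameter_space = packaged default")
  }

  bounds <- default_screen_bounds()
  if (!is.null(raw$screen_bounds)) {
    bounds <- dplyr::bind_rows(lapply(raw$screen_bounds, tibble::as_tibble))
    if (!all(c("name", "low", "high") %in% names(bounds)) ||
        any(bounds$low >= bounds$high)) {
      problems <- c(problems, "screen_bounds need name/low/high with low < high")
    }
  } else {
    defaults_used <- c(defaults_used, "screen_bounds = packaged default")
  }

  arms <- default_arms()
  if (!is.null(raw$arms)) {
    arms <- lapply(raw$arms, function(a) {
      regs <- lapply(a$regimens, function(r) {
        regimen(r$drug_id, r$dose_mg, r$interval_days,
                r$first_dose_day %||% 0, r$n_doses %||% Inf)
      })
      arm_spec(a$arm_id, regs, a$horizon %||% 400)
    })
  } else {
    defaults_used <- c(defaults_used, "arms = three reference arms")
  }

  params <- tryCatch(do.call(model_params, raw$model_params %||% list()),
                     error = function(e) {
                       problems <<- c(problems, conditionMessage(e))
                       model_params()
                     })

  output_dir <- raw$output_dir %||% "results"
  if (is.null(raw$output_dir)) {
    defaults_used <- c(defaults_used, "output_dir = 'results'")
  }

  if (length(problems)) {
    rlang::abort(paste0("invalid configuration:\n- ",
                        paste(problems, collapse = "\n- ")),
                 class = "tcevct_validation_error")
  }
  if (echo && length(defaults_used)) {
    message("config defaults applied: ", paste(defaults_used, collapse = "; "))
  }
  structure(
    list(cohort_size = as.integer(cohort_size),
         seeds = list(cohort = as.integer(seeds$cohort),
                      bootstrap = as.integer(seeds$bootstrap)),
         space = space, bounds = bounds, arms = arms, params = params,
         output_dir = output_dir),
    class = "tcevct_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cohort and trial outputs as plain-text tables
#'
#' `write_cohort()` stores one row per virtual patient (sampled axes,
#' screened observables, plausibility flag and reasons) as CSV with
#' `# key=value` header metadata recording the seed. `read_cohort()` checks
#' that every expected column is present and names any missing one.
#' `write_trial()` stores per-patient responses and the per-arm summary.
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- dplyr::select(cohort, -dplyr::any_of(c("pre_state")))
  df$reasons <- vapply(df$reasons, paste, character(1), collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", attr(cohort, "seed") %||% NA), con)
  writeLines(sprintf("# n=%d", nrow(cohort)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param space parameter space the cohort must cover.
#' @export
read_cohort <- function(path, space = default_parameter_space()) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("patient_id", space$name, "plausible")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("cohort file is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "tcevct_validation_error")
  }
  tibble::as_tibble(df)
}

#' @rdname write_cohort
#' @param trial a `tcevct_trial`.
#' @param dir output directory (created if needed).
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  jsonlite::write_json(trial$summary, file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Miniature end-to-end smoke fixture
#'
#' Builds a 24-patient cohort spanning the TMB ladder by construction
#' (stratified Latin hypercube guarantees one patient per TMB stratum),
#' runs the three reference arms, and returns the cohort, trial and a digest
#' of the response table. Deterministic for a fixed seed: the digest is
#' stable across runs.
#'
#' @param seed integer seed.
#' @return A list with `cohort`, `trial`, `digest` (md5 of the formatted
#'   response table).
#' @export
make_smoke_fixture <- function(seed = 1L) {
  space <- default_parameter_space()
  draws <- lhs_sample(space, 24, seed)
  # four constructed patients spanning the TMB ladder guarantee one patient
  # per RECIST class in the combination arm
  pin <- function(i, tmb, kg, d0, cea) {
    draws$n_clones[i] <<- tmb; draws$k_growth[i] <<- kg
    draws$d_init[i] <<- d0; draws$cea_total[i] <<- cea
    draws$q_in[i] <<- 1; draws$s_naive[i] <<- 5e7; draws$s_treg[i] <<- 8.6e5
    draws$pdl1_cancer[i] <<- 1e4; draws$pdl1_apc[i] <<- 3e4
    draws$pd1_total[i] <<- 1e4; draws$c_max[i] <<- 1e12
    draws$chi[i] <<- 10; draws$lam[i] <<- 10; draws$kd_cd3[i] <<- 2e-7
    draws$r_pdl2[i] <<- 0.035; draws$cd3_total[i] <<- 1e5
  }
  pin(21, 30, 0.011, 3, 1e5)     # PD
  pin(22, 116, 0.011, 4.5, 1e5)  # SD
  pin(23, 123, 0.011, 4.5, 1e5)  # PR
  pin(24, 220, 0.008, 1.5, 5e5)  # CR
  co <- generate_cohort(space, seed = seed, draws = draws)
  tr <- run_trial(co)
  tab <- tidy(tr)
  txt <- paste(
    sprintf("%d,%s,%.6f,%s", tab$patient_id, tab$arm_id, tab$pct_change,
            tab$recist),
    collapse = "\n"
  )
  tf <- tempfile()
  writeLines(txt, tf)
  digest <- unname(tools::md5sum(tf))
  unlink(tf)
  list(cohort = co, trial = tr, digest = digest)
}
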