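#' Latin hypercube sample of virtual patients
#'
#' Stratified uniform sampling: for each axis the `n` draws occupy the `n`
#' equal-probability strata of the axis range (on its linear or log10 scale),
#' one draw per stratum, uniformly jittered within the stratum, with
#' independent random stratum-to-patient permutations across axes.
#' Reproducible for a fixed `seed`.
#'
#' @param space parameter-space tibble (see [default_parameter_space()]).
#' @param n number of patients (>= 1).
#' @param seed integer seed.
#' @return A tibble with `patient_id` (1..n) and one column per axis, values
#'   on the natural (untransformed) scale.
#' @export
lhs_sample <- function(space, n, seed = 1L) {
  validate_parameter_space(space)
  if (n < 1) rlang::abort("`n` must be >= 1.", class = "tcevct_validation_error")
  set.seed(seed)
  cols <- lapply(seq_len(nrow(space)), function(j) {
    r <- space[j, ]
    u <- (sample.int(n) - 1 + stats::runif(n)) / n   # one draw per stratum
    if (r$scale == "log10") {
      10^(log10(r$low) + u * (log10(r$high) - log10(r$low)))
    } else {
      r$low + u * (r$high - r$low)
    }
  })
  names(cols) <- space$name
  out <- tibble::as_tibble(cols)
  dplyr::bind_cols(tibble::tibble(patient_id = seq_len(n)), out)
}

#' Normalize sampled parameter values to [0, 1]
#'
#' Maps values back to their position within the axis range under the axis's
#' sampling scale (log axes are normalized in log space). Used by the binned
#' response-rate analysis.
#'
#' @param values numeric vector on the natural scale.
#' @param axis one row of a parameter-space tibble.
#' @return Values in \[0, 1\].
#' @export
normalize_axis <- function(values, axis) {
  if (axis$scale == "log10") {
    (log10(values) - log10(axis$low)) / (log10(axis$high) - log10(axis$low))
  } else {
    (values - axis$low) / (axis$high - axis$low)
  }
}

#' Screen one virtual patient for physiological plausibility
#'
#' A patient is plausible iff their tumor developed (no `no_tumor` flag) and
#' every screened observable lies within its clinical bounds. Violated
#' bounds are reported in axis order, `no_tumor` first.
#'
#' @param pre result of [initialize_pretreatment()].
#' @param bounds screen-bounds tibble (see [default_screen_bounds()]).
#' @return A list with `plausible` (flag) and `reasons` (character vector,
#'   empty when plausible).
#' @export
screen_patient <- function(pre, bounds = default_screen_bounds()) {
  reasons <- character()
  if (isTRUE(pre$no_tumor)) reasons <- c(reasons, "no_tumor")
  obs <- pre$observables
  for (i in seq_len(nrow(bounds))) {
    b <- bounds[i, ]
    v <- obs[[b$name]]
    if (is.null(v)) {
      rlang::abort(sprintf("screened observable `%s` missing from pre-state", b$name),
                   class = "tcevct_validation_error")
    }
    if (v < b$low) reasons <- c(reasons, paste0(b$name, "_low"))
    if (v > b$high) reasons <- c(reasons, paste0(b$name, "_high"))
  }
  list(plausible = length(reasons) == 0L, reasons = reasons)
}

#' Generate a screened virtual cohort
#'
#' Composes [lhs_sample()], [initialize_pretreatment()] and
#' [screen_patient()]: samples `n` virtual patients, grows each tumor to its
#' pre-treatment size and applies the physiological screen. Implausible
#' patients are retained with their exclusion reasons (never deleted), so
#' exclusion counts are reproducible.
#'
#' @param space parameter-space tibble.
#' @param n cohort size (the reference virtual trial uses 2000).
#' @param seed integer seed for the Latin hypercube.
#' @param bounds screen-bounds tibble.
#' @param base_params baseline [model_params()] the sampled axes overwrite.
#' @param progress print a progress note every 250 patients.
#' @param draws optional pre-built draw tibble (one row per patient, columns
#'   `patient_id` + axis names) replacing the internal Latin hypercube;
#'   used by constructed fixtures.
#' @return A tibble of class `tcevct_cohort`: `patient_id`, one column per
#'   axis, screened observables, `plausible`, `reasons` (list-column) and
#'   `pre_state` (list-column of named state vectors). Attributes: `space`,
#'   `bounds`, `seed`, `base_params`.
#' @export
generate_cohort <- function(space = default_parameter_space(), n = 2000,
                            seed = 1L, bounds = default_screen_bounds(),
                            base_params = model_params(), progress = FALSE,
                            draws = NULL) {
  if (is.null(draws)) draws <- lhs_sample(space, n, seed)
  n <- nrow(draws)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patient_params(draws[i, ], base_params)
    pre <- initialize_pretreatment(p)
    scr <- screen_patient(pre, bounds)
    res[[i]] <- list(obs = pre$observables, plausible = scr$plausible,
                     reasons = scr$reasons, state = pre$state,
                     no_tumor = pre$no_tumor)
    if (progress && i %% 250 == 0) message("initialized ", i, "/", n, " patients")
  }
  out <- dplyr::bind_cols(
    draws,
    dplyr::bind_rows(lapply(res, `[[`, "obs")),
    tibble::tibble(
      no_tumor = vapply(res, `[[`, logical(1), "no_tumor"),
      plausible = vapply(res, `[[`, logical(1), "plausible"),
      reasons = lapply(res, `[[`, "reasons"),
      pre_state = lapply(res, `[[`, "state")
    )
  )
  attr(out, "space") <- space
  attr(out, "bounds") <- bounds
  attr(out, "seed") <- seed
  attr(out, "base_params") <- base_params
  class(out) <- c("tcevct_cohort", class(out))
  out
}

#' Assemble full model parameters for one sampled patient
#'
#' @param draw one-row tibble (or named list) of sampled axis values.
#' @param base_params baseline [model_params()].
#' @return A `tcevct_params` list with the sampled fields overridden.
#' @export
patient_params <- function(draw, base_params = model_params()) {
  draw <- as.list(draw)
  draw$patient_id <- NULL
  keep <- intersect(names(draw), names(base_params))
  p <- base_params
  p[keep] <- draw[keep]
  p
}
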