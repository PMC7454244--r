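#' Partial rank correlation coefficients (PRCC)
#'
#' Global sensitivity of an outcome to each sampled parameter axis,
#' controlling for all other axes: every column is rank-transformed, then for
#' axis j the PRCC is the Pearson correlation between the residuals of
#' rank-regressing axis j, and the outcome, on the remaining axes. P-values
#' use the t statistic (PRCC times `sqrt(df / (1 - PRCC^2))`) with
#' `df = n - 2 - (p - 1)` degrees of freedom (the standard approximation for
#' Latin-hypercube sensitivity analyses).
#'
#' @param params data frame / matrix of sampled parameters (n patients x p
#'   axes, no missing values, n > p + 2).
#' @param outcome numeric outcome vector of length n (e.g. day-400 tumor
#'   volume).
#' @return A tibble with `axis`, `prcc`, `p_value`, ordered as the input
#'   columns.
#' @export
prcc <- function(params, outcome) {
  x <- as.matrix(params)
  n <- nrow(x)
  p <- ncol(x)
  if (anyNA(x) || anyNA(outcome)) {
    rlang::abort("PRCC input must not contain missing values.",
                 class = "tcevct_validation_error")
  }
  if (length(outcome) != n || n <= p + 2) {
    rlang::abort("need length(outcome) == nrow(params) and n > p + 2.",
                 class = "tcevct_validation_error")
  }
  rx <- apply(x, 2, rank)
  ry <- rank(outcome)
  df <- n - 2 - (p - 1)
  out <- lapply(seq_len(p), function(j) {
    others <- cbind(1, rx[, -j, drop = FALSE])
    qr_o <- qr(others)
    if (qr_o$rank < ncol(others)) {
      rlang::abort(
        paste0("collinear rank design when conditioning on axes other than `",
               colnames(x)[j], "`"),
        class = "tcevct_validation_error"
      )
    }
    res_x <- qr.resid(qr_o, rx[, j])
    res_y <- qr.resid(qr_o, ry)
    r <- sum(res_x * res_y) / sqrt(sum(res_x^2) * sum(res_y^2))
    t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(axis = colnames(x)[j], prcc = r,
                   p_value = 2 * stats::pt(-abs(t_stat), df))
  })
  dplyr::bind_rows(out)
}

#' Wilcoxon rank-sum comparison of a biomarker between two groups
#'
#' Two-sided rank-sum test used for responder versus non-responder biomarker
#' distributions: exact enumeration when both samples are small (total <= 12)
#' and untied, otherwise the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @return A tibble with `statistic` (rank-sum W of `x`), `p_value`, and the
#'   significance `stars` used in figure legends (ns, * <= 0.05, ** <= 0.01,
#'   *** <= 0.001, **** <= 0.0001).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) {
    rlang::abort("both samples must be non-empty.", class = "tcevct_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    stars = p_stars(wt$p.value)
  )
}

#' @rdname wilcoxon_rank_sum
#' @param p p-value(s).
#' @return For [p_stars()], the star string(s).
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' ROC curve and AUC of a candidate predictive biomarker
#'
#' Threshold sweep over the unique biomarker values ("responder" predicted
#' when score >= threshold); the AUC equals the Mann-Whitney concordance
#' probability with ties counted one-half.
#'
#' @param scores numeric biomarker values.
#' @param labels logical (or 0/1) responder flags; both classes must be
#'   present.
#' @return A list of class `tcevct_roc`: `curve` (tibble `threshold`, `tpr`,
#'   `fpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    rlang::abort("scores and labels must be complete and equal-length.",
                 class = "tcevct_validation_error")
  }
  if (!any(labels) || all(labels)) {
    rlang::abort("both responder and non-responder labels are required.",
                 class = "tcevct_validation_error")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  thresholds <- c(sort(unique(scores)), Inf)
  curve <- tibble::tibble(
    threshold = thresholds,
    tpr = vapply(thresholds, function(th) sum(scores[labels] >= th) / n1, numeric(1)),
    fpr = vapply(thresholds, function(th) sum(scores[!labels] >= th) / n0, numeric(1))
  )
  # Mann-Whitney with midranks: ties count 1/2
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(curve = curve, auc = auc), class = "tcevct_roc")
}

#' @export
print.tcevct_roc <- function(x, ...) {
  cat("ROC curve:", nrow(x$curve), "thresholds, AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' Response rate across consecutive bins of a sorted biomarker
#'
#' Sorts patients ascending by one sampled axis, forms consecutive groups of
#' `bin_size` from the first patient (a trailing remainder forms a final,
#' flagged short bin), and computes each group's response rate with its
#' Agresti-Coull interval. The bin x-coordinate is the mean of the axis
#' values normalized to \[0, 1\] under the axis's sampling scale (log axes
#' normalized in log space).
#'
#' @param cohort a [generate_cohort()] tibble (plausible patients are used).
#' @param responses response tibble for one arm (`patient_id`, `recist`).
#' @param axis_name name of the sampled axis.
#' @param bin_size patients per bin (default 20).
#' @return A tibble with `bin`, `n`, `k`, `orr`, `ci_low`, `ci_high`,
#'   `mean_value`, `mean_normalized`, `short_bin`.
#' @export
orr_by_bins <- function(cohort, responses, axis_name, bin_size = 20) {
  space <- attr(cohort, "space")
  if (!axis_name %in% space$name) {
    rlang::abort(sprintf("unknown axis `%s`", axis_name),
                 class = "tcevct_validation_error")
  }
  axis <- space[space$name == axis_name, ]
  df <- cohort |>
    dplyr::filter(.data$plausible) |>
    dplyr::select("patient_id", value = dplyr::all_of(axis_name)) |>
    dplyr::inner_join(
      dplyr::transmute(responses, .data$patient_id,
                       resp = .data$recist %in% c("CR", "PR")),
      by = "patient_id"
    ) |>
    dplyr::arrange(.data$value)
  if (nrow(df) < bin_size) {
    rlang::abort("fewer patients than one bin.", class = "tcevct_validation_error")
  }
  df$bin <- (seq_len(nrow(df)) - 1) %/% bin_size + 1
  df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      k = sum(.data$resp),
      mean_value = mean(.data$value),
      mean_normalized = mean(normalize_axis(.data$value, axis)),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(orr_with_ci(.data$k, .data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(short_bin = .data$n < bin_size) |>
    dplyr::select("bin", "n", "k", "orr", "ci_low", "ci_high",
                  "mean_value", "mean_normalized", "short_bin")
}

#' Responder vs non-responder biomarker tests for a trial arm
#'
#' Runs [wilcoxon_rank_sum()] for every sampled axis between PR/CR and
#' non-PR/CR patients of one arm.
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param responses response tibble for one arm.
#' @return A tibble with `axis`, `statistic`, `p_value`, `stars`,
#'   `n_responders`, `n_nonresponders`.
#' @export
biomarker_group_tests <- function(cohort, responses) {
  space <- attr(cohort, "space")
  df <- cohort |>
    dplyr::filter(.data$plausible) |>
    dplyr::inner_join(
      dplyr::transmute(responses, .data$patient_id,
                       resp = .data$recist %in% c("CR", "PR")),
      by = "patient_id"
    )
  out <- lapply(space$name, function(ax) {
    x <- df[[ax]][df$resp]
    y <- df[[ax]][!df$resp]
    dplyr::mutate(wilcoxon_rank_sum(x, y), axis = ax,
                  n_responders = length(x), n_nonresponders = length(y),
                  .before = 1)
  })
  dplyr::bind_rows(out)
}
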