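# low-overhead one-row result tibble (these tests run inside tight
# simulation loops)
.test_result <- function(statistic, df, p_value) {
  tibble::new_tibble(list(statistic = statistic, df = df, p_value = p_value),
                     nrow = 1L)
}

#' Paired two-tailed t test
#'
#' Classical paired Student t test on the within-pair differences, with
#' `n - 1` degrees of freedom and a two-tailed p-value. Degenerate inputs are
#' handled explicitly: if every difference is zero the test is a perfect null
#' (`t = 0`, `p = 1`); if the differences are constant but nonzero the
#' statistic is unbounded and `p = 0` is returned.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2), aligned by pair.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop("input error: paired vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("input error: need at least 2 pairs", call. = FALSE)
  d <- x - y
  stderr <- stats::sd(d) / sqrt(length(d))
  if (stderr == 0 || stderr < 10 * .Machine$double.eps * abs(mean(d))) {
    if (all(d == 0)) {
      return(.test_result(0, length(d) - 1, 1))
    }
    return(.test_result(sign(mean(d)) * Inf, length(d) - 1, 0))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  .test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Welch two-sample t test
#'
#' Unpaired two-tailed t test with the Welch correction for unequal
#' variances (Welch-Satterthwaite degrees of freedom). Identical degenerate
#' groups return `t = 0`, `p = 1`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("input error: each group needs at least 2 observations", call. = FALSE)
  }
  stderr <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  if (stderr == 0 ||
      stderr < 10 * .Machine$double.eps * max(abs(mean(x)), abs(mean(y)))) {
    if (mean(x) == mean(y)) {
      return(.test_result(0, length(x) + length(y) - 2, 1))
    }
    return(.test_result(sign(mean(x) - mean(y)) * Inf,
                        length(x) + length(y) - 2, 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  .test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Fold change
#'
#' Ratio of two positive values, conventionally the 37 degC group mean over
#' the 25 degC group mean (or tumor over normal).
#'
#' @param value_hi Numerator value(s).
#' @param value_lo Denominator value(s); must be positive.
#' @return `value_hi / value_lo`. Vectorised.
#' @export
fold_change <- function(value_hi, value_lo) {
  if (any(value_lo <= 0)) {
    stop("invalid input: fold-change denominator must be positive", call. = FALSE)
  }
  value_hi / value_lo
}

#' Fisher's combined probability test
#'
#' Combines `m` independent p-values into a single probability via
#' `X2 = -2 * sum(log(p))`, referred to the upper tail of a chi-square
#' distribution with `2 m` degrees of freedom. With a single p-value the
#' combination is the identity; the combined p is exchangeable in its inputs
#' and monotone in each of them.
#'
#' @param p_values Numeric vector of p-values, each in `(0, 1]`.
#' @return The combined p-value.
#' @examples
#' fisher_combined(c(0.0087, 0.000289, 0.000321))
#' @export
fisher_combined <- function(p_values) {
  if (length(p_values) < 1) {
    stop("invalid probability: need at least one p-value", call. = FALSE)
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("invalid probability: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::pchisq(-2 * sum(log(p_values)), df = 2 * length(p_values),
                lower.tail = FALSE)
}

#' Pairwise ordinary least-squares regression
#'
#' Simple linear regression of `y` on `x` with the coefficient of
#' determination `R^2 = 1 - SSE/SST`, used to assess how independent two
#' measured parameters are (low `R^2` means nearly independent markers).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble with `slope`, `intercept` and `r_squared`.
#' @export
pairwise_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("input error: need >= 3 aligned points", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate fit: zero variance in x", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  )
}

#' Significance label for a p-value
#'
#' Standard star notation: `***` for `p < 0.001`, `**` for
#' `0.001 <= p < 0.01`, `*` for `0.01 <= p < 0.05`, `ns` otherwise. Boundary
#' values fall in the less significant band. Vectorised; `NA` propagates.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad)) {
    stop("invalid probability: p-values must lie in (0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Published single-parameter p-values of the reference breast cohort
#'
#' The per-parameter p-values reported for the reference paired
#' tumor/adjacent-normal breast biopsy cohort, for the four contrasts
#' (within-group temperature contrasts, paired t; between-group contrasts at
#' fixed temperature, Welch t) in each preparation arm. These serve as the
#' summary-input mode of [combine_pvalue_table()]: the published combined
#' probabilities can be reproduced from them without the unpublished raw
#' per-sample data.
#'
#' @return Tibble with columns `preparation`, `parameter`, `contrast`,
#'   `p_value` (24 rows).
#' @export
published_single_parameter_pvalues <- function() {
  contrasts <- c("N37_vs_N25", "T37_vs_T25", "T25_vs_N25", "T37_vs_N37")
  tibble::tibble(
    preparation = rep(c("deparaffinized", "formalin_fixed"), each = 12),
    parameter = rep(rep(c("rho_b", "rho_s", "k"), each = 4), 2),
    contrast = rep(contrasts, 6),
    p_value = c(
      1.03e-1, 1.15e-3, 2.33e-1, 1.30e-3,   # deparaffinized rho_b
      3.05e-1, 8.00e-3, 1.65e-1, 2.15e-2,   # deparaffinized rho_s
      2.94e-1, 5.15e-3, 6.02e-4, 1.49e-3,   # deparaffinized k
      9.57e-2, 1.40e-2, 7.00e-2, 8.70e-3,   # formalin-fixed rho_b
      1.43e-1, 7.44e-3, 1.21e-1, 2.89e-4,   # formalin-fixed rho_s
      2.14e-2, 6.00e-3, 1.03e-3, 3.21e-4    # formalin-fixed k
    )
  )
}

.parameter_sets <- list(
  "rho_b" = "rho_b",
  "rho_s" = "rho_s",
  "k" = "k",
  "rho_b+rho_s" = c("rho_b", "rho_s"),
  "rho_b+k" = c("rho_b", "k"),
  "rho_s+k" = c("rho_s", "k"),
  "rho_b+rho_s+k" = c("rho_b", "rho_s", "k")
)

#' Expand single-parameter p-values into the full combination table
#'
#' From a table of per-parameter p-values (one per preparation x parameter x
#' contrast), builds the complete delineation grid of 7 parameter sets
#' (singletons, the three pairs, and the triple) by applying
#' [fisher_combined()] to the single-parameter p-values of the same
#' preparation and contrast, and attaches significance labels. Combined cells
#' whose inputs are incomplete are left `NA`.
#'
#' @param pvalues Tibble in the layout of
#'   [published_single_parameter_pvalues()].
#' @return Tibble with columns `preparation`, `parameter_set`, `contrast`,
#'   `p_value`, `label`.
#' @examples
#' combine_pvalue_table(published_single_parameter_pvalues())
#' @export
combine_pvalue_table <- function(pvalues) {
  needed <- c("preparation", "parameter", "contrast", "p_value")
  if (!all(needed %in% names(pvalues))) {
    stop("input error: expected columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  combos <- expand.grid(
    preparation = unique(pvalues$preparation),
    parameter_set = names(.parameter_sets),
    contrast = unique(pvalues$contrast),
    stringsAsFactors = FALSE
  )
  combos$p_value <- vapply(seq_len(nrow(combos)), function(i) {
    members <- .parameter_sets[[combos$parameter_set[i]]]
    p <- pvalues$p_value[pvalues$preparation == combos$preparation[i] &
                           pvalues$contrast == combos$contrast[i] &
                           pvalues$parameter %in% members]
    if (length(p) != length(members) || anyNA(p)) return(NA_real_)
    fisher_combined(p)
  }, numeric(1))
  combos$label <- significance_label(combos$p_value)
  out <- tibble::as_tibble(combos)
  out$parameter_set <- factor(out$parameter_set, levels = names(.parameter_sets))
  dplyr::arrange(out, .data$preparation, .data$parameter_set, .data$contrast)
}

# single-parameter p-values from per-sample endpoint values:
# paired t across temperature within group, Welch t between groups at a
# fixed temperature
.single_parameter_pvalues <- function(wide) {
  params <- c("rho_b", "rho_s", "k")
  rows <- list()
  for (prep in unique(wide$preparation)) {
    w <- wide[wide$preparation == prep, ]
    tum <- w[w$group == "tumor", ]
    nor <- w[w$group == "normal", ]
    for (par in params) {
      v25 <- paste0(par, "_25")
      v37 <- paste0(par, "_37")
      p_of <- function(expr) tryCatch(expr$p_value, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        preparation = prep,
        parameter = par,
        contrast = c("N37_vs_N25", "T37_vs_T25", "T25_vs_N25", "T37_vs_N37"),
        p_value = c(
          if (nrow(nor) >= 2) p_of(paired_t_test(nor[[v37]], nor[[v25]])) else NA_real_,
          if (nrow(tum) >= 2) p_of(paired_t_test(tum[[v37]], tum[[v25]])) else NA_real_,
          if (nrow(tum) >= 2 && nrow(nor) >= 2)
            p_of(welch_t_test(tum[[v25]], nor[[v25]])) else NA_real_,
          if (nrow(tum) >= 2 && nrow(nor) >= 2)
            p_of(welch_t_test(tum[[v37]], nor[[v37]])) else NA_real_
        )
      )
    }
  }
  dplyr::bind_rows(rows)
}

# per-sample endpoint values in wide form (one row per sample)
.profiles_to_wide <- function(profiles, endpoints = c(25, 37)) {
  pr <- profiles[profiles$temperature_c %in% endpoints, ]
  tidyr::pivot_wider(
    pr,
    id_cols = c("sample_id", "patient_id", "group", "preparation"),
    names_from = "temperature_c",
    values_from = c("rho_b_ohm_cm", "rho_s_ohm_sq", "k_w_m_k"),
    names_glue = "{sub('_ohm_cm|_ohm_sq|_w_m_k', '', .value)}_{temperature_c}"
  )
}

#' Multi-parameter delineation table
#'
#' The central statistical analysis: from per-sample electrothermal profiles
#' with group metadata, computes for each preparation arm the four contrasts
#' (normal and tumor temperature contrasts by paired t test; tumor versus
#' normal at 25 and at 37 degC by Welch t test) for each single parameter,
#' combines them over every parameter subset with Fisher's method, attaches
#' significance labels, and reports group fold changes and the pairwise
#' regression R-squared between parameters.
#'
#' Combined cells are always derived from the table's own single-parameter
#' p-values, never recomputed from raw data. Analyses use the 25 and 37 degC
#' endpoint entries of the profiles; intermediate setpoints are ignored here.
#'
#' @param profiles Profile tibble from [build_profiles()] (requires both
#'   endpoint temperatures per sample and `group`/`preparation` metadata).
#' @return An object of class `delineation_table`: a list with
#'   `single_parameter` (12 rows per preparation), `cells` (28 labelled cells
#'   per preparation), `fold_changes`, and `r_squared` (pairwise parameter
#'   regressions per group, endpoints pooled).
#' @export
delineation_table <- function(profiles) {
  wide <- .profiles_to_wide(profiles)
  singles <- .single_parameter_pvalues(wide)
  singles$label <- significance_label(singles$p_value)
  cells <- combine_pvalue_table(singles)

  folds <- wide |>
    dplyr::group_by(.data$preparation, .data$group) |>
    dplyr::summarise(
      rho_b = fold_change(mean(.data$rho_b_37), mean(.data$rho_b_25)),
      rho_s = fold_change(mean(.data$rho_s_37), mean(.data$rho_s_25)),
      k = fold_change(mean(.data$k_37), mean(.data$k_25)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("rho_b", "rho_s", "k"),
                        names_to = "parameter", values_to = "fold_37_over_25")

  long <- profiles[profiles$temperature_c %in% c(25, 37), ]
  pairs <- list(c("rho_b_ohm_cm", "rho_s_ohm_sq"),
                c("rho_b_ohm_cm", "k_w_m_k"),
                c("rho_s_ohm_sq", "k_w_m_k"))
  r2 <- dplyr::bind_rows(lapply(unique(long$group), function(grp) {
    g <- long[long$group == grp, ]
    dplyr::bind_rows(lapply(pairs, function(pp) {
      fit <- pairwise_regression(g[[pp[1]]], g[[pp[2]]])
      tibble::tibble(group = grp,
                     pair = paste(sub("_ohm_cm|_ohm_sq|_w_m_k", "", pp),
                                  collapse = " vs "),
                     r_squared = fit$r_squared)
    }))
  }))

  structure(
    list(single_parameter = singles, cells = cells,
         fold_changes = folds, r_squared = r2),
    class = "delineation_table"
  )
}

#' @export
print.delineation_table <- function(x, ...) {
  cat("<delineation_table>\n")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$cells,
                  cell = sprintf("%.3g (%s)", .data$p_value, .data$label)),
    id_cols = c("preparation", "parameter_set"),
    names_from = "contrast", values_from = "cell"
  )
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Classify a specimen as tumor or normal from its technical repeats
#'
#' Implements the bimodal classification rule that avoids the need for a
#' paired adjacent-normal sample: the same specimen is measured at 25 and
#' 37 degC, and it is called a tumor when the temperature-driven increase in
#' both bulk and surface resistivity is statistically significant (paired t
#' across the technical repeats at level `alpha`) and both fold changes
#' exceed `fold_threshold`. The default threshold 3.8 sits midway between the
#' published tumor (about 4.1-4.8) and normal (about 2.9-3.5) fold ranges.
#'
#' @param repeat_profiles Profile tibble of the technical repeats of one
#'   specimen (>= 2 repeats, each with both 25 and 37 degC entries).
#' @param alpha Significance level for the paired tests.
#' @param fold_threshold Minimum fold change (37 over 25 degC) required for
#'   both resistivities.
#' @return A list with `call` ("tumor" or "normal") and an `evidence` tibble
#'   of per-parameter p-values and fold changes.
#' @export
classify_sample <- function(repeat_profiles, alpha = 0.05, fold_threshold = 3.8) {
  need <- repeat_profiles$temperature_c %in% c(25, 37)
  wide <- tidyr::pivot_wider(
    repeat_profiles[need, c("sample_id", "temperature_c",
                            "rho_b_ohm_cm", "rho_s_ohm_sq")],
    names_from = "temperature_c",
    values_from = c("rho_b_ohm_cm", "rho_s_ohm_sq"),
    names_glue = "{sub('_ohm_cm|_ohm_sq', '', .value)}_{temperature_c}"
  )
  if (nrow(wide) < 2 || anyNA(wide)) {
    stop("cannot classify: need >= 2 technical repeats with both ",
         "endpoint temperatures", call. = FALSE)
  }
  evidence <- dplyr::bind_rows(lapply(c("rho_b", "rho_s"), function(par) {
    ht <- paired_t_test(wide[[paste0(par, "_37")]], wide[[paste0(par, "_25")]])
    tibble::tibble(
      parameter = par,
      p_value = ht$p_value,
      fold = fold_change(mean(wide[[paste0(par, "_37")]]),
                         mean(wide[[paste0(par, "_25")]]))
    )
  }))
  is_tumor <- all(evidence$p_value < alpha) && all(evidence$fold > fold_threshold)
  list(call = if (is_tumor) "tumor" else "normal", evidence = evidence)
}
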