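#' Correlate immune-cell fractions with a TF activity score
#'
#' Spearman correlation between each deconvolved cell-type fraction and the
#' per-sample activity score of the designated TF, with shared-permutation
#' p-values and BH adjustment across cell types. Constant fraction columns
#' are flagged missing with a warning. Per-sample fraction sums above
#' `1 + 1e-6` are an error (deconvolution outputs may fall short of 1 but
#' must not exceed it).
#'
#' @param fractions Samples x cell-types numeric matrix in \[0, 1\] (e.g. the
#'   table read by [read_fraction_table()]).
#' @param scores Named per-sample activity values covering the fraction
#'   samples.
#' @param n_p Permutations.
#' @param seed Integer seed.
#' @param lineage Optional tibble `cell_type`, `lineage` joined onto the
#'   result.
#' @return Tibble: `cell_type`, `s`, `p_value`, `q_value` (+ `lineage`).
#' @export
correlate_fractions_with_score <- function(fractions, scores, n_p = 1000L,
                                           seed = 1L, lineage = NULL) {
  if (!is.matrix(fractions)) fractions <- as.matrix(fractions)
  if (any(fractions < -1e-9 | fractions > 1 + 1e-9)) {
    abort("Fractions must lie in [0, 1].", class = "prtf_data_error")
  }
  sums <- rowSums(fractions)
  if (any(sums > 1 + 1e-6)) {
    abort("Per-sample fraction sums exceed 1.", class = "prtf_data_error")
  }
  samples <- rownames(fractions)
  if (is.null(samples) || !all(samples %in% names(scores))) {
    abort("`scores` must be named and cover every fraction sample.",
          class = "prtf_usage_error")
  }
  tab <- spearman_table(fractions, scores[samples], n_p, seed,
                        "fraction_corr")
  out <- tab |>
    rename(cell_type = "entity") |>
    mutate(q_value = bh_adjust(.data$p_value))
  if (!is.null(lineage)) out <- left_join(out, lineage, by = "cell_type")
  out
}

#' Two-sample Kolmogorov-Smirnov tail comparison
#'
#' Two-sided two-sample KS test, `D = sup |ECDF1 - ECDF2|`, used to compare
#' the distribution of an immune-cell fraction between K+ and K- samples
#' (optionally within P strata). Asymptotic p-value by default.
#'
#' @param values_group1,values_group2 Non-empty numeric vectors.
#' @param exact Use the exact p-value (small samples); default asymptotic.
#' @return One-row tibble: `d`, `p_value`, `n1`, `n2`.
#' @export
ks_tail_test <- function(values_group1, values_group2, exact = FALSE) {
  if (!length(values_group1) || !length(values_group2)) {
    abort("Both groups must be non-empty.", class = "prtf_usage_error")
  }
  kt <- suppressWarnings(
    stats::ks.test(values_group1, values_group2, exact = exact)
  )
  tibble(d = unname(kt$statistic), p_value = kt$p.value,
         n1 = length(values_group1), n2 = length(values_group2))
}

#' One-tailed myeloid-vs-lymphoid score comparison
#'
#' Welch two-sample t-test of the activity score in myeloid versus lymphoid
#' samples, one-tailed for myeloid > lymphoid. Validates an activity score
#' on sorted immune-cell expression profiles.
#'
#' @param scores Per-sample activity scores.
#' @param lineage_labels Per-sample labels; exactly the values `"myeloid"`
#'   and `"lymphoid"` are compared (others dropped).
#' @param var_equal Pool variances (classic t-test) instead of Welch.
#' @return One-row tibble: `statistic`, `p_value` (one-tailed), `n_myeloid`,
#'   `n_lymphoid`.
#' @export
lineage_score_test <- function(scores, lineage_labels, var_equal = FALSE) {
  lab <- tolower(as.character(lineage_labels))
  mye <- scores[lab == "myeloid"]; lym <- scores[lab == "lymphoid"]
  if (length(mye) < 2L || length(lym) < 2L) {
    abort("Each lineage needs >= 2 samples (variance undefined otherwise).",
          class = "prtf_usage_error")
  }
  tt <- stats::t.test(mye, lym, alternative = "greater",
                      var.equal = var_equal)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         n_myeloid = length(mye), n_lymphoid = length(lym))
}
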