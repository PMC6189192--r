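#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate, via
#' [stats::p.adjust()]. Adjusted values are never smaller than the raw ones
#' and are capped at 1; the procedure is not idempotent in general.
#'
#' @param pvalues Numeric vector of p-values in (0, 1] (`NA` passed through).
#' @return Adjusted vector in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues > 0 & pvalues <= 1)
  if (!all(ok)) {
    abort("p-values must lie in (0, 1].", class = "prtf_usage_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Standardized midranks of a vector; NULL when constant (Spearman undefined).
std_ranks <- function(x) {
  r <- rank(x, ties.method = "average")
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) return(NULL)
  (r - mean(r)) / s
}

#' Spearman correlation with a permutation p-value
#'
#' Spearman's S is the Pearson correlation of midranks. Significance is the
#' least-bias empirical p-value over `n_p` random reassignments of one
#' vector across samples: `(1 + exceedances) / (1 + n_p)`, with floor
#' `1 / (n_p + 1)`. Two-sided by default (exceedance in `|S|`).
#'
#' @param x,y Paired numeric vectors (>= 3 observations).
#' @param n_p Number of permutations.
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return One-row tibble: `s`, `p_value`, `n`, `n_p`.
#' @export
spearman_with_permutation_p <- function(x, y, n_p = 1000L, seed = 1L,
                                        alternative = c("two.sided",
                                                        "greater", "less")) {
  alternative <- match.arg(alternative)
  n_p <- assert_count(n_p, "n_p")
  if (length(x) != length(y) || length(x) < 3L) {
    abort("Need >= 3 paired observations.", class = "prtf_usage_error")
  }
  zx <- std_ranks(x); zy <- std_ranks(y)
  if (is.null(zx) || is.null(zy)) {
    warn("Constant input vector; Spearman correlation undefined.")
    return(tibble(s = NA_real_, p_value = NA_real_, n = length(x),
                  n_p = n_p))
  }
  n <- length(x)
  s_obs <- sum(zx * zy) / (n - 1)
  null <- with_stream(seed, "spearman", {
    idx <- replicate(n_p, sample.int(n))
    colSums(zx * matrix(zy[idx], nrow = n)) / (n - 1)
  })
  exceed <- switch(alternative,
                   two.sided = sum(abs(null) >= abs(s_obs)),
                   greater = sum(null >= s_obs),
                   less = sum(null <= s_obs))
  tibble(s = s_obs, p_value = (1 + exceed) / (1 + n_p), n = n, n_p = n_p)
}

# Shared-permutation Spearman of many entities against one score vector.
# Z: samples x entities matrix of raw values; score: per-sample vector.
# One permutation set serves every entity (one matrix product per table).
spearman_table <- function(Z, score, n_p, seed, stream,
                           alternative = "two.sided") {
  n <- nrow(Z)
  zs <- std_ranks(score)
  if (is.null(zs)) abort("Score vector is constant.", class = "prtf_data_error")
  ZR <- apply(Z, 2L, std_ranks, simplify = FALSE)
  const <- vapply(ZR, is.null, logical(1))
  Zm <- matrix(0, n, ncol(Z))
  if (any(!const)) Zm[, !const] <- do.call(cbind, ZR[!const])
  s_obs <- as.vector(crossprod(Zm, zs)) / (n - 1)
  null <- with_stream(seed, stream, {
    idx <- replicate(n_p, sample.int(n))
    crossprod(Zm, matrix(zs[idx], nrow = n)) / (n - 1)
  })
  exceed <- switch(alternative,
                   two.sided = rowSums(abs(null) >= abs(s_obs)),
                   greater = rowSums(null >= s_obs),
                   less = rowSums(null <= s_obs))
  p <- (1 + exceed) / (1 + n_p)
  s_obs[const] <- NA_real_
  p[const] <- NA_real_
  if (any(const)) {
    warn(sprintf("%d constant entity vector(s); correlation flagged missing.",
                 sum(const)))
  }
  tibble(entity = colnames(Z), s = s_obs, p_value = p)
}

as_sample_scores <- function(scores, samples, name) {
  if (is.data.frame(scores)) {
    if (!all(c("sample", "e_reported") %in% names(scores))) {
      abort(sprintf("`%s` tibble must have columns sample and e_reported.",
                    name), class = "prtf_usage_error")
    }
    scores <- stats::setNames(scores$e_reported, scores$sample)
  }
  if (is.null(names(scores)) || !all(samples %in% names(scores))) {
    abort(sprintf("`%s` must cover every expression sample.", name),
          class = "prtf_usage_error")
  }
  scores[samples]
}

#' Gene- and TF-level Spearman correlations with the P and R scores
#'
#' For every gene (expression) and every retained TF (activity score),
#' Spearman correlations with the per-sample P and R enrichment scores,
#' permutation p-values (one shared permutation set per table) and BH-
#' adjusted q-values computed within each table.
#'
#' @param expr Genes x samples matrix.
#' @param activity `tf_activity` object (or TFs x samples matrix).
#' @param p_scores,r_scores Per-sample enrichment scores: named vectors or
#'   [score_signature()] tibbles (their `e_reported` column is used).
#' @param n_p Permutations per table.
#' @param seed Integer seed.
#' @return List of class `pr_correlations` with tibbles `genes` and `tfs`,
#'   each with columns `entity`, `s_with_p`, `p_p`, `q_p`, `s_with_r`,
#'   `p_r`, `q_r`.
#' @export
correlation_tables <- function(expr, activity, p_scores, r_scores,
                               n_p = 1000L, seed = 1L) {
  assert_expression_matrix(expr)
  A <- if (inherits(activity, "tf_activity")) activity$values else activity
  samples <- colnames(expr)
  if (!setequal(samples, colnames(A))) {
    abort("Expression and activity matrices cover different samples.",
          class = "prtf_usage_error")
  }
  A <- A[, samples, drop = FALSE]
  p_vec <- as_sample_scores(p_scores, samples, "p_scores")
  r_vec <- as_sample_scores(r_scores, samples, "r_scores")

  one_table <- function(Z, stream_prefix) {
    tp <- spearman_table(Z, p_vec, n_p, seed, paste0(stream_prefix, "_P"))
    tr <- spearman_table(Z, r_vec, n_p, seed, paste0(stream_prefix, "_R"))
    tibble(entity = tp$entity,
           s_with_p = tp$s, p_p = tp$p_value, q_p = bh_adjust(tp$p_value),
           s_with_r = tr$s, p_r = tr$p_value, q_r = bh_adjust(tr$p_value))
  }
  structure(
    list(genes = one_table(t(expr), "gene_corr"),
         tfs = one_table(t(A), "tf_corr")),
    class = "pr_correlations"
  )
}

#' One-tailed overlap enrichment between two subtype labelings
#'
#' For every pair of categories, the hypergeometric upper-tail probability of
#' seeing the observed overlap or more in the 2x2 contingency table (the
#' one-tailed Fisher exact test for enrichment). Within each category of the
#' first labeling, pairs are ranked by overlap size so the best and
#' second-best matches are immediate.
#'
#' @param labels_a,labels_b Per-sample category vectors over the same
#'   samples (aligned by names when named, else by position).
#' @return Tibble: `category_a`, `category_b`, `n_a`, `n_b`, `overlap`,
#'   `p_value`, `q_value` (BH across pairs), `overlap_rank` (1 = largest
#'   overlap within `category_a`).
#' @export
subtype_overlap <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    labels_a <- labels_a[common]; labels_b <- labels_b[common]
  }
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must cover the same samples.",
          class = "prtf_usage_error")
  }
  la <- as.character(labels_a); lb <- as.character(labels_b)
  cats_a <- if (is.factor(labels_a)) levels(labels_a) else unique(la)
  cats_b <- if (is.factor(labels_b)) levels(labels_b) else unique(lb)
  empty_a <- setdiff(cats_a, unique(la)); empty_b <- setdiff(cats_b, unique(lb))
  if (length(empty_a) || length(empty_b)) {
    warn(sprintf("Empty categor(ies) skipped: %s",
                 paste(c(empty_a, empty_b), collapse = ", ")))
    cats_a <- setdiff(cats_a, empty_a); cats_b <- setdiff(cats_b, empty_b)
  }
  if (length(cats_a) < 2L || length(cats_b) < 2L) {
    abort("Each labeling needs >= 2 non-empty categories.",
          class = "prtf_usage_error")
  }
  N <- length(la)
  grid <- tidyr::expand_grid(category_a = cats_a, category_b = cats_b)
  res <- purrr::pmap_dfr(grid, function(category_a, category_b) {
    n_a <- sum(la == category_a); n_b <- sum(lb == category_b)
    k <- sum(la == category_a & lb == category_b)
    tibble(category_a, category_b, n_a = n_a, n_b = n_b, overlap = k,
           p_value = stats::phyper(k - 1, n_a, N - n_a, n_b,
                                   lower.tail = FALSE))
  })
  res$q_value <- bh_adjust(res$p_value)
  res |>
    group_by(.data$category_a) |>
    mutate(overlap_rank = rank(-.data$overlap, ties.method = "first")) |>
    ungroup()
}

#' Enrichment of a target set along a correlation ranking
#'
#' Ranks genes by decreasing statistic (e.g. each gene's Spearman
#' correlation with the R enrichment score) and applies the running
#' enrichment score of [running_enrichment()] to the target set, with a
#' permutation p-value from [build_null()]. A positive, significant high-tail
#' score means the targets cluster among the genes most positively
#' correlated with the programme.
#'
#' @param gene_stats Named numeric vector of per-gene statistics (`NA`
#'   entries dropped).
#' @param targets Character vector of target gene ids.
#' @param n_p Permutations (ignored when `null` supplied).
#' @param seed Integer seed.
#' @param null Optional shared `signature_null` with matching `(n, m)`.
#' @return One-row tibble: `e_minus`, `e_plus`, `p_minus`, `p_plus`,
#'   `e_reported`, `tail`, `n`, `m`.
#' @export
target_set_enrichment <- function(gene_stats, targets, n_p = 1000L,
                                  seed = 1L, null = NULL) {
  gene_stats <- gene_stats[!is.na(gene_stats)]
  if (is.null(names(gene_stats))) {
    abort("`gene_stats` must be named by gene id.", class = "prtf_usage_error")
  }
  obs <- running_enrichment(gene_stats, targets)
  n <- attr(obs, "n"); m <- attr(obs, "m")
  if (is.null(null)) null <- build_null(n, m, n_p = n_p, seed = seed)
  signature_pvalues(obs, null) |>
    mutate(n = n, m = m)
}

#' Identify programme-sustaining transcription factors
#'
#' A TF sustains the proliferation programme (P->P) when (i) its activity
#' score is positively and significantly correlated with the P enrichment
#' score and (ii) its annotated targets are significantly enriched among the
#' genes most positively correlated with the P score; R->R analogously.
#' Significance is BH-adjusted within each criterion family (activity
#' correlations across TFs; enrichment p-values across TFs).
#'
#' @param tf_table `tfs` tibble from [correlation_tables()].
#' @param enrichments_p,enrichments_r Tibbles with a `tf` column plus
#'   [target_set_enrichment()] columns, computed against the `s_with_p`
#'   (resp. `s_with_r`) gene ranking.
#' @param alpha BH-adjusted significance threshold per criterion.
#' @return Tibble with one row per (TF, programme) call: `tf`, `programme`
#'   (`"P->P"` / `"R->R"`), `activity_s`, `activity_q`, `enrichment_score`,
#'   `enrichment_q`.
#' @export
find_sustaining_tfs <- function(tf_table, enrichments_p, enrichments_r,
                                alpha = 0.05) {
  assert_scalar_prob(alpha, "alpha")
  if (!setequal(tf_table$entity, enrichments_p$tf) ||
      !setequal(tf_table$entity, enrichments_r$tf)) {
    abort("Correlation and enrichment tables cover different TFs.",
          class = "prtf_usage_error")
  }
  one_side <- function(s_col, q_col, enr, label) {
    enr <- enr |> mutate(enr_q = bh_adjust(.data$p_plus))
    tf_table |>
      left_join(enr, by = c(entity = "tf")) |>
      filter(!is.na(.data[[s_col]]),
             .data[[s_col]] > 0, .data[[q_col]] < alpha,
             .data$e_plus > 0, .data$enr_q < alpha) |>
      mutate(programme = label) |>
      select(tf = "entity", "programme",
             activity_s = dplyr::all_of(s_col),
             activity_q = dplyr::all_of(q_col),
             enrichment_score = "e_plus", enrichment_q = "enr_q")
  }
  bind_rows(
    one_side("s_with_p", "q_p", enrichments_p, "P->P"),
    one_side("s_with_r", "q_r", enrichments_r, "R->R")
  )
}
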