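#' Running enrichment score of a gene set in one sample
#'
#' Genes are ranked by decreasing expression; walking down the ranking, the
#' running score gains `1/m` at each of the `m` set members and loses
#' `1/(n - m)` at each of the other `n - m` genes, ending exactly at zero.
#' The most negative prefix value `E-` measures enrichment in the low-
#' expression tail, the most positive prefix value `E+` enrichment in the
#' high-expression tail. The score depends only on the ranks of the member
#' genes, never on expression magnitudes.
#'
#' Expression ties are broken by the input order of the genes (stable rule);
#' set members absent from the expression vector are dropped with a warning
#' and `m` adjusted.
#'
#' @param expr_column Named numeric vector of per-gene expression for one
#'   sample.
#' @param gene_set Character vector of member gene ids (or a list element from
#'   [read_gmt()]).
#' @return Numeric vector `c(e_minus, e_plus)` with `-1 <= e_minus <= 0 <=
#'   e_plus <= 1`, carrying attributes `n` and `m`.
#' @examples
#' x <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
#' running_enrichment(x, c("a", "b")) # members at the top: e_plus = 1
#' @export
running_enrichment <- function(expr_column, gene_set) {
  if (is.null(names(expr_column))) {
    abort("`expr_column` must be named by gene id.", class = "prtf_usage_error")
  }
  members <- unique(as.character(gene_set))
  n <- length(expr_column)
  in_universe <- members %in% names(expr_column)
  if (!all(in_universe)) {
    warn(sprintf("%d gene-set member(s) absent from the expression universe; dropped.",
                 sum(!in_universe)))
    members <- members[in_universe]
  }
  m <- length(members)
  if (m == 0L) abort("No gene-set member left after intersection.",
                     class = "prtf_data_error")
  if (m >= n) abort("Gene set covers the whole universe; score undefined.",
                    class = "prtf_data_error")
  r <- rank(-expr_column, ties.method = "first")
  pos <- sort(r[match(members, names(expr_column))])
  out <- enrichment_extrema(pos, n, m)
  attr(out, "n") <- n
  attr(out, "m") <- m
  out
}

# Prefix-sum extrema from sorted member positions. The running score rises
# only at member positions, so the maximum sits at a member position and the
# minimum just before one (or at the final zero).
enrichment_extrema <- function(pos, n, m) {
  j <- seq_len(m)
  at <- j / m - (pos - j) / (n - m)
  c(e_minus = min(0, at - 1 / m), e_plus = max(0, at))
}

#' Permutation null for the running enrichment score
#'
#' Because the score is rank-only, permuting a sample's expression values is
#' equivalent to placing the `m` memberships uniformly at random among the
#' `n` ranks; the null therefore depends only on `(n, m)` and one null can be
#' shared by every sample scored against the same universe and set size.
#'
#' @param n Gene-universe size.
#' @param m Gene-set size (`1 <= m < n`).
#' @param n_p Number of permutations.
#' @param seed Integer seed; the null is deterministic given the seed.
#' @param exhaustive If `TRUE`, enumerate all `choose(n, m)` membership
#'   placements instead of sampling (small universes only); `n_p` is ignored.
#' @return Object of class `signature_null` with fields `n`, `m`, `n_p`,
#'   `scores_minus`, `scores_plus`, `seed`.
#' @export
build_null <- function(n, m, n_p = 1000L, seed = 1L, exhaustive = FALSE) {
  n <- assert_count(n, "n"); m <- assert_count(m, "m")
  if (m >= n) abort("`m` must be < `n`.", class = "prtf_usage_error")
  if (exhaustive) {
    placements <- utils::combn(n, m)
    sc <- apply(placements, 2L, enrichment_extrema, n = n, m = m)
    n_p <- ncol(placements)
  } else {
    n_p <- assert_count(n_p, "n_p")
    sc <- with_stream(seed, "signature_null", {
      vapply(seq_len(n_p),
             function(i) enrichment_extrema(sort(sample.int(n, m)), n, m),
             numeric(2))
    })
  }
  structure(
    list(n = n, m = m, n_p = n_p,
         scores_minus = unname(sc[1L, ]), scores_plus = unname(sc[2L, ]),
         seed = as.integer(seed), exhaustive = exhaustive),
    class = "signature_null"
  )
}

#' Permutation p-values for observed enrichment extrema
#'
#' Least-bias (add-one smoothed) empirical p-values: `p_minus` is the
#' fraction of null low-tail scores at or below the observed `e_minus`,
#' `p_plus` the fraction of null high-tail scores at or above the observed
#' `e_plus`, each computed as `(1 + exceedances) / (1 + n_p)` with floor
#' `1 / (n_p + 1)`. The reported score is the extremum of the more
#' significant tail.
#'
#' @param obs Result of [running_enrichment()] (or `c(e_minus, e_plus)`).
#' @param null A `signature_null` built with the same `(n, m)`.
#' @return One-row tibble: `e_minus`, `e_plus`, `p_minus`, `p_plus`,
#'   `e_reported`, `tail`.
#' @export
signature_pvalues <- function(obs, null) {
  stopifnot(inherits(null, "signature_null"))
  obs_n <- attr(obs, "n", exact = TRUE)
  obs_m <- attr(obs, "m", exact = TRUE)
  if (!is.null(obs_n) && (obs_n != null$n || obs_m != null$m)) {
    abort(sprintf("Observed score computed at (n=%d, m=%d) but null built for (n=%d, m=%d).",
                  obs_n, obs_m, null$n, null$m),
          class = "prtf_usage_error")
  }
  e_minus <- obs[[1L]]; e_plus <- obs[[2L]]
  p_minus <- (1 + sum(null$scores_minus <= e_minus)) / (1 + null$n_p)
  p_plus <- (1 + sum(null$scores_plus >= e_plus)) / (1 + null$n_p)
  low <- p_minus < p_plus
  tibble(
    e_minus = e_minus, e_plus = e_plus,
    p_minus = p_minus, p_plus = p_plus,
    e_reported = if (low) e_minus else e_plus,
    tail = if (low) "low" else "high"
  )
}

#' Score a gene signature in every sample of a cohort
#'
#' Computes the running-enrichment extrema of `gene_set` in each sample of
#' `expr` and their permutation p-values against a shared `(n, m)` null.
#'
#' @param expr Numeric genes x samples matrix (typically mean-centered).
#' @param gene_set Character vector of member gene ids.
#' @param n_p Permutations for the null (ignored when `null` is supplied).
#' @param seed Integer seed for the null.
#' @param null Optional pre-built [build_null()] object to reuse.
#' @param set_name Label stored in the `signature` column.
#' @return Tibble with one row per sample: `sample`, `signature`, `e_minus`,
#'   `e_plus`, `p_minus`, `p_plus`, `e_reported`, `tail`.
#' @export
score_signature <- function(expr, gene_set, n_p = 1000L, seed = 1L,
                            null = NULL, set_name = "signature") {
  assert_expression_matrix(expr)
  members <- unique(as.character(gene_set))
  present <- members %in% rownames(expr)
  if (!all(present)) {
    warn(sprintf("%d member(s) of '%s' absent from the expression matrix; dropped.",
                 sum(!present), set_name))
    members <- members[present]
  }
  n <- nrow(expr); m <- length(members)
  if (m == 0L) abort("Empty gene set after intersection.",
                     class = "prtf_data_error")
  if (m >= n) abort("Gene set covers the whole universe.",
                    class = "prtf_data_error")
  if (is.null(null)) null <- build_null(n, m, n_p = n_p, seed = seed)
  if (null$n != n || null$m != m) {
    abort("Supplied null does not match this (n, m).",
          class = "prtf_usage_error")
  }
  member_idx <- match(members, rownames(expr))
  purrr::map_dfr(seq_len(ncol(expr)), function(k) {
    r <- rank(-expr[, k], ties.method = "first")
    obs <- enrichment_extrema(sort(r[member_idx]), n, m)
    signature_pvalues(obs, null)
  }) |>
    mutate(sample = colnames(expr), signature = set_name, .before = 1L)
}

#' Call P/R subtype membership from signature scores
#'
#' A sample is positive for a signature when the signature is significantly
#' up-regulated: the high tail is the more significant one and its
#' permutation p-value is below `alpha`. Significant down-regulation is a
#' negative call.
#'
#' @param p_scores,r_scores Tibbles from [score_signature()] for the
#'   proliferation (P) and remodelling (R) signatures over the same samples.
#' @param alpha Significance threshold for the positive call (default 0.05).
#' @return Tibble: `sample`, `p_call`, `r_call` (logical) and `pr_subtype`
#'   (`"P+/R-"` etc.).
#' @export
classify_samples <- function(p_scores, r_scores, alpha = 0.05) {
  assert_scalar_prob(alpha, "alpha")
  if (!setequal(p_scores$sample, r_scores$sample)) {
    abort("P and R score tables cover different samples.",
          class = "prtf_usage_error")
  }
  pos_call <- function(tbl) tbl$tail == "high" & tbl$p_plus < alpha
  p <- tibble(sample = p_scores$sample, p_call = pos_call(p_scores))
  r <- tibble(sample = r_scores$sample, r_call = pos_call(r_scores))
  left_join(p, r, by = "sample") |>
    mutate(pr_subtype = paste0(ifelse(.data$p_call, "P+", "P-"), "/",
                               ifelse(.data$r_call, "R+", "R-")))
}
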