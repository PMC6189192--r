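#' Parse a TRRUST-dialect regulatory table
#'
#' Expects at least three tab-separated columns — TF, target gene, mode of
#' regulation — with an optional reference column and no header. Edges whose
#' mode is `Unknown` (case-insensitive) are discarded; duplicate
#' `(tf, target)` rows with the same mode collapse to one edge; pairs listed
#' with conflicting modes are dropped entirely with a warning.
#'
#' @param x Path to a TSV file, or a data frame with columns `tf`, `target`,
#'   `mode` (first three columns are used regardless of names when unnamed).
#' @return Tibble with columns `tf`, `target`, `mode` (`"Activation"` /
#'   `"Repression"`), of class `regulatory_network`, with a `provenance`
#'   attribute.
#' @export
parse_trrust <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    lines <- readLines(x, warn = FALSE)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad)) {
      abort(sprintf("Malformed regulatory table line %d: fewer than 3 fields.",
                    bad[1L]),
            class = "prtf_parse_error")
    }
    df <- tibble(
      tf = vapply(fields, `[[`, character(1), 1L),
      target = vapply(fields, `[[`, character(1), 2L),
      mode = vapply(fields, `[[`, character(1), 3L)
    )
    prov <- x
  } else if (is.data.frame(x)) {
    df <- tibble(tf = as.character(x[[1L]]), target = as.character(x[[2L]]),
                 mode = as.character(x[[3L]]))
    if (all(c("tf", "target", "mode") %in% names(x))) {
      df <- tibble(tf = as.character(x$tf), target = as.character(x$target),
                   mode = as.character(x$mode))
    }
    prov <- "data.frame"
  } else {
    abort("`x` must be a file path or a data frame.",
          class = "prtf_usage_error")
  }

  n_in <- nrow(df)
  mode_norm <- tolower(df$mode)
  keep <- mode_norm %in% c("activation", "repression")
  unknown <- mode_norm == "unknown"
  if (any(!keep & !unknown)) {
    abort(sprintf("Unrecognised regulation mode '%s'.",
                  df$mode[which(!keep & !unknown)[1L]]),
          class = "prtf_parse_error")
  }
  df <- df[keep, ]
  df$mode <- ifelse(tolower(df$mode) == "activation", "Activation", "Repression")
  df <- dplyr::distinct(df)

  conf <- df |>
    dplyr::count(.data$tf, .data$target) |>
    filter(.data$n > 1L)
  if (nrow(conf)) {
    warn(sprintf("%d TF-target pair(s) annotated with conflicting modes; excluded.",
                 nrow(conf)))
    df <- dplyr::anti_join(df, conf, by = c("tf", "target"))
  }
  inform(sprintf("parse_trrust: kept %d edge(s) of %d input row(s).",
                 nrow(df), n_in))
  structure(df, class = c("regulatory_network", class(df)),
            provenance = prov)
}

#' Build the ternary target matrix of a regulatory network
#'
#' Encodes the network as a genes x TFs matrix with entries +1 (activation),
#' -1 (repression) and 0 (no annotated regulation), restricted to target
#' genes present in the expression universe. TFs left without any expressed
#' target are dropped and recorded.
#'
#' @param net `regulatory_network` tibble from [parse_trrust()] or
#'   [generate_regulatory_network()].
#' @param expression_genes Character vector of gene ids available in the
#'   expression matrix.
#' @return Numeric genes x TFs matrix with a `dropped_tfs` attribute
#'   (tibble `tf`, `reason`).
#' @export
build_ternary_matrix <- function(net, expression_genes) {
  if (!nrow(net)) abort("Empty regulatory network.", class = "prtf_data_error")
  expressed <- net$target %in% expression_genes
  if (!any(expressed)) {
    abort("No network target gene is present in the expression universe.",
          class = "prtf_data_error")
  }
  all_tfs <- unique(net$tf)
  net <- net[expressed, ]
  genes <- sort(unique(net$target))
  tfs <- unique(net$tf)
  Tm <- matrix(0, length(genes), length(tfs),
               dimnames = list(genes, tfs))
  Tm[cbind(match(net$target, genes), match(net$tf, tfs))] <-
    ifelse(net$mode == "Activation", 1, -1)
  dropped <- setdiff(all_tfs, tfs)
  attr(Tm, "dropped_tfs") <- tibble(
    tf = dropped,
    reason = rep("no expressed target", length(dropped))
  )
  if (length(dropped)) {
    inform(sprintf("build_ternary_matrix: dropped %d TF(s) with no expressed target.",
                   length(dropped)))
  }
  Tm
}

#' Infer per-sample TF activity scores by least squares
#'
#' Models each sample's expression over the network target genes as a linear
#' combination of TF activities acting through the ternary design,
#' `G[i, k] = sum_j T[i, j] * A[j, k]` (plus an optional intercept), and
#' solves each sample independently in the least-squares sense. All samples
#' share one pivoted QR decomposition of the design; when design columns are
#' collinear, the non-identifiable coefficients are returned as `NA` and
#' logged.
#'
#' @param expr Numeric genes x samples expression matrix; rows are matched to
#'   the rownames of `ternary` (genes missing from `expr` are an error).
#' @param ternary Genes x TFs ternary matrix from [build_ternary_matrix()].
#' @param intercept Fit a per-sample intercept (default `TRUE`); it is
#'   estimated but never reported as an activity.
#' @return Object of class `tf_activity`: list with `values` (TFs x samples
#'   matrix), `pvalues` (`NULL` until [tf_pvalues_and_calls()]),
#'   `dropped_tfs` tibble, and the `intercept` flag.
#' @export
infer_activities <- function(expr, ternary, intercept = TRUE) {
  assert_expression_matrix(expr)
  missing_genes <- setdiff(rownames(ternary), rownames(expr))
  if (length(missing_genes)) {
    abort(sprintf("%d ternary target gene(s) absent from `expr`.",
                  length(missing_genes)),
          class = "prtf_usage_error")
  }
  if (ncol(expr) < 1L) abort("Need at least one sample.",
                             class = "prtf_usage_error")
  G <- expr[rownames(ternary), , drop = FALSE]
  X <- if (intercept) cbind(`(Intercept)` = 1, ternary) else ternary
  qx <- qr(X)
  if (qx$rank == 0L) {
    abort("Design has rank zero; no identifiable TF subset.",
          class = "prtf_inference_error")
  }
  coefs <- qr.coef(qx, G)
  if (intercept) coefs <- coefs[-1L, , drop = FALSE]
  rownames(coefs) <- colnames(ternary)
  non_ident <- rownames(coefs)[apply(coefs, 1L, function(x) all(is.na(x)))]
  dropped <- attr(ternary, "dropped_tfs") %||% tibble(tf = character(),
                                                      reason = character())
  if (length(non_ident)) {
    inform(sprintf("infer_activities: %d TF(s) non-identifiable (collinear design).",
                   length(non_ident)))
  }
  structure(
    list(values = coefs,
         pvalues = NULL,
         k_calls = NULL,
         dropped_tfs = bind_rows(
           dropped,
           tibble(tf = non_ident,
                  reason = rep("non-identifiable", length(non_ident)))),
         intercept = intercept),
    class = "tf_activity"
  )
}

#' Drop TFs whose activity is constant across samples
#'
#' Only TFs whose activity score varies across tumour samples carry
#' information; rows with (numerically) zero standard deviation, or entirely
#' non-identifiable rows, are removed and recorded in `dropped_tfs`.
#'
#' @param activity `tf_activity` object.
#' @param tol Standard-deviation tolerance treated as zero.
#' @return Filtered `tf_activity` object.
#' @export
filter_constant_tfs <- function(activity, tol = 1e-12) {
  stopifnot(inherits(activity, "tf_activity"))
  v <- activity$values
  sds <- apply(v, 1L, function(x) if (all(is.na(x))) NA_real_ else
    stats::sd(x, na.rm = TRUE))
  na_rows <- is.na(sds)
  const_rows <- !na_rows & sds <= tol
  drop <- na_rows | const_rows
  if (all(drop)) {
    abort("All TFs dropped (constant or non-identifiable activities).",
          class = "prtf_data_error")
  }
  activity$dropped_tfs <- bind_rows(
    activity$dropped_tfs,
    tibble(tf = rownames(v)[na_rows],
           reason = rep("non-identifiable", sum(na_rows))),
    tibble(tf = rownames(v)[const_rows],
           reason = rep("zero standard deviation", sum(const_rows)))
  ) |> dplyr::distinct()
  activity$values <- v[!drop, , drop = FALSE]
  if (!is.null(activity$pvalues)) {
    activity$pvalues <- activity$pvalues[!drop, , drop = FALSE]
  }
  activity
}

#' Pooled permutation null for TF activity scores
#'
#' For every sample, the expression values over the target-gene universe are
#' shuffled across genes `n_perm` times and activities re-inferred on each
#' shuffled sample; the resulting scores are pooled across samples and
#' permutations into one reference vector per TF, of length
#' `n_perm * n_samples`. Pooling across samples follows from using
#' mean-centered input: sample-specific location is removed upstream.
#'
#' @inheritParams infer_activities
#' @param n_perm Permutations per sample.
#' @param seed Integer seed; the null is deterministic given the seed.
#' @return Object of class `tf_null`: list with `scores` (TFs x
#'   `n_perm * n_samples` matrix), `n_perm`, `n_samples`, `seed`,
#'   `intercept`.
#' @export
build_tf_null <- function(expr, ternary, n_perm = 100L, seed = 1L,
                          intercept = TRUE) {
  n_perm <- assert_count(n_perm, "n_perm")
  assert_expression_matrix(expr)
  G <- expr[rownames(ternary), , drop = FALSE]
  X <- if (intercept) cbind(`(Intercept)` = 1, ternary) else ternary
  qx <- qr(X)
  n_genes <- nrow(G); n_samples <- ncol(G)
  scores <- with_stream(seed, "tf_null", {
    blocks <- lapply(seq_len(n_samples), function(k) {
      idx <- replicate(n_perm, sample.int(n_genes))
      P <- matrix(G[idx, k], nrow = n_genes, ncol = n_perm)
      co <- qr.coef(qx, P)
      if (intercept) co <- co[-1L, , drop = FALSE]
      co
    })
    do.call(cbind, blocks)
  })
  rownames(scores) <- colnames(ternary)
  structure(
    list(scores = scores, n_perm = n_perm, n_samples = n_samples,
         seed = as.integer(seed), intercept = intercept),
    class = "tf_null"
  )
}

#' Empirical p-values and K± activity calls
#'
#' For each retained TF and sample, the add-one smoothed upper-tail p-value
#' of the observed activity score against that TF's pooled reference vector:
#' `p = (1 + #{null >= observed}) / (1 + n)`. A sample is called K+ for the
#' designated TF when `p < alpha` (strict), K- otherwise.
#'
#' @param activity `tf_activity` object (after [filter_constant_tfs()]).
#' @param null `tf_null` from [build_tf_null()]; must cover every retained TF.
#' @param designated_tf TF id whose high activity defines the K+ call.
#' @param alpha Call threshold (default 0.05, strict inequality).
#' @return The `tf_activity` object with `pvalues` filled in and, when
#'   `designated_tf` is given, `k_calls`: a tibble `sample`, `activity`,
#'   `p_value`, `k_call`.
#' @export
tf_pvalues_and_calls <- function(activity, null, designated_tf = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(activity, "tf_activity"), inherits(null, "tf_null"))
  assert_scalar_prob(alpha, "alpha")
  tfs <- rownames(activity$values)
  if (!all(tfs %in% rownames(null$scores))) {
    abort("Null does not cover every retained TF.",
          class = "prtf_usage_error")
  }
  pv <- matrix(NA_real_, nrow(activity$values), ncol(activity$values),
               dimnames = dimnames(activity$values))
  for (tf in tfs) {
    ref <- sort(null$scores[tf, ])      # drops NA
    n_ref <- length(ref)
    obs <- activity$values[tf, ]
    ok <- !is.na(obs)
    cnt_ge <- n_ref - findInterval(obs[ok], ref, left.open = TRUE)
    pv[tf, ok] <- (1 + cnt_ge) / (1 + n_ref)
  }
  activity$pvalues <- pv
  if (!is.null(designated_tf)) {
    if (!designated_tf %in% tfs) {
      abort(sprintf("Designated TF '%s' not among retained TFs.", designated_tf),
            class = "prtf_usage_error")
    }
    p <- unname(pv[designated_tf, ])
    activity$k_calls <- tibble(
      sample = colnames(activity$values),
      activity = unname(activity$values[designated_tf, ]),
      p_value = p,
      k_call = !is.na(p) & p < alpha
    )
    activity$designated_tf <- designated_tf
  }
  activity
}

#' @export
print.tf_activity <- function(x, ...) {
  cat(sprintf("<tf_activity: %d TF(s) x %d sample(s); p-values %s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$pvalues)) "absent" else "present"))
  if (nrow(x$dropped_tfs)) {
    cat(sprintf("  dropped TFs: %d (%s)\n", nrow(x$dropped_tfs),
                paste(unique(x$dropped_tfs$reason), collapse = "; ")))
  }
  invisible(x)
}

#' Tidy a TF activity object into a long tibble
#'
#' @param x `tf_activity` object.
#' @param ... Unused.
#' @return Tibble with one row per (TF, sample): `tf`, `sample`, `activity`
#'   and, when present, `p_value`.
#' @method tidy tf_activity
#' @export
tidy.tf_activity <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "tf") |>
    tidyr::pivot_longer(-"tf", names_to = "sample", values_to = "activity")
  if (!is.null(x$pvalues)) {
    pv <- as_tibble(x$pvalues, rownames = "tf") |>
      tidyr::pivot_longer(-"tf", names_to = "sample", values_to = "p_value")
    out <- left_join(out, pv, by = c("tf", "sample"))
  }
  out
}

#' @method glance tf_activity
#' @export
glance.tf_activity <- function(x, ...) {
  tibble(
    n_tfs = nrow(x$values),
    n_samples = ncol(x$values),
    n_dropped = nrow(x$dropped_tfs),
    has_pvalues = !is.null(x$pvalues),
    intercept = x$intercept
  )
}
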