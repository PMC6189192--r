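#' Collapse probe-level expression to one row per gene
#'
#' Microarray platforms measure several probes per gene. Following common
#' meta-analysis practice, only annotated probes are kept and, for each gene,
#' the most variable probe — the one with the largest interquartile range
#' (IQR) across samples — represents the gene.
#'
#' The IQR uses the linear-interpolation quantile convention
#' (`stats::quantile()` type 7). When two probes of a gene tie exactly on IQR
#' the probe that appears first in the input matrix wins; a message records
#' the tie.
#'
#' @param values Numeric probes x samples matrix with unique probe rownames.
#' @param probe_to_gene Data frame with columns `probe` and `gene`, or a named
#'   character vector (names = probes, values = gene ids). Probes absent from
#'   the map are treated as unannotated and dropped.
#' @return Numeric genes x samples matrix (one row per mapped gene), not yet
#'   centered.
#' @examples
#' m <- rbind(A1 = c(1, 2, 3, 4), A2 = c(0, 10, 20, 30))
#' colnames(m) <- paste0("s", 1:4)
#' collapse_probes(m, c(A1 = "GENE", A2 = "GENE"))
#' @export
collapse_probes <- function(values, probe_to_gene) {
  if (!is.matrix(values) || is.null(rownames(values))) {
    abort("`values` must be a matrix with probe rownames.",
          class = "prtf_usage_error")
  }
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene),
                           as.character(probe_to_gene$probe))
  } else {
    map <- probe_to_gene
  }
  map <- map[nzchar(map) & !is.na(map)]
  keep <- rownames(values) %in% names(map)
  if (!any(keep)) {
    abort("No probe has a gene annotation; nothing to collapse.",
          class = "prtf_data_error")
  }
  values <- values[keep, , drop = FALSE]
  genes <- unname(map[rownames(values)])

  iqr <- apply(values, 1L, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    q[2L] - q[1L]
  })

  pick <- tibble(
    probe = rownames(values),
    gene = genes,
    iqr = iqr,
    ord = seq_along(genes)
  ) |>
    group_by(.data$gene) |>
    mutate(tie = sum(.data$iqr == max(.data$iqr)) > 1L) |>
    filter(.data$iqr == max(.data$iqr)) |>
    filter(.data$ord == min(.data$ord)) |>
    ungroup() |>
    arrange(.data$ord)

  if (any(pick$tie)) {
    inform(sprintf(
      "collapse_probes: IQR tie for %d gene(s); first probe in input order kept.",
      sum(pick$tie)))
  }

  out <- values[pick$probe, , drop = FALSE]
  rownames(out) <- pick$gene
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' value at rank r becomes the across-sample mean of the r-th order
#' statistics. Within-column ties receive the mean of the order-statistic
#' means they span (midrank interpolation). The heavy lifting is done by
#' [limma::normalizeQuantiles()].
#'
#' @param m Numeric genes x samples matrix.
#' @param log2_transform If `TRUE`, apply `log2()` element-wise after
#'   normalization; all input values must then be positive.
#' @return Matrix of the same dimensions.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' rownames(m) <- paste0("g", 1:3)
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(m, log2_transform = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort("`m` must be a numeric matrix.", class = "prtf_usage_error")
  }
  if (log2_transform && any(m <= 0)) {
    abort("log2 transform requested but the matrix has non-positive values.",
          class = "prtf_data_error")
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (log2_transform) out <- log2(out)
  out
}

#' Mean-center every gene
#'
#' Subtracts from each gene row its mean across samples, so centered rows sum
#' to zero. When `batch` labels are supplied, centering is performed within
#' each batch independently — the per-dataset correction used when several
#' cohorts are combined, which removes dataset-level location offsets.
#'
#' @param m Numeric genes x samples matrix.
#' @param batch Optional vector of batch labels, one per sample (recycled from
#'   a named vector by sample id when names are present).
#' @return Matrix with attribute `centered = TRUE`. Idempotent.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3))
#' colnames(m) <- paste0("s", 1:3)
#' mean_center_genes(m)
#' @export
mean_center_genes <- function(m, batch = NULL) {
  assert_expression_matrix(m, "m")
  if (is.null(batch)) {
    out <- m - rowMeans(m)
  } else {
    if (!is.null(names(batch))) batch <- batch[colnames(m)]
    if (length(batch) != ncol(m) || anyNA(batch)) {
      abort("`batch` must provide one label per sample.",
            class = "prtf_usage_error")
    }
    out <- m
    for (b in unique(batch)) {
      idx <- which(batch == b)
      out[, idx] <- m[, idx, drop = FALSE] -
        rowMeans(m[, idx, drop = FALSE])
    }
  }
  attr(out, "centered") <- TRUE
  out
}
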