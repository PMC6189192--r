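#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated — set name,
#' description, then member gene identifiers.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("Empty GMT file.", class = "prtf_data_error")
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      abort(sprintf("Malformed GMT line: %s", substr(l, 1, 60)),
            class = "prtf_data_error")
    }
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1))
  sets
}

#' Read / write a genes x samples expression matrix as TSV
#'
#' The TSV carries gene ids in the first column and sample ids in the header.
#' `write_expression_tsv()` additionally writes a small YAML sidecar
#' (`<path>.meta.yaml`) recording the centered flag and any batch map.
#'
#' @param path File path.
#' @return `read_expression_tsv()` returns a numeric matrix; the sidecar, when
#'   present, is restored into the `centered` attribute and a `batch`
#'   attribute.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(m, "centered") <- isTRUE(meta$centered)
    if (!is.null(meta$batch)) attr(m, "batch") <- unlist(meta$batch)
  }
  m
}

#' @rdname read_expression_tsv
#' @param m Numeric genes x samples matrix.
#' @param batch Optional per-sample batch labels recorded in the sidecar.
#' @export
write_expression_tsv <- function(m, path, batch = NULL) {
  assert_expression_matrix(m, "m")
  df <- tibble::as_tibble(m, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  meta <- list(centered = isTRUE(attr(m, "centered")))
  if (!is.null(batch)) meta$batch <- as.list(batch)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an immune-cell fraction table
#'
#' Accepts the usual deconvolution output layout: rows are samples (first
#' column holds the sample id), remaining numeric columns are cell types.
#' Non-numeric trailer columns (e.g. p-values or RMSE diagnostics appended by
#' deconvolution tools) are dropped with a message.
#'
#' @param path TSV file path.
#' @return Numeric samples x cell-types matrix.
#' @export
read_fraction_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  num <- vapply(df[-1L], is.numeric, logical(1))
  if (!all(num)) {
    inform(sprintf("read_fraction_table: dropping non-numeric column(s): %s",
                   paste(names(df[-1L])[!num], collapse = ", ")))
  }
  m <- as.matrix(df[, -1L, drop = FALSE][, num, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}
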