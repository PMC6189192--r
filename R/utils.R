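#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by ungroup summarise
#'   across bind_rows left_join rename n
#' @keywords internal
"_PACKAGE"

# Derived seed for a named random stream. Stages consume independent,
# reproducible streams from one master seed so any stage can be rerun in
# isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name),
          class = "prtf_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "prtf_config_error")
  }
  invisible(as.integer(x))
}

assert_expression_matrix <- function(m, name = "expression") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix.", name),
          class = "prtf_usage_error")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must carry gene rownames and sample colnames.", name),
          class = "prtf_usage_error")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` has duplicated gene or sample identifiers.", name),
          class = "prtf_usage_error")
  }
  invisible(m)
}
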