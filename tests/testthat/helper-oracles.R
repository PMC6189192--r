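# Brute-force running-score extrema: explicit increment vector and full
# prefix sum, independent of the package's member-position arithmetic.
oracle_extrema <- function(pos, n, m) {
  h <- rep(-1 / (n - m), n)
  h[pos] <- 1 / m
  cs <- cumsum(h)
  c(e_minus = min(0, min(cs)), e_plus = max(0, max(cs)))
}

# Expression vector whose decreasing-order ranks place the gene set members
# at the requested positions.
expr_with_member_ranks <- function(n, member_ranks) {
  x <- stats::setNames(seq(n, 1), paste0("g", seq_len(n)))
  list(expr = x, members = paste0("g", member_ranks))
}

# Small, fast cohort for pipeline-level tests; ... overrides any default.
small_config <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(n_samples = 60L, n_genes = 300L, n_tfs = 8L, targets_per_tf = 6L,
         p_set_size = 25L, r_set_size = 25L, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

expect_no_na <- function(x) expect_false(anyNA(x))
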