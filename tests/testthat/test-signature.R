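test_that("running_enrichment reproduces hand-computed extrema", {
  # members at the very top: full positive excursion
  top <- expr_with_member_ranks(5, c(1, 2))
  expect_equal(as.numeric(running_enrichment(top$expr, top$members)),
               c(0, 1))
  # members at the bottom: mirror case
  bot <- expr_with_member_ranks(5, c(4, 5))
  expect_equal(as.numeric(running_enrichment(bot$expr, bot$members)),
               c(-1, 0))
  # n = 4, m = 2, members at ranks 2 and 4: prefix sums -1/2, 0, -1/2, 0
  mid <- expr_with_member_ranks(4, c(2, 4))
  expect_equal(as.numeric(running_enrichment(mid$expr, mid$members)),
               c(-0.5, 0))
})

test_that("running_enrichment agrees with the brute-force prefix-sum oracle", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    m <- sample(seq_len(n - 1), 1)
    ranks <- sort(sample.int(n, m))
    inst <- expr_with_member_ranks(n, ranks)
    got <- running_enrichment(inst$expr, inst$members)
    expect_equal(as.numeric(got), as.numeric(oracle_extrema(ranks, n, m)),
                 tolerance = 1e-12)
    # bounds and zero endpoint are structural
    expect_gte(got[["e_minus"]], -1); expect_lte(got[["e_minus"]], 0)
    expect_gte(got[["e_plus"]], 0); expect_lte(got[["e_plus"]], 1)
  }
})

test_that("scores are rank-only: monotone transforms change nothing", {
  set.seed(8)
  x <- stats::setNames(rnorm(30), paste0("g", 1:30))
  members <- sample(names(x), 6)
  base <- running_enrichment(x, members)
  for (f in list(function(v) 2 * v + 5, function(v) exp(v),
                 function(v) rank(v))) {
    expect_equal(as.numeric(running_enrichment(f(x), members)),
                 as.numeric(base))
  }
})

test_that("degenerate gene sets are rejected, absent members dropped", {
  x <- stats::setNames(1:5, paste0("g", 1:5))
  expect_warning(out <- running_enrichment(x, c("g1", "nope")), "absent")
  expect_identical(attr(out, "m", exact = TRUE), 1L)
  expect_error(suppressWarnings(running_enrichment(x, "nope")),
               class = "prtf_data_error")
  expect_error(running_enrichment(x, names(x)), class = "prtf_data_error")
})

test_that("exhaustive null equals brute-force enumeration over placements", {
  for (n in c(4, 6)) {
    for (m in seq_len(min(3, n - 1))) {
      null <- build_null(n, m, exhaustive = TRUE)
      plc <- utils::combn(n, m)
      oracle <- apply(plc, 2, oracle_extrema, n = n, m = m)
      expect_equal(null$n_p, ncol(plc))
      expect_equal(null$scores_minus, unname(oracle[1, ]), tolerance = 1e-12)
      expect_equal(null$scores_plus, unname(oracle[2, ]), tolerance = 1e-12)
    }
  }
})

test_that("sampled null is seed-deterministic and within bounds", {
  n1 <- build_null(50, 5, n_p = 200, seed = 9)
  n2 <- build_null(50, 5, n_p = 200, seed = 9)
  n3 <- build_null(50, 5, n_p = 200, seed = 10)
  expect_identical(n1$scores_plus, n2$scores_plus)
  expect_false(identical(n1$scores_plus, n3$scores_plus))
  expect_true(all(n1$scores_minus >= -1 & n1$scores_minus <= 0))
  expect_true(all(n1$scores_plus >= 0 & n1$scores_plus <= 1))
})

test_that("signature p-values follow the add-one smoothed formula", {
  null <- build_null(4, 2, exhaustive = TRUE)   # 6 placements
  inst <- expr_with_member_ranks(4, c(1, 2))
  obs <- running_enrichment(inst$expr, inst$members)
  res <- signature_pvalues(obs, null)
  # only the top placement reaches e_plus = 1: p_plus = (1 + 1)/(1 + 6)
  expect_equal(res$p_plus, 2 / 7)
  expect_identical(res$tail, "high")
  expect_equal(res$e_reported, res$e_plus)

  # floor: observed above every sampled null value
  small <- structure(c(e_minus = 0, e_plus = 1), n = 50L, m = 5L)
  null50 <- build_null(50, 5, n_p = 999, seed = 2)
  res50 <- signature_pvalues(small, null50)
  expect_gte(res50$p_plus, 1 / 1000)
  expect_lte(res50$p_plus, (1 + sum(null50$scores_plus == 1)) / 1000)

  # mismatched (n, m) is a usage error
  expect_error(signature_pvalues(obs, null50), class = "prtf_usage_error")
})

test_that("classification requires significant up-regulation only", {
  mk <- function(p_plus, p_minus, tail) {
    tibble::tibble(sample = "s1", signature = "x", e_minus = -0.2,
                   e_plus = 0.3, p_minus = p_minus, p_plus = p_plus,
                   e_reported = 0.3, tail = tail)
  }
  # significant P high tail, unremarkable R -> P+/R-
  out <- classify_samples(mk(0.001, 0.8, "high"), mk(0.4, 0.6, "high"))
  expect_identical(out$pr_subtype, "P+/R-")
  # both high and significant -> P+/R+
  out2 <- classify_samples(mk(0.01, 0.9, "high"), mk(0.02, 0.7, "high"))
  expect_identical(out2$pr_subtype, "P+/R+")
  # significant *low* tail is not a positive call
  out3 <- classify_samples(mk(0.9, 0.001, "low"), mk(0.5, 0.5, "high"))
  expect_identical(out3$pr_subtype, "P-/R-")
})

test_that("score_signature matches per-sample running_enrichment", {
  set.seed(5)
  expr <- matrix(rnorm(40 * 6), 40, 6,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  members <- paste0("g", c(2, 9, 17, 30))
  null <- build_null(40, 4, n_p = 500, seed = 3)
  tbl <- score_signature(expr, members, null = null, set_name = "P")
  expect_identical(nrow(tbl), 6L)
  for (k in c(1L, 4L)) {
    direct <- running_enrichment(expr[, k], members)
    expect_equal(tbl$e_plus[k], direct[["e_plus"]])
    expect_equal(tbl$e_minus[k], direct[["e_minus"]])
  }
})
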