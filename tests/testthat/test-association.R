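test_that("bh_adjust reproduces the step-up procedure", {
  # hand calculation: p_(i) * 4/i = (.04, .04, .04, .04) after cummin
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # order-preserving on sorted input
  expect_false(is.unsorted(bh_adjust(sort(p))))
  expect_error(bh_adjust(c(0.5, 0)), class = "prtf_usage_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "prtf_usage_error")
})

test_that("Spearman permutation test: sign, invariance, floor, missingness", {
  x <- 1:10
  expect_equal(spearman_with_permutation_p(x, x^3, n_p = 99, seed = 1)$s, 1)
  expect_equal(spearman_with_permutation_p(x, -exp(x), n_p = 99, seed = 1)$s,
               -1)
  # matches the classical estimate and is monotone-invariant
  set.seed(4)
  a <- rnorm(25); b <- a + rnorm(25)
  res <- spearman_with_permutation_p(a, b, n_p = 199, seed = 2)
  expect_equal(res$s, cor(a, b, method = "spearman"))
  res2 <- spearman_with_permutation_p(exp(a), rank(b), n_p = 199, seed = 2)
  expect_equal(res2$s, res$s)
  expect_equal(res2$p_value, res$p_value)
  # strong correlation at moderate n sits at or near the permutation floor
  expect_lte(res$p_value, 3 / 200)
  expect_warning(cres <- spearman_with_permutation_p(rep(1, 10), rnorm(10)),
                 "Constant")
  expect_true(is.na(cres$s))
})

test_that("overlap enrichment equals the one-tailed Fisher exact test", {
  # perfectly aligned 10 + 10 split: p = 1 / C(20, 10)
  la <- rep(c("A1", "A2"), each = 10)
  lb <- rep(c("B1", "B2"), each = 10)
  ov <- subtype_overlap(la, lb)
  best <- ov[ov$category_a == "A1" & ov$category_b == "B1", ]
  expect_equal(best$p_value, 1 / choose(20, 10))
  expect_identical(best$overlap_rank, 1L)

  # brute-force agreement with fisher.test on random small tables
  set.seed(9)
  for (i in 1:20) {
    n <- 24
    a <- sample(c("x", "y"), n, replace = TRUE)
    b <- sample(c("u", "v"), n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    ov <- subtype_overlap(a, b)
    for (j in seq_len(nrow(ov))) {
      tab <- table(factor(a == ov$category_a[j], c(TRUE, FALSE)),
                   factor(b == ov$category_b[j], c(TRUE, FALSE)))
      expect_equal(ov$p_value[j],
                   fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-12)
    }
  }

  # empty factor level: warned and skipped
  fa <- factor(rep("A1", 20), levels = c("A1", "A2", "A3"))
  expect_warning(expect_error(subtype_overlap(fa, lb),
                              class = "prtf_usage_error"),
                 "Empty")
})

test_that("correlation tables recover planted structure and flag constants", {
  set.seed(6)
  n <- 80
  p_scores <- stats::setNames(rnorm(n), paste0("s", 1:n))
  r_scores <- stats::setNames(-p_scores + rnorm(n, sd = 0.5), names(p_scores))
  expr <- rbind(
    gene_r = r_scores + rnorm(n, sd = 0.3),   # tracks R
    gene_flat = rep(1, n),                    # constant: flagged NA
    gene_noise = rnorm(n)
  )
  colnames(expr) <- names(p_scores)
  A <- rbind(TF_p = p_scores + rnorm(n, sd = 0.3), TF_noise = rnorm(n))
  colnames(A) <- names(p_scores)
  # the constant gene is flagged in both the P and the R correlation pass
  expect_warning(expect_warning(
    tabs <- correlation_tables(expr, A, p_scores, r_scores,
                               n_p = 499, seed = 3),
    "constant"), "constant")
  genes <- tabs$genes
  expect_gt(genes$s_with_r[genes$entity == "gene_r"], 0.5)
  expect_lt(genes$q_r[genes$entity == "gene_r"], 0.05)
  expect_true(is.na(genes$s_with_p[genes$entity == "gene_flat"]))
  tfs <- tabs$tfs
  expect_gt(tfs$s_with_p[tfs$entity == "TF_p"], 0.5)
  expect_lt(tfs$q_p[tfs$entity == "TF_p"], 0.05)
  # q-values never smaller than raw p
  expect_true(all(genes$q_r >= genes$p_r, na.rm = TRUE))
  # shared-permutation table p agrees with the single-pair routine
  single <- spearman_with_permutation_p(expr["gene_r", ], r_scores,
                                        n_p = 499, seed = 11)
  expect_equal(genes$s_with_r[genes$entity == "gene_r"], single$s)
})

test_that("target-set enrichment peaks when targets lead the ranking", {
  stats_vec <- stats::setNames(seq(1, 0, length.out = 20), paste0("g", 1:20))
  res <- target_set_enrichment(stats_vec, paste0("g", 1:4), n_p = 200,
                               seed = 5)
  expect_equal(res$e_plus, 1)
  expect_identical(res$tail, "high")
  # uniformly placed targets are unremarkable
  set.seed(12)
  res2 <- target_set_enrichment(stats_vec, sample(names(stats_vec), 4),
                                n_p = 200, seed = 5)
  expect_gte(res2$p_plus, 1 / 201)
})

test_that("sustaining-TF calls need both significant arms with matching sign", {
  tf_table <- tibble::tibble(
    entity = c("TF_good", "TF_corr_only", "TF_neg"),
    s_with_p = c(0.6, 0.6, -0.6), p_p = c(0.001, 0.001, 0.001),
    q_p = c(0.004, 0.004, 0.004),
    s_with_r = c(-0.5, -0.5, 0.5), p_r = c(0.9, 0.9, 0.9),
    q_r = c(0.9, 0.9, 0.9))
  enr <- function(p_plus) tibble::tibble(
    tf = c("TF_good", "TF_corr_only", "TF_neg"),
    e_minus = -0.1, e_plus = c(0.8, 0.1, 0.8),
    p_minus = 0.9, p_plus = p_plus, e_reported = 0.8, tail = "high",
    n = 100, m = 5)
  out <- find_sustaining_tfs(tf_table,
                             enrichments_p = enr(c(0.001, 0.8, 0.001)),
                             enrichments_r = enr(c(0.9, 0.9, 0.9)))
  expect_identical(out$tf, "TF_good")
  expect_identical(out$programme, "P->P")
})
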