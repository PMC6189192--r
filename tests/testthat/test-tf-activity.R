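test_that("parse_trrust filters, collapses and rejects as specified", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("KLF4\tIL1B\tActivation\t123",
               "TP53\tX\tUnknown\t456",
               "KLF4\tIL1B\tActivation\t789",
               "JUN\tFOS\tActivation\t1",
               "JUN\tFOS\tRepression\t2"), path)
  suppressMessages(expect_warning(net <- parse_trrust(path), "conflicting"))
  expect_identical(nrow(net), 1L)
  expect_identical(net$tf, "KLF4")
  expect_identical(net$mode, "Activation")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tActivation", "broken line"), bad)
  expect_error(parse_trrust(bad), "line 2", class = "prtf_parse_error")
})

test_that("ternary matrix restricts to expressed targets and drops empty TFs", {
  net <- parse_trrust(data.frame(
    tf = c("T1", "T1", "T2"),
    target = c("a", "b", "zz"),
    mode = c("Activation", "Repression", "Activation"))) |>
    suppressMessages()
  tern <- suppressMessages(build_ternary_matrix(net, c("a", "b", "c")))
  expect_identical(dim(tern), c(2L, 1L))
  expect_identical(tern["a", "T1"], 1)
  expect_identical(tern["b", "T1"], -1)
  expect_identical(attr(tern, "dropped_tfs")$tf, "T2")
  expect_error(build_ternary_matrix(net, "qq"), class = "prtf_data_error")
})

test_that("least-squares activities match hand calculations", {
  # one TF, one activated and one repressed target, exact fit
  tern <- matrix(c(1, -1), 2, 1, dimnames = list(c("a", "b"), "T1"))
  expr <- matrix(c(3, -3), 2, 1, dimnames = list(c("a", "b"), "s1"))
  act <- infer_activities(expr, tern, intercept = TRUE)
  expect_equal(act$values["T1", "s1"], 3)

  # identity design, no intercept: activities equal expression
  tern2 <- diag(2); dimnames(tern2) <- list(c("a", "b"), c("T1", "T2"))
  expr2 <- matrix(c(1.5, -2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  act2 <- infer_activities(expr2, tern2, intercept = FALSE)
  expect_equal(unname(act2$values[, "s1"]), c(1.5, -2))

  # normal equations by hand: T = (1, 1, -1)', G = (1, 3, -2) -> 3a = 6
  tern3 <- matrix(c(1, 1, -1), 3, 1, dimnames = list(c("a", "b", "c"), "T1"))
  expr3 <- matrix(c(1, 3, -2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  act3 <- infer_activities(expr3, tern3, intercept = FALSE)
  expect_equal(act3$values["T1", "s1"], 2)
})

test_that("solver matches the normal-equation oracle on random instances", {
  set.seed(14)
  for (i in 1:30) {
    n_genes <- sample(10:30, 1); n_tfs <- sample(2:8, 1)
    repeat {
      tern <- matrix(sample(c(-1, 0, 1), n_genes * n_tfs, replace = TRUE,
                            prob = c(0.2, 0.5, 0.3)), n_genes, n_tfs)
      X <- cbind(1, tern)
      if (qr(X)$rank == n_tfs + 1L) break
    }
    dimnames(tern) <- list(paste0("g", 1:n_genes), paste0("T", 1:n_tfs))
    expr <- matrix(rnorm(n_genes * 3), n_genes, 3,
                   dimnames = list(rownames(tern), paste0("s", 1:3)))
    act <- infer_activities(expr, tern, intercept = TRUE)
    # independent route: solve the normal equations directly
    ref <- solve(crossprod(X), crossprod(X, expr))[-1L, , drop = FALSE]
    expect_lt(max(abs(act$values - ref)), 1e-8)
    # residuals orthogonal to every design column
    fitted <- X %*% solve(crossprod(X), crossprod(X, expr))
    expect_lt(max(abs(crossprod(X, expr - fitted))), 1e-8)
  }
})

test_that("collinear designs yield NA activities, flagged not silent", {
  tern <- cbind(T1 = c(1, 1, 0), T2 = c(1, 1, 0), T3 = c(0, 0, 1))
  rownames(tern) <- paste0("g", 1:3)
  expr <- matrix(rnorm(6), 3, 2, dimnames = list(rownames(tern),
                                                 c("s1", "s2")))
  act <- suppressMessages(infer_activities(expr, tern, intercept = FALSE))
  expect_true(any(is.na(act$values)))
  expect_true(any(act$dropped_tfs$reason == "non-identifiable"))
})

test_that("constant-activity TFs are filtered with recorded reasons", {
  vals <- rbind(T1 = c(0, 0, 0), T2 = c(1, 2, 3), T3 = c(NA, NA, NA))
  colnames(vals) <- paste0("s", 1:3)
  act <- structure(list(values = vals, pvalues = NULL, k_calls = NULL,
                        dropped_tfs = tibble::tibble(tf = character(),
                                                     reason = character()),
                        intercept = TRUE),
                   class = "tf_activity")
  out <- filter_constant_tfs(act)
  expect_identical(rownames(out$values), "T2")
  expect_setequal(out$dropped_tfs$reason,
                  c("zero standard deviation", "non-identifiable"))
  act$values <- vals[c("T1", "T3"), ]
  expect_error(filter_constant_tfs(act), class = "prtf_data_error")
})

test_that("pooled TF null has the stated size and is centered on centered input", {
  set.seed(2)
  cfg_genes <- 60; n_samples <- 10; n_perm <- 100
  tern <- matrix(sample(c(-1, 0, 1), cfg_genes * 4, replace = TRUE,
                        prob = c(0.15, 0.7, 0.15)), cfg_genes, 4,
                 dimnames = list(paste0("g", 1:cfg_genes), paste0("T", 1:4)))
  tern[1, 1] <- 1  # ensure no empty column
  expr <- matrix(rnorm(cfg_genes * n_samples), cfg_genes, n_samples,
                 dimnames = list(rownames(tern), paste0("s", 1:n_samples)))
  expr <- mean_center_genes(expr)
  null <- build_tf_null(expr, tern, n_perm = n_perm, seed = 4)
  expect_equal(ncol(null$scores), n_perm * n_samples)
  # same seed reproduces; different seed does not
  null2 <- build_tf_null(expr, tern, n_perm = n_perm, seed = 4)
  expect_identical(null$scores, null2$scores)
  # pooled null mean ~ 0 within 3 standard errors
  for (tf in rownames(null$scores)) {
    v <- null$scores[tf, ]
    expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("permuting a constant expression sample leaves activities unchanged", {
  tern <- cbind(T1 = c(1, -1, 1), T2 = c(0, 1, 1))
  rownames(tern) <- paste0("g", 1:3)
  expr <- matrix(2, 3, 1, dimnames = list(rownames(tern), "s1"))
  obs <- infer_activities(expr, tern)$values
  null <- build_tf_null(expr, tern, n_perm = 5, seed = 1)
  for (j in seq_len(ncol(null$scores))) {
    expect_equal(unname(null$scores[, j]), unname(obs[, 1]), tolerance = 1e-10)
  }
})

test_that("TF p-values use add-one smoothing and the strict K+ rule", {
  vals <- matrix(c(10, 0.5), 1, 2,
                 dimnames = list("T1", c("s1", "s2")))
  act <- structure(list(values = vals, pvalues = NULL, k_calls = NULL,
                        dropped_tfs = tibble::tibble(tf = character(),
                                                     reason = character()),
                        intercept = TRUE),
                   class = "tf_activity")
  null <- structure(list(scores = matrix(seq(-1, 1, length.out = 999), 1,
                                         dimnames = list("T1", NULL)),
                         n_perm = 999, n_samples = 1, seed = 1,
                         intercept = TRUE),
                    class = "tf_null")
  out <- tf_pvalues_and_calls(act, null, designated_tf = "T1", alpha = 0.05)
  # observed above all 999 null values: p = 1/1000 -> K+
  expect_equal(out$pvalues["T1", "s1"], 1 / 1000)
  expect_true(out$k_calls$k_call[1])
  # observed at the null median: p ~ 0.5
  expect_equal(out$pvalues["T1", "s2"], 0.25, tolerance = 0.02)

  # p exactly alpha is K- (strict inequality)
  null2 <- null
  null2$scores <- matrix(seq_len(999), 1, dimnames = list("T1", NULL))
  act2 <- act; act2$values[1, ] <- c(950.5, 0.5)  # 49 null values >= obs
  out2 <- tf_pvalues_and_calls(act2, null2, designated_tf = "T1")
  expect_equal(out2$k_calls$p_value[1], 0.05)
  expect_false(out2$k_calls$k_call[1])

  expect_error(tf_pvalues_and_calls(act, null, designated_tf = "nope"),
               class = "prtf_usage_error")
})

test_that("activities are recovered from a generated regulon structure", {
  set.seed(33)
  net <- generate_regulatory_network(5, 8, 0.3, paste0("g", 1:120), seed = 3)
  tern <- build_ternary_matrix(net, paste0("g", 1:120))
  A_true <- matrix(rnorm(5 * 40), 5, 40,
                   dimnames = list(colnames(tern), paste0("s", 1:40)))
  expr <- matrix(rnorm(120 * 40, sd = 0.1), 120, 40,
                 dimnames = list(paste0("g", 1:120), paste0("s", 1:40)))
  expr[rownames(tern), ] <- expr[rownames(tern), ] + tern %*% A_true
  act <- infer_activities(expr[rownames(tern), , drop = FALSE], tern)
  for (tf in rownames(A_true)) {
    expect_gt(cor(A_true[tf, ], act$values[tf, ]), 0.95)
  }
  # tidy/glance views
  td <- tidy(act)
  expect_identical(nrow(td), 5L * 40L)
  expect_identical(glance(act)$n_tfs, 5L)
})
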