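#' Assemble a pipeline configuration
#'
#' Collects inputs and tuning parameters for [run_pr_pipeline()]. Every data
#' slot accepts either an in-memory object (matrix / tibble / list, as
#' produced by this package) or a file path in the corresponding plain-text
#' format ([read_expression_tsv()], [read_gmt()], [parse_trrust()],
#' [read_fraction_table()], TSV clinical table). Paths are checked up front
#' so a missing input aborts before any computation.
#'
#' @param expression Genes x samples matrix or TSV path.
#' @param gene_sets Named list with elements `P` and `R` (character vectors)
#'   or a GMT path containing sets named `P` and `R`.
#' @param network `regulatory_network` tibble or regulatory-table TSV path.
#' @param clinical Optional clinical tibble/TSV (`os_time`, `os_event`,
#'   `rfs_time`, `rfs_event`, `stage`, `age`, `gender`).
#' @param fractions Optional samples x cell-types matrix or TSV path.
#' @param lineage Optional `cell_type`/`lineage` tibble or TSV path.
#' @param external_labels Optional named per-sample category vector (e.g.
#'   CMS calls) for the subtype-overlap analysis.
#' @param batch Optional named per-sample batch labels for per-batch
#'   centering.
#' @param n_p_signature,n_perm_tf,n_p_correlation Permutation counts for the
#'   signature null, the pooled TF null (per sample) and the Spearman nulls.
#' @param alpha Significance level for calls.
#' @param designated_tf TF whose activity defines the K call; defaults to
#'   `"KLF4"` when present among retained TFs, else the first retained TF.
#' @param intercept Fit an intercept in the activity regression.
#' @param stratified_ks Also run the K+/K- fraction KS tests within P strata.
#' @param seed Master seed; stages draw named sub-streams from it.
#' @param out_dir Optional directory for TSV outputs plus a YAML manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, gene_sets, network,
                            clinical = NULL, fractions = NULL,
                            lineage = NULL, external_labels = NULL,
                            batch = NULL,
                            n_p_signature = 1000L, n_perm_tf = 50L,
                            n_p_correlation = 1000L, alpha = 0.05,
                            designated_tf = NULL, intercept = TRUE,
                            stratified_ks = FALSE, seed = 1L,
                            out_dir = NULL) {
  assert_scalar_prob(alpha, "alpha")
  cfg <- list(expression = expression, gene_sets = gene_sets,
              network = network, clinical = clinical, fractions = fractions,
              lineage = lineage, external_labels = external_labels,
              batch = batch,
              n_p_signature = assert_count(n_p_signature, "n_p_signature"),
              n_perm_tf = assert_count(n_perm_tf, "n_perm_tf"),
              n_p_correlation = assert_count(n_p_correlation,
                                             "n_p_correlation"),
              alpha = alpha, designated_tf = designated_tf,
              intercept = isTRUE(intercept),
              stratified_ks = isTRUE(stratified_ks),
              seed = assert_count(seed, "seed", min = 0L),
              out_dir = out_dir)
  for (slot in c("expression", "gene_sets", "network", "clinical",
                 "fractions", "lineage")) {
    v <- cfg[[slot]]
    if (is.character(v) && length(v) == 1L && !file.exists(v)) {
      abort(sprintf("Input `%s` points to a missing file: %s", slot, v),
            class = "prtf_config_error")
    }
  }
  structure(cfg, class = "pipeline_config")
}

load_slot <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

read_clinical_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full stratification / TF-activity / survival / immune pipeline
#'
#' Executes, in order: per-batch mean-centering; P and R signature scoring
#' with permutation p-values; P±/R± classification; ternary-matrix
#' construction and TF activity inference with pooled permutation null and
#' K± calls; gene- and TF-level correlation tables against the P/R scores;
#' subtype overlap against external labels (when given); programme-
#' sustaining TF identification; Kaplan-Meier/log-rank stratifications and
#' multivariate Cox models (when clinical data are given); and immune-
#' fraction association with the designated TF's activity (when fractions
#' are given). Fully deterministic given the config seed. When `out_dir` is
#' set, every result table is written as TSV together with a YAML manifest;
#' a stage failure writes a `FAILED` marker naming the stage and re-throws.
#'
#' @param config A [pipeline_config()], or a `synthetic_cohort` (its
#'   components and planted labels are wired in automatically; extra
#'   arguments are passed to [pipeline_config()]).
#' @param ... When `config` is a `synthetic_cohort`: overrides forwarded to
#'   [pipeline_config()].
#' @return List of class `pr_pipeline_result`; see the methods vignette for
#'   the component tables.
#' @export
run_pr_pipeline <- function(config, ...) {
  if (inherits(config, "synthetic_cohort")) {
    cohort <- config
    config <- pipeline_config(
      expression = cohort$expression,
      gene_sets = cohort$gene_sets,
      network = cohort$network,
      clinical = cohort$clinical,
      fractions = cohort$fractions,
      lineage = cohort$lineage,
      external_labels = stats::setNames(cohort$true_labels$pr_subtype,
                                        cohort$true_labels$sample),
      batch = cohort$batch,
      designated_tf = cohort$designated_tf,
      seed = cohort$config$seed,
      ...)
  }
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  out <- list(config = cfg[setdiff(names(cfg), c(
    "expression", "gene_sets", "network", "clinical", "fractions",
    "lineage", "external_labels", "batch"))])
  stage <- "load_inputs"
  on_fail <- function(e) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
    }
    abort(sprintf("[%s] %s", stage, conditionMessage(e)), parent = e)
  }
  withCallingHandlers(
    error = function(e) on_fail(e),
    {
      expr <- load_slot(cfg$expression, read_expression_tsv)
      assert_expression_matrix(expr)
      sets <- load_slot(cfg$gene_sets, read_gmt)
      if (!all(c("P", "R") %in% names(sets))) {
        abort("`gene_sets` must provide sets named 'P' and 'R'.",
              class = "prtf_config_error")
      }
      net <- load_slot(cfg$network, parse_trrust)
      clinical <- load_slot(cfg$clinical, read_clinical_tsv)
      fractions <- load_slot(cfg$fractions, read_fraction_table)
      lineage <- load_slot(cfg$lineage, read_clinical_tsv)
      batch <- cfg$batch %||% attr(expr, "batch")

      stage <- "preprocess"
      expr <- mean_center_genes(expr, batch = batch)

      stage <- "signature_scoring"
      out$scores_p <- score_signature(
        expr, sets$P, n_p = cfg$n_p_signature,
        seed = derive_seed(cfg$seed, "sig_P"), set_name = "P")
      out$scores_r <- score_signature(
        expr, sets$R, n_p = cfg$n_p_signature,
        seed = derive_seed(cfg$seed, "sig_R"), set_name = "R")
      out$pr_calls <- classify_samples(out$scores_p, out$scores_r,
                                       alpha = cfg$alpha)

      stage <- "tf_activity"
      tern <- build_ternary_matrix(net, rownames(expr))
      act <- infer_activities(expr, tern, intercept = cfg$intercept) |>
        filter_constant_tfs()
      tf_null <- build_tf_null(expr, tern, n_perm = cfg$n_perm_tf,
                               seed = derive_seed(cfg$seed, "tf_null"),
                               intercept = cfg$intercept)
      designated <- cfg$designated_tf %||%
        (if ("KLF4" %in% rownames(act$values)) "KLF4"
         else rownames(act$values)[1L])
      act <- tf_pvalues_and_calls(act, tf_null, designated_tf = designated,
                                  alpha = cfg$alpha)
      out$activity <- act

      stage <- "association"
      out$correlations <- correlation_tables(
        expr, act, out$scores_p, out$scores_r,
        n_p = cfg$n_p_correlation, seed = derive_seed(cfg$seed, "corr"))
      gene_tbl <- out$correlations$genes
      s_p <- stats::setNames(gene_tbl$s_with_p, gene_tbl$entity)
      s_r <- stats::setNames(gene_tbl$s_with_r, gene_tbl$entity)
      null_cache <- list()
      enrich_one <- function(stat_vec, tf, which) {
        targets <- net$target[net$tf == tf]
        stat_vec <- stat_vec[!is.na(stat_vec)]
        m <- sum(unique(targets) %in% names(stat_vec))
        key <- sprintf("%d_%d", length(stat_vec), m)
        if (is.null(null_cache[[key]])) {
          null_cache[[key]] <<- build_null(
            length(stat_vec), m, n_p = cfg$n_p_correlation,
            seed = derive_seed(cfg$seed, paste0("tse_", key)))
        }
        suppressWarnings(
          target_set_enrichment(stat_vec, targets,
                                null = null_cache[[key]])) |>
          mutate(tf = tf, ranking = which, .before = 1L)
      }
      retained <- rownames(act$values)
      out$enrichments_p <- purrr::map_dfr(retained, ~enrich_one(s_p, .x, "P"))
      out$enrichments_r <- purrr::map_dfr(retained, ~enrich_one(s_r, .x, "R"))
      out$sustaining_tfs <- find_sustaining_tfs(
        out$correlations$tfs, out$enrichments_p, out$enrichments_r,
        alpha = cfg$alpha)

      if (!is.null(cfg$external_labels)) {
        stage <- "subtype_overlap"
        called <- stats::setNames(out$pr_calls$pr_subtype,
                                  out$pr_calls$sample)
        out$overlap <- subtype_overlap(cfg$external_labels, called)
      }

      if (!is.null(clinical)) {
        stage <- "survival"
        cl <- left_join(clinical, out$pr_calls, by = "sample") |>
          left_join(tibble(sample = out$scores_p$sample,
                           p_score = out$scores_p$e_reported,
                           r_score = out$scores_r$e_reported),
                    by = "sample") |>
          left_join(select(act$k_calls, "sample", "k_call"), by = "sample") |>
          mutate(pk_subtype = paste0(ifelse(.data$p_call, "P+", "P-"), "/",
                                     ifelse(.data$k_call, "K+", "K-")),
                 gender_male = as.integer(.data$gender == "male"))
        lr <- function(strat, outcome) {
          g <- cl[[strat]]
          if (length(unique(g)) < 2L) return(NULL)
          logrank_test(cl[[paste0(outcome, "_time")]],
                       cl[[paste0(outcome, "_event")]], g) |>
            mutate(stratification = strat, outcome = outcome, .before = 1L)
        }
        out$logrank <- bind_rows(
          lr("pr_subtype", "os"), lr("pr_subtype", "rfs"),
          lr("pk_subtype", "os"), lr("pk_subtype", "rfs"))
        covs <- list(pr = c("p_score", "r_score", "stage", "age",
                            "gender_male"),
                     p_only = c("p_score", "stage", "age", "gender_male"),
                     r_only = c("r_score", "stage", "age", "gender_male"))
        out$cox <- purrr::map(c(os = "os", rfs = "rfs"), function(oc) {
          purrr::map(covs, ~cox_fit(cl, .x, outcome = oc))
        })
        out$clinical_annotated <- cl
      }

      if (!is.null(fractions)) {
        stage <- "immune_association"
        scores <- stats::setNames(act$k_calls$activity, act$k_calls$sample)
        out$fraction_correlations <- correlate_fractions_with_score(
          fractions, scores, n_p = cfg$n_p_correlation,
          seed = derive_seed(cfg$seed, "fractions"),
          lineage = if (!is.null(lineage))
            select(lineage, "cell_type", "lineage") else NULL)
        kc <- stats::setNames(act$k_calls$k_call, act$k_calls$sample)
        kvec <- kc[rownames(fractions)]
        ks_for <- function(rows, stratum) {
          purrr::map_dfr(colnames(fractions), function(ct) {
            g1 <- fractions[rows & kvec, ct]
            g2 <- fractions[rows & !kvec, ct]
            if (!length(g1) || !length(g2)) return(NULL)
            ks_tail_test(g1, g2) |>
              mutate(cell_type = ct, stratum = stratum, .before = 1L)
          })
        }
        out$ks_tests <- ks_for(rep(TRUE, nrow(fractions)), "all")
        if (cfg$stratified_ks) {
          pc <- stats::setNames(out$pr_calls$p_call, out$pr_calls$sample)
          pvec <- pc[rownames(fractions)]
          out$ks_tests <- bind_rows(out$ks_tests,
                                    ks_for(pvec, "P+"), ks_for(!pvec, "P-"))
        }
      }
    }
  )
  out <- structure(out, class = "pr_pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

# Flatten result tables, write TSVs and a manifest.
pipeline_tables <- function(res) {
  act <- res$activity
  tabs <- list(
    signature_scores_P = res$scores_p,
    signature_scores_R = res$scores_r,
    pr_calls = res$pr_calls,
    tf_activities = as_tibble(act$values, rownames = "tf"),
    tf_pvalues = as_tibble(act$pvalues, rownames = "tf"),
    tf_dropped = act$dropped_tfs,
    k_calls = act$k_calls,
    gene_correlations = res$correlations$genes,
    tf_correlations = res$correlations$tfs,
    target_enrichments_P = res$enrichments_p,
    target_enrichments_R = res$enrichments_r,
    sustaining_tfs = res$sustaining_tfs
  )
  if (!is.null(res$overlap)) tabs$subtype_overlap <- res$overlap
  if (!is.null(res$logrank)) {
    tabs$logrank_tests <- res$logrank
    tabs$cox_fits <- purrr::imap_dfr(res$cox, function(models, oc) {
      purrr::imap_dfr(models, function(fit, nm) {
        tidy(fit) |> mutate(outcome = oc, model = nm, .before = 1L)
      })
    })
  }
  if (!is.null(res$fraction_correlations)) {
    tabs$fraction_correlations <- res$fraction_correlations
    tabs$ks_tests <- res$ks_tests
  }
  tabs
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- pipeline_tables(res)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tabs[[nm]], p, progress = FALSE)
    paths[nm] <- p
  }
  manifest <- list(
    package = "prtf",
    version = as.character(utils::packageVersion("prtf")),
    seed = res$config$seed,
    parameters = res$config,
    tables = as.list(basename(paths))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(paths)
}

#' @export
print.pr_pipeline_result <- function(x, ...) {
  cat("<pr_pipeline_result>\n")
  cat(sprintf("  samples: %d  P+: %d  R+: %d\n", nrow(x$pr_calls),
              sum(x$pr_calls$p_call), sum(x$pr_calls$r_call)))
  if (!is.null(x$activity$k_calls)) {
    cat(sprintf("  designated TF %s: %d K+ call(s)\n",
                x$activity$designated_tf, sum(x$activity$k_calls$k_call)))
  }
  cat(sprintf("  sustaining TFs: %d\n", nrow(x$sustaining_tfs)))
  invisible(x)
}

#' Run a complete synthetic demonstration
#'
#' Generates a default synthetic cohort, runs [run_pr_pipeline()] with
#' test-scale permutation counts, writes all output tables, the manifest and
#' a YAML summary report (P±/R±/K± call counts, recovered sustaining TFs,
#' log-rank p-values, top fraction correlations) under `out_dir`.
#'
#' @param seed Master seed for the cohort and all permutation families.
#' @param out_dir Output directory.
#' @param config Optional [synthetic_config()] override (its seed is
#'   replaced by `seed`).
#' @return The `pr_pipeline_result`, invisibly, with the summary attached as
#'   attribute `summary`.
#' @export
make_demo <- function(seed = 7L, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory %s", out_dir),
                   class = "prtf_io_error")
  }
  cfg <- config %||% synthetic_config()
  cfg$seed <- assert_count(seed, "seed", min = 0L)
  cohort <- generate_cohort(cfg)
  res <- run_pr_pipeline(cohort, out_dir = out_dir,
                         n_p_signature = 1000L, n_perm_tf = 50L,
                         n_p_correlation = 1000L, stratified_ks = TRUE)
  truth <- cohort$true_labels
  calls <- res$pr_calls
  acc <- mean(calls$p_call[match(truth$sample, calls$sample)] ==
                truth$p_pos) / 2 +
    mean(calls$r_call[match(truth$sample, calls$sample)] == truth$r_pos) / 2
  summary <- list(
    seed = cfg$seed,
    n_samples = ncol(cohort$expression),
    calls = list(p_pos = sum(calls$p_call), r_pos = sum(calls$r_call),
                 k_pos = sum(res$activity$k_calls$k_call)),
    pr_recovery_accuracy = acc,
    sustaining_tfs = as.list(stats::setNames(res$sustaining_tfs$programme,
                                             res$sustaining_tfs$tf)),
    designated_tf = cohort$designated_tf,
    designated_in_RR = cohort$designated_tf %in%
      res$sustaining_tfs$tf[res$sustaining_tfs$programme == "R->R"],
    logrank_p = as.list(stats::setNames(res$logrank$p_value,
                                        paste(res$logrank$stratification,
                                              res$logrank$outcome,
                                              sep = "_"))),
    top_fraction_correlations = utils::head(
      res$fraction_correlations[order(res$fraction_correlations$q_value), ],
      3L) |> as.list()
  )
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  attr(res, "summary") <- summary
  invisible(res)
}
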