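#' Configuration for a synthetic cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. The defaults
#' describe the cohort used throughout the package's validation runs:
#' 300 samples, 2000 genes, 50 TFs with 10 targets each (30% repressing),
#' 50-gene P and R signatures shifted by 2 noise standard deviations in
#' positive samples, strongly anti-correlated P/R membership, and a doubled
#' hazard for R+ samples.
#'
#' `effect_size = 0` defines the null cohort: no signature shifts, no
#' TF-to-target coupling and no planted activity shift, so expression is
#' exchangeable across genes and every downstream call rate should match its
#' nominal significance level.
#'
#' @param n_samples,n_genes,n_tfs,targets_per_tf Cohort dimensions.
#' @param frac_repressing Probability that a regulatory edge is repressing.
#' @param p_set_size,r_set_size Signature sizes (disjoint gene sets).
#' @param effect_size Shift (in noise-SD units) applied to signature genes in
#'   positive samples and to the planted TF activities.
#' @param noise_sd Baseline expression noise SD.
#' @param frac_p_pos,frac_r_pos Marginal fractions of P+ / R+ samples.
#' @param pr_anticorrelation Strength of the negative P/R association: the
#'   joint P+/R+ probability is shrunk from independence (`frac_p_pos *
#'   frac_r_pos`) by this factor toward zero, preserving both marginals; at
#'   1 a P+ sample is always R- and vice versa.
#' @param hazard_ratio_rpos Hazard multiplier for R+ samples.
#' @param baseline_hazard_os,baseline_hazard_rfs,censor_rate Exponential
#'   event/censoring rates (per time unit).
#' @param n_batches Optional batch structure: batches receive distinct
#'   gene-wise offsets, removable by per-batch mean-centering.
#' @param seed Master integer seed.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 300L, n_genes = 2000L, n_tfs = 50L,
                             targets_per_tf = 10L, frac_repressing = 0.3,
                             p_set_size = 50L, r_set_size = 50L,
                             effect_size = 2, noise_sd = 1,
                             frac_p_pos = 0.35, frac_r_pos = 0.35,
                             pr_anticorrelation = 0.8,
                             hazard_ratio_rpos = 2,
                             baseline_hazard_os = 0.015,
                             baseline_hazard_rfs = 0.025,
                             censor_rate = 0.01,
                             n_batches = 1L, seed = 7L) {
  cfg <- list(
    n_samples = assert_count(n_samples, "n_samples"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_tfs = assert_count(n_tfs, "n_tfs"),
    targets_per_tf = assert_count(targets_per_tf, "targets_per_tf"),
    frac_repressing = assert_scalar_prob(frac_repressing, "frac_repressing"),
    p_set_size = assert_count(p_set_size, "p_set_size"),
    r_set_size = assert_count(r_set_size, "r_set_size"),
    effect_size = effect_size, noise_sd = noise_sd,
    frac_p_pos = assert_scalar_prob(frac_p_pos, "frac_p_pos"),
    frac_r_pos = assert_scalar_prob(frac_r_pos, "frac_r_pos"),
    pr_anticorrelation = assert_scalar_prob(pr_anticorrelation,
                                            "pr_anticorrelation"),
    hazard_ratio_rpos = hazard_ratio_rpos,
    baseline_hazard_os = baseline_hazard_os,
    baseline_hazard_rfs = baseline_hazard_rfs,
    censor_rate = censor_rate,
    n_batches = assert_count(n_batches, "n_batches"),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$effect_size < 0 || cfg$noise_sd <= 0) {
    abort("`effect_size` must be >= 0 and `noise_sd` > 0.",
          class = "prtf_config_error")
  }
  if (cfg$hazard_ratio_rpos <= 0 || cfg$baseline_hazard_os <= 0 ||
      cfg$baseline_hazard_rfs <= 0 || cfg$censor_rate <= 0) {
    abort("Hazard parameters must be positive.", class = "prtf_config_error")
  }
  if (cfg$p_set_size + cfg$r_set_size > cfg$n_genes) {
    abort("Signature sizes exceed the gene universe.",
          class = "prtf_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a random regulatory network
#'
#' Each TF receives exactly `targets_per_tf` distinct target genes drawn
#' uniformly from the gene universe; each edge is Repression with probability
#' `frac_repressing`, else Activation. Emulates a parsed curated regulatory
#' table restricted to activating/repressing interactions.
#'
#' @param n_tfs,targets_per_tf Network dimensions.
#' @param frac_repressing Per-edge repression probability.
#' @param gene_universe Non-empty character vector of candidate target genes
#'   (`targets_per_tf <= length(gene_universe)`).
#' @param seed Integer seed.
#' @return `regulatory_network` tibble: `tf`, `target`, `mode`.
#' @export
generate_regulatory_network <- function(n_tfs, targets_per_tf,
                                        frac_repressing, gene_universe,
                                        seed = 1L) {
  n_tfs <- assert_count(n_tfs, "n_tfs")
  targets_per_tf <- assert_count(targets_per_tf, "targets_per_tf")
  assert_scalar_prob(frac_repressing, "frac_repressing")
  if (!length(gene_universe)) {
    abort("Empty gene universe.", class = "prtf_config_error")
  }
  if (targets_per_tf > length(gene_universe)) {
    abort("`targets_per_tf` exceeds the gene universe size.",
          class = "prtf_config_error")
  }
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  with_stream(seed, "network", {
    edges <- purrr::map_dfr(tf_ids, function(tf) {
      tibble(tf = tf,
             target = sample(gene_universe, targets_per_tf),
             mode = ifelse(stats::runif(targets_per_tf) < frac_repressing,
                           "Repression", "Activation"))
    })
    structure(edges, class = c("regulatory_network", class(edges)),
              provenance = "synthetic")
  })
}

#' Exponential survival times with a group hazard ratio
#'
#' Event times are exponential with rate `baseline_hazard *
#' hazard_ratio^positive`; censoring times are independent exponential with
#' rate `censor_rate`; the observed time is the minimum.
#'
#' @param positive Logical per-sample indicator of the high-hazard group.
#' @param baseline_hazard,censor_rate Positive rates.
#' @param hazard_ratio Positive hazard multiplier for positive samples.
#' @param seed Integer seed.
#' @param sample_ids Optional sample identifiers.
#' @return Tibble: `sample`, `time`, `event` (0/1), `positive`.
#' @export
generate_survival <- function(positive, baseline_hazard, hazard_ratio,
                              censor_rate, seed = 1L, sample_ids = NULL) {
  if (baseline_hazard <= 0 || censor_rate <= 0 || hazard_ratio <= 0) {
    abort("Rates and hazard ratio must be positive.",
          class = "prtf_config_error")
  }
  positive <- as.logical(positive)
  n <- length(positive)
  sample_ids <- sample_ids %||% sprintf("s%03d", seq_len(n))
  with_stream(seed, "survival", {
    event_time <- stats::rexp(n, rate = baseline_hazard *
                                hazard_ratio^positive)
    censor_time <- stats::rexp(n, rate = censor_rate)
    tibble(sample = sample_ids,
           time = pmin(event_time, censor_time),
           event = as.integer(event_time <= censor_time),
           positive = positive)
  })
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds an expression cohort in which every downstream inference has a
#' known answer: disjoint P and R signature gene sets shifted upward in
#' positive samples; a random regulatory network whose TF activities act on
#' target-gene expression through the ternary design; a designated
#' R-driving TF whose activity is set to `effect_size` in R+ (= K+)
#' samples and a symmetric P-driving TF set high in P+ samples (both given all-activating regulons
#' so their target signatures are coherent); exponential survival with an
#' elevated hazard for R+ samples; and immune-cell fractions in which the
#' myeloid types `Neutrophils` and `Macrophages_M0` increase monotonically
#' (logistic transform plus noise) with the designated TF's activity while
#' the remaining cell types are independent.
#'
#' With `effect_size = 0` all planted structure (signature shifts, TF
#' coupling, activity shifts) is switched off and the cohort is a pure null.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort`: `expression` (genes x samples,
#'   uncentered), `network`, `true_activities` (TFs x samples),
#'   `true_labels`, `clinical`, `fractions` (samples x cell types),
#'   `lineage`, `gene_sets` (named list `P`, `R`), `designated_tf`, `batch`,
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  samples <- sprintf("s%03d", seq_len(cfg$n_samples))
  p_set <- genes[seq_len(cfg$p_set_size)]
  r_set <- genes[cfg$p_set_size + seq_len(cfg$r_set_size)]
  target_universe <- setdiff(genes, c(p_set, r_set))

  # subtype labels: joint P/R membership with the requested marginals and
  # negative association — pr_anticorrelation shrinks the P+/R+ cell from
  # independence (p*r) toward zero, so a P+ sample is almost surely R- at
  # high anticorrelation while both marginal fractions are preserved
  joint <- (1 - cfg$pr_anticorrelation) * cfg$frac_p_pos * cfg$frac_r_pos
  cell_prob <- c(pp = joint,
                 p_only = cfg$frac_p_pos - joint,
                 r_only = cfg$frac_r_pos - joint,
                 neither = 1 - cfg$frac_p_pos - cfg$frac_r_pos + joint)
  if (any(cell_prob < 0)) {
    abort("frac_p_pos + frac_r_pos too large for this pr_anticorrelation.",
          class = "prtf_config_error")
  }
  labels <- with_stream(cfg$seed, "labels", {
    cell <- sample(names(cell_prob), cfg$n_samples, replace = TRUE,
                   prob = cell_prob)
    tibble(sample = samples,
           p_pos = cell %in% c("pp", "p_only"),
           r_pos = cell %in% c("pp", "r_only"))
  })
  labels$k_pos <- labels$r_pos & cfg$effect_size > 0
  labels$pr_subtype <- paste0(ifelse(labels$p_pos, "P+", "P-"), "/",
                              ifelse(labels$r_pos, "R+", "R-"))

  network <- generate_regulatory_network(
    cfg$n_tfs, cfg$targets_per_tf, cfg$frac_repressing,
    target_universe, seed = derive_seed(cfg$seed, "cohort_network"))
  tf_ids <- unique(network$tf)
  designated_tf <- tf_ids[1L]
  p_driver_tf <- if (cfg$n_tfs >= 2L) tf_ids[2L] else NULL
  # coherent regulons for the planted programme drivers
  network$mode[network$tf %in% c(designated_tf, p_driver_tf)] <- "Activation"

  activities <- with_stream(cfg$seed, "activities", {
    matrix(stats::rnorm(cfg$n_tfs * cfg$n_samples), cfg$n_tfs, cfg$n_samples,
           dimnames = list(tf_ids, samples))
  })
  if (cfg$effect_size > 0) {
    activities[designated_tf, labels$r_pos] <- cfg$effect_size
    if (!is.null(p_driver_tf)) {
      activities[p_driver_tf, labels$p_pos] <- cfg$effect_size
    }
  }

  expr <- with_stream(cfg$seed, "expression", {
    matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, sd = cfg$noise_sd),
           cfg$n_genes, cfg$n_samples, dimnames = list(genes, samples))
  })
  if (cfg$effect_size > 0) {
    expr[p_set, labels$p_pos] <- expr[p_set, labels$p_pos] + cfg$effect_size
    expr[r_set, labels$r_pos] <- expr[r_set, labels$r_pos] + cfg$effect_size
    tern <- build_ternary_matrix(network, genes)
    expr[rownames(tern), ] <- expr[rownames(tern), ] +
      tern %*% activities[colnames(tern), , drop = FALSE]
  }

  batch <- NULL
  if (cfg$n_batches > 1L) {
    batch <- stats::setNames(
      sprintf("batch%d", rep_len(seq_len(cfg$n_batches), cfg$n_samples)),
      samples)
    offsets <- with_stream(cfg$seed, "batch_offsets", {
      matrix(stats::rnorm(cfg$n_genes * cfg$n_batches), cfg$n_genes,
             cfg$n_batches)
    })
    expr <- expr + offsets[, match(batch, sprintf("batch%d",
                                                  seq_len(cfg$n_batches)))]
  }

  os <- generate_survival(labels$r_pos, cfg$baseline_hazard_os,
                          cfg$hazard_ratio_rpos, cfg$censor_rate,
                          seed = derive_seed(cfg$seed, "os"),
                          sample_ids = samples)
  rfs <- generate_survival(labels$r_pos, cfg$baseline_hazard_rfs,
                           cfg$hazard_ratio_rpos, cfg$censor_rate,
                           seed = derive_seed(cfg$seed, "rfs"),
                           sample_ids = samples)
  clinical <- with_stream(cfg$seed, "clinical", {
    tibble(
      sample = samples,
      os_time = os$time, os_event = os$event,
      rfs_time = rfs$time, rfs_event = rfs$event,
      stage = sample(1:4, cfg$n_samples, replace = TRUE,
                     prob = c(0.15, 0.3, 0.35, 0.2)),
      age = round(stats::rnorm(cfg$n_samples, 68, 10)),
      gender = sample(c("female", "male"), cfg$n_samples, replace = TRUE)
    )
  })

  lineage <- tibble(
    cell_type = c("Neutrophils", "Macrophages_M0", "Monocytes",
                  "B_cells_naive", "T_cells_CD4", "NK_cells",
                  "Mast_cells_resting"),
    lineage = c("myeloid", "myeloid", "myeloid",
                "lymphoid", "lymphoid", "lymphoid", "other"),
    coupled = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  act_des <- activities[designated_tf, ]
  fractions <- with_stream(cfg$seed, "fractions", {
    f <- vapply(seq_len(nrow(lineage)), function(i) {
      latent <- if (lineage$coupled[i]) {
        act_des + stats::rnorm(cfg$n_samples)
      } else {
        stats::rnorm(cfg$n_samples)
      }
      0.12 * stats::plogis(latent)
    }, numeric(cfg$n_samples))
    dimnames(f) <- list(samples, lineage$cell_type)
    f
  })

  structure(
    list(expression = expr, network = network,
         true_activities = activities, true_labels = labels,
         clinical = clinical, fractions = fractions, lineage = lineage,
         gene_sets = list(P = p_set, R = r_set),
         designated_tf = designated_tf, p_driver_tf = p_driver_tf,
         batch = batch, config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d genes x %d samples, %d TFs; designated TF %s; effect %.2g>\n",
    nrow(x$expression), ncol(x$expression), length(unique(x$network$tf)),
    x$designated_tf, x$config$effect_size))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Expression as a genes x samples TSV, the network in regulatory-table
#' dialect (TF, target, mode, reference), clinical / label / fraction tables
#' as TSV, and the configuration as YAML.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    network = file.path(dir, "network.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    labels = file.path(dir, "true_labels.tsv"),
    fractions = file.path(dir, "fractions.tsv"),
    lineage = file.path(dir, "lineage.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_expression_tsv(cohort$expression, paths[["expression"]],
                       batch = cohort$batch)
  readr::write_tsv(cohort$network |>
                     mutate(reference = "synthetic"),
                   paths[["network"]], col_names = FALSE, progress = FALSE)
  readr::write_tsv(cohort$clinical, paths[["clinical"]], progress = FALSE)
  readr::write_tsv(cohort$true_labels, paths[["labels"]], progress = FALSE)
  readr::write_tsv(as_tibble(cohort$fractions, rownames = "sample"),
                   paths[["fractions"]], progress = FALSE)
  readr::write_tsv(cohort$lineage, paths[["lineage"]], progress = FALSE)
  yaml::write_yaml(unclass(cohort$config), paths[["config"]])
  invisible(paths)
}
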