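# Configuration-driven orchestration: simulate/load -> QC -> features ->
# clustering -> DE -> gene cytometry -> dual-axis trajectory -> regulons ->
# projection, with per-stage seeds fanned out from one global seed and a
# machine-readable JSON run report.

#' Read a pipeline run configuration from a YAML file
#'
#' @param path YAML file. Top-level keys: `seed`, `out_dir`, `stages`
#'   (logical toggles named qc, features, cluster, de, cytometry, trajectory,
#'   regulon, projection), `simulate` (simulation parameters passed to
#'   [sim_config()]) or `input_dir` (Matrix Market bundle), and per-stage
#'   parameter blocks (`params`).
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order, writes every intermediate
#' artifact under `out_dir` (CSV tables, Matrix Market counts, GMT regulons,
#' JSON report), and returns the report. Disabling QC while requesting
#' downstream stages is allowed: the raw counts are used, with a logged
#' warning in the report.
#'
#' @param cfg Configuration list (see [read_run_config()]); programmatic use
#'   can pass the list directly.
#' @return Run report (list), invisibly; written as `report.json`.
#' @export
run_pipeline <- function(cfg) {
  out_dir <- cfg$out_dir %||% "gliaxes_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  stages <- utils::modifyList(
    list(qc = TRUE, features = TRUE, cluster = TRUE, de = TRUE,
         cytometry = TRUE, trajectory = TRUE, regulon = FALSE,
         projection = FALSE),
    cfg$stages %||% list())
  prm <- cfg$params %||% list()
  report <- list(package_version = as.character(utils::packageVersion("gliaxes")),
                 seed = seed, stages = stages, parameters = prm,
                 counts = list(), warnings = character(0))
  warn <- function(msg) {
    report$warnings <<- c(report$warnings, msg)
    message("[gliaxes] ", msg)
  }

  # --- input: simulate or load ------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- stage_seed(seed, "simulate")
    sc <- do.call(sim_config, sim_args)
    sim <- simulate_sc_counts(sc)
    counts <- sim$counts
    write_simulation(sim, file.path(out_dir, "simulated"))
    report$counts$simulated <- dim(counts)
  } else if (!is.null(cfg$input_dir)) {
    counts <- read_counts_mtx(cfg$input_dir)
    report$counts$loaded <- dim(counts)
  } else stop("config needs either a 'simulate' block or 'input_dir'")

  # --- QC + normalization -----------------------------------------------------
  if (isTRUE(stages$qc)) {
    rules <- do.call(qc_rules, prm$qc %||% list())
    counts <- filter_cells_and_genes(counts, rules)
    qc_rep <- attr(counts, "qc_report")
    utils::write.csv(qc_rep, file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    report$counts$post_qc <- dim(counts)
  } else warn("QC disabled; downstream stages run on raw input")
  norm <- normalize_log_cpm(counts, method = prm$normalize_method %||%
                              "library_size")

  # --- feature selection ------------------------------------------------------
  features <- NULL
  if (isTRUE(stages$features)) {
    features <- select_features_danb(counts,
                                     top_fraction = prm$top_fraction %||% 0.25)
    writeLines(features, file.path(out_dir, "feature_genes.txt"))
    report$counts$features <- length(features)
  }

  # --- clustering ---------------------------------------------------------
  if (isTRUE(stages$cluster)) {
    xf <- if (!is.null(features)) subset_norm(norm, genes = features) else norm
    k <- prm$k %||% estimate_k(xf)
    cl <- consensus_cluster(xf, k = k, seed = stage_seed(seed, "cluster"))
    utils::write.csv(data.frame(cell = names(cl$cluster),
                                cluster = cl$cluster),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    report$counts$k <- k
    if (!is.null(counts$cell_meta$group))
      report$counts$ari_vs_groups <-
        adjusted_rand_index(cl$cluster, counts$cell_meta$group)
  }

  # --- differential expression ------------------------------------------------
  de_age <- de_phago <- NULL
  if (isTRUE(stages$de)) {
    groups <- counts$cell_meta$group
    if (is.null(groups)) {
      warn("no 'group' metadata; DE stage skipped")
    } else {
      kw <- kruskal_wallis_de(norm, groups, alpha = prm$fdr %||% 0.05)
      write_de_csv(kw, file.path(out_dir, "de_kruskal_wallis.csv"))
      ctr <- prm$contrasts %||% list(
        ageing = c("WT6m", "WT24m"), phagocytosis = c("XO4neg", "XO4pos"))
      if (all(unlist(ctr) %in% groups)) {
        de_age <- pairwise_de(counts, ctr$ageing[1], ctr$ageing[2],
                              alpha = prm$fdr %||% 0.05)
        de_phago <- pairwise_de(counts, ctr$phagocytosis[1],
                                ctr$phagocytosis[2],
                                alpha = prm$fdr %||% 0.05)
        write_de_csv(de_age, file.path(out_dir, "de_ageing.csv"))
        write_de_csv(de_phago, file.path(out_dir, "de_phagocytosis.csv"))
        report$counts$de_ageing <- sum(de_age$significant, na.rm = TRUE)
        report$counts$de_phagocytosis <- sum(de_phago$significant, na.rm = TRUE)
      } else warn("contrast groups absent; pairwise DE skipped")
    }
  }

  # --- gene cytometry -----------------------------------------------------
  if (isTRUE(stages$cytometry) && !is.null(de_age) && !is.null(de_phago)) {
    cyt <- gene_cytometry(de_phago, de_age,
                          fdr_threshold = prm$fdr %||% 0.05)
    utils::write.csv(cyt$table, file.path(out_dir, "gene_cytometry.csv"),
                     row.names = FALSE)
    report$counts$cytometry <- as.list(cyt$overlap)
  }

  # --- dual-axis trajectory ---------------------------------------------------
  if (isTRUE(stages$trajectory) && !is.null(de_age) && !is.null(de_phago)) {
    axes <- tryCatch(
      dual_axis_pseudotime(norm, de_age, de_phago,
                           fdr = prm$fdr %||% 0.05,
                           reference_group = prm$reference_group %||% "WT6m",
                           knn = prm$knn %||% 15),
      error = function(e) { warn(conditionMessage(e)); NULL })
    if (!is.null(axes)) {
      utils::write.csv(rbind(axes$ageing, axes$phagocytosis),
                       file.path(out_dir, "pseudotime.csv"), row.names = FALSE)
      utils::write.csv(axes$joint, file.path(out_dir, "pseudotime_joint.csv"),
                       row.names = FALSE)
      report$counts$ageing_specific_genes <- length(axes$ageing_specific_genes)
      report$counts$phago_specific_genes <- length(axes$phago_specific_genes)
    }
  }

  # --- regulon activity ---------------------------------------------------
  if (isTRUE(stages$regulon) && !is.null(cfg$regulon_gmt)) {
    regs <- read_gmt(cfg$regulon_gmt)
    act <- regulon_activity(norm, regs,
                            top_fraction = prm$auc_top_fraction %||% 0.05)
    act <- binarize_activity(act)
    summ <- summarize_regulon_activity(
      act, counts$cell_meta$group,
      min_targets = prm$min_targets %||% 100,
      min_active_fraction = prm$min_active_fraction %||% 0.10)
    utils::write.csv(act$auc, file.path(out_dir, "regulon_auc.csv"))
    utils::write.csv(summ$group_means,
                     file.path(out_dir, "regulon_group_means.csv"))
    report$counts$regulons_retained <- length(summ$retained)
  }

  # --- projection onto bulk ---------------------------------------------------
  if (isTRUE(stages$projection) && !is.null(cfg$bulk_dir)) {
    bulk <- normalize_log_cpm(read_counts_mtx(cfg$bulk_dir))
    proj <- project_cells_to_bulk(norm, bulk)
    utils::write.csv(proj$z, file.path(out_dir, "projection_z.csv"))
    jsonlite::write_json(proj$sample_order,
                         file.path(out_dir, "bulk_order.json"))
    report$counts$projection <- dim(proj$z)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
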