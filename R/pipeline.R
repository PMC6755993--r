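#' Analysis configuration
#'
#' Collects every threshold of the discovery pipeline in one validated
#' object. Defaults follow the published procedure: classifier gene filter
#' log2fc > 1 at FDR < 0.05 with AUC > 0.9 keeping 10 genes and a 0.5
#' posterior call threshold; candidate regulators log2fc < -0.5 at
#' FDR < 1e-4; candidate targets |log2fc| > 0.25 at FDR < 0.05; 1000
#' permutations; 100 bootstraps at 0.95 consensus; strict DPI.
#'
#' @param de_lfc_classifier,de_fdr_classifier Classifier DE filter.
#' @param auc_min,n_classifier_genes Classifier AUC filter and gene count.
#' @param posterior_threshold Mesenchymal posterior call threshold.
#' @param regulator_lfc_max,regulator_fdr Candidate-regulator filter.
#' @param target_abs_lfc_min,target_fdr Candidate-target filter (the FDR is
#'   also the network significance level).
#' @param n_permutations,n_bootstraps,bootstrap_consensus,dpi_tolerance
#'   Network inference layers.
#' @param mra_fdr MRA significance level.
#' @param rng_seed Root seed; per-stage seeds are derived from it.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(de_lfc_classifier = 1.0,
                            de_fdr_classifier = 0.05,
                            auc_min = 0.9,
                            n_classifier_genes = 10L,
                            posterior_threshold = 0.5,
                            regulator_lfc_max = -0.5,
                            regulator_fdr = 1e-4,
                            target_abs_lfc_min = 0.25,
                            target_fdr = 0.05,
                            n_permutations = 1000L,
                            n_bootstraps = 100L,
                            bootstrap_consensus = 0.95,
                            dpi_tolerance = 0.0,
                            mra_fdr = 0.05,
                            rng_seed = 1L) {
  cfg <- list(de_lfc_classifier = de_lfc_classifier,
              de_fdr_classifier = de_fdr_classifier,
              auc_min = auc_min,
              n_classifier_genes = as.integer(n_classifier_genes),
              posterior_threshold = posterior_threshold,
              regulator_lfc_max = regulator_lfc_max,
              regulator_fdr = regulator_fdr,
              target_abs_lfc_min = target_abs_lfc_min,
              target_fdr = target_fdr,
              n_permutations = as.integer(n_permutations),
              n_bootstraps = as.integer(n_bootstraps),
              bootstrap_consensus = bootstrap_consensus,
              dpi_tolerance = dpi_tolerance,
              mra_fdr = mra_fdr,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(de_fdr_classifier > 0, de_fdr_classifier < 1,
              auc_min >= 0, auc_min <= 1,
              posterior_threshold > 0, posterior_threshold < 1,
              regulator_fdr > 0, regulator_fdr < 1,
              target_fdr > 0, target_fdr < 1,
              bootstrap_consensus > 0, bootstrap_consensus <= 1,
              dpi_tolerance >= 0, dpi_tolerance <= 1,
              mra_fdr > 0, mra_fdr < 1,
              n_classifier_genes > 0, n_permutations > 0, n_bootstraps > 0)
  })
  structure(cfg, class = "analysis_config")
}

run_stage_ <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full master-regulator discovery pipeline
#'
#' Stages, in order: per-feature differential expression (miRNA and gene) ->
#' classifier gene selection and nearest-shrunken-centroid training (when
#' subtype labels are available) -> signed MI network inference -> master
#' regulator analysis against the signature -> preranked GSEA -> survival
#' stratification (subtype and top-regulator expression) -> sequence-based
#' target triangulation for the top master regulator. All randomness derives
#' from `config$rng_seed` through fixed per-stage offsets, so a fixed seed
#' reproduces the report exactly.
#'
#' @param gene_expr,mirna_expr Paired [expression_matrix()] objects.
#' @param samples A `sample_table` with a `subtype` column (or a mesenchymal
#'   posterior-based labeling produced beforehand with [predict_nsc()]) and,
#'   optionally, `time`/`event`/`age`/`stage`/`grade` for the survival stage.
#' @param signature Character vector of signature gene ids.
#' @param gene_sets Optional named list of additional gene sets for GSEA (the
#'   signature is always included).
#' @param predictions Optional list of `target_predictions` for the
#'   triangulation stage.
#' @param config An [analysis_config()].
#' @param output_dir Optional directory: when given, every stage table plus a
#'   JSON report (with file hashes) is written there.
#' @return A list of class `pipeline_report`.
#' @export
run_full_pipeline <- function(gene_expr, mirna_expr, samples, signature,
                              gene_sets = NULL, predictions = NULL,
                              config = analysis_config(),
                              output_dir = NULL) {
  stopifnot(inherits(gene_expr, "ExpressionMatrix"),
            inherits(mirna_expr, "ExpressionMatrix"))
  if (!identical(gene_expr$sample_ids, mirna_expr$sample_ids)) {
    offending <- union(setdiff(gene_expr$sample_ids, mirna_expr$sample_ids),
                       setdiff(mirna_expr$sample_ids, gene_expr$sample_ids))
    stop_validation("sample mismatch between matrices: %s",
                    paste(utils::head(offending, 10), collapse = ", "))
  }
  samples <- validate_sample_table(as.data.frame(samples))
  samples <- samples[match(gene_expr$sample_ids, samples$sample_id), ]
  if (anyNA(samples$sample_id)) {
    stop_validation("annotation is missing some matrix samples")
  }
  if (!"subtype" %in% names(samples) || anyNA(samples$subtype)) {
    stop_validation("samples need subtype labels (provide them or classify first)")
  }
  mes <- samples$subtype == "mesenchymal"
  log_line <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  report <- list(config = unclass(config), seed = config$rng_seed,
                 stages = character(0))

  # -- differential expression -------------------------------------------
  de_gene <- run_stage_("diffexp", differential_expression_table(gene_expr, mes))
  de_mirna <- run_stage_("diffexp", differential_expression_table(mirna_expr, mes))
  log_line("diffexp", "%d genes, %d miRNAs tested (%d mesenchymal vs %d other samples)",
           nrow(de_gene), nrow(de_mirna), sum(mes), sum(!mes))
  report$stages <- c(report$stages, "diffexp")
  report$de_gene <- de_gene
  report$de_mirna <- de_mirna

  # -- classifier ---------------------------------------------------------
  gene_z <- znormalize(gene_expr)
  classifier <- run_stage_("classify", {
    genes <- two_step_feature_selection(gene_z, mes, config)
    model <- train_nsc(subset_expression(gene_z, features = genes),
                       ifelse(mes, "mesenchymal", "other"),
                       seed = config$rng_seed + 11L)
    posteriors <- predict_nsc(model, gene_z, config$posterior_threshold)
    list(genes = genes, model = model, posteriors = posteriors)
  })
  log_line("classify", "%d classifier genes selected; delta = %.3f",
           length(classifier$genes), classifier$model$delta)
  report$stages <- c(report$stages, "classify")
  report$classifier_genes <- classifier$genes
  report$classifier_model <- classifier$model
  report$posteriors <- classifier$posteriors

  # -- network ------------------------------------------------------------
  net_cfg <- config
  net_cfg$rng_seed <- config$rng_seed + 23L
  network <- run_stage_("infer_network",
                        infer_network(gene_expr, mirna_expr, mes, net_cfg))
  log_line("infer_network", "%d candidate regulators, %d candidate targets, %d kept edges",
           length(network$regulators), length(network$targets),
           sum(network$edges$kept))
  report$stages <- c(report$stages, "infer_network")
  report$network <- network

  # -- MRA ----------------------------------------------------------------
  mra <- run_stage_("mra", {
    regs <- regulons(network)
    if (!length(regs)) stop("network has no non-empty regulon")
    rank_master_regulators(mra_enrichment(regs, signature, network$targets))
  })
  log_line("mra", "top master regulator: %s (adj_p = %.3g)",
           mra$regulator[1], mra$adj_p[1])
  report$stages <- c(report$stages, "mra")
  report$mra <- mra
  report$top_master_regulator <- list(regulator = mra$regulator[1],
                                      adj_p = mra$adj_p[1])

  # -- GSEA ---------------------------------------------------------------
  gsea <- run_stage_("gsea", {
    ranked <- rank_by_log2fc(gene_expr, mes)
    collection <- c(list(signature = signature), gene_sets)
    gsea_run(ranked, collection, n_permutations = config$n_permutations,
             seed = config$rng_seed + 37L)
  })
  report$stages <- c(report$stages, "gsea")
  report$gsea <- gsea

  # -- survival -----------------------------------------------------------
  if (all(c("time", "event") %in% names(samples)) && !anyNA(samples$time)) {
    surv <- run_stage_("survival", {
      lr_subtype <- logrank_test(samples$time, samples$event,
                                 ifelse(mes, "mesenchymal", "other"))
      covar <- data.frame(mesenchymal = as.numeric(mes))
      for (cv in intersect(c("age", "stage", "grade"), names(samples))) {
        covar[[cv]] <- samples[[cv]]
      }
      top <- report$top_master_regulator$regulator
      strat <- stratify_by_mean(mirna_expr$values[top, ], mirna_expr$sample_ids)
      lr_mirna <- logrank_test(samples$time, samples$event, strat)
      list(logrank_subtype = lr_subtype,
           cox_univariate = cox_fit(samples$time, samples$event,
                                    covar[, "mesenchymal", drop = FALSE]),
           cox_multivariate = cox_fit(samples$time, samples$event, covar),
           km_mesenchymal = km_estimate(samples$time[mes], samples$event[mes]),
           km_other = km_estimate(samples$time[!mes], samples$event[!mes]),
           stratified_by = top,
           logrank_top_regulator = lr_mirna)
    })
    log_line("survival", "subtype log-rank p = %.3g", surv$logrank_subtype$p_value)
    report$stages <- c(report$stages, "survival")
    report$survival <- surv
  }

  # -- target prioritization ---------------------------------------------
  if (!is.null(predictions)) {
    prio <- run_stage_("prioritize", {
      top <- report$top_master_regulator$regulator
      regs <- regulons(network)
      intersect_target_evidence(regs[[top]], signature, predictions, top,
                                mirna_expr = mirna_expr, gene_expr = gene_expr)
    })
    log_line("prioritize", "%d prioritized target(s): %s",
             length(prio$prioritized), paste(prio$prioritized, collapse = ", "))
    report$stages <- c(report$stages, "prioritize")
    report$targets <- prio
  }

  class(report) <- "pipeline_report"
  if (!is.null(output_dir)) {
    write_pipeline_report(report, output_dir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (seed %d): stages [%s]\n", x$seed,
              paste(x$stages, collapse = " -> ")))
  cat(sprintf("top master regulator: %s (adj_p = %.3g)\n",
              x$top_master_regulator$regulator, x$top_master_regulator$adj_p))
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Serializes every stage table as TSV plus a JSON summary that records the
#' config echo, the seed, the stage order and an md5 hash of every emitted
#' file.
#'
#' @param report A `pipeline_report`.
#' @param output_dir Directory (created if needed).
#' @return The JSON summary path, invisibly.
#' @export
write_pipeline_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    write_results_table(df, p)
    files[[name]] <<- p
  }
  emit(report$de_gene, "de_genes.tsv")
  emit(report$de_mirna, "de_mirnas.tsv")
  emit(report$posteriors, "classifier_posteriors.tsv")
  emit(report$network$edges[report$network$edges$kept,
                            c("regulator", "target", "mi", "perm_p", "adj_p",
                              "support", "sign")],
       "network_edges.tsv")
  emit(report$mra, "mra.tsv")
  emit(report$gsea[, setdiff(names(report$gsea), "leading_edge")], "gsea.tsv")
  if (!is.null(report$targets)) emit(report$targets$evidence, "target_evidence.tsv")
  model_path <- file.path(output_dir, "classifier_model.json")
  nsc_model_to_json(report$classifier_model, model_path)
  files[["classifier_model.json"]] <- model_path

  summary <- list(
    seed = report$seed,
    config = report$config,
    stages = report$stages,
    top_master_regulator = report$top_master_regulator,
    files = lapply(files, function(p) unname(tools::md5sum(p)))
  )
  json_path <- file.path(output_dir, "report.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
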