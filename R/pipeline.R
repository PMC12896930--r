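CONFIG_FIELDS <- c("pipeline", "alpha", "lfc_cut", "score_cut", "r_cut",
                   "hk_min_count", "hk_max_cv", "min_cpm_count", "top_n",
                   "evidence_mode", "seed")

#' Pipeline configuration
#'
#' Houses every analysis threshold in one validated object: the DEM call
#' (adjusted p < `alpha`, |log2FC| >= `lfc_cut`), the strong-regulation score
#' cut, the clinical-correlation cut, the housekeeping selection criteria,
#' the low-expression floor, the network size and the evidence mode.
#' Unknown keys are rejected.
#'
#' @param pipeline `"P1"` or `"P2"`.
#' @param alpha adjusted-p threshold.
#' @param lfc_cut absolute log2-fold-change threshold.
#' @param score_cut cumulative-score threshold (strict).
#' @param r_cut absolute Spearman-r threshold.
#' @param hk_min_count,hk_max_cv housekeeping selection criteria.
#' @param min_cpm_count low-expression floor (count scale).
#' @param top_n genes displayed in the network.
#' @param evidence_mode `"all_three"` or `"any_strong"`.
#' @param seed integer seed recorded in provenance.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pipeline = "P2", alpha = 0.05, lfc_cut = 1,
                            score_cut = 4, r_cut = 0.4, hk_min_count = 50,
                            hk_max_cv = 0.20, min_cpm_count = 10, top_n = 10,
                            evidence_mode = "all_three", seed = 1L) {
  stopifnot(pipeline %in% c("P1", "P2"), alpha > 0, alpha < 1, lfc_cut >= 0,
            score_cut > 0, r_cut >= 0, r_cut <= 1,
            evidence_mode %in% c("all_three", "any_strong"))
  structure(list(pipeline = pipeline, alpha = alpha, lfc_cut = lfc_cut,
                 score_cut = score_cut, r_cut = r_cut,
                 hk_min_count = hk_min_count, hk_max_cv = hk_max_cv,
                 min_cpm_count = min_cpm_count, top_n = top_n,
                 evidence_mode = evidence_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @return `read_pipeline_config` returns a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), CONFIG_FIELDS)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "mirstage_schema_error")
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "mirstage_stage_error", parent = e)
  })
}

#' Run the full stage-wise analysis
#'
#' One call from raw counts to exported results: per-sample QC, the chosen
#' normalization pipeline with RLE diagnostics, moderated differential
#' expression for both stage contrasts with the Venn partition, and — when
#' an interaction table and gene sets are supplied — cumulative target
#' scoring, network export and over-representation per contrast, plus
#' Spearman clinical correlation when clinical codes are available. All
#' tables are written as TSV/JSON under `out_dir` together with a
#' provenance record (config hash, package version, per-stage row counts).
#' The run is deterministic given the inputs.
#'
#' @param counts raw [ncounter_set()].
#' @param sheet sample sheet.
#' @param out_dir output directory (created if missing).
#' @param interactions optional interaction tibble from
#'   [load_interactions()] or a path to the TSV.
#' @param gene_sets optional named list of gene sets or a GMT path.
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(counts, sheet, out_dir, interactions = NULL,
                         gene_sets = NULL, config = pipeline_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ncfg <- norm_config(hk_min_count = config$hk_min_count,
                      hk_max_cv = config$hk_max_cv,
                      min_cpm_count = config$min_cpm_count)
  rows <- list()

  qc <- stage("qc", qc_samples(counts))
  write_qc(qc, file.path(out_dir, "qc.tsv"), file.path(out_dir, "qc.json"))
  rows$qc <- nrow(qc)

  norm <- stage("normalize",
                normalize_pipeline(counts, sheet, config$pipeline, ncfg))
  readr::write_tsv(tibble::as_tibble(norm$log2_expr, rownames = "probe_id"),
                   file.path(out_dir, "normalized_log2.tsv"))
  jsonlite::write_json(
    list(factors = norm$factors, housekeeping = norm$housekeeping,
         pipeline = norm$pipeline),
    file.path(out_dir, "normalization.json"), auto_unbox = TRUE, digits = NA)
  rle_res <- stage("rle", rle_stats(norm))
  readr::write_tsv(rle_res$per_sample, file.path(out_dir, "rle_per_sample.tsv"))
  readr::write_tsv(rle_res$summary, file.path(out_dir, "rle_summary.tsv"))
  rows$normalized_probes <- nrow(norm$log2_expr)

  de <- stage("de", fit_moderated(norm, sheet, alpha = config$alpha,
                                  lfc_cut = config$lfc_cut))
  readr::write_tsv(tidy(de), file.path(out_dir, "de_results.tsv"))
  readr::write_tsv(volcano_data(de), file.path(out_dir, "volcano_data.tsv"))
  venn <- stage("venn", classify_and_partition(de))
  jsonlite::write_json(
    venn[c("early_only", "advanced_only", "shared", "n_early", "n_advanced",
           "union_size")],
    file.path(out_dir, "venn_partition.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(venn$table, file.path(out_dir, "dem_table.tsv"))
  rows$dems <- venn$union_size

  results <- list(qc = qc, norm = norm, rle = rle_res, de = de, venn = venn)

  if (!is.null(interactions)) {
    if (is.character(interactions)) {
      interactions <- stage("interactions", load_interactions(interactions))
    }
    hi <- stage("interactions",
                filter_high_confidence(interactions, config$evidence_mode))
    universe <- unique(hi$target_gene)
    if (is.character(gene_sets)) gene_sets <- stage("enrich", read_gmt(gene_sets))
    results$scores <- list()
    for (ctr in c("early", "advanced")) {
      lfc <- expand_composite_probes(
        dplyr::filter(de_contrast(de, ctr), .data$significant))
      if (!length(lfc)) next
      scores <- stage("scores", cumulative_scores(lfc, hi, config$score_cut))
      readr::write_tsv(
        dplyr::select(scores, -"contributing"),
        file.path(out_dir, paste0("gene_scores_", ctr, ".tsv")))
      net <- stage("network", build_network(scores, lfc, config$top_n, ctr))
      export_network(net, file.path(out_dir, paste0("network_", ctr, ".graphml")),
                     "graphml")
      export_network(net, file.path(out_dir, paste0("network_", ctr, ".sif")), "sif")
      export_network(net, file.path(out_dir, paste0("network_", ctr, "_nodes.tsv")),
                     "tsv")
      results$scores[[ctr]] <- scores
      results$network[[ctr]] <- net
      if (!is.null(gene_sets)) {
        strong <- scores$target_gene[scores$strongly_regulated]
        if (length(strong)) {
          enr <- stage("enrich", ora_test(strong, gene_sets, universe,
                                          config$alpha))
          readr::write_tsv(enr, file.path(out_dir, paste0("enrichment_", ctr, ".tsv")))
          results$enrichment[[ctr]] <- enr
        }
      }
    }
  }

  codes <- tryCatch(encode_clinical(sheet), warning = function(w) NULL)
  if (!is.null(codes) && ncol(codes) > 1) {
    corr <- stage("correlate",
                  spearman_all(norm, codes, alpha = config$alpha,
                               r_cut = config$r_cut))
    readr::write_tsv(corr, file.path(out_dir, "correlations.tsv"))
    top <- top_associations(corr)
    readr::write_tsv(top, file.path(out_dir, "top_correlations.tsv"))
    if (nrow(top)) {
      readr::write_tsv(boxplot_data(norm, codes, unique(top$probe_id)),
                       file.path(out_dir, "correlation_boxplot_data.tsv"))
    }
    results$correlations <- corr
    rows$correlations <- nrow(corr)
  }

  provenance <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("mirstage")),
    r_version = R.version.string,
    row_counts = rows,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
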