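#' Full single-run analysis pipeline
#'
#' Chains aberrant feature detection, metabolite/pathway annotation,
#' enrichment, redundancy clustering and (when a biomarker panel is given)
#' biomarker ranking plus novel-biomarker candidate extraction for one
#' patient-versus-controls run.
#'
#' @param run A [sample_run()] object.
#' @param metabolites Metabolite table, see [load_metabolites()].
#' @param pathways Pathway table, see [load_pathways()].
#' @param biomarker_ids Optional character vector of known biomarker
#'   metabolite ids for the run's disorder.
#' @param alpha Significance level for both the BH feature correction and
#'   the Holm pathway correction (default 0.05).
#' @param tol_ppm Annotation mass tolerance in ppm (default 5).
#' @param cluster_mode `"exact"` or `"subset"` pathway overlap rule.
#' @param drop_rt_inconsistent Drop RT-inconsistent annotations before
#'   enrichment (default `FALSE`).
#' @return A list of class `msea_result` with elements `calls`,
#'   `annotations`, `enrichment`, `clusters` and, when `biomarker_ids` is
#'   given, `ranks` (feature / pathway-sorted / cluster-sorted biomarker
#'   ranks with universe sizes, and pathway/cluster biomarker ranks) and
#'   `candidates`.
#' @export
msea_pipeline <- function(run, metabolites, pathways, biomarker_ids = NULL,
                          alpha = 0.05, tol_ppm = 5,
                          cluster_mode = c("exact", "subset"),
                          drop_rt_inconsistent = FALSE) {
  cluster_mode <- match.arg(cluster_mode)
  calls <- call_aberrant(run, alpha = alpha)
  ann <- annotate_run(run, metabolites, tol_ppm = tol_ppm)
  enr <- run_msea(calls, ann, pathways, alpha = alpha,
                  drop_rt_inconsistent = drop_rt_inconsistent)
  clusters <- cluster_pathways(enr, mode = cluster_mode)
  out <- list(run = run, calls = calls, annotations = ann,
              enrichment = enr, clusters = clusters)
  if (!is.null(biomarker_ids)) {
    fr <- feature_rank(calls, ann, biomarker_ids)
    pr <- pathway_sorted_rank(calls, ann, enr, biomarker_ids)
    cr <- pathway_sorted_rank(calls, ann, clusters, biomarker_ids)
    out$ranks <- list(
      feature = fr,
      pathway_sorted = pr,
      cluster_sorted = cr,
      pathway_biomarker_rank =
        pathway_biomarker_rank(enr, pathways, biomarker_ids),
      cluster_biomarker_rank =
        pathway_biomarker_rank(clusters, pathways, biomarker_ids),
      universe_feature = attr(fr, "universe"),
      universe_pathway = attr(pr, "universe"))
    out$candidates <- novel_biomarker_candidates(enr, ann, pathways,
                                                 biomarker_ids)
  }
  class(out) <- "msea_result"
  out
}

#' @export
print.msea_result <- function(x, ...) {
  cat("<msea_result> ", x$run$sample_id, "\n",
      "  aberrant features : ", sum(x$calls$is_aberrant), " of ",
      nrow(x$calls), "\n",
      "  annotations       : ", nrow(x$annotations), "\n",
      "  tested pathways   : ", nrow(x$enrichment),
      " (", sum(x$enrichment$significant), " enriched)\n",
      "  pathway clusters  : ", nrow(x$clusters), "\n", sep = "")
  if (!is.null(x$ranks)) {
    cat("  biomarker ranks   : feature ",
        paste(x$ranks$feature$rank, collapse = "/"),
        " of ", x$ranks$universe_feature,
        "; pathway-sorted ",
        paste(x$ranks$pathway_sorted$rank, collapse = "/"),
        " of ", x$ranks$universe_pathway, "\n", sep = "")
  }
  invisible(x)
}

#' Write all pipeline outputs of a run to a directory
#'
#' Writes `aberrant_calls.tsv`, `annotations.tsv`, `enrichment.tsv`,
#' `clusters.tsv` and, when present, `ranks.tsv` and `candidates.tsv`.
#'
#' @param result Output of [msea_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_msea_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_aberrant_calls(result$calls, file.path(dir, "aberrant_calls.tsv"))
  write_annotations(result$annotations, file.path(dir, "annotations.tsv"))
  write_enrichment(result$enrichment, file.path(dir, "enrichment.tsv"))
  write_clusters(result$clusters, file.path(dir, "clusters.tsv"))
  if (!is.null(result$ranks)) {
    rk <- data.frame(
      metabolite_id = result$ranks$feature$metabolite_id,
      feature_rank = result$ranks$feature$rank,
      pathway_feature_rank = result$ranks$pathway_sorted$rank,
      cluster_feature_rank = result$ranks$cluster_sorted$rank,
      pathway_biomarker_rank = result$ranks$pathway_biomarker_rank,
      cluster_biomarker_rank = result$ranks$cluster_biomarker_rank,
      universe_feature = result$ranks$universe_feature,
      universe_pathway = result$ranks$universe_pathway,
      stringsAsFactors = FALSE)
    utils::write.table(rk, file.path(dir, "ranks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$candidates)) {
    write_candidates(result$candidates, file.path(dir, "candidates.tsv"))
  }
  invisible(dir)
}
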