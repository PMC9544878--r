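#' Pathway sharing across the cohort
#'
#' Counts, for every pathway that is significantly enriched anywhere in the
#' cohort, the number of distinct disorders and the number of runs sharing
#' that enrichment. Pathways enriched across many unrelated disorders are
#' candidate confounders (diet, medication) rather than disease signals.
#' A pathway is flagged as a biomarker pathway when it contains a known
#' biomarker metabolite of any panel disorder.
#'
#' @param enrichments A list of [run_msea()] results, one per run.
#' @param disorders Character vector of the runs' disorder labels, aligned
#'   with `enrichments`.
#' @param pathways Pathway table, see [load_pathways()].
#' @param panel Biomarker panel table (columns `disorder`, `metabolite_id`),
#'   see [load_biomarkers()]; may be `NULL` to skip biomarker flagging.
#' @return A data.frame with one row per enriched pathway: `pathway_id`,
#'   `source`, `n_disorders_shared`, `n_runs_shared`,
#'   `is_biomarker_pathway_for_any`, sorted by decreasing sharing.
#' @export
pathway_sharing <- function(enrichments, disorders, pathways, panel = NULL) {
  stopifnot(length(enrichments) == length(disorders))
  pieces <- lapply(seq_along(enrichments), function(i) {
    enr <- enrichments[[i]]
    sig <- enr[enr$significant, , drop = FALSE]
    if (nrow(sig) == 0L) return(NULL)
    data.frame(pathway_id = sig$pathway_id, source = sig$source,
               run = i, disorder = disorders[i], stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  if (is.null(long) || nrow(long) == 0L) {
    return(data.frame(pathway_id = character(0), source = character(0),
                      n_disorders_shared = integer(0),
                      n_runs_shared = integer(0),
                      is_biomarker_pathway_for_any = logical(0),
                      stringsAsFactors = FALSE))
  }
  spl <- split(long, paste(long$source, long$pathway_id, sep = "\r"))
  out <- data.frame(
    pathway_id = vapply(spl, function(x) x$pathway_id[1L], character(1)),
    source = vapply(spl, function(x) x$source[1L], character(1)),
    n_disorders_shared =
      vapply(spl, function(x) length(unique(x$disorder)), integer(1)),
    n_runs_shared = vapply(spl, function(x) length(unique(x$run)),
                           integer(1)),
    stringsAsFactors = FALSE)
  if (is.null(panel)) {
    out$is_biomarker_pathway_for_any <- NA
  } else {
    bio <- biomarker_pathways(unique(panel$metabolite_id), pathways)
    out$is_biomarker_pathway_for_any <- out$pathway_id %in% bio
  }
  out <- out[order(-out$n_disorders_shared, -out$n_runs_shared,
                   out$pathway_id), ]
  rownames(out) <- NULL
  out
}

#' Are biomarker pathways more disorder-specific than the rest?
#'
#' Two-sided Wilcoxon rank-sum test comparing the number of disorders
#' sharing each biomarker pathway against the non-biomarker pathways. The
#' exact distribution is used for small untied samples, the normal
#' approximation with tie correction otherwise (the default behaviour of
#' [stats::wilcox.test()]; sharing counts are heavily tied in practice).
#'
#' @param sharing Output of [pathway_sharing()] (with biomarker flags).
#' @return The two-sided p-value, or `NA` when either group is empty.
#' @export
specificity_test <- function(sharing) {
  flag <- sharing$is_biomarker_pathway_for_any
  if (any(is.na(flag))) stop("sharing table has no biomarker flags")
  x <- sharing$n_disorders_shared[flag]
  y <- sharing$n_disorders_shared[!flag]
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  suppressWarnings(stats::wilcox.test(x, y,
                                      alternative = "two.sided")$p.value)
}

#' Putative novel biomarker candidates of a run
#'
#' For every significantly enriched biomarker pathway (a pathway containing
#' a known biomarker of the panel), lists the other pathway members that are
#' annotated to an aberrant feature, with the known biomarkers removed.
#' Candidates whose supporting annotations are all retention-time
#' inconsistent are flagged, since RT mismatch is the dominant
#' false-positive mechanism for putative annotations.
#'
#' @param enrichment Output of [run_msea()] for the run.
#' @param annotations Feature annotations of the run, see [annotate_run()].
#' @param pathways Pathway table, see [load_pathways()].
#' @param biomarker_ids The disorder's known biomarker metabolite ids.
#' @return A data.frame with columns `pathway_id`, `source`,
#'   `metabolite_id`, `rt_inconsistent` (all supporting annotations RT
#'   inconsistent).
#' @export
novel_biomarker_candidates <- function(enrichment, annotations, pathways,
                                       biomarker_ids) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  bio <- biomarker_pathways(biomarker_ids, pathways)
  sig <- sig[sig$pathway_id %in% bio, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(pathway_id = character(0), source = character(0),
                      metabolite_id = character(0),
                      rt_inconsistent = logical(0),
                      stringsAsFactors = FALSE))
  }
  pieces <- lapply(seq_len(nrow(sig)), function(i) {
    cand <- setdiff(sig$aberrant_metabolite_ids[[i]], biomarker_ids)
    if (length(cand) == 0L) return(NULL)
    data.frame(pathway_id = sig$pathway_id[i], source = sig$source[i],
               metabolite_id = cand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    return(data.frame(pathway_id = character(0), source = character(0),
                      metabolite_id = character(0),
                      rt_inconsistent = logical(0),
                      stringsAsFactors = FALSE))
  }
  consistent_ids <- unique(
    annotations$metabolite_id[annotations$rt_status != "inconsistent"])
  out$rt_inconsistent <- !(out$metabolite_id %in% consistent_ids)
  rownames(out) <- NULL
  out
}

#' Write novel-biomarker candidates to a tab-separated file
#'
#' @param candidates Output of [novel_biomarker_candidates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
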