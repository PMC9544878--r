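#' Aberrant feature-metabolite pairs of a run
#'
#' The ranking universe: every unique (aberrant feature, annotated
#' metabolite) pair, deduplicated over adduct routes, sorted by patient
#' intensity in descending order (ties broken by feature id, then
#' metabolite id). The 1-based row index of a pair is its rank.
#'
#' @param calls Aberrant calls, see [call_aberrant()].
#' @param annotations Feature annotations, see [annotate_run()].
#' @return A data.frame with columns `feature_id`, `metabolite_id`,
#'   `source`, `patient_intensity`, `rank`.
#' @export
aberrant_pairs <- function(calls, annotations) {
  ab <- calls[calls$is_aberrant, c("feature_id", "patient_intensity")]
  pairs <- unique(annotations[annotations$feature_id %in% ab$feature_id,
                              c("feature_id", "metabolite_id", "source")])
  pairs$patient_intensity <-
    ab$patient_intensity[match(pairs$feature_id, ab$feature_id)]
  pairs <- pairs[order(-pairs$patient_intensity, pairs$feature_id,
                       pairs$metabolite_id), ]
  pairs$rank <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  pairs
}

#' Biomarker rank in the intensity-sorted aberrant feature list
#'
#' Ranks every biomarker metabolite by the position of its highest-ranked
#' associated pair in the intensity-sorted universe of aberrant
#' feature-metabolite pairs. A biomarker with no aberrant associated feature
#' receives `NA`.
#'
#' @param calls Aberrant calls, see [call_aberrant()].
#' @param annotations Feature annotations, see [annotate_run()].
#' @param biomarker_ids Character vector of biomarker metabolite ids.
#' @return A data.frame with columns `metabolite_id` and `rank`; the
#'   universe size (total pairs) is attached as attribute `universe`.
#' @export
feature_rank <- function(calls, annotations, biomarker_ids) {
  pairs <- aberrant_pairs(calls, annotations)
  rank_from_pairs(pairs, biomarker_ids, universe = nrow(pairs))
}

rank_from_pairs <- function(pairs, biomarker_ids, universe) {
  rk <- vapply(biomarker_ids, function(b) {
    r <- pairs$rank[pairs$metabolite_id == b]
    if (length(r) == 0L) NA_integer_ else min(r)
  }, integer(1))
  out <- data.frame(metabolite_id = biomarker_ids, rank = unname(rk),
                    stringsAsFactors = FALSE)
  attr(out, "universe") <- universe
  out
}

#' Biomarker rank after sorting features by pathway or cluster p-value
#'
#' Enriched pathways (or pathway clusters) are ordered by ascending p-value
#' (ties broken by id), each is expanded into its aberrant
#' feature-metabolite pairs sorted by patient intensity descending, and the
#' expansions are concatenated. A pair's first occurrence defines its rank,
#' so pairs in the most enriched pathways come first. The biomarker rank is
#' the minimum rank over the biomarker's pairs; biomarkers not associated
#' with any enriched pathway receive `NA`.
#'
#' @param calls Aberrant calls, see [call_aberrant()].
#' @param annotations Feature annotations, see [annotate_run()].
#' @param items An [run_msea()] result (significant pathways are used) or a
#'   [cluster_pathways()] result.
#' @param biomarker_ids Character vector of biomarker metabolite ids.
#' @return A data.frame with columns `metabolite_id` and `rank`; the
#'   universe size (pathway-associated pairs) is attached as attribute
#'   `universe`.
#' @export
pathway_sorted_rank <- function(calls, annotations, items, biomarker_ids) {
  pairs <- aberrant_pairs(calls, annotations)
  it <- rank_items(items)
  ord <- order(it$p, it$id)
  pieces <- lapply(ord, function(i) {
    which(pairs$metabolite_id %in% it$aberrant_sets[[i]])
  })
  expansion <- unlist(pieces, use.names = FALSE)
  expansion <- expansion[!duplicated(expansion)]
  ranked <- pairs[expansion, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rank_from_pairs(ranked, biomarker_ids, universe = nrow(ranked))
}

# normalise enrichment results / clusters into (id, p, aberrant set) items
rank_items <- function(items) {
  if (inherits(items, "msea_clusters")) {
    list(id = items$cluster_id, p = items$cluster_p,
         aberrant_sets = items$aberrant_metabolite_union,
         members = items$aberrant_metabolite_union)
  } else {
    enr <- items[items$significant, , drop = FALSE]
    list(id = enr$pathway_id, p = enr$raw_p,
         aberrant_sets = enr$aberrant_metabolite_ids,
         members = NULL)
  }
}

#' Rank of the best biomarker-containing pathway or cluster
#'
#' Sorts the enriched pathways (or pathway clusters) by ascending p-value
#' (ties broken by id) and returns the 1-based position of the first entry
#' that contains a biomarker metabolite among its members.
#'
#' @param items An [run_msea()] result (significant pathways are used) or a
#'   [cluster_pathways()] result.
#' @param pathways Pathway table, used for the member sets.
#' @param biomarker_ids Character vector of biomarker metabolite ids.
#' @return The 1-based rank, or `NA` when no entry contains a biomarker.
#' @export
pathway_biomarker_rank <- function(items, pathways, biomarker_ids) {
  if (inherits(items, "msea_clusters")) {
    ord <- order(items$cluster_p, items$representative_pathway_id)
    contains <- vapply(items$member_pathway_ids[ord], function(ids) {
      mem <- unlist(pathways$members[pathways$pathway_id %in% ids])
      any(mem %in% biomarker_ids)
    }, logical(1))
  } else {
    enr <- items[items$significant, , drop = FALSE]
    ord <- order(enr$raw_p, enr$pathway_id)
    contains <- vapply(enr$pathway_id[ord], function(id) {
      mem <- pathways$members[[match(id, pathways$pathway_id)]]
      any(mem %in% biomarker_ids)
    }, logical(1))
  }
  pos <- which(contains)
  if (length(pos) == 0L) NA_integer_ else unname(pos[1L])
}

#' Permutation test of observed biomarker ranks
#'
#' Tests whether observed biomarker ranks across runs are smaller (better)
#' than expected by chance. Under the null, each run's biomarker pairs
#' occupy uniformly random distinct positions within that run's universe;
#' the run's null rank is the minimum of those positions (the best-ranked
#' biomarker pair, matching the observed-rank definition). The test
#' statistic is the median rank across runs, and
#' `p = (1 + #{null median <= observed median}) / (n_perm + 1)`.
#'
#' @param observed_ranks Observed per-run biomarker ranks (NAs dropped with
#'   their runs).
#' @param universe_sizes Per-run universe sizes, aligned with
#'   `observed_ranks`.
#' @param n_biomarker_pairs Per-run number of biomarker-associated pairs
#'   (default 1), aligned with `observed_ranks`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draws.
#' @return The permutation p-value.
#' @export
rank_permutation_test <- function(observed_ranks, universe_sizes,
                                  n_biomarker_pairs = 1L, n_perm = 10000L,
                                  seed = 1L) {
  keep <- !is.na(observed_ranks)
  observed_ranks <- observed_ranks[keep]
  universe_sizes <- universe_sizes[keep]
  n_biomarker_pairs <- rep_len(n_biomarker_pairs, length(keep))[keep]
  if (length(observed_ranks) == 0L) stop("no observed ranks")
  if (any(observed_ranks > universe_sizes)) {
    stop("observed rank exceeds its universe size")
  }
  obs <- stats::median(observed_ranks)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_runs <- length(observed_ranks)
  null_medians <- vapply(seq_len(n_perm), function(i) {
    mins <- vapply(seq_len(n_runs), function(r) {
      min(sample.int(universe_sizes[r], n_biomarker_pairs[r]))
    }, integer(1))
    stats::median(mins)
  }, numeric(1))
  (1 + sum(null_medians <= obs)) / (n_perm + 1)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' ROC AUC of a candidate ranking score for biomarker status
#'
#' Scores every aberrant feature-metabolite pair and measures how well the
#' score separates biomarker-associated pairs from the rest, as the area
#' under the ROC curve (equivalently the Mann-Whitney probability that a
#' random biomarker pair outscores a random non-biomarker pair). Intensity
#' and absolute fold change rank descending (higher is more
#' biomarker-like); the feature p-value ranks ascending.
#'
#' @param run The [sample_run()] (needed for control intensities when
#'   `score = "abs_fold_change"`).
#' @param calls Aberrant calls, see [call_aberrant()].
#' @param annotations Feature annotations, see [annotate_run()].
#' @param biomarker_ids Character vector of biomarker metabolite ids.
#' @param score One of `"intensity"`, `"abs_fold_change"`, `"p_value"`.
#'   Absolute fold change is `max(fc, 1/fc)` with
#'   `fc = patient / median(controls)` (a zero control median maps to
#'   infinity).
#' @return The AUC in `[0, 1]`, or `NA` when either class is empty.
#' @export
score_roc <- function(run, calls, annotations, biomarker_ids,
                      score = c("intensity", "abs_fold_change", "p_value")) {
  score <- match.arg(score)
  pairs <- aberrant_pairs(calls, annotations)
  if (nrow(pairs) == 0L) return(NA_real_)
  s <- switch(score,
    intensity = pairs$patient_intensity,
    abs_fold_change = {
      med <- apply(run$controls, 1L, stats::median)
      names(med) <- run$features$feature_id
      fc <- pairs$patient_intensity / med[pairs$feature_id]
      fc[is.nan(fc)] <- 1 # 0 / 0
      unname(pmax(fc, 1 / fc))
    },
    p_value = {
      p <- calls$raw_p[match(pairs$feature_id, calls$feature_id)]
      -p # smaller p scores higher
    })
  label <- pairs$metabolite_id %in% biomarker_ids
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(s)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
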