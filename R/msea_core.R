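#' One-sided Fisher exact test for pathway over-representation
#'
#' Exact upper-tail probability `P(X >= a)` under the hypergeometric null
#' fixed at the 2x2 table's margins, i.e. the chance of observing at least
#' `a` aberrant pathway-associated features when aberrance and pathway
#' association are independent. This is the enrichment direction of Fisher's
#' exact test.
#'
#' @param a Aberrant and pathway-associated feature count.
#' @param b Non-aberrant, pathway-associated count.
#' @param c Aberrant, not associated count.
#' @param d Non-aberrant, not associated count.
#' @return The one-sided p-value; vectorised over the four arguments.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("contingency counts must be >= 0")
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Family-wise error-rate adjustment of a vector of raw p-values,
#' positionally aligned with the input.
#'
#' @param raw_ps Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, clipped at 1.
#' @export
holm_adjust <- function(raw_ps) {
  check_probabilities(raw_ps)
  stats::p.adjust(raw_ps, method = "holm")
}

#' Metabolite set enrichment analysis of one run
#'
#' For every pathway, counts the run's features in a 2x2 table of aberrance
#' (rows) by pathway association (columns) over the background universe of
#' all detected features (both ion modes, associated and unassociated), and
#' computes the one-sided Fisher exact p. Only pathways associated with more
#' than one aberrant feature are tested; skipped pathways do not enter the
#' Bonferroni-Holm correction denominator. By default the Holm family pools
#' the tested pathways of both source databases.
#'
#' @param calls Aberrant calls of the run, see [call_aberrant()].
#' @param annotations Feature annotations, see [annotate_run()].
#' @param pathways Pathway table, see [load_pathways()].
#' @param alpha Significance level on the Holm-adjusted p (default 0.05).
#' @param min_aberrant Minimum aberrant associated features for a pathway to
#'   be tested (default 2, i.e. "more than one").
#' @param drop_rt_inconsistent Drop RT-inconsistent annotations before
#'   mapping (default `FALSE`; the RT check is a post-hoc plausibility
#'   filter).
#' @param holm_by_source Apply the Holm correction within each source
#'   database separately instead of jointly (default `FALSE`).
#' @return A data.frame of class `msea_enrichment` with one row per tested
#'   pathway, sorted by increasing raw p (ties broken by pathway id):
#'   columns `pathway_id`, `name`, `source`, `category`, `a`, `b`, `c`, `d`,
#'   `raw_p`, `holm_p`, `significant`, plus list-columns
#'   `aberrant_feature_ids` and `aberrant_metabolite_ids` (the pathway
#'   members annotated to aberrant features).
#' @export
run_msea <- function(calls, annotations, pathways, alpha = 0.05,
                     min_aberrant = 2L, drop_rt_inconsistent = FALSE,
                     holm_by_source = FALSE) {
  ann <- annotations
  if (drop_rt_inconsistent) {
    ann <- ann[ann$rt_status != "inconsistent", , drop = FALSE]
  }
  assoc <- map_to_pathways(ann, pathways)
  aberrant_ids <- calls$feature_id[calls$is_aberrant]
  n_total <- nrow(calls)
  n_aberrant <- length(aberrant_ids)

  assoc$aberrant <- assoc$feature_id %in% aberrant_ids
  spl <- split(assoc, assoc$pathway_id)
  a <- vapply(spl, function(x) sum(x$aberrant), integer(1))
  n_assoc <- vapply(spl, nrow, integer(1))
  tested_ids <- names(spl)[a >= min_aberrant]
  if (length(tested_ids) == 0L) return(empty_enrichment())

  spl <- spl[tested_ids]
  a <- a[tested_ids]
  b <- n_assoc[tested_ids] - a
  cc <- n_aberrant - a
  d <- n_total - n_aberrant - b
  raw_p <- fisher_one_sided(a, b, cc, d)

  idx <- match(tested_ids, pathways$pathway_id)
  src <- pathways$source[idx]
  holm_p <- rep(NA_real_, length(raw_p))
  if (holm_by_source) {
    for (s in unique(src)) {
      sel <- src == s
      holm_p[sel] <- holm_adjust(raw_p[sel])
    }
  } else {
    holm_p <- holm_adjust(raw_p)
  }

  # pathway members annotated to at least one aberrant feature
  ab_ann <- unique(ann[ann$feature_id %in% aberrant_ids,
                       c("feature_id", "metabolite_id")])
  ab_mets <- lapply(idx, function(i) {
    sort(unique(ab_ann$metabolite_id[
      ab_ann$metabolite_id %in% pathways$members[[i]]]))
  })
  ab_feats <- lapply(spl, function(x) sort(x$feature_id[x$aberrant]))

  out <- data.frame(pathway_id = tested_ids,
                    name = pathways$name[idx],
                    source = src,
                    category = pathways$category[idx],
                    a = unname(a), b = unname(b), c = unname(cc),
                    d = unname(d),
                    raw_p = unname(raw_p), holm_p = unname(holm_p),
                    significant = unname(holm_p < alpha),
                    stringsAsFactors = FALSE)
  out$aberrant_feature_ids <- unname(ab_feats)
  out$aberrant_metabolite_ids <- ab_mets
  out <- out[order(out$raw_p, out$pathway_id), ]
  rownames(out) <- NULL
  class(out) <- c("msea_enrichment", "data.frame")
  out
}

empty_enrichment <- function() {
  out <- data.frame(pathway_id = character(0), name = character(0),
                    source = character(0), category = character(0),
                    a = integer(0), b = integer(0), c = integer(0),
                    d = integer(0), raw_p = numeric(0), holm_p = numeric(0),
                    significant = logical(0), stringsAsFactors = FALSE)
  out$aberrant_feature_ids <- list()
  out$aberrant_metabolite_ids <- list()
  class(out) <- c("msea_enrichment", "data.frame")
  out
}

#' Write enrichment results to a tab-separated file
#'
#' List-columns are semicolon-joined.
#'
#' @param enrichment Output of [run_msea()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(enrichment, path) {
  out <- as.data.frame(enrichment[, c("pathway_id", "name", "source",
                                      "category", "a", "b", "c", "d",
                                      "raw_p", "holm_p", "significant")])
  out$aberrant_feature_ids <-
    vapply(enrichment$aberrant_feature_ids, paste, character(1),
           collapse = ";")
  out$aberrant_metabolite_ids <-
    vapply(enrichment$aberrant_metabolite_ids, paste, character(1),
           collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
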