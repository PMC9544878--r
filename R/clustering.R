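#' Cluster enriched pathways driven by the same aberrant metabolites
#'
#' Database pathways frequently share members, so one set of aberrant
#' metabolites can enrich many near-identical pathways. Enriched pathways
#' with 100% overlap of their aberrant metabolite sets are grouped: in
#' `exact` mode two pathways are linked when their sets are equal, in
#' `subset` mode when one set is entirely contained in the other. Clusters
#' are the connected components of the link graph, computed per source
#' database (metabolite ids do not cross databases). Clusters whose member
#' pathways were enriched by the identical set of aberrant *features* in the
#' other source database are cross-referenced in `cross_source_links`.
#'
#' @param enrichment Output of [run_msea()]; only significant pathways are
#'   clustered.
#' @param mode `"exact"` (default) or `"subset"` overlap rule.
#' @param link_on Link pathways on shared aberrant `"metabolites"` (default)
#'   or aberrant `"features"`.
#' @return A data.frame of class `msea_clusters`, sorted by `cluster_p`
#'   (representative's raw Fisher p; ties broken by representative id), with
#'   columns `cluster_id`, `source`, `representative_pathway_id`,
#'   `cluster_p`, `n_pathways` and list-columns `member_pathway_ids`,
#'   `aberrant_metabolite_union`, `aberrant_feature_union`,
#'   `cross_source_links`.
#' @export
cluster_pathways <- function(enrichment, mode = c("exact", "subset"),
                             link_on = c("metabolites", "features")) {
  mode <- match.arg(mode)
  link_on <- match.arg(link_on)
  enr <- enrichment[enrichment$significant, , drop = FALSE]
  if (nrow(enr) == 0L) return(empty_clusters())

  sets <- if (link_on == "metabolites") enr$aberrant_metabolite_ids else
    enr$aberrant_feature_ids

  rows <- list()
  for (s in unique(enr$source)) {
    sel <- which(enr$source == s)
    comp <- overlap_components(sets[sel], mode)
    for (k in seq_len(max(comp))) {
      members <- sel[comp == k]
      rep_id <- select_representative(enr[members, , drop = FALSE])
      rep_row <- members[match(rep_id, enr$pathway_id[members])]
      rows[[length(rows) + 1L]] <- list(
        source = s,
        representative_pathway_id = rep_id,
        cluster_p = enr$raw_p[rep_row],
        n_pathways = length(members),
        member_pathway_ids = sort(enr$pathway_id[members]),
        aberrant_metabolite_union =
          sort(unique(unlist(enr$aberrant_metabolite_ids[members]))),
        aberrant_feature_union =
          sort(unique(unlist(enr$aberrant_feature_ids[members]))))
    }
  }

  out <- data.frame(
    source = vapply(rows, `[[`, character(1), "source"),
    representative_pathway_id =
      vapply(rows, `[[`, character(1), "representative_pathway_id"),
    cluster_p = vapply(rows, `[[`, numeric(1), "cluster_p"),
    n_pathways = vapply(rows, `[[`, integer(1), "n_pathways"),
    stringsAsFactors = FALSE)
  out$member_pathway_ids <- lapply(rows, `[[`, "member_pathway_ids")
  out$aberrant_metabolite_union <-
    lapply(rows, `[[`, "aberrant_metabolite_union")
  out$aberrant_feature_union <- lapply(rows, `[[`, "aberrant_feature_union")
  out <- out[order(out$cluster_p, out$representative_pathway_id), ]
  rownames(out) <- NULL

  # number clusters within source by ascending p
  out$cluster_id <- character(nrow(out))
  for (s in unique(out$source)) {
    sel <- which(out$source == s)
    out$cluster_id[sel] <- sprintf("%s_C%02d", s, seq_along(sel))
  }

  # clusters of the other source enriched by the identical feature set
  keys <- vapply(out$aberrant_feature_union, paste, character(1),
                 collapse = "\r")
  out$cross_source_links <- lapply(seq_len(nrow(out)), function(i) {
    sort(out$cluster_id[keys == keys[i] & out$source != out$source[i]])
  })

  out <- out[, c("cluster_id", "source", "representative_pathway_id",
                 "cluster_p", "n_pathways", "member_pathway_ids",
                 "aberrant_metabolite_union", "aberrant_feature_union",
                 "cross_source_links")]
  class(out) <- c("msea_clusters", "data.frame")
  out
}

# connected components of the 100%-overlap link graph; returns a component
# index per element of `sets`
overlap_components <- function(sets, mode) {
  n <- length(sets)
  if (n == 1L) return(1L)
  edges <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      linked <- if (mode == "exact") {
        setequal(sets[[i]], sets[[j]])
      } else {
        all(sets[[i]] %in% sets[[j]]) || all(sets[[j]] %in% sets[[i]])
      }
      if (linked) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$membership)
}

#' Select the most descriptive pathway of a cluster
#'
#' Applies three sequential filters to the cluster members: (1) keep the
#' pathways associated with the highest number of aberrant features; (2) of
#' those, keep the pathway(s) with the lowest raw p-value; (3) when still
#' tied, prefer pathways categorised "Metabolic" (SMPDB) or "Metabolism"
#' (KEGG). Any remaining tie is broken by the lexicographically smallest
#' pathway id, making the choice deterministic and order-invariant.
#'
#' @param members Rows of an [run_msea()] result forming one cluster.
#' @return The representative pathway id.
#' @export
select_representative <- function(members) {
  stopifnot(nrow(members) > 0L)
  n_feat <- lengths(members$aberrant_feature_ids)
  members <- members[n_feat == max(n_feat), , drop = FALSE]
  members <- members[members$raw_p == min(members$raw_p), , drop = FALSE]
  preferred <- (members$source == "SMPDB" & members$category == "Metabolic") |
    (members$source == "KEGG" & members$category == "Metabolism")
  if (any(preferred)) members <- members[preferred, , drop = FALSE]
  min(members$pathway_id)
}

empty_clusters <- function() {
  out <- data.frame(cluster_id = character(0), source = character(0),
                    representative_pathway_id = character(0),
                    cluster_p = numeric(0), n_pathways = integer(0),
                    stringsAsFactors = FALSE)
  out$member_pathway_ids <- list()
  out$aberrant_metabolite_union <- list()
  out$aberrant_feature_union <- list()
  out$cross_source_links <- list()
  class(out) <- c("msea_clusters", "data.frame")
  out
}

#' Write pathway clusters to a tab-separated file
#'
#' List-columns are semicolon-joined.
#'
#' @param clusters Output of [cluster_pathways()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters <- function(clusters, path) {
  out <- as.data.frame(clusters[, c("cluster_id", "source",
                                    "representative_pathway_id",
                                    "cluster_p", "n_pathways")])
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  out$member_pathway_ids <- join(clusters$member_pathway_ids)
  out$aberrant_metabolite_union <- join(clusters$aberrant_metabolite_union)
  out$cross_source_links <- join(clusters$cross_source_links)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
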