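#' Load a metabolite reference table
#'
#' Reads a tab-separated metabolite table (columns `metabolite_id`, `name`,
#' `monoisotopic_mass`, `source`, optional `known_rt`) such as a flattened
#' export of HMDB or KEGG compound records. The returned table is sorted by
#' neutral monoisotopic mass so that mass-window queries can use binary
#' search, see [match_metabolites()].
#'
#' @param path Path to a tab-separated file with a header line.
#' @param source Optional source filter (`"HMDB"` or `"KEGG"`); when given,
#'   only records of that source are returned.
#' @return A `data.frame` with columns `metabolite_id`, `name`,
#'   `monoisotopic_mass` (Da, neutral), `source` and `known_rt` (minutes,
#'   `NA` when unknown), sorted by increasing mass.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("metabolite_id\tname\tmonoisotopic_mass\tsource\tknown_rt",
#'              "C00073\tL-Methionine\t149.051049\tKEGG\t"), tsv)
#' load_metabolites(tsv)
#' @export
load_metabolites <- function(path, source = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("metabolite_id", "name", "monoisotopic_mass", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("metabolite table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(df$known_rt)) df$known_rt <- NA_character_
  df$monoisotopic_mass <- suppressWarnings(as.numeric(df$monoisotopic_mass))
  df$known_rt <- suppressWarnings(as.numeric(df$known_rt))
  if (!is.null(source)) df <- df[df$source == source, , drop = FALSE]
  validate_metabolites(df)
  df <- df[order(df$monoisotopic_mass, df$metabolite_id),
           c("metabolite_id", "name", "monoisotopic_mass", "source",
             "known_rt")]
  rownames(df) <- NULL
  df
}

validate_metabolites <- function(df) {
  bad <- which(!is.finite(df$monoisotopic_mass) | df$monoisotopic_mass <= 0)
  if (length(bad) > 0L) {
    stop("non-positive or unparseable monoisotopic mass in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (id ", paste(utils::head(df$metabolite_id[bad], 5L),
                        collapse = ", "), ")")
  }
  key <- paste(df$source, df$metabolite_id)
  dup <- unique(df$metabolite_id[duplicated(key)])
  if (length(dup) > 0L) {
    stop("duplicated metabolite id within source: ",
         paste(dup, collapse = ", "))
  }
  invisible(df)
}

#' Load a pathway reference table
#'
#' Reads a tab-separated pathway table (columns `pathway_id`, `name`,
#' `source`, `category`, `member_metabolite_ids` with semicolon-joined
#' member ids), emulating SMPDB primary-pathway and KEGG human-pathway
#' exports. Member ids are expected to come from the matching metabolite
#' source (HMDB ids for SMPDB pathways, KEGG compound ids for KEGG
#' pathways); cross-database id linking is deliberately not attempted.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `data.frame` with a list-column `members` holding the member
#'   metabolite id character vectors.
#' @export
load_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("pathway_id", "name", "source", "category",
                "member_metabolite_ids")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("pathway table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  members <- strsplit(df$member_metabolite_ids, ";", fixed = TRUE)
  members <- lapply(members, function(x) unique(x[nzchar(x)]))
  df$members <- members
  pathway_table(df[, c("pathway_id", "name", "source", "category",
                       "members")])
}

#' Build a pathway table from in-memory pieces
#'
#' @param df A data.frame with columns `pathway_id`, `name`, `source`,
#'   `category` and a list-column `members`.
#' @return The validated pathway table.
#' @export
pathway_table <- function(df) {
  if (any(lengths(df$members) == 0L)) {
    stop("pathway with empty member set: ",
         paste(df$pathway_id[lengths(df$members) == 0L], collapse = ", "))
  }
  key <- paste(df$source, df$pathway_id)
  if (anyDuplicated(key)) {
    stop("duplicated pathway id within source: ",
         paste(unique(df$pathway_id[duplicated(key)]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Load a biomarker panel table
#'
#' Reads a tab-separated biomarker panel (columns `disorder`,
#' `biomarker_name`, `metabolite_id`, `source`). A biomarker compound may be
#' listed once per source database (an HMDB row and a KEGG row sharing the
#' same `biomarker_name`), since ids are not linked across databases.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param metabolites Optional metabolite table; when given, panel ids that do
#'   not resolve against it are reported with a warning.
#' @return A `data.frame` with one row per (disorder, metabolite id, source).
#' @export
load_biomarkers <- function(path, metabolites = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("disorder", "biomarker_name", "metabolite_id", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("biomarker table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(metabolites)) {
    unresolved <- setdiff(df$metabolite_id, metabolites$metabolite_id)
    if (length(unresolved) > 0L) {
      warning("biomarker id(s) not found in metabolite table: ",
              paste(unresolved, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df[, required]
}

#' Biomarker pathways of a disorder panel
#'
#' A pathway is a biomarker pathway for a disorder when it contains at least
#' one of the disorder's known biomarker metabolites among its members. The
#' result may be empty: several disorders have no biomarker that is a member
#' of any database pathway.
#'
#' @param biomarker_ids Character vector of biomarker metabolite ids (ids of
#'   both source databases may be mixed).
#' @param pathways A pathway table, see [load_pathways()].
#' @return Character vector of pathway ids whose member set intersects the
#'   panel, in pathway-table order.
#' @export
biomarker_pathways <- function(biomarker_ids, pathways) {
  if (length(biomarker_ids) == 0L) return(character(0))
  hit <- vapply(pathways$members,
                function(m) any(m %in% biomarker_ids), logical(1))
  pathways$pathway_id[hit]
}

#' Write reference tables back to tab-separated files
#'
#' Serialisation uses the canonical column order of the loaders, so that a
#' load/write cycle is content-identical.
#'
#' @param metabolites,pathways,panel Reference tables as returned by the
#'   loaders (any of them may be `NULL` to skip).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference_tables <- function(metabolites = NULL, pathways = NULL,
                                   panel = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(metabolites)) {
    p <- file.path(dir, "metabolites.tsv")
    out <- metabolites
    out$monoisotopic_mass <- format(out$monoisotopic_mass, digits = 15,
                                    trim = TRUE, scientific = FALSE)
    out$known_rt <- ifelse(is.na(out$known_rt), "",
                           format(out$known_rt, digits = 15, trim = TRUE))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(pathways)) {
    p <- file.path(dir, "pathways.tsv")
    out <- pathways[, c("pathway_id", "name", "source", "category")]
    out$member_metabolite_ids <-
      vapply(pathways$members, paste, character(1), collapse = ";")
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(panel)) {
    p <- file.path(dir, "biomarkers.tsv")
    utils::write.table(panel, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
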