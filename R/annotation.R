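#' Electrospray adducts used for neutral-mass estimation
#'
#' The four adduct species corrected for when estimating neutral masses:
#' protonated and sodiated ions in positive mode, deprotonated and
#' chlorinated ions in negative mode. Shifts are ion-mass conventions
#' including the electron mass, in Da; the neutral mass is recovered as
#' `mz - mass_shift`.
#'
#' @return A data.frame with columns `label`, `ion_mode`, `mass_shift`.
#' @export
adducts <- function() {
  data.frame(label = c("M+H", "M+Na", "M-H", "M+Cl"),
             ion_mode = c("positive", "positive", "negative", "negative"),
             mass_shift = c(1.007276, 22.989218, -1.007276, 34.969402),
             stringsAsFactors = FALSE)
}

#' Candidate neutral masses of a feature m/z
#'
#' One candidate per adduct compatible with the feature's ion mode;
#' candidates with non-positive neutral mass are dropped.
#'
#' @param mz Feature m/z (Th), positive scalar.
#' @param ion_mode `"positive"` or `"negative"`.
#' @return A data.frame with columns `adduct` and `neutral_mass` (Da).
#' @export
neutral_masses <- function(mz, ion_mode) {
  stopifnot(length(mz) == 1L, mz > 0)
  ad <- adducts()
  ad <- ad[ad$ion_mode == ion_mode, , drop = FALSE]
  out <- data.frame(adduct = ad$label,
                    neutral_mass = mz - ad$mass_shift,
                    stringsAsFactors = FALSE)
  out <- out[out$neutral_mass > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match a neutral mass against the metabolite reference
#'
#' Returns every metabolite whose monoisotopic mass lies within `tol_ppm`
#' parts per million of the observed neutral mass. The ppm denominator is
#' the database (theoretical) mass, i.e. a record matches when
#' `1e6 * |observed - db| / db <= tol_ppm`. Multiple hits are expected and
#' returned in full.
#'
#' @param neutral_mass Observed neutral mass (Da).
#' @param metabolites Metabolite table sorted by mass, see
#'   [load_metabolites()].
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @return A data.frame of matching records with their signed `ppm_error`.
#' @export
match_metabolites <- function(neutral_mass, metabolites, tol_ppm = 5) {
  stopifnot(length(neutral_mass) == 1L)
  hits <- ppm_window_hits(neutral_mass, metabolites, tol_ppm)
  out <- metabolites[hits$idx, c("metabolite_id", "name",
                                 "monoisotopic_mass", "source", "known_rt"),
                     drop = FALSE]
  out$ppm_error <- hits$ppm_error
  rownames(out) <- NULL
  out
}

# Binary-search window lookup: for each observed mass, the indices of
# database records within tol_ppm (denominator = database mass) and their
# signed ppm errors. Returns a list with parallel vectors `row` (index into
# `observed`), `idx` (row of `metabolites`), `ppm_error`.
ppm_window_hits <- function(observed, metabolites, tol_ppm) {
  masses <- metabolites$monoisotopic_mass
  if (is.unsorted(masses)) {
    stop("metabolite table must be sorted by mass; use load_metabolites()")
  }
  tol <- tol_ppm * 1e-6
  # widen the search window slightly, then filter on the exact criterion
  lo <- observed / (1 + tol) * (1 - 1e-12)
  hi <- observed / (1 - tol) * (1 + 1e-12)
  start <- findInterval(lo, masses, left.open = TRUE) + 1L
  end <- findInterval(hi, masses)
  cnt <- pmax(end - start + 1L, 0L)
  row <- rep.int(seq_along(observed), cnt)
  idx <- sequence(cnt, from = start)
  ppm <- 1e6 * (observed[row] - masses[idx]) / masses[idx]
  keep <- abs(ppm) <= tol_ppm
  list(row = row[keep], idx = idx[keep], ppm_error = ppm[keep])
}

#' Annotate every feature of a run with putative metabolites
#'
#' For each feature, neutral-mass candidates are formed under every adduct
#' compatible with the feature's ion mode and matched against the metabolite
#' reference within `tol_ppm`. When the metabolite has a known retention
#' time on the LC system, the annotation is flagged `consistent` when the
#' feature RT lies within `rt_tol` minutes of it and `inconsistent`
#' otherwise; `unknown` when no reference RT exists. RT-inconsistent
#' annotations are kept (downstream steps may drop them via a switch), since
#' the RT check is a plausibility filter rather than a hard constraint.
#'
#' @param run A [sample_run()] object.
#' @param metabolites Metabolite table, see [load_metabolites()].
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @param rt_tol Retention-time plausibility window in minutes (default 0.1).
#' @return A data.frame with one row per (feature, metabolite, adduct) link:
#'   `feature_id`, `metabolite_id`, `source`, `adduct`, `neutral_mass_obs`,
#'   `ppm_error`, `rt_status`.
#' @export
annotate_run <- function(run, metabolites, tol_ppm = 5, rt_tol = 0.1) {
  feats <- run$features
  ad <- adducts()
  cand <- merge(feats[, c("feature_id", "mz", "rt", "ion_mode")], ad,
                by = "ion_mode")
  cand$neutral_mass <- cand$mz - cand$mass_shift
  cand <- cand[cand$neutral_mass > 0, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_annotations())
  hits <- ppm_window_hits(cand$neutral_mass, metabolites, tol_ppm)
  if (length(hits$row) == 0L) return(empty_annotations())
  out <- data.frame(
    feature_id = cand$feature_id[hits$row],
    metabolite_id = metabolites$metabolite_id[hits$idx],
    source = metabolites$source[hits$idx],
    adduct = cand$label[hits$row],
    neutral_mass_obs = cand$neutral_mass[hits$row],
    ppm_error = hits$ppm_error,
    stringsAsFactors = FALSE)
  known_rt <- metabolites$known_rt[hits$idx]
  feat_rt <- cand$rt[hits$row]
  out$rt_status <- ifelse(is.na(known_rt), "unknown",
                          ifelse(abs(feat_rt - known_rt) <= rt_tol,
                                 "consistent", "inconsistent"))
  out <- out[order(out$feature_id, out$metabolite_id, out$adduct), ]
  rownames(out) <- NULL
  out
}

empty_annotations <- function() {
  data.frame(feature_id = character(0), metabolite_id = character(0),
             source = character(0), adduct = character(0),
             neutral_mass_obs = numeric(0), ppm_error = numeric(0),
             rt_status = character(0), stringsAsFactors = FALSE)
}

#' Map annotated features to pathways
#'
#' A feature is associated with a pathway when at least one of its
#' annotations' metabolite ids is a member of the pathway (within the same
#' source database). The association is binary per (feature, pathway):
#' annotation multiplicity (several adducts or several member metabolites)
#' does not count twice.
#'
#' @param annotations Output of [annotate_run()].
#' @param pathways Pathway table, see [load_pathways()].
#' @return A data.frame with columns `feature_id`, `pathway_id`, `source`,
#'   one row per association.
#' @export
map_to_pathways <- function(annotations, pathways) {
  long <- pathway_members_long(pathways)
  m <- merge(unique(annotations[, c("feature_id", "metabolite_id")]),
             long, by = "metabolite_id")
  out <- unique(m[, c("feature_id", "pathway_id", "source")])
  out <- out[order(out$pathway_id, out$feature_id), ]
  rownames(out) <- NULL
  out
}

# (pathway_id, source, metabolite_id) long form of the member list-column
pathway_members_long <- function(pathways) {
  n <- lengths(pathways$members)
  data.frame(pathway_id = rep.int(pathways$pathway_id, n),
             source = rep.int(pathways$source, n),
             metabolite_id = unlist(pathways$members, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Write annotations to a tab-separated file
#'
#' @param annotations Output of [annotate_run()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
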