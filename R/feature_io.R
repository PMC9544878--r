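#' Construct a sample run
#'
#' A sample run is one patient-versus-batch-controls comparison: an aligned
#' LC-MS feature table holding, per feature, the m/z, retention time, ion
#' mode, the patient intensity and the intensities of the batch controls.
#' Positive- and negative-mode features live in the same table and are
#' distinguished by `ion_mode`.
#'
#' @param features A data.frame with columns `feature_id`, `mz` (Th), `rt`
#'   (minutes), `ion_mode` (`"positive"`/`"negative"`) and
#'   `patient_intensity`.
#' @param controls A numeric matrix of control intensities, one row per
#'   feature (same order as `features`), at least two columns.
#' @param sample_id,disorder,batch_id Run metadata; `disorder` may be `NA`.
#' @return An object of class `sample_run`.
#' @export
sample_run <- function(features, controls, sample_id,
                       disorder = NA_character_, batch_id = NA_character_) {
  controls <- as.matrix(controls)
  storage.mode(controls) <- "double"
  if (nrow(features) != nrow(controls)) {
    stop("features and controls disagree on the number of features")
  }
  if (ncol(controls) < 2L) {
    stop("a run needs at least 2 control intensity columns, got ",
         ncol(controls))
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicated feature id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  }
  if (any(!is.finite(features$mz) | features$mz <= 0)) {
    stop("all feature m/z values must be positive")
  }
  if (any(!is.finite(features$rt) | features$rt < 0)) {
    stop("all feature retention times must be non-negative")
  }
  if (!all(features$ion_mode %in% c("positive", "negative"))) {
    stop("ion_mode must be 'positive' or 'negative'")
  }
  rownames(features) <- NULL
  structure(list(sample_id = sample_id, disorder = disorder,
                 batch_id = batch_id,
                 features = features[, c("feature_id", "mz", "rt",
                                         "ion_mode", "patient_intensity")],
                 controls = controls),
            class = "sample_run")
}

#' @export
print.sample_run <- function(x, ...) {
  cat("<sample_run> ", x$sample_id,
      if (!is.na(x$disorder)) paste0(" (", x$disorder, ")"), "\n",
      "  ", nrow(x$features), " features (",
      sum(x$features$ion_mode == "positive"), " positive / ",
      sum(x$features$ion_mode == "negative"), " negative), ",
      ncol(x$controls), " batch controls\n", sep = "")
  invisible(x)
}

#' Read an aligned feature table
#'
#' Expects a tab-separated table with header columns `feature_id`, `mz`,
#' `rt_min`, `ion_mode`, `patient` and at least two control columns named
#' `ctrl_*`. Rows whose intensities or coordinates cannot be parsed as
#' numbers are dropped with a message reporting the count.
#'
#' @param path Path to the tab-separated feature table.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param disorder,batch_id Optional run metadata.
#' @return A [sample_run()] object.
#' @export
read_feature_table <- function(path, sample_id = NULL,
                               disorder = NA_character_,
                               batch_id = NA_character_) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("feature_id", "mz", "rt_min", "ion_mode", "patient")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ctrl_cols <- grep("^ctrl_", names(df), value = TRUE)
  if (length(ctrl_cols) < 2L) {
    stop("feature table needs at least 2 control columns (ctrl_*), found ",
         length(ctrl_cols))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  mz <- num(df$mz); rt <- num(df$rt_min); patient <- num(df$patient)
  ctrl <- vapply(df[ctrl_cols], num, numeric(nrow(df)))
  ctrl <- matrix(ctrl, nrow = nrow(df),
                 dimnames = list(NULL, ctrl_cols))
  ok <- is.finite(mz) & is.finite(rt) & is.finite(patient) &
    rowSums(!is.finite(ctrl)) == 0L
  if (any(!ok)) {
    message("dropped ", sum(!ok), " row(s) with unparseable values from ",
            basename(path))
  }
  features <- data.frame(feature_id = df$feature_id[ok], mz = mz[ok],
                         rt = rt[ok], ion_mode = df$ion_mode[ok],
                         patient_intensity = patient[ok],
                         stringsAsFactors = FALSE)
  sample_run(features, ctrl[ok, , drop = FALSE], sample_id = sample_id,
             disorder = disorder, batch_id = batch_id)
}

#' Write a sample run as a feature table
#'
#' Numeric fields are written with full precision, so a write/read cycle
#' round-trips all values exactly.
#'
#' @param run A [sample_run()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(run, path) {
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  out <- data.frame(feature_id = run$features$feature_id,
                    mz = fmt(run$features$mz),
                    rt_min = fmt(run$features$rt),
                    ion_mode = run$features$ion_mode,
                    patient = fmt(run$features$patient_intensity),
                    stringsAsFactors = FALSE)
  ctrl <- run$controls
  colnames(ctrl) <- sprintf("ctrl_%d", seq_len(ncol(ctrl)))
  for (j in seq_len(ncol(ctrl))) out[[colnames(ctrl)[j]]] <- fmt(ctrl[, j])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
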