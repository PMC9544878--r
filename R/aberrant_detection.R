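#' Robust patient-versus-controls test for one feature
#'
#' Standardises the patient intensity against the batch controls with a
#' robust Z score, `(patient - median(controls)) / (1.4826 * MAD(controls))`,
#' and converts it to a two-sided normal p-value. The median/MAD location and
#' scale are preferred over mean/SD because a single outlying control among
#' ~10 would otherwise inflate the scale estimate. Degenerate spreads are
#' handled explicitly: when the MAD is zero the mean/SD pair is used; when
#' the controls are exactly constant the p-value is 1 if the patient equals
#' that constant and the smallest representable double (with a degeneracy
#' flag) otherwise.
#'
#' @param patient Patient intensity (scalar, or vector for many features).
#' @param controls Numeric vector of control intensities (one feature), or a
#'   matrix with one row per feature.
#' @return A data.frame with columns `statistic`, `raw_p`, `direction`
#'   (`"up"`/`"down"`) and `degenerate`.
#' @export
feature_test <- function(patient, controls) {
  if (is.matrix(controls)) {
    ctrl <- controls
  } else {
    ctrl <- matrix(controls, nrow = 1L)
  }
  n <- nrow(ctrl)
  if (length(patient) != n) {
    stop("patient intensities and control rows disagree in length")
  }
  if (ncol(ctrl) < 2L) stop("need at least 2 control intensities")
  med <- apply(ctrl, 1L, stats::median)
  scale_mad <- apply(ctrl, 1L, stats::mad) # includes the 1.4826 constant
  mean_c <- rowMeans(ctrl)
  sd_c <- apply(ctrl, 1L, stats::sd)

  statistic <- numeric(n)
  degenerate <- logical(n)

  use_mad <- scale_mad > 0
  statistic[use_mad] <- (patient[use_mad] - med[use_mad]) /
    scale_mad[use_mad]
  use_sd <- !use_mad & sd_c > 0
  statistic[use_sd] <- (patient[use_sd] - mean_c[use_sd]) / sd_c[use_sd]
  flat <- !use_mad & !use_sd
  if (any(flat)) {
    equal <- flat & patient == med
    off <- flat & patient != med
    statistic[equal] <- 0
    statistic[off] <- sign(patient[off] - med[off]) * Inf
    degenerate[off] <- TRUE
  }
  raw_p <- 2 * stats::pnorm(-abs(statistic))
  raw_p[degenerate] <- .Machine$double.xmin
  raw_p <- pmin(raw_p, 1)
  data.frame(statistic = statistic, raw_p = raw_p,
             direction = ifelse(statistic < 0, "down", "up"),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of a vector of raw p-values, positionally
#' aligned with the input.
#'
#' @param raw_ps Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, clipped at 1.
#' @export
benjamini_hochberg <- function(raw_ps) {
  check_probabilities(raw_ps)
  stats::p.adjust(raw_ps, method = "BH")
}

check_probabilities <- function(p) {
  if (length(p) > 0L && (any(!is.finite(p)) || any(p < 0) || any(p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  invisible(p)
}

#' Call aberrant features in a run
#'
#' Applies [feature_test()] to every feature of a run and corrects across
#' all features of the run jointly (both ion modes pooled) with
#' Benjamini-Hochberg. A feature is aberrant when its adjusted p-value is
#' below `alpha`.
#'
#' @param run A [sample_run()] object.
#' @param alpha Significance level for the BH-adjusted p (default 0.05).
#' @return A data.frame with one row per feature: `feature_id`,
#'   `patient_intensity`, `statistic`, `raw_p`, `adjusted_p`, `is_aberrant`,
#'   `direction`, `degenerate`.
#' @export
call_aberrant <- function(run, alpha = 0.05) {
  feats <- run$features
  if (nrow(feats) == 0L) {
    return(data.frame(feature_id = character(0),
                      patient_intensity = numeric(0),
                      statistic = numeric(0), raw_p = numeric(0),
                      adjusted_p = numeric(0), is_aberrant = logical(0),
                      direction = character(0), degenerate = logical(0),
                      stringsAsFactors = FALSE))
  }
  tst <- feature_test(feats$patient_intensity, run$controls)
  adjusted <- benjamini_hochberg(tst$raw_p)
  data.frame(feature_id = feats$feature_id,
             patient_intensity = feats$patient_intensity,
             statistic = tst$statistic, raw_p = tst$raw_p,
             adjusted_p = adjusted, is_aberrant = adjusted < alpha,
             direction = tst$direction, degenerate = tst$degenerate,
             stringsAsFactors = FALSE)
}

#' Write aberrant calls to a tab-separated file
#'
#' @param calls Output of [call_aberrant()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_aberrant_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
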