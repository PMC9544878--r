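# Independent oracles, hand-coded from textbook definitions. These must not
# share code paths with the package implementation.

# step-up FDR adjustment: q_(k) = min_{j >= k} min(1, m/j * p_(j))
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, m / seq_len(m) * ps)
  for (k in seq.int(m - 1L, 1L)) if (m > 1L) q[k] <- min(q[k], q[k + 1L])
  out <- numeric(m)
  out[o] <- q
  out
}

# step-down FWER adjustment: q_(k) = max_{j <= k} min(1, (m-j+1) * p_(j))
holm_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, (m - seq_len(m) + 1) * ps)
  q <- cummax(q)
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force hypergeometric upper tail P(X >= a) by summing the point
# probabilities choose(m, k) choose(n, K - k) / choose(N, K) in log space
fisher_tail_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  if (a > min(m, K)) return(0)
  if (a <= max(0L, K - n)) return(1)
  ks <- seq.int(a, min(m, K))
  terms <- lchoose(m, ks) + lchoose(n, K - ks) - lchoose(m + n, K)
  sum(exp(terms))
}

# pairwise-link + union-find connected components
components_oracle <- function(sets, mode = c("exact", "subset")) {
  mode <- match.arg(mode)
  n <- length(sets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      linked <- if (mode == "exact") {
        setequal(sets[[i]], sets[[j]])
      } else {
        all(sets[[i]] %in% sets[[j]]) || all(sets[[j]] %in% sets[[i]])
      }
      if (linked) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# AUC by the explicit Mann-Whitney U count (pairwise comparisons)
auc_oracle <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  wins <- 0
  for (x in pos) wins <- wins + sum(x > neg) + 0.5 * sum(x == neg)
  wins / (length(pos) * length(neg))
}

# small helpers to build in-memory fixtures -------------------------------

make_metabolites <- function(ids, masses, source = "HMDB", known_rt = NA) {
  df <- data.frame(metabolite_id = ids,
                   name = paste("met", ids),
                   monoisotopic_mass = masses,
                   source = source,
                   known_rt = rep_len(known_rt, length(ids)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$monoisotopic_mass), ]
  rownames(df) <- NULL
  df
}

make_pathways <- function(ids, members, source = "SMPDB",
                          category = "Metabolic") {
  df <- data.frame(pathway_id = ids, name = paste("pw", ids),
                   source = rep_len(source, length(ids)),
                   category = rep_len(category, length(ids)),
                   stringsAsFactors = FALSE)
  df$members <- members
  pathway_table(df)
}

# a run whose aberrance calls are fully controlled: null features have the
# patient equal to the control median, aberrant features a huge patient
# intensity. Controls have non-degenerate spread.
make_controlled_run <- function(feature_ids, mz, aberrant,
                                patient_intensity = NULL,
                                ion_mode = "positive", rt = 5) {
  n <- length(feature_ids)
  controls <- matrix(rep(c(95, 98, 100, 102, 105), each = n), nrow = n,
                     ncol = 5L)
  patient <- ifelse(aberrant, 1e6, 100)
  if (!is.null(patient_intensity)) {
    patient[aberrant] <- patient_intensity[aberrant]
  }
  features <- data.frame(feature_id = feature_ids, mz = mz,
                         rt = rep_len(rt, n),
                         ion_mode = rep_len(ion_mode, n),
                         patient_intensity = patient,
                         stringsAsFactors = FALSE)
  sample_run(features, controls, sample_id = "FIX", disorder = "DX",
             batch_id = "B1")
}
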