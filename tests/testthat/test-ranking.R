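# fixture: controlled intensities, one-to-one annotations
ranking_fixture <- function() {
  db <- make_metabolites(sprintf("m%d", 1:6), c(100, 150, 200, 250, 300,
                                                350))
  ids <- sprintf("F%d", 1:6)
  mz <- db$monoisotopic_mass[match(sprintf("m%d", 1:6),
                                   db$metabolite_id)] + 1.007276
  run <- make_controlled_run(ids, mz, aberrant = rep(TRUE, 6),
                             patient_intensity = c(9e5, 8e5, 7e5, 6e5,
                                                   5e5, 4e5))
  calls <- call_aberrant(run)
  ann <- annotate_run(run, db)
  list(run = run, calls = calls, ann = ann, db = db)
}

test_that("feature rank is the min intensity-sorted row index", {
  fix <- ranking_fixture()
  # biomarker on the top-intensity feature -> rank 1
  fr <- feature_rank(fix$calls, fix$ann, "m1")
  expect_equal(fr$rank, 1L)
  expect_equal(attr(fr, "universe"), 6L)
  # biomarker with two features at positions 4 and... min rule
  fr2 <- feature_rank(fix$calls, fix$ann, c("m4", "m2"))
  expect_equal(fr2$rank, c(4L, 2L))
  # unassociated biomarker -> NA
  expect_true(is.na(feature_rank(fix$calls, fix$ann, "zz")$rank))

  # brute-force sort-and-scan oracle on a seeded simulated run
  spec <- simulation_spec(spiked_pathways = list(spike(1L, 15L, 20)),
                          seed = 3L)
  refs <- simulate_reference(spec)
  sim <- simulate_run(spec, refs)
  calls <- call_aberrant(sim$run)
  ann <- annotate_run(sim$run, refs$metabolites)
  bio <- refs$panel$metabolite_id[1L]
  got <- feature_rank(calls, ann, bio)
  pairs <- unique(ann[ann$feature_id %in%
                        calls$feature_id[calls$is_aberrant],
                      c("feature_id", "metabolite_id")])
  pairs$int <- calls$patient_intensity[match(pairs$feature_id,
                                             calls$feature_id)]
  pairs <- pairs[order(-pairs$int, pairs$feature_id, pairs$metabolite_id), ]
  oracle <- min(which(pairs$metabolite_id == bio))
  expect_equal(got$rank, oracle)
})

test_that("pathway-sorted rank expands pathways by p then intensity", {
  fix <- ranking_fixture()
  # two "enriched pathways": first {m2,m3} (smaller p), second {m1,m4}
  enr <- data.frame(pathway_id = c("PA", "PB"), name = c("PA", "PB"),
                    source = "SMPDB", category = "Metabolic",
                    a = c(2L, 2L), b = 0L, c = 2L, d = 10L,
                    raw_p = c(1e-6, 1e-3), holm_p = c(2e-6, 1e-3),
                    significant = TRUE, stringsAsFactors = FALSE)
  enr$aberrant_feature_ids <- list(c("F2", "F3"), c("F1", "F4"))
  enr$aberrant_metabolite_ids <- list(c("m2", "m3"), c("m1", "m4"))
  class(enr) <- c("msea_enrichment", "data.frame")

  # expansion: PA pairs (m2,m3 by intensity) then PB pairs (m1,m4)
  pr <- pathway_sorted_rank(fix$calls, fix$ann, enr, c("m1", "m2", "m4"))
  expect_equal(pr$rank, c(3L, 1L, 4L))
  expect_equal(attr(pr, "universe"), 4L)
  # biomarker only in the 2nd pathway, first has 2 pairs -> rank 3
  expect_equal(pathway_sorted_rank(fix$calls, fix$ann, enr, "m1")$rank, 3L)
  # biomarker in no enriched pathway -> NA
  expect_true(is.na(pathway_sorted_rank(fix$calls, fix$ann, enr,
                                        "m6")$rank))
})

test_that("pathway and cluster biomarker ranks sort by p with id ties", {
  pws <- make_pathways(c("PA", "PB", "PC"),
                       list(c("m2", "m3"), c("m1", "m4"), c("m5")))
  enr <- data.frame(pathway_id = c("PA", "PB", "PC"),
                    name = c("PA", "PB", "PC"),
                    source = "SMPDB", category = "Metabolic",
                    a = 2L, b = 0L, c = 2L, d = 10L,
                    raw_p = c(1e-6, 1e-3, 1e-5), holm_p = 1e-3,
                    significant = TRUE, stringsAsFactors = FALSE)
  enr$aberrant_feature_ids <- list(c("F2", "F3"), c("F1", "F4"), "F5")
  enr$aberrant_metabolite_ids <- list(c("m2", "m3"), c("m1", "m4"), "m5")
  class(enr) <- c("msea_enrichment", "data.frame")

  # sorted by p: PA, PC, PB; biomarker m1 sits in PB -> rank 3
  expect_equal(pathway_biomarker_rank(enr, pws, "m1"), 3L)
  expect_equal(pathway_biomarker_rank(enr, pws, "m5"), 2L)
  expect_equal(pathway_biomarker_rank(enr, pws, c("m3", "m5")), 1L)
  expect_true(is.na(pathway_biomarker_rank(enr, pws, "zz")))

  cl <- cluster_pathways(enr)
  # three singleton clusters ordered PA, PC, PB
  expect_equal(pathway_biomarker_rank(cl, pws, "m1"), 3L)
  expect_equal(pathway_biomarker_rank(cl, pws, "m5"), 2L)
})

test_that("the permutation test matches exact enumeration and extremes", {
  # all ranks 1 over 20 large-universe runs: p at the permutation floor
  p <- rank_permutation_test(rep(1L, 20), rep(1000L, 20),
                             n_perm = 1000L, seed = 1L)
  expect_equal(p, 1 / 1001)

  # single run, universe 10, one biomarker pair: null min-rank is uniform
  # on 1..10, so P(null <= r) = r/10 exactly
  for (r in c(2L, 5L, 9L)) {
    p <- rank_permutation_test(r, 10L, n_perm = 20000L, seed = 2L)
    expect_equal(p, r / 10, tolerance = 0.05)
  }

  # observed ranks drawn from the null itself give p ~ 0.5
  set.seed(9)
  ps <- vapply(1:20, function(i) {
    obs <- vapply(1:15, function(j) min(sample.int(200L, 3L)), integer(1))
    rank_permutation_test(obs, rep(200L, 15), n_biomarker_pairs = 3L,
                          n_perm = 2000L, seed = i)
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("score ROC equals the Mann-Whitney oracle and its anchors", {
  fix <- ranking_fixture()
  # m1 has the single highest intensity -> perfect separation
  expect_equal(score_roc(fix$run, fix$calls, fix$ann, "m1", "intensity"),
               1.0)
  # constant score -> AUC 0.5 (all ties)
  const_run <- fix$run
  const_calls <- fix$calls
  const_calls$patient_intensity <- 500
  const_ann <- fix$ann
  expect_equal(score_roc(const_run, const_calls, const_ann, "m1",
                         "intensity"), 0.5)

  # 50-pair fixture against the explicit pairwise U count
  set.seed(17)
  db <- make_metabolites(sprintf("m%02d", 1:50),
                         seq(100, 900, length.out = 50))
  ids <- sprintf("F%02d", 1:50)
  mz <- db$monoisotopic_mass[match(sprintf("m%02d", 1:50),
                                   db$metabolite_id)] + 1.007276
  ints <- round(runif(50, 1e4, 1e6))
  run <- make_controlled_run(ids, mz, aberrant = rep(TRUE, 50),
                             patient_intensity = ints)
  calls <- call_aberrant(run)
  ann <- annotate_run(run, db)
  bio <- sprintf("m%02d", sample(1:50, 8))
  for (sc in c("intensity", "abs_fold_change", "p_value")) {
    got <- score_roc(run, calls, ann, bio, sc)
    pairs <- aberrant_pairs(calls, ann)
    s <- switch(sc,
      intensity = pairs$patient_intensity,
      abs_fold_change = {
        med <- apply(run$controls, 1, median)
        fc <- pairs$patient_intensity /
          med[match(pairs$feature_id, run$features$feature_id)]
        pmax(fc, 1 / fc)
      },
      p_value = -calls$raw_p[match(pairs$feature_id, calls$feature_id)])
    expect_equal(got, auc_oracle(s, pairs$metabolite_id %in% bio),
                 tolerance = 1e-12)
  }
})

test_that("pathway context prioritises biomarkers over raw intensity", {
  # spike-in with high-intensity orphan confounders outside all pathways:
  # the pathway-sorted rank beats (or ties) the intensity rank
  n_better <- 0L; n_runs <- 25L
  spec <- simulation_spec(n_orphan_metabolites = 30L,
                          spiked_orphans = 30L,
                          orphan_fold_change = 100,
                          spiked_pathways = list(spike(1L, 15L, 20)),
                          seed = 8L)
  refs <- simulate_reference(spec)
  bio <- refs$panel$metabolite_id[1L]
  fr_all <- pr_all <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    sim <- simulate_run(spec, refs, seed = 500L + i)
    calls <- call_aberrant(sim$run)
    ann <- annotate_run(sim$run, refs$metabolites)
    enr <- run_msea(calls, ann, refs$pathways)
    fr_all[i] <- feature_rank(calls, ann, bio)$rank
    pr <- pathway_sorted_rank(calls, ann, enr, bio)
    # worst case when the biomarker pathway is not enriched
    pr_all[i] <- if (is.na(pr$rank)) attr(pr, "universe") + 1L else pr$rank
  }
  expect_lte(median(pr_all), median(fr_all))
})
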