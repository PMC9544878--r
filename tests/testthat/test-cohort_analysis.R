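fake_cohort_enr <- function(sig_sets) {
  # sig_sets: list of character vectors of significant pathway ids per run
  lapply(sig_sets, function(ids) {
    n <- length(ids)
    out <- data.frame(pathway_id = ids, name = ids, source = "SMPDB",
                      category = "Metabolic", a = 2L, b = 0L, c = 2L,
                      d = 10L, raw_p = 1e-5, holm_p = 1e-4,
                      significant = rep(TRUE, n),
                      stringsAsFactors = FALSE)
    out$aberrant_feature_ids <- rep(list("F1"), n)
    out$aberrant_metabolite_ids <- rep(list("m1"), n)
    class(out) <- c("msea_enrichment", "data.frame")
    out
  })
}

test_that("pathway sharing counts disorders and runs", {
  pws <- make_pathways(c("P1", "P2", "P3"),
                       list("m1", "m9", c("m2", "m3")))
  panel <- data.frame(disorder = "DX", biomarker_name = "b",
                      metabolite_id = "m1", source = "HMDB",
                      stringsAsFactors = FALSE)
  enr <- fake_cohort_enr(list(c("P1", "P2"), "P2", "P2"))
  sharing <- pathway_sharing(enr, c("DA", "DA", "DB"), pws, panel)
  p1 <- sharing[sharing$pathway_id == "P1", ]
  p2 <- sharing[sharing$pathway_id == "P2", ]
  expect_equal(p1$n_disorders_shared, 1L)
  expect_equal(p1$n_runs_shared, 1L)
  expect_equal(p2$n_disorders_shared, 2L)
  expect_equal(p2$n_runs_shared, 3L)
  expect_true(p1$is_biomarker_pathway_for_any)
  expect_false(p2$is_biomarker_pathway_for_any)

  # sharing counts sum to total significant (pathway, run) pairs
  expect_equal(sum(sharing$n_runs_shared),
               sum(vapply(enr, function(e) sum(e$significant),
                          integer(1))))
})

test_that("a planted cohort-wide pathway tops the sharing table", {
  spec <- simulation_spec(n_metabolites = 80L, n_pathways = 8L,
                          pathway_size_range = c(10L, 10L),
                          n_features_decoy = 300L, seed = 31L)
  refs <- simulate_reference(spec)
  # 10 runs over 5 disorders, every run spiking pathway 2 ("drug"
  # confounder) plus a disorder-specific pathway
  enrs <- list(); disorders <- character(0)
  for (i in 1:10) {
    d <- ((i - 1) %% 5) + 3L # disorder pathways 3..7
    sp <- simulation_spec(n_metabolites = 80L, n_pathways = 8L,
                          pathway_size_range = c(10L, 10L),
                          n_features_decoy = 300L, seed = 31L,
                          spiked_pathways = list(spike(2L, 8L, 30),
                                                 spike(d, 8L, 30)))
    sim <- simulate_run(sp, refs, seed = 700L + i)
    enrs[[i]] <- run_msea(call_aberrant(sim$run),
                          annotate_run(sim$run, refs$metabolites),
                          refs$pathways)
    disorders <- c(disorders, sprintf("D_%s", refs$pathways$pathway_id[d]))
  }
  panel <- refs$panel[refs$panel$disorder %in% disorders, ]
  sharing <- pathway_sharing(enrs, disorders, refs$pathways, panel)
  expect_equal(sharing$pathway_id[1L], refs$pathways$pathway_id[2L])
  expect_equal(sharing$n_disorders_shared[1L], 5L)
  expect_false(sharing$is_biomarker_pathway_for_any[1L])
  # the confounder is less disorder-specific than the biomarker pathways
  p <- specificity_test(sharing)
  expect_lt(p, 0.5)
})

test_that("the specificity Wilcoxon behaves at its anchors", {
  mk <- function(shared_bio, shared_other) {
    data.frame(pathway_id = sprintf("P%02d", seq_len(length(shared_bio) +
                                                       length(shared_other))),
               source = "SMPDB",
               n_disorders_shared = c(shared_bio, shared_other),
               n_runs_shared = c(shared_bio, shared_other),
               is_biomarker_pathway_for_any =
                 rep(c(TRUE, FALSE), c(length(shared_bio),
                                       length(shared_other))),
               stringsAsFactors = FALSE)
  }
  # identical distributions: p = 1 on the exact small-sample computation
  expect_equal(specificity_test(mk(c(1, 2, 3), c(1, 2, 3))), 1,
               tolerance = 0.05)
  # full separation with n = 5 per group: significant
  expect_lt(specificity_test(mk(rep(1, 5), rep(10, 5))), 0.05)
  # random labels give roughly uniform p
  set.seed(4)
  ps <- vapply(1:200, function(i) {
    specificity_test(mk(sample(1:13, 6, replace = TRUE),
                        sample(1:13, 20, replace = TRUE)))
  }, numeric(1))
  expect_gt(mean(ps < 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("novel candidates are aberrant members minus known biomarkers", {
  pws <- make_pathways("P1", list(c("A", "B", "C")))
  enr <- data.frame(pathway_id = "P1", name = "P1", source = "SMPDB",
                    category = "Metabolic", a = 2L, b = 0L, c = 1L,
                    d = 10L, raw_p = 1e-5, holm_p = 1e-4,
                    significant = TRUE, stringsAsFactors = FALSE)
  enr$aberrant_feature_ids <- list(c("F1", "F2"))
  enr$aberrant_metabolite_ids <- list(c("A", "B"))
  class(enr) <- c("msea_enrichment", "data.frame")
  ann <- data.frame(feature_id = c("F1", "F2"),
                    metabolite_id = c("A", "B"), source = "HMDB",
                    adduct = "M+H", neutral_mass_obs = 1, ppm_error = 0,
                    rt_status = c("unknown", "inconsistent"),
                    stringsAsFactors = FALSE)
  cand <- novel_biomarker_candidates(enr, ann, pws, "A")
  expect_equal(cand$metabolite_id, "B")
  expect_true(cand$rt_inconsistent) # only support is RT-inconsistent
  expect_false("A" %in% cand$metabolite_id)

  # aberrant subset of biomarkers -> empty candidate list
  cand2 <- novel_biomarker_candidates(enr, ann, pws, c("A", "B"))
  expect_equal(nrow(cand2), 0L)

  # planted perturbed non-biomarker member is recovered end to end
  spec <- simulation_spec(spiked_pathways = list(spike(1L, 15L, 20)),
                          seed = 6L)
  refs <- simulate_reference(spec)
  sim <- simulate_run(spec, refs)
  bio <- refs$panel$metabolite_id[1L] # first member, perturbed
  res <- msea_pipeline(sim$run, refs$metabolites, refs$pathways,
                       biomarker_ids = bio)
  perturbed <- refs$pathways$members[[1L]][2:15]
  expect_gt(length(intersect(res$candidates$metabolite_id, perturbed)), 0L)
  expect_false(bio %in% res$candidates$metabolite_id)
})
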