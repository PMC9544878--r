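---
title: "Pathway enrichment for untargeted metabolomics screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway enrichment for untargeted metabolomics screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msea)
```

## The problem

Untargeted LC-MS metabolomics of a patient plasma sample yields thousands of
aligned features (m/z, retention time, ion mode, intensity), of which a few
hundred typically deviate from the batch controls. Manual review of that list
is infeasible, and genuinely diagnostic metabolites can be buried under diet
and medication effects. The package places aberrant features in pathway
context: when an inherited enzymatic defect perturbs a biochemical pathway,
several of its substrates and products shift together, and a set-enrichment
statistic on pathway membership can surface that coordinated signal even when
no single feature stands out.

The unit of analysis is one *run*: a single patient against the roughly ten
control samples of its analytical batch. All statistics are within-run;
cohort-level functions only aggregate per-run results.

## Model and procedure

**Aberrant feature detection.** Each feature's patient intensity is
standardised against the batch controls with a robust Z score,

$$z = \frac{x_{\text{patient}} - \mathrm{median}(x_{\text{ctrl}})}
          {1.4826 \cdot \mathrm{MAD}(x_{\text{ctrl}})},$$

converted to a two-sided normal p-value and corrected across all features of
the run (both ion modes pooled) by Benjamini–Hochberg; a feature is aberrant
at adjusted $p < \alpha$ (default $\alpha = 0.05$). The median/MAD pair is
used because a single outlying control among ten would otherwise inflate a
mean/SD scale. When the MAD is zero the mean/SD pair substitutes; exactly
constant controls yield $p = 1$ when the patient matches the constant and a
flagged floor p-value otherwise.

*Calibration caveat.* With $k$ controls the statistic is approximately
$t$-like with far fewer than $k$ degrees of freedom (scale-estimation noise),
so the normal p-values are liberal at $k \approx 10$: more features are
called aberrant than a nominal FDR of 5% suggests. This mirrors practice —
screening pipelines deliberately over-call at the feature level — and does
not distort downstream pathway inference, because the Fisher test below
conditions on the realised number of aberrant features. The FDR property is
verified in the test suite in the statistic's calibration domain (hundreds of
controls); at ten controls the feature list should be read as a candidate
set, not an error-controlled discovery set.

**Annotation.** Neutral masses are estimated from each feature's m/z under
the adducts compatible with its ion mode — M+H (+1.007276 Da) and M+Na
(+22.989218 Da) in positive mode, M−H (−1.007276 Da) and M+Cl
(+34.969402 Da) in negative mode — and matched against the metabolite
reference within 5 ppm. The ppm denominator is the database (theoretical)
mass, so the acceptance window around an observed mass is
$[m_{\text{obs}}/(1+\text{tol}),\, m_{\text{obs}}/(1-\text{tol})]$, which is
marginally asymmetric; the boundary is inclusive. Multiple annotations per
feature are expected and kept. When a metabolite's retention time is known on
the LC system, annotations further than 0.1 min from it are flagged
`inconsistent` but retained: the RT check is a post-hoc plausibility filter,
and a switch (`drop_rt_inconsistent`) excludes flagged annotations from
enrichment for users who prefer a hard filter. In-source fragments,
isotopologues and multimers are not modelled.

**Enrichment.** For each pathway the run's features are cross-classified as
aberrant/non-aberrant versus pathway-associated/unassociated; association is
binary per (feature, pathway) regardless of how many annotations support it.
The background universe is *all* detected features of the run, associated or
not, both ion modes. The one-sided Fisher exact p is the hypergeometric upper
tail $P(X \ge a)$ at the table's margins. Only pathways associated with more
than one aberrant feature are tested, and skipped pathways do not enter the
Bonferroni–Holm denominator; the Holm family pools the tested pathways of
both source databases (a per-source switch exists). Pathways with Holm
$p < 0.05$ are reported as enriched. Whether the original background should
exclude never-annotatable features is unknowable from the available
description; the full feature table was chosen because the contrast is
explicitly between pathway-associated and pathway-unassociated features.

**Redundancy clustering.** Enriched pathways driven by the same aberrant
metabolites are grouped. Two link rules are exposed: `exact` (identical
aberrant metabolite sets; the default, matching how redundant enrichment is
described in practice) and `subset` (one set fully contained in the other,
the literal reading of "100% overlap in either direction"). Clusters are
connected components of the link graph, computed separately per source
database since metabolite ids do not map across databases; clusters of the
two sources enriched by the identical aberrant *feature* set are
cross-referenced instead. The representative pathway is chosen by three
sequential filters — most associated aberrant features, lowest p, then a
preference for the "Metabolic" (SMPDB) / "Metabolism" (KEGG) category — with
a lexicographic id tie-break making the choice deterministic. The cluster's
p-value is its representative's raw Fisher p; no combined statistic is
defined.

**Biomarker ranking.** The ranking universe is the set of unique aberrant
(feature, metabolite) pairs, deduplicated over adduct routes. Three ranks
are reported per biomarker metabolite, all as 1-based row indices with the
minimum taken over the biomarker's pairs: the *feature rank* (pairs sorted
by patient intensity, descending), and the *pathway / cluster feature ranks*
(pairs listed pathway-by-pathway in ascending p order, sorted by intensity
within a pathway, first occurrence counting). Separately, the *pathway (or
cluster) biomarker rank* is the position of the first biomarker-containing
pathway (cluster) in the p-sorted list. Patient intensity is used as the
within-pathway score because, as a standalone classifier of biomarker
status, it outperforms absolute fold change and the feature p-value
(`score_roc()` reproduces this comparison on synthetic data). Significance
of observed ranks across runs is assessed by permutation: under the null
each run's biomarker pairs occupy uniformly random distinct positions in
that run's universe, the statistic is the median across runs, and
$p = (1 + \#\{\text{null} \le \text{obs}\})/(n_{\text{perm}} + 1)$. Note the
null is *within-universe*: it measures whether biomarkers sit high in a
given list, not the benefit of shrinking the list — so it is informative
for the feature-level rank, while the value of pathway sorting shows up as
the smaller universe and smaller median rank.

**Cohort analyses.** Across runs, `pathway_sharing()` counts the distinct
disorders (and runs) in which each pathway is enriched; pathways recurring
across many unrelated disorders are candidate diet/medication confounders.
`specificity_test()` compares the sharing counts of biomarker-containing
versus other pathways with a two-sided Wilcoxon rank-sum test (exact for
small untied samples, normal approximation with tie correction otherwise,
as implemented in `stats::wilcox.test`; sharing counts are heavily tied).
`novel_biomarker_candidates()` lists, per enriched biomarker pathway, the
member metabolites annotated to aberrant features minus the known
biomarkers, flagging candidates whose only support is RT-inconsistent.

## The synthetic cohort generator

No patient data ships with the package; `simulate_reference()` and
`simulate_run()` generate ground-truth-labelled inputs that emulate the
structure of a screening batch.

* **Masses.** Metabolite masses are uniform on 50–1000 Da with a guaranteed
  pairwise gap (default 0.02 Da, over twice the 5 ppm tolerance at
  1000 Da), so annotation is unambiguous by design; collisions can be
  enabled for multi-annotation tests.
* **Features.** Each metabolite emits a feature per adduct with
  probabilities 0.9 / 0.3 / 0.7 / 0.2 for M+H / M+Na / M−H / M+Cl (at least
  one feature is forced, via M+H). The ppm error is applied to the neutral
  mass, `mz = m(1 + e) + shift` with `e ~ N(0, sd)`, so the observed
  neutral-mass ppm error equals `e` exactly and the analytic recovery
  probability at tolerance `t` is exactly `P(|e| <= t)` — the bound the
  acceptance tests check. Default error SD is 2 ppm.
* **Intensities.** Control intensities are log-normal per feature
  (multiplicative MS noise), with `meanlog` uniform on `log(1e4)`–`log(1e6)`
  and `sdlog` uniform on 0.2–0.8; the patient value is an independent draw
  times the fold change of the generating metabolite (1 for unperturbed).
  Ten controls per batch is the default, matching a typical analytical
  batch.
* **Perturbation designs.** The study condition used throughout the tests
  and the acceptance script is one pathway of 20 members with 15 perturbed
  at 20-fold against 1500 decoy features; the confounder design adds 30
  orphan metabolites (members of no pathway) perturbed at 100-fold, which
  depress intensity-based biomarker ranks without touching pathway-sorted
  ranks. Decoy feature masses are rejected until every mode-compatible
  adduct reading stays at least 20 ppm from all reference metabolites, so
  decoys never annotate.
* **Determinism.** All draws derive from the spec seed (reference tables)
  and a per-run seed; identical seeds give byte-identical outputs.

What the generator does *not* emulate: chromatographic peak shape,
intensity drift and batch effects, correlated features from in-source
fragmentation, technical duplicates, or realistic pathway size/overlap
distributions. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean generative model, not performance on
real screening data.

## Numerical and design choices

* Fisher p-values come from the hypergeometric upper tail
  (`stats::phyper`); the test suite checks them against an independent
  log-space tail sum on every 2×2 table with total at most 60.
* BH and Holm adjustments delegate to `stats::p.adjust` behind stable
  module functions that validate inputs; tests compare them elementwise to
  hand-coded step-up/step-down formulas.
* Ties are broken deterministically everywhere: by feature id then
  metabolite id in intensity sorts, by pathway id in p sorts, and
  lexicographically in representative selection.
* Degenerate inputs (zero-spread controls, empty feature tables, features
  matching nothing, biomarkers without aberrant features) return defined
  values (`p = 1` or floor p with a flag, empty tables, `NA` ranks) rather
  than errors.
* Intensities of zero are treated as observed values; no imputation is
  performed.
* Technical injection duplicates are assumed merged upstream; one table is
  one patient-versus-controls comparison.
* Problem sizes in the tests (2000-feature runs, 100 spike-in seeds, 200
  null seeds, 10 000 permutations) were chosen as the smallest designs
  that leave the Monte-Carlo error well inside the asserted bounds.

## Known limitations

* Feature-level p-values are liberal at typical control counts (see the
  calibration caveat above); pathway-level inference is unaffected.
* Pathway membership quality bounds everything downstream: disorders whose
  biomarkers appear in no database pathway are invisible to enrichment.
* The enrichment statistic ignores pathway topology and annotation
  multiplicity beyond binary association.
* Cross-database identifier linking is deliberately not attempted; a
  biomarker should be listed once per source database.
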