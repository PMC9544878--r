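#' Specification of a synthetic screening cohort
#'
#' Describes the reference databases and the single-patient-versus-controls
#' runs that the generator emulates: metabolites with well-spaced
#' monoisotopic masses, pathways drawing members from them, features
#' emitted per metabolite through electrospray adducts with Gaussian ppm
#' mass error, log-normal control intensity distributions (multiplicative
#' MS noise), a patient sample with selected pathway members perturbed by a
#' multiplicative fold change, decoy features at masses away from every
#' reference metabolite, and optional "orphan" metabolites that belong to
#' no pathway (high-intensity perturbed orphans act as confounders for
#' ranking experiments).
#'
#' @param n_metabolites Number of pathway-pool metabolites.
#' @param n_orphan_metabolites Number of metabolites outside all pathways.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Member-count range per pathway.
#' @param pathway_layout `"disjoint"` (consecutive blocks of a shuffled
#'   pool; requires enough metabolites) or `"random"` (members sampled from
#'   the pool, so pathways overlap).
#' @param n_identical_pathways Number of extra pathways duplicating the
#'   member set of the first pathway (planted redundancy for clustering).
#' @param n_features_decoy Number of decoy features per run.
#' @param n_controls Batch controls per run (default 10).
#' @param control_log_mean_range,control_log_sd_range Ranges the per-feature
#'   log-normal meanlog/sdlog parameters are drawn from (natural log scale).
#' @param spiked_pathways A list of [spike()] entries naming the perturbed
#'   pathways; empty for a null run.
#' @param spiked_orphans Number of orphan metabolites perturbed.
#' @param orphan_fold_change Fold change applied to perturbed orphans.
#' @param mass_range Metabolite neutral-mass range in Da.
#' @param min_mass_gap Minimum pairwise mass spacing in Da (default 0.02,
#'   i.e. more than twice the 5 ppm tolerance at 1000 Da, so annotations
#'   are unambiguous); set to 0 to allow collisions.
#' @param mass_error_sd_ppm SD of the Gaussian ppm error applied to the
#'   neutral mass of each emitted feature.
#' @param adduct_probabilities Per-adduct emission probabilities; every
#'   metabolite is forced to emit at least its protonated feature when no
#'   adduct fires.
#' @param rt_known_frac Fraction of metabolites with a known reference RT.
#' @param seed Seed for the reference tables; runs derive their own seeds.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_metabolites = 240L,
                            n_orphan_metabolites = 0L,
                            n_pathways = 12L,
                            pathway_size_range = c(20L, 20L),
                            pathway_layout = c("disjoint", "random"),
                            n_identical_pathways = 0L,
                            n_features_decoy = 1500L,
                            n_controls = 10L,
                            control_log_mean_range = log(c(1e4, 1e6)),
                            control_log_sd_range = c(0.2, 0.8),
                            spiked_pathways = list(),
                            spiked_orphans = 0L,
                            orphan_fold_change = 1,
                            mass_range = c(50, 1000),
                            min_mass_gap = 0.02,
                            mass_error_sd_ppm = 2,
                            adduct_probabilities = c("M+H" = 0.9,
                                                     "M+Na" = 0.3,
                                                     "M-H" = 0.7,
                                                     "M+Cl" = 0.2),
                            rt_known_frac = 0.3,
                            seed = 1L) {
  pathway_layout <- match.arg(pathway_layout)
  if (length(spiked_pathways) > 0L &&
      !all(vapply(spiked_pathways, inherits, logical(1), "msea_spike"))) {
    stop("spiked_pathways must be a list of spike() entries")
  }
  for (sp in spiked_pathways) {
    if (sp$fold_change <= 0) stop("fold_change must be > 0")
  }
  if (n_controls < 2L) stop("need at least 2 controls")
  spec <- list(n_metabolites = as.integer(n_metabolites),
               n_orphan_metabolites = as.integer(n_orphan_metabolites),
               n_pathways = as.integer(n_pathways),
               pathway_size_range = as.integer(pathway_size_range),
               pathway_layout = pathway_layout,
               n_identical_pathways = as.integer(n_identical_pathways),
               n_features_decoy = as.integer(n_features_decoy),
               n_controls = as.integer(n_controls),
               control_log_mean_range = control_log_mean_range,
               control_log_sd_range = control_log_sd_range,
               spiked_pathways = spiked_pathways,
               spiked_orphans = as.integer(spiked_orphans),
               orphan_fold_change = orphan_fold_change,
               mass_range = mass_range,
               min_mass_gap = min_mass_gap,
               mass_error_sd_ppm = mass_error_sd_ppm,
               adduct_probabilities = adduct_probabilities,
               rt_known_frac = rt_known_frac,
               seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  spec
}

#' Declare a spiked pathway
#'
#' @param pathway Pathway index (into the generated pathway table) or id.
#' @param n_members Number of leading members perturbed in the patient.
#' @param fold_change Multiplicative fold change applied to those members'
#'   patient intensities (> 0; values below 1 model decreases).
#' @return A list of class `msea_spike`.
#' @export
spike <- function(pathway = 1L, n_members = 15L, fold_change = 20) {
  structure(list(pathway = pathway, n_members = as.integer(n_members),
                 fold_change = fold_change),
            class = "msea_spike")
}

#' Generate synthetic reference tables
#'
#' Draws metabolite masses uniformly over `mass_range` with guaranteed
#' pairwise spacing `min_mass_gap`, assembles pathways per the layout,
#' and builds a biomarker panel naming, for every pathway, its first member
#' as the known biomarker of a synthetic disorder `D_<pathway id>` (spiked
#' pathways always perturb their leading members, so the panel biomarker of
#' a spiked pathway is among the perturbed metabolites).
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `metabolites`, `pathways`, `panel` in the
#'   loaders' formats. Fully deterministic given `spec$seed`.
#' @export
simulate_reference <- function(spec) {
  set.seed(spec$seed)
  n_tot <- spec$n_metabolites + spec$n_orphan_metabolites
  masses <- spaced_uniform(n_tot, spec$mass_range, spec$min_mass_gap)
  masses <- sample(masses) # decouple id order from mass order
  ids <- sprintf("MET%04d", seq_len(n_tot))
  known_rt <- stats::runif(n_tot, 0.5, 14.5)
  known_rt[stats::runif(n_tot) > spec$rt_known_frac] <- NA_real_
  metabolites <- data.frame(metabolite_id = ids,
                            name = sprintf("synthetic metabolite %04d",
                                           seq_len(n_tot)),
                            monoisotopic_mass = masses,
                            source = "HMDB",
                            known_rt = known_rt,
                            stringsAsFactors = FALSE)
  metabolites <- metabolites[order(metabolites$monoisotopic_mass), ]
  rownames(metabolites) <- NULL

  pool <- ids[seq_len(spec$n_metabolites)]
  orphans <- if (spec$n_orphan_metabolites > 0L) {
    ids[(spec$n_metabolites + 1L):n_tot]
  } else character(0)

  size_choices <- seq.int(spec$pathway_size_range[1L],
                          spec$pathway_size_range[2L])
  sizes <- size_choices[sample.int(length(size_choices), spec$n_pathways,
                                   replace = TRUE)]
  members <- vector("list", spec$n_pathways)
  if (spec$pathway_layout == "disjoint") {
    if (sum(sizes) > length(pool)) {
      stop("disjoint layout needs at least ", sum(sizes), " metabolites")
    }
    shuffled <- sample(pool)
    offset <- cumsum(c(0L, sizes))
    for (i in seq_len(spec$n_pathways)) {
      members[[i]] <- shuffled[(offset[i] + 1L):offset[i + 1L]]
    }
  } else {
    for (i in seq_len(spec$n_pathways)) {
      members[[i]] <- sample(pool, sizes[i])
    }
  }
  if (spec$n_identical_pathways > 0L) {
    members <- c(members, rep(members[1L], spec$n_identical_pathways))
  }
  n_pw <- length(members)
  pathways <- data.frame(
    pathway_id = sprintf("PW%04d", seq_len(n_pw)),
    name = sprintf("synthetic pathway %04d", seq_len(n_pw)),
    source = "SMPDB",
    category = sample(c("Metabolic", "Disease", "Drug"), n_pw,
                      replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    stringsAsFactors = FALSE)
  pathways$members <- members
  pathways <- pathway_table(pathways)

  panel <- data.frame(
    disorder = sprintf("D_%s", pathways$pathway_id),
    biomarker_name = vapply(members, `[`, character(1), 1L),
    metabolite_id = vapply(members, `[`, character(1), 1L),
    source = "HMDB", stringsAsFactors = FALSE)

  list(metabolites = metabolites, pathways = pathways, panel = panel,
       orphans = orphans)
}

# n sorted draws over `range` with pairwise gaps of at least `gap`
spaced_uniform <- function(n, range, gap) {
  span <- diff(range) - (n - 1) * gap
  if (span <= 0) stop("mass range too narrow for the requested spacing")
  range[1L] + sort(stats::runif(n)) * span + (seq_len(n) - 1L) * gap
}

#' Simulate one patient-versus-controls run
#'
#' Emits features per metabolite through the adduct model with Gaussian ppm
#' error on the neutral mass (`mz = m * (1 + e) + shift`, so the observed
#' neutral-mass ppm error equals the simulated error exactly), draws
#' control intensities from per-feature log-normal distributions, applies
#' the spiked fold changes multiplicatively to the patient draw, and adds
#' decoy features whose candidate neutral masses under every mode adduct
#' stay at least 4x the annotation tolerance away from all reference
#' metabolites.
#'
#' @param spec A [simulation_spec()].
#' @param refs Output of [simulate_reference()] for the same spec.
#' @param seed Run seed (default `spec$seed + 1`); keep distinct from the
#'   reference seed when generating cohorts.
#' @return A list with elements `run` (a [sample_run()]) and `truth`, a
#'   data.frame labelling every feature with the generating metabolite
#'   (`NA` for decoys), the adduct used and whether it was truly perturbed.
#' @export
simulate_run <- function(spec, refs, seed = spec$seed + 1L) {
  set.seed(seed)
  mets <- refs$metabolites
  ad <- adducts()

  # perturbation map: metabolite id -> fold change
  fold <- structure(rep(1, nrow(mets)), names = mets$metabolite_id)
  disorder <- NA_character_
  for (sp in spec$spiked_pathways) {
    pw_id <- if (is.numeric(sp$pathway)) {
      refs$pathways$pathway_id[sp$pathway]
    } else sp$pathway
    i <- match(pw_id, refs$pathways$pathway_id)
    if (is.na(i)) stop("unknown spiked pathway: ", pw_id)
    mem <- refs$pathways$members[[i]]
    if (sp$n_members > length(mem)) {
      stop("cannot perturb ", sp$n_members, " members of ", pw_id,
           " (has ", length(mem), ")")
    }
    fold[mem[seq_len(sp$n_members)]] <- sp$fold_change
    if (is.na(disorder)) disorder <- sprintf("D_%s", pw_id)
  }
  if (spec$spiked_orphans > 0L) {
    if (spec$spiked_orphans > length(refs$orphans)) {
      stop("not enough orphan metabolites to perturb")
    }
    fold[refs$orphans[seq_len(spec$spiked_orphans)]] <-
      spec$orphan_fold_change
  }

  # adduct emission per metabolite; force M+H when nothing fires
  p_ad <- spec$adduct_probabilities[ad$label]
  emit <- matrix(stats::runif(nrow(mets) * nrow(ad)),
                 nrow = nrow(mets)) < rep(p_ad, each = nrow(mets))
  none <- rowSums(emit) == 0L
  emit[none, 1L] <- TRUE

  met_row <- rep(seq_len(nrow(mets)), times = nrow(ad))[as.vector(emit)]
  ad_row <- rep(seq_len(nrow(ad)), each = nrow(mets))[as.vector(emit)]
  ord <- order(met_row, ad_row)
  met_row <- met_row[ord]; ad_row <- ad_row[ord]

  e <- stats::rnorm(length(met_row), 0, spec$mass_error_sd_ppm * 1e-6)
  neutral_obs <- mets$monoisotopic_mass[met_row] * (1 + e)
  mz <- neutral_obs + ad$mass_shift[ad_row]
  ion_mode <- ad$ion_mode[ad_row]
  rt <- ifelse(is.na(mets$known_rt[met_row]),
               stats::runif(length(met_row), 0.5, 14.5),
               mets$known_rt[met_row])
  gen_met <- mets$metabolite_id[met_row]
  gen_adduct <- ad$label[ad_row]

  # decoy features: far from every reference metabolite under both
  # mode-compatible adduct readings
  n_decoy <- spec$n_features_decoy
  if (n_decoy > 0L) {
    guard <- 20e-6 # 4x the 5 ppm annotation tolerance
    dec_mass <- numeric(0); dec_mode <- character(0)
    dec_adduct <- character(0)
    while (length(dec_mass) < n_decoy) {
      m <- stats::runif(2L * n_decoy, spec$mass_range[1L],
                        spec$mass_range[2L])
      a_i <- sample(seq_len(nrow(ad)), length(m), replace = TRUE)
      ok <- rep(TRUE, length(m))
      for (j in seq_len(nrow(ad))) {
        same_mode <- ad$ion_mode[a_i] == ad$ion_mode[j]
        cand <- m + ad$mass_shift[a_i] - ad$mass_shift[j]
        near <- nearest_ppm(cand, mets$monoisotopic_mass) < guard * 1e6
        ok <- ok & !(same_mode & near)
      }
      dec_mass <- c(dec_mass, m[ok])
      dec_mode <- c(dec_mode, ad$ion_mode[a_i[ok]])
      dec_adduct <- c(dec_adduct, ad$label[a_i[ok]])
    }
    keep <- seq_len(n_decoy)
    dec_mass <- dec_mass[keep]; dec_mode <- dec_mode[keep]
    dec_adduct <- dec_adduct[keep]
    dec_mz <- dec_mass + ad$mass_shift[match(dec_adduct, ad$label)]
    mz <- c(mz, dec_mz)
    ion_mode <- c(ion_mode, dec_mode)
    rt <- c(rt, stats::runif(n_decoy, 0.5, 14.5))
    gen_met <- c(gen_met, rep(NA_character_, n_decoy))
    gen_adduct <- c(gen_adduct, dec_adduct)
  }

  n_feat <- length(mz)
  meanlog <- stats::runif(n_feat, spec$control_log_mean_range[1L],
                          spec$control_log_mean_range[2L])
  sdlog <- stats::runif(n_feat, spec$control_log_sd_range[1L],
                        spec$control_log_sd_range[2L])
  controls <- matrix(stats::rlnorm(n_feat * spec$n_controls,
                                   meanlog, sdlog),
                     nrow = n_feat, ncol = spec$n_controls)
  feat_fold <- ifelse(is.na(gen_met), 1, fold[gen_met])
  patient <- stats::rlnorm(n_feat, meanlog, sdlog) * feat_fold

  feature_id <- character(n_feat)
  pos <- ion_mode == "positive"
  feature_id[pos] <- sprintf("ESIpos_%d", seq_len(sum(pos)))
  feature_id[!pos] <- sprintf("ESIneg_%d", seq_len(sum(!pos)))

  features <- data.frame(feature_id = feature_id, mz = mz, rt = rt,
                         ion_mode = ion_mode,
                         patient_intensity = patient,
                         stringsAsFactors = FALSE)
  run <- sample_run(features, controls,
                    sample_id = sprintf("SIM_%d", seed),
                    disorder = disorder, batch_id = "B1")
  truth <- data.frame(feature_id = feature_id, metabolite_id = gen_met,
                      adduct = gen_adduct,
                      perturbed = feat_fold != 1,
                      stringsAsFactors = FALSE)
  list(run = run, truth = truth)
}

# distance in ppm from each value to the nearest reference mass
nearest_ppm <- function(x, masses) {
  i <- findInterval(x, masses)
  lo <- masses[pmax(i, 1L)]
  hi <- masses[pmin(i + 1L, length(masses))]
  1e6 * pmin(abs(x - lo), abs(x - hi)) / x
}
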