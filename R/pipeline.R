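#' Per-breed dataset sizes of the Sicilian goat survey cohort
#'
#' The published per-breed animal counts of a 15-breed Italian goat
#' SNP-chip survey centered on the Capra Comune di Sicilia (CCS):
#' the initial genotyped set, the set remaining after quality control and
#' exclusion of direct relatives (used for ROH and selection-signature
#' analyses), and the set after capping every breed at 35 animals (used
#' for population-structure analyses).
#'
#' @return A tibble: `breed`, `initial_n`, `post_qc_n`, `capped_n`.
#' @export
goat_survey_counts <- function() {
  tibble::tribble(
    ~breed, ~initial_n, ~post_qc_n, ~capped_n,
    "ARG", 48, 46, 35,
    "ASP", 24, 24, 24,
    "BIA", 24, 24, 24,
    "CAM", 30, 30, 30,
    "CCS", 78, 72, 35,
    "DDS", 32, 25, 25,
    "GAR", 40, 37, 35,
    "GCI", 43, 40, 35,
    "GIR", 59, 56, 35,
    "JON", 16, 15, 15,
    "MAL", 16, 16, 16,
    "MES", 24, 23, 23,
    "MON", 24, 23, 23,
    "NIC", 24, 24, 24,
    "SAR", 33, 32, 32)
}

#' Cohort accounting for a multi-breed survey design
#'
#' Summarizes the per-breed bookkeeping of a characterization study that
#' compares one focal breed against the rest: the number of comparison
#' animals (initial sizes summed over the non-focal breeds), the post-QC
#' total, and the total after applying a per-breed cap.
#'
#' @param counts Tibble with columns `breed`, `initial_n`, `post_qc_n`
#'   (default [goat_survey_counts()]).
#' @param focal_breed Breed excluded from the comparison count.
#' @param cap Per-breed maximum applied to the post-QC sizes.
#' @return A one-row tibble: `comparison_n`, `post_qc_total`,
#'   `capped_total`.
#' @export
cohort_accounting <- function(counts = goat_survey_counts(),
                              focal_breed = "CCS", cap = 35) {
  counts <- tibble::as_tibble(counts)
  tibble::tibble(
    comparison_n = sum(counts$initial_n[counts$breed != focal_breed]),
    post_qc_total = sum(counts$post_qc_n),
    capped_total = sum(pmin(counts$post_qc_n, cap)))
}

#' Run the full genomic characterization pipeline
#'
#' Orchestrates the standard stages on a genotype cohort: quality control,
#' exclusion of direct relatives, then two branches mirroring the usual
#' survey design: the post-QC, relative-free set feeds ROH detection,
#' F_ROH and (optionally) selection-signature scans, while a per-breed
#' capped copy feeds diversity, Reynolds distances, the bootstrap NJ breed
#' tree and MDS of individual IBS distances. A manifest logs the animal and
#' SNP counts at every stage; counts are conserved
#' (animals in = animals out + removed) at each step.
#'
#' @param gm A [genotypes] object with breed metadata.
#' @param qc Named list of [apply_qc()] arguments (optional overrides).
#' @param relatedness_threshold Kinship-proxy threshold for
#'   [exclude_related()].
#' @param max_per_breed Cap for the population-structure branch.
#' @param roh A [roh_params()] list.
#' @param bootstrap_B Bootstrap replicates for the breed tree.
#' @param mds_k MDS dimensions.
#' @param contrasts Optional named list of two-group contrasts, each a list
#'   with elements `trait` (metadata column) and optionally `fraction`
#'   (top-quantile retention, default 0.01): runs FST and delta H-score
#'   scans of "present" vs "absent" animals.
#' @param seed Integer seed propagated to every stochastic step.
#' @return A list: `manifest` (stage-by-stage counts), `qc_report`,
#'   `removed_related`, `diversity`, `reynolds`, `tree`, `mds`,
#'   `roh_segments`, `froh`, `scans`, plus the two working cohorts
#'   (`cohort_roh`, `cohort_structure`).
#' @export
run_pipeline <- function(gm, qc = list(), relatedness_threshold = 0.25,
                         max_per_breed = 35, roh = roh_params(),
                         bootstrap_B = 100, mds_k = 3, contrasts = NULL,
                         seed = 1) {
  manifest <- list()
  log_stage <- function(stage, gm_after, n_removed_samples) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, n_samples = nrow(gm_after$calls),
      n_snps = ncol(gm_after$calls), n_samples_removed = n_removed_samples)
  }
  log_stage("input", gm, 0L)

  qc_res <- do.call(apply_qc, c(list(gm), qc))
  log_stage("qc", qc_res$genotypes,
            nrow(gm$calls) - nrow(qc_res$genotypes$calls))

  rel <- exclude_related(qc_res$genotypes, relatedness_threshold)
  log_stage("exclude_related", rel$genotypes, length(rel$removed))
  cohort_roh <- rel$genotypes

  # branch B: ROH / inbreeding / selection on the uncapped post-QC set
  segments <- detect_roh(cohort_roh, roh)
  froh <- compute_froh(segments, cohort_roh)
  scans <- list()
  if (!is.null(contrasts)) {
    for (nm in names(contrasts)) {
      ct <- contrasts[[nm]]
      trait <- cohort_roh$samples[[ct$trait]]
      grp_a <- cohort_roh$samples$sample_id[trait == "present"]
      grp_b <- cohort_roh$samples$sample_id[trait == "absent"]
      frac <- ct$fraction %||% 0.01
      fst_scan <- select_top(snp_fst(cohort_roh, grp_a, grp_b), frac)
      dh <- delta_h(roh_incidence(segments, cohort_roh, grp_a),
                    roh_incidence(segments, cohort_roh, grp_b))
      dh_scan <- select_top(dh, frac)
      scans[[nm]] <- list(fst = fst_scan, delta_h = dh_scan,
                          n_present = length(grp_a),
                          n_absent = length(grp_b))
    }
  }

  # branch A: population structure on the capped set
  cohort_structure <- cap_breed_size(cohort_roh, max_per_breed, seed = seed)
  log_stage("breed_cap", cohort_structure,
            nrow(cohort_roh$calls) - nrow(cohort_structure$calls))
  diversity <- breed_diversity(cohort_structure)
  n_breeds <- length(unique(cohort_structure$samples$breed))
  if (n_breeds >= 3) {
    reynolds <- reynolds_matrix(cohort_structure)
    tree <- bootstrap_breed_tree(cohort_structure, B = bootstrap_B,
                                 seed = seed)
  } else {
    warning("fewer than 3 breeds: skipping distance-tree branch",
            call. = FALSE)
    reynolds <- NULL
    tree <- NULL
  }
  mds <- classical_mds(ibs_distance(cohort_structure), k = mds_k)

  list(manifest = dplyr::bind_rows(manifest), qc_report = qc_res$report,
       removed_related = rel$removed, diversity = diversity,
       reynolds = reynolds, tree = tree, mds = mds,
       roh_segments = segments, froh = froh, scans = scans,
       cohort_roh = cohort_roh, cohort_structure = cohort_structure)
}

#' Tabulate binary morphological traits by sex
#'
#' For each trait column and status, the percentage of animals with that
#' status among animals of known status, by sex and overall, rounded to
#' whole percent (the usual presentation of qualitative trait surveys).
#'
#' @param samples Sample metadata tibble with `sex` and trait columns coded
#'   "present"/"absent"/"unknown".
#' @param traits Trait column names; defaults to those of `horns`,
#'   `wattles`, `ears` that are present.
#' @return A tibble: `trait`, `status`, `group` (male/female/total),
#'   `n`, `percent`.
#' @export
tabulate_traits <- function(samples,
                            traits = intersect(c("horns", "wattles", "ears"),
                                               names(samples))) {
  samples <- tibble::as_tibble(samples)
  if (!nrow(samples)) stop("metadata is empty", call. = FALSE)
  out <- list()
  groups <- list(male = samples$sex == "male",
                 female = samples$sex == "female",
                 total = rep(TRUE, nrow(samples)))
  for (tr in traits) {
    v <- samples[[tr]]
    for (gname in names(groups)) {
      vv <- v[groups[[gname]]]
      known <- vv[!is.na(vv) & vv != "unknown"]
      for (status in c("present", "absent")) {
        n_st <- sum(known == status)
        pct <- if (length(known)) round(100 * n_st / length(known)) else NA
        out[[length(out) + 1]] <- tibble::tibble(
          trait = tr, status = status, group = gname, n = n_st,
          percent = pct)
      }
    }
  }
  dplyr::bind_rows(out)
}
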